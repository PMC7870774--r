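# Global similarity diagnostics: pairwise Spearman correlation of normalized
# counts and per-model variation coefficients of the model-vs-reference
# correlation coefficients.

#' Pairwise Spearman correlation matrix of samples
#'
#' Spearman rank correlation (average ranks for ties) between every pair of
#' sample columns of a normalized count matrix. Constant columns have no
#' rank variance, so their off-diagonal correlations are undefined and
#' reported as `NA`; the diagonal is set to exactly 1 regardless.
#'
#' @param m normalized count matrix, genes x samples (>= 2 samples).
#' @return symmetric correlation matrix with unit diagonal and a
#'   `"method"` attribute of `"spearman"`.
#' @export
spearman_matrix <- function(m) {
  if (ncol(m) < 2L) stop("need at least 2 samples")
  cc <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(cc) <- 1
  attr(cc, "method") <- "spearman"
  cc
}

#' Variation coefficient of a model's reference correlations
#'
#' For one cell model, collects the Spearman correlation coefficients
#' between each of the model's replicates and every control (reference)
#' sample, and returns `100 * sd / mean` of those coefficients (sample
#' standard deviation, n - 1 denominator). A small value means the model's
#' replicates agree with the reference equally well -- low inter-replicate
#' variation. With `basis = "intra"` the coefficients are instead the
#' pairwise correlations among the model's own replicates.
#'
#' @param corr correlation matrix from [spearman_matrix()] covering the
#'   model and control samples.
#' @param samples sample table.
#' @param model_label the model to score (matched against `model_label`
#'   of the test-group rows).
#' @param basis `"cross"` (model vs control; default) or `"intra"`
#'   (within-model pairs).
#' @return the variation coefficient (percent), or `NA` when the model has
#'   fewer than 2 replicates.
#' @export
variation_coefficient <- function(corr, samples, model_label,
                                  basis = c("cross", "intra")) {
  basis <- match.arg(basis)
  mod <- samples$sample_id[samples$group == "test" &
                             samples$model_label == model_label]
  mod <- intersect(mod, rownames(corr))
  if (length(mod) < 2L) return(NA_real_)
  if (basis == "cross") {
    ctl <- intersect(samples$sample_id[samples$group == "control"], rownames(corr))
    vals <- as.vector(corr[mod, ctl, drop = FALSE])
  } else {
    sub <- corr[mod, mod, drop = FALSE]
    vals <- sub[upper.tri(sub)]
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L) return(NA_real_)
  100 * stats::sd(vals) / mean(vals)
}

#' Write a correlation matrix as TSV
#' @param corr correlation matrix.
#' @param path output path.
#' @export
write_correlation <- function(corr, path) {
  df <- data.frame(sample_id = rownames(corr), corr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
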