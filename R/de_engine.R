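# Differential-expression engine: median-of-ratios size factors, per-gene
# negative-binomial dispersion (method of moments within groups, shrunk toward
# a fitted mean-dispersion trend), a per-gene NB Wald test via Fisher scoring,
# and BH adjustment. Deliberately a simplified engine: no Cox-Reid adjustment,
# no outlier refitting, no independent filtering beyond the baseMean threshold
# applied downstream; these simplifications are documented in the vignette.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with strictly positive counts in every sample, so the geometric mean
#' is positive) of the ratio of the sample's count to the gene's geometric
#' mean across samples.
#'
#' @param m numeric count matrix, genes x samples (non-negative, possibly
#'   fractional expected counts).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(m) {
  validate_counts_matrix(m, "count")
  if (ncol(m) < 2L) stop("need at least 2 samples to estimate size factors")
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    stop("no gene has positive counts in all samples; median-of-ratios is ",
         "undefined (consider filtering samples or supplying size factors)")
  }
  sub <- m[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub / geo, 2L, stats::median)
}

#' Divide each sample's counts by its size factor
#' @param m count matrix, genes x samples.
#' @param sf size factors named by sample (order must match columns when
#'   unnamed).
#' @return normalized count matrix of the same shape.
#' @export
normalize_counts <- function(m, sf) {
  if (!is.null(names(sf))) sf <- sf[colnames(m)]
  if (anyNA(sf) || any(sf <= 0)) stop("size factors must be positive for every sample")
  sweep(m, 2L, sf, "/")
}

rowVars_ <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  (rowSums(x * x) - n * mu * mu) / (n - 1)
}

#' Estimate per-gene NB dispersions
#'
#' Gene-wise dispersions are estimated by the method of moments on normalized
#' counts within each group (pooled across the two groups, weighted by
#' residual degrees of freedom), then shrunk in log space toward a
#' mean-dispersion trend `alpha(mu) = a0 + a1/mu` fitted to binned medians of
#' the gene-wise estimates. Genes with zero counts everywhere get `NA` and
#' are excluded from testing.
#'
#' @param m count matrix, genes x samples.
#' @param sf size factors.
#' @param group character/factor vector over columns with two levels
#'   (`control`, `test`), each represented by >= 2 samples.
#' @param prior_df weight (pseudo-degrees-of-freedom) of the trend in the
#'   log-space shrinkage; gene-wise weight is the residual df of the design.
#' @param min_disp floor for dispersions.
#' @param n_bins number of mean-quantile bins for the trend fit.
#' @return named numeric vector of dispersions (NA for untestable genes),
#'   with the trend coefficients in attribute `"trend"` and the raw
#'   gene-wise estimates in attribute `"genewise"`.
#' @export
estimate_dispersions <- function(m, sf, group, prior_df = 10,
                                 min_disp = 1e-8, n_bins = 20L) {
  x <- normalize_counts(m, sf)
  group <- as.character(group)
  idx <- split(seq_along(group), group)
  if (length(idx) != 2L || any(lengths(idx) < 2L)) {
    stop("need exactly two groups with >= 2 samples each")
  }
  if (!is.null(names(sf))) sf <- sf[colnames(m)]
  num <- rep(0, nrow(m)); den <- 0
  for (j in idx) {
    xg <- x[, j, drop = FALSE]
    mu_g <- rowMeans(xg)
    v_g <- rowVars_(xg)
    xi <- mean(1 / sf[j])           # Poisson part of Var(K/s) = mu/s + a*mu^2
    a_g <- ifelse(mu_g > 0, (v_g - mu_g * xi) / (mu_g * mu_g), NA_real_)
    w <- length(j) - 1L
    num <- num + ifelse(is.na(a_g), 0, w * a_g)
    den <- den + w
  }
  alpha_gw <- num / den
  mu <- rowMeans(x)
  alpha_gw[mu == 0] <- NA_real_

  ok <- !is.na(alpha_gw) & mu > 0
  a0 <- min_disp; a1 <- 0
  if (sum(ok) >= 10L) {
    lmu <- log(mu[ok])
    bins <- cut(lmu, breaks = unique(stats::quantile(lmu, probs = seq(0, 1, length.out = n_bins + 1L))),
                include.lowest = TRUE)
    med_a <- tapply(alpha_gw[ok], bins, stats::median)
    med_mu <- tapply(mu[ok], bins, stats::median)
    keep <- !is.na(med_a) & !is.na(med_mu)
    if (sum(keep) >= 2L) {
      fit <- stats::lm(pmax(med_a[keep], min_disp) ~ I(1 / med_mu[keep]))
      a0 <- max(unname(stats::coef(fit)[1L]), min_disp)
      a1 <- max(unname(stats::coef(fit)[2L]), 0)
    }
  }
  alpha_tr <- pmax(a0 + a1 / mu, min_disp)
  d <- den
  alpha <- exp((d * log(pmax(alpha_gw, min_disp)) + prior_df * log(alpha_tr)) /
                 (d + prior_df))
  alpha[!ok] <- NA_real_
  names(alpha) <- rownames(m)
  attr(alpha, "trend") <- c(asymptote = a0, scale = a1)
  attr(alpha, "genewise") <- stats::setNames(alpha_gw, rownames(m))
  alpha
}

# Per-group NB mean on the normalized scale by Fisher scoring, vectorized
# over genes. Solves sum_j (y_gj - s_j m_g) / (1 + alpha_g s_j m_g) = 0 for
# eta_g = log m_g. Returns eta and the Fisher information I = sum mu/(1+a*mu).
nb_group_fit <- function(y, s, alpha) {
  tot <- rowSums(y)
  eta <- log(tot / sum(s))          # -Inf when the group total is zero
  zero <- tot == 0
  act <- which(!zero & !is.na(alpha))
  if (length(act) > 0L) {
    for (it in 1:100) {
      mu <- exp(eta[act]) %o% s
      w <- 1 + alpha[act] * mu
      U <- rowSums((y[act, , drop = FALSE] - mu) / w)
      I <- rowSums(mu / w)
      step <- U / I
      step <- pmax(pmin(step, 5), -5)
      eta[act] <- eta[act] + step
      if (max(abs(step)) < 1e-12) break
    }
  }
  mu <- exp(eta) %o% s
  info <- rowSums(mu / (1 + alpha * mu))
  info[zero] <- 0
  list(eta = eta, info = info, zero = zero)
}

#' Per-gene negative-binomial Wald test (test vs control)
#'
#' Fits group means on the normalized scale by Fisher scoring with the
#' supplied per-gene dispersions, and tests the log fold change
#' (test over control) with a Wald z statistic; the variance of the log
#' fold change is the sum of the two groups' inverse Fisher informations.
#' When one group has all-zero counts, the test statistic uses a half-count
#' floor in that group, and the reported `log2FoldChange` falls back to
#' pseudo-counted (+0.5) normalized group means so volcano coordinates stay
#' finite. Genes with `NA` dispersion (all-zero counts) are excluded:
#' their p-value and padj are `NA` and they do not enter the BH ranking.
#'
#' @param m count matrix, genes x samples.
#' @param sf size factors.
#' @param group vector over columns with levels `control` and `test`.
#' @param disp per-gene dispersions from [estimate_dispersions()].
#' @return `data.frame` with `gene_id`, `baseMean` (mean of normalized
#'   counts over all samples), `log2FoldChange`, `pvalue`, `padj`.
#' @export
wald_test <- function(m, sf, group, disp) {
  group <- as.character(group)
  if (!setequal(unique(group), c("control", "test"))) {
    stop("group must contain exactly the levels 'control' and 'test'")
  }
  if (!is.null(names(sf))) sf <- sf[colnames(m)]
  if (!is.null(names(disp))) disp <- disp[rownames(m)]
  x <- normalize_counts(m, sf)
  baseMean <- rowMeans(x)

  jc <- group == "control"; jt <- group == "test"
  fc <- nb_group_fit(m[, jc, drop = FALSE], sf[jc], disp)
  ft <- nb_group_fit(m[, jt, drop = FALSE], sf[jt], disp)

  # half-count floor for a zero group: as if 0.5 reads were seen in total
  floor_fit <- function(f, s, alpha) {
    z <- which(f$zero & !is.na(alpha))
    if (length(z) > 0L) {
      f$eta[z] <- log(0.5 / sum(s))
      mu <- exp(f$eta[z]) %o% s
      f$info[z] <- rowSums(mu / (1 + alpha[z] * mu))
    }
    f
  }
  fc2 <- floor_fit(fc, sf[jc], disp)
  ft2 <- floor_fit(ft, sf[jt], disp)

  b <- ft2$eta - fc2$eta
  se <- sqrt(1 / fc2$info + 1 / ft2$info)
  z <- b / se
  pvalue <- 2 * stats::pnorm(-abs(z))

  both_zero <- fc$zero & ft$zero
  excluded <- is.na(disp) | both_zero
  pvalue[excluded] <- NA_real_

  lfc <- (ft$eta - fc$eta) / log(2)
  any_zero <- fc$zero | ft$zero
  if (any(any_zero)) {
    mt <- rowMeans(x[, jt, drop = FALSE]); mc <- rowMeans(x[, jc, drop = FALSE])
    lfc[any_zero] <- log2((mt[any_zero] + 0.5) / (mc[any_zero] + 0.5))
  }
  lfc[excluded] <- NA_real_

  data.frame(
    gene_id = rownames(m),
    baseMean = baseMean,
    log2FoldChange = lfc,
    pvalue = pvalue,
    padj = adjust_bh(pvalue),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure (via [stats::p.adjust()]): the adjusted value
#' of the i-th smallest p is `min_{j >= i} (m * p_(j) / j)` capped at 1,
#' with m the number of non-missing p-values. `NA` entries stay `NA` and do
#' not count toward m.
#'
#' @param pvalues numeric vector in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Run the full DE path for one two-group comparison
#'
#' Size factors are estimated jointly on the comparison's samples
#' (control plus test), counts are normalized, dispersions estimated and
#' the Wald test applied. Deterministic: identical inputs give identical
#' output tables.
#'
#' @param m count matrix covering at least the comparison's samples.
#' @param samples sample table restricted to (or covering) the comparison.
#' @param sample_ids optional explicit sample subset to use.
#' @param prior_df passed to [estimate_dispersions()].
#' @return a `DEResult` data.frame as from [wald_test()].
#' @export
run_de <- function(m, samples, sample_ids = NULL, prior_df = 10) {
  if (is.null(sample_ids)) sample_ids <- intersect(colnames(m), samples$sample_id)
  miss <- setdiff(sample_ids, colnames(m))
  if (length(miss) > 0L) stop("samples absent from count matrix: ",
                              paste(miss, collapse = ", "))
  mm <- m[, sample_ids, drop = FALSE]
  grp <- samples$group[match(sample_ids, samples$sample_id)]
  sf <- estimate_size_factors(mm)
  disp <- estimate_dispersions(mm, sf, grp, prior_df = prior_df)
  wald_test(mm, sf, grp, disp)
}

#' Write a DEResult table as TSV
#' @param res DEResult data.frame.
#' @param path output path.
#' @export
write_de_result <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
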