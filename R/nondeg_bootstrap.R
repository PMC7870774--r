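# Non-DEG / DEG extraction, UpSet-style set overlaps, and bootstrap selection
# of the replicates most similar to the reference group.

#' Extract non-differentially-expressed genes
#'
#' Non-DEGs are genes with adjusted p strictly above `alpha` AND baseMean
#' strictly above `basemean_min` (both inequalities strict, so a gene exactly
#' at a boundary belongs to neither the DEG nor the non-DEG set). Genes with
#' undefined padj are excluded. The non-DEG count is the pipeline's
#' similarity metric: more non-DEGs, more reference-like.
#'
#' @param r DEResult data.frame with `padj` and `baseMean`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param basemean_min baseMean threshold (default 10).
#' @return character vector of gene ids.
#' @export
extract_non_degs <- function(r, alpha = 0.05, basemean_min = 10) {
  keep <- !is.na(r$padj) & r$padj > alpha & r$baseMean > basemean_min
  r$gene_id[keep]
}

#' Extract differentially expressed genes with direction flags
#'
#' DEGs are genes with padj strictly below `alpha` and baseMean strictly
#' above `count_min`. Membership does not require a fold-change threshold;
#' `lfc_flag` only annotates direction: `up` when log2FC > lfc_flag, `down`
#' when log2FC < -lfc_flag, otherwise `small_effect` (significant but
#' below the fold-change annotation line).
#'
#' @param r DEResult data.frame.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param count_min baseMean threshold (default 10).
#' @param lfc_flag |log2FC| annotation threshold (default 1).
#' @return data.frame with `gene_id`, `log2FoldChange`, `direction`.
#' @export
extract_degs <- function(r, alpha = 0.05, count_min = 10, lfc_flag = 1) {
  keep <- !is.na(r$padj) & r$padj < alpha & r$baseMean > count_min
  sub <- r[keep, , drop = FALSE]
  direction <- ifelse(sub$log2FoldChange > lfc_flag, "up",
                      ifelse(sub$log2FoldChange < -lfc_flag, "down", "small_effect"))
  data.frame(gene_id = sub$gene_id,
             log2FoldChange = sub$log2FoldChange,
             direction = direction,
             stringsAsFactors = FALSE)
}

#' Exclusive-intersection (UpSet) overlap table
#'
#' Each gene in the union of the input sets is counted in exactly one
#' combination cell -- the cell of the sets it belongs to -- so the cell
#' counts sum to the size of the union. Cells are sorted by decreasing
#' count and truncated to `top_n`.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @param top_n number of cells to keep (default 50).
#' @return data.frame with `combination` (set names joined by "&"),
#'   `degree` (number of sets in the cell) and `count`; the union size is
#'   in attribute `"union_size"`.
#' @export
overlap_sets <- function(sets, top_n = 50L) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  df <- data.frame(combination = names(tab),
                   degree = vapply(strsplit(names(tab), "&", fixed = TRUE),
                                   length, integer(1L)),
                   count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$combination), , drop = FALSE]
  rownames(df) <- NULL
  out <- utils::head(df, top_n)
  attr(out, "union_size") <- length(universe)
  out
}

#' Bootstrap-select the k test replicates most similar to the reference
#'
#' Runs the full DE path (size factors, dispersions, Wald test -- all
#' re-estimated per combination, since each combination is a fresh
#' comparison) for every k-subset of the test replicates against the full
#' control set, and keeps the combination with the most non-DEGs. The DEG
#' count is reported alongside for each combination. Ties are broken by the
#' lexicographically smallest sorted replicate-id tuple, so the result does
#' not depend on the order of `test_replicates`.
#'
#' @param m count matrix covering control and test samples.
#' @param control_ids sample ids of the (fixed) reference group.
#' @param test_replicates sample ids of the candidate test replicates.
#' @param k number of replicates to select (default 3).
#' @param alpha,basemean_min non-DEG/DEG thresholds (defaults 0.05 / 10).
#' @param allow_fewer when `TRUE` and only `k - 1` replicates are available,
#'   proceed with all of them (the study's microtissue exception) instead of
#'   failing.
#' @param prior_df passed to the DE path.
#' @return list with `all_combinations` (data.frame: `combination`,
#'   `n_non_deg`, `n_deg`) and `selected` (list: `replicates`, `n_non_deg`,
#'   `n_deg`).
#' @export
bootstrap_select_replicates <- function(m, control_ids, test_replicates, k = 3L,
                                        alpha = 0.05, basemean_min = 10,
                                        allow_fewer = FALSE, prior_df = 10) {
  test_replicates <- as.character(test_replicates)
  if (length(test_replicates) < k) {
    if (allow_fewer && length(test_replicates) == k - 1L && length(test_replicates) >= 2L) {
      k <- length(test_replicates)
    } else {
      stop("only ", length(test_replicates), " test replicates for k = ", k,
           " (set allow_fewer = TRUE to proceed with k - 1)")
    }
  }
  combos <- utils::combn(sort(test_replicates), k, simplify = FALSE)
  res <- lapply(combos, function(cmb) {
    ids <- c(control_ids, cmb)
    grp <- c(rep("control", length(control_ids)), rep("test", length(cmb)))
    st <- sample_table(ids, grp)
    de <- run_de(m, st, sample_ids = ids, prior_df = prior_df)
    c(n_non_deg = length(extract_non_degs(de, alpha, basemean_min)),
      n_deg = nrow(extract_degs(de, alpha, basemean_min)))
  })
  tab <- data.frame(
    combination = vapply(combos, paste, character(1L), collapse = ","),
    n_non_deg = vapply(res, `[[`, numeric(1L), "n_non_deg"),
    n_deg = vapply(res, `[[`, numeric(1L), "n_deg"),
    stringsAsFactors = FALSE
  )
  # max non-DEG count; ties -> lexicographically smallest sorted id tuple
  best <- which(tab$n_non_deg == max(tab$n_non_deg))
  best <- best[order(tab$combination[best])][1L]
  list(
    all_combinations = tab,
    selected = list(replicates = combos[[best]],
                    n_non_deg = tab$n_non_deg[best],
                    n_deg = tab$n_deg[best])
  )
}
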