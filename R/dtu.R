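# Differential-transcript-usage cascade: three isoform filters applied in a
# fixed order (low expression on counts -> similar usage on percentages ->
# detection on percentages), synchronization of the count and percentage
# views, single-isoform pruning, one-way ANOVA on usage percentages, and the
# dominant-isoform DTU call that refines the non-DEG set.

group_index <- function(iso, samples) {
  grp <- samples$group[match(colnames(iso$counts), samples$sample_id)]
  if (anyNA(grp)) {
    stop("isoform table contains sample(s) missing from the sample table: ",
         paste(colnames(iso$counts)[is.na(grp)], collapse = ", "))
  }
  list(control = which(grp == "control"), test = which(grp == "test"))
}

filter_step <- function(name, removed, reason) {
  data.frame(step = rep_len(name, length(removed)),
             isoform_id = removed,
             reason = rep_len(reason, length(removed)),
             stringsAsFactors = FALSE)
}

#' Low-expression filter (counts view)
#'
#' Removes an isoform when its group-mean counts-per-million is strictly
#' below `cpm_floor` in EITHER group: an isoform expressed at less than one
#' in a million reads in one dataset is below the noise floor at this
#' sequencing depth and cannot be compared. CPM is computed on the supplied
#' (normalized) counts against per-sample library sizes, which default to
#' the column sums of the count matrix.
#'
#' @param iso an `isoform_table` (counts should already be normalized).
#' @param samples sample table covering the table's columns.
#' @param cpm_floor CPM threshold (default 1).
#' @param lib_size optional per-sample library sizes (named or in column
#'   order); default `colSums(iso$counts)`.
#' @return list with `step` = "low_expression", `removed`, `kept` (isoform
#'   ids) and a `trace` data.frame.
#' @export
filter_low_expression <- function(iso, samples, cpm_floor = 1, lib_size = NULL) {
  gi <- group_index(iso, samples)
  if (is.null(lib_size)) lib_size <- colSums(iso$counts)
  if (!is.null(names(lib_size))) lib_size <- lib_size[colnames(iso$counts)]
  cpm <- sweep(iso$counts, 2L, lib_size, "/") * 1e6
  mean_c <- rowMeans(cpm[, gi$control, drop = FALSE])
  mean_t <- rowMeans(cpm[, gi$test, drop = FALSE])
  low <- mean_c < cpm_floor | mean_t < cpm_floor
  removed <- rownames(iso$counts)[low]
  list(step = "low_expression",
       removed = removed,
       kept = rownames(iso$counts)[!low],
       trace = filter_step("low_expression", removed,
                           sprintf("mean CPM < %g in at least one group", cpm_floor)))
}

#' Similar-usage filter (percentages view)
#'
#' Removes an isoform when the absolute difference between its mean usage
#' percentage in the control and test groups is less than or equal to
#' `delta_pct` points (inclusive boundary): only isoforms with sufficient
#' differential usage are kept.
#'
#' @param iso an `isoform_table`.
#' @param samples sample table.
#' @param delta_pct percentage-point threshold (default 10).
#' @param isoforms optional subset of isoform ids to assess (cascade
#'   survivors); default all.
#' @return list as in [filter_low_expression()] with `step` = "similar_usage".
#' @export
filter_similar_usage <- function(iso, samples, delta_pct = 10, isoforms = NULL) {
  gi <- group_index(iso, samples)
  if (is.null(isoforms)) isoforms <- rownames(iso$usage)
  u <- iso$usage[isoforms, , drop = FALSE]
  delta <- abs(rowMeans(u[, gi$control, drop = FALSE]) -
                 rowMeans(u[, gi$test, drop = FALSE]))
  similar <- delta <= delta_pct
  removed <- isoforms[similar]
  list(step = "similar_usage",
       removed = removed,
       kept = isoforms[!similar],
       trace = filter_step("similar_usage", removed,
                           sprintf("|mean usage difference| <= %g points", delta_pct)))
}

#' Detection filter (percentages view)
#'
#' Discards an isoform when, in either group, the fraction of samples in
#' which it is not detected (usage percentage equal to zero) exceeds
#' `max_missing_frac`. For a group with fewer than `small_n` samples the
#' rule hardens: the isoform must be detected in every sample of that group.
#'
#' @param iso an `isoform_table`.
#' @param samples sample table.
#' @param max_missing_frac maximum tolerated missing fraction (default 0.2).
#' @param small_n group-size threshold below which full detection is
#'   required (default 5).
#' @param isoforms optional subset to assess; default all.
#' @return list as in [filter_low_expression()] with `step` = "detection".
#' @export
filter_detection <- function(iso, samples, max_missing_frac = 0.2,
                             small_n = 5L, isoforms = NULL) {
  gi <- group_index(iso, samples)
  if (is.null(isoforms)) isoforms <- rownames(iso$usage)
  u <- iso$usage[isoforms, , drop = FALSE]
  bad <- rep(FALSE, length(isoforms))
  for (g in gi) {
    n_g <- length(g)
    n_zero <- rowSums(u[, g, drop = FALSE] == 0)
    bad <- bad | if (n_g < small_n) n_zero > 0 else (n_zero / n_g) > max_missing_frac
  }
  removed <- isoforms[bad]
  list(step = "detection",
       removed = removed,
       kept = isoforms[!bad],
       trace = filter_step("detection", removed,
                           sprintf("undetected in > %g%% of samples (or any sample when n < %d) in a group",
                                   100 * max_missing_frac, small_n)))
}

#' Synchronize filter views and prune single-isoform genes
#'
#' The survivor set is the set of isoforms that passed every filter step in
#' both the count and percentage views (an isoform deleted from one view is
#' deleted from the other). Afterwards, every gene left with exactly one
#' surviving isoform has that isoform removed too -- differential usage is
#' undefined for a single isoform. Usage percentages are NOT renormalized
#' after removals; the downstream ANOVA runs on the original percentages.
#'
#' @param iso the starting `isoform_table`.
#' @param steps list of filter-step results (from the filter functions).
#' @return list with `iso` (the pruned `isoform_table`), `trace` (data.frame
#'   over all steps including `single_isoform_prune`) and `survivors`.
#' @export
synchronize_and_prune <- function(iso, steps) {
  survivors <- rownames(iso$counts)
  traces <- list()
  for (st in steps) {
    survivors <- setdiff(survivors, st$removed)
    traces[[length(traces) + 1L]] <- st$trace
  }
  genes <- iso$gene[survivors]
  tab <- table(genes)
  lone <- survivors[genes %in% names(tab)[tab == 1L]]
  survivors <- setdiff(survivors, lone)
  traces[[length(traces) + 1L]] <-
    filter_step("single_isoform_prune", lone, "gene left with a single isoform")
  trace <- do.call(rbind, traces)
  if (length(survivors) == 0L) {
    warning("no isoforms survive the filter cascade; DTU call set will be empty")
  }
  list(iso = subset_isoforms(iso, survivors), trace = trace, survivors = survivors)
}

#' Run the full DTU filter cascade
#'
#' Applies, in order: low-expression (counts), similar-usage (percentages),
#' detection (percentages) -- each on the previous step's survivors so the
#' trace attributes every removal to the first rule that fires -- then
#' synchronizes and prunes single-isoform genes.
#'
#' @param iso an `isoform_table` (counts already normalized).
#' @param samples sample table.
#' @param cpm_floor,delta_pct,max_missing_frac,small_n filter thresholds
#'   (defaults 1 CPM, 10 points, 0.2, 5).
#' @param lib_size optional library sizes for the CPM filter.
#' @return as [synchronize_and_prune()].
#' @export
run_dtu_cascade <- function(iso, samples, cpm_floor = 1, delta_pct = 10,
                            max_missing_frac = 0.2, small_n = 5L,
                            lib_size = NULL) {
  s1 <- filter_low_expression(iso, samples, cpm_floor, lib_size = lib_size)
  s2 <- filter_similar_usage(iso, samples, delta_pct, isoforms = s1$kept)
  s3 <- filter_detection(iso, samples, max_missing_frac, small_n, isoforms = s2$kept)
  synchronize_and_prune(iso, list(s1, s2, s3))
}

#' One-way ANOVA of isoform usage between groups
#'
#' Classical equal-variance one-way fixed-effects ANOVA (two levels:
#' control vs test) on usage percentages -- percentages are approximately
#' linearly distributed, unlike raw counts. With two levels the F statistic
#' is the square of the pooled-variance t statistic. Degenerate isoforms
#' with zero within-group variance in both groups get the limit convention:
#' p = 1 when the group means are equal, p = 0 otherwise.
#'
#' @param iso an `isoform_table` (cascade survivors).
#' @param samples sample table.
#' @return named numeric vector of p-values, one per isoform.
#' @export
anova_isoform_usage <- function(iso, samples) {
  gi <- group_index(iso, samples)
  if (length(gi$control) < 2L || length(gi$test) < 2L) {
    stop("need >= 2 samples per group for ANOVA")
  }
  g <- factor(rep(c("control", "test"), c(length(gi$control), length(gi$test))))
  cols <- c(gi$control, gi$test)
  apply_one <- function(u) {
    uc <- u[seq_along(gi$control)]
    ut <- u[-seq_along(gi$control)]
    if (stats::var(uc) == 0 && stats::var(ut) == 0) {
      return(if (isTRUE(all.equal(mean(uc), mean(ut)))) 1 else 0)
    }
    stats::oneway.test(u ~ g, var.equal = TRUE)$p.value
  }
  u <- iso$usage[, cols, drop = FALSE]
  p <- apply(u, 1L, apply_one)
  stats::setNames(as.numeric(p), rownames(iso$usage))
}

#' Call DTU genes from the dominant isoform's usage shift
#'
#' For every gene surviving the cascade, the dominant isoform is the one
#' with the highest mean usage percentage in the control samples (ties
#' broken lexicographically by isoform id). The gene is called DTU when its
#' dominant isoform's ANOVA p-value is strictly below `alpha` (default 0.01;
#' stricter than the gene-level threshold because isoform-level calls carry
#' a higher false-positive rate; no multiplicity adjustment is applied, per
#' the procedure). A significant minor isoform alone never flags the gene,
#' but a column records whether the test group's dominant isoform identity
#' differs from the control's, for inspection.
#'
#' @param iso the cascade-surviving `isoform_table`.
#' @param pvals per-isoform ANOVA p-values covering the survivors.
#' @param samples sample table.
#' @param alpha DTU significance threshold on the raw p (default 0.01).
#' @return list with `dtu_genes`, `dominant` (gene -> isoform), `alpha`,
#'   `anova_p`, and a per-gene `table` (gene_id, dominant_isoform,
#'   control_mean_pct, test_mean_pct, anova_p, dominant_switched, is_dtu).
#' @export
call_dtu_genes <- function(iso, pvals, samples, alpha = 0.01) {
  gi <- group_index(iso, samples)
  ids <- rownames(iso$usage)
  if (length(ids) == 0L) {
    return(list(dtu_genes = character(0), dominant = character(0),
                alpha = alpha, anova_p = pvals,
                table = data.frame(gene_id = character(0),
                                   dominant_isoform = character(0),
                                   control_mean_pct = numeric(0),
                                   test_mean_pct = numeric(0),
                                   anova_p = numeric(0),
                                   dominant_switched = logical(0),
                                   is_dtu = logical(0))))
  }
  miss <- setdiff(ids, names(pvals))
  if (length(miss) > 0L) stop("p-values missing for isoform(s): ",
                              paste(miss, collapse = ", "))
  mean_c <- rowMeans(iso$usage[, gi$control, drop = FALSE])
  mean_t <- rowMeans(iso$usage[, gi$test, drop = FALSE])
  rows <- lapply(split(ids, unname(iso$gene[ids])), function(members) {
    members <- members[order(-mean_c[members], members)]
    dom <- members[1L]
    dom_t <- members[order(-mean_t[members], members)][1L]
    data.frame(gene_id = unname(iso$gene[dom]),
               dominant_isoform = dom,
               control_mean_pct = unname(mean_c[dom]),
               test_mean_pct = unname(mean_t[dom]),
               anova_p = unname(pvals[dom]),
               dominant_switched = dom_t != dom,
               is_dtu = unname(pvals[dom]) < alpha,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  list(dtu_genes = tab$gene_id[tab$is_dtu],
       dominant = stats::setNames(tab$dominant_isoform, tab$gene_id),
       alpha = alpha,
       anova_p = pvals,
       table = tab)
}

#' Remove DTU genes from the non-DEG set
#'
#' Genes similar at the gene level but with significantly altered isoform
#' composition are dropped, yielding the refined similarity set
#' (the "non-DEGs minus DTU" list). Always a subset of the non-DEGs.
#'
#' @param non_degs character vector of non-DEG gene ids.
#' @param dtu a DTU call set from [call_dtu_genes()] (or a character vector
#'   of DTU gene ids).
#' @return character vector: `non_degs` without the DTU genes.
#' @export
derive_nondeg_dtu_minus <- function(non_degs, dtu) {
  dtu_genes <- if (is.list(dtu)) dtu$dtu_genes else dtu
  setdiff(non_degs, dtu_genes)
}
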