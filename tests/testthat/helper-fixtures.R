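# Shared fixtures and independent oracles used across test files.

# Small, fast simulation settings for unit tests (not the study design;
# acceptance tests use the full 24-vs-3 defaults).
small_cfg <- function(seed = 1L, ...) {
  args <- list(n_genes = 300L, n_control = 8L, n_test = 3L,
               library_size_range = c(2e6, 4e6), seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# Hand-designed cascade fixture: 5 genes / 12 isoforms, 6 control + 3 test
# samples, library size fixed at 1e6 so counts equal CPM directly. Every
# cascade rule removes at least one planned isoform:
#   low_expression: B1 (test mean CPM 0.5)
#   similar_usage : A3 (delta 5), C3 (delta 0)
#   detection     : D1 (zero in 2/6 = 33% of controls), E1 (zero in 1 of 3
#                   test samples; small-n all-detected rule)
#   single-isoform prune: B2, D2, E2
# Survivors: A1, A2 (gene G1) and C1, C2 (gene G3).
make_cascade_fixture <- function() {
  ctrl <- paste0("c", 1:6); tst <- paste0("t", 1:3)
  samp <- c(ctrl, tst)
  rows <- list(
    A1 = c(rep(500, 6), rep(200, 3)),
    A2 = c(rep(300, 6), rep(550, 3)),
    A3 = c(rep(200, 6), rep(250, 3)),
    B1 = c(rep(300, 6), rep(0.5, 3)),
    B2 = c(rep(700, 6), rep(999.5, 3)),
    C1 = c(rep(400, 6), rep(520, 3)),
    C2 = c(rep(300, 6), rep(180, 3)),
    C3 = c(rep(300, 6), rep(300, 3)),
    D1 = c(0, 0, 300, 300, 300, 300, 400, 400, 400),
    D2 = c(1000, 1000, 700, 700, 700, 700, 600, 600, 600),
    E1 = c(rep(400, 6), 0, 200, 200),
    E2 = c(rep(600, 6), 1000, 800, 800)
  )
  counts <- do.call(rbind, rows)
  colnames(counts) <- samp
  gene_map <- stats::setNames(
    rep(c("G1", "G2", "G3", "G4", "G5"), c(3, 2, 3, 2, 2)),
    rownames(counts))
  iso <- isoform_table(counts, gene_map)
  samples <- sample_table(samp, rep(c("control", "test"), c(6, 3)))
  list(
    iso = iso, samples = samples, lib_size = rep(1e6, 9),
    expected = list(
      low_expression = "B1",
      similar_usage = c("A3", "C3"),
      detection = c("D1", "E1"),
      single_isoform_prune = c("B2", "D2", "E2"),
      survivors = c("A1", "A2", "C1", "C2")
    )
  )
}

# --- independent oracles (coded from the definitions, not from the package) ---

sf_oracle <- function(m) {
  pos <- rowSums(m > 0) == ncol(m)
  geo <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  apply(sweep(m[pos, , drop = FALSE], 1L, geo, "/"), 2L, median)
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m * p[o] / seq_len(m)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

spearman_oracle <- function(m) {
  stats::cor(apply(m, 2L, rank))
}

overlap_oracle <- function(sets) {
  universe <- unique(unlist(sets))
  pat <- vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1L))],
          collapse = "&")
  }, character(1L))
  table(pat)
}

# a tiny GMT written to a temp file
write_tmp_gmt <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}
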