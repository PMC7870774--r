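# Truth-labelled simulator for gene- and isoform-level RNA-seq counts with
# the study design's structure: a large reference ("control") group versus a
# small test group, negative-binomial gene counts with a mean-dispersion
# trend and unequal library sizes, a configurable fraction of DE genes, and
# multi-isoform genes whose counts are a multinomial split of the gene count
# -- so a gene can show differential transcript usage while its total stays
# non-DE, the phenomenon the refined non-DEG set is built to catch.

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 24 reference samples versus 3
#' test replicates, library sizes log-uniform between 20 and 40 million
#' reads, a mean-dispersion trend `alpha(mu) = asymptote + scale/mu`, 30%
#' DE genes with |log2FC| >= 1, and 10% DTU genes whose control-dominant
#' isoform loses 30 usage percentage points in the test group.
#'
#' @param n_genes number of genes (default 2000).
#' @param isoform_count_probs probabilities of a gene having 1..K isoforms.
#' @param n_control,n_test group sizes (>= 2 each).
#' @param library_size_range (min, max) reads; sizes drawn log-uniformly.
#' @param dispersion_asymptote,dispersion_scale trend parameters.
#' @param frac_de fraction of genes differentially expressed.
#' @param lfc_sd standard deviation of the Normal(0, sd) log2FC draw.
#' @param lfc_min minimum |log2FC| (rejection sampling).
#' @param frac_dtu fraction of multi-isoform genes with shifted usage.
#' @param dtu_shift_pct usage percentage points moved off the dominant
#'   isoform in the test group.
#' @param usage_concentration Dirichlet concentration for isoform usage.
#' @param expr_sdlog log-sd of the lognormal relative-expression draw.
#' @param allow_de_dtu_overlap draw DE and DTU gene sets independently
#'   instead of disjointly (default FALSE).
#' @param model_label,time_point_h metadata for the simulated test group.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L,
                              isoform_count_probs = c(0.25, 0.30, 0.20, 0.15, 0.10),
                              n_control = 24L, n_test = 3L,
                              library_size_range = c(20e6, 40e6),
                              dispersion_asymptote = 0.05,
                              dispersion_scale = 2,
                              frac_de = 0.3, lfc_sd = 2, lfc_min = 1,
                              frac_dtu = 0.1, dtu_shift_pct = 30,
                              usage_concentration = 2,
                              expr_sdlog = 1.5,
                              allow_de_dtu_overlap = FALSE,
                              model_label = "invitro", time_point_h = 0L,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              isoform_count_probs = isoform_count_probs / sum(isoform_count_probs),
              n_control = as.integer(n_control), n_test = as.integer(n_test),
              library_size_range = library_size_range,
              dispersion_asymptote = dispersion_asymptote,
              dispersion_scale = dispersion_scale,
              frac_de = frac_de, lfc_sd = lfc_sd, lfc_min = lfc_min,
              frac_dtu = frac_dtu, dtu_shift_pct = dtu_shift_pct,
              usage_concentration = usage_concentration,
              expr_sdlog = expr_sdlog,
              allow_de_dtu_overlap = isTRUE(allow_de_dtu_overlap),
              model_label = model_label, time_point_h = as.integer(time_point_h),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, cfg$n_control >= 2L, cfg$n_test >= 2L,
            cfg$frac_de >= 0, cfg$frac_de <= 1,
            cfg$frac_dtu >= 0, cfg$frac_dtu <= 1,
            cfg$dtu_shift_pct >= 0, cfg$dtu_shift_pct <= 100,
            cfg$library_size_range[1L] > 0,
            diff(cfg$library_size_range) >= 0)
  class(cfg) <- "simulation_config"
  cfg
}

rdirichlet_ <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  g / sum(g)
}

#' Simulate a two-group gene/isoform experiment
#'
#' Gene counts are negative binomial with mean = relative expression x
#' library size (times `2^lfc` in the test group for DE genes) and
#' dispersion from the configured trend. Isoform counts are a multinomial
#' split of each gene count by the group's usage vector, so each gene's
#' count equals the sum of its isoform counts exactly. For DTU genes the
#' test group's usage moves `dtu_shift_pct` points off the control-dominant
#' isoform, redistributed proportionally over the remaining isoforms
#' (floored at zero, with a message, when the dominant usage is smaller
#' than the shift). DE and DTU gene sets are disjoint by default, so DTU
#' genes stay non-DE at the gene level. Fully reproducible from the seed.
#'
#' @param cfg a [simulation_config()].
#' @return list with `counts` (gene matrix), `iso` ([isoform_table()]),
#'   `samples` ([sample_table()]), `truth` (per-gene data.frame),
#'   `library_sizes`, and the `config`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- cfg$n_genes
  n_s <- cfg$n_control + cfg$n_test
  wid <- max(4L, nchar(as.character(n)))
  genes <- sprintf(paste0("gene_%0", wid, "d"), seq_len(n))
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(cfg$n_control)),
                  sprintf("%s_r%d", cfg$model_label, seq_len(cfg$n_test)))
  grp <- rep(c("control", "test"), c(cfg$n_control, cfg$n_test))
  samples <- sample_table(sample_ids, grp,
                          model_label = ifelse(grp == "test", cfg$model_label, "in_vivo"),
                          time_point_h = cfg$time_point_h,
                          replicate_id = sample_ids)

  lo <- cfg$library_size_range[1L]; hi <- cfg$library_size_range[2L]
  L <- exp(stats::runif(n_s, log(lo), log(hi)))
  names(L) <- sample_ids

  q <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$expr_sdlog)
  rel <- q / sum(q)

  k_iso <- sample.int(length(cfg$isoform_count_probs), n, replace = TRUE,
                      prob = cfg$isoform_count_probs)

  is_de <- rep(FALSE, n); lfc <- rep(0, n)
  n_de <- round(cfg$frac_de * n)
  if (n_de > 0L) {
    de_idx <- sample.int(n, n_de)
    is_de[de_idx] <- TRUE
    draw_lfc <- function(m) {
      out <- numeric(0)
      while (length(out) < m) {
        cand <- stats::rnorm(m, 0, cfg$lfc_sd)
        out <- c(out, cand[abs(cand) >= cfg$lfc_min])
      }
      out[seq_len(m)]
    }
    lfc[de_idx] <- draw_lfc(n_de)
  }

  multi <- which(k_iso >= 2L)
  is_dtu <- rep(FALSE, n)
  n_dtu <- round(cfg$frac_dtu * n)
  pool <- if (cfg$allow_de_dtu_overlap) multi else setdiff(multi, which(is_de))
  if (n_dtu > length(pool)) n_dtu <- length(pool)
  if (n_dtu > 0L) is_dtu[sample(pool, n_dtu)] <- TRUE

  # per-gene usage vectors (fractions) for control and test
  usage_c <- vector("list", n); usage_t <- vector("list", n)
  floored <- 0L
  for (g in seq_len(n)) {
    k <- k_iso[g]
    u <- if (k == 1L) 1 else rdirichlet_(k, cfg$usage_concentration)
    usage_c[[g]] <- u
    ut <- u
    if (is_dtu[g]) {
      dom <- which.max(u)
      shift <- cfg$dtu_shift_pct / 100
      if (u[dom] < shift) { shift <- u[dom]; floored <- floored + 1L }
      ut[dom] <- u[dom] - shift
      rest <- setdiff(seq_len(k), dom)
      w <- u[rest]
      ut[rest] <- u[rest] + shift * (if (sum(w) > 0) w / sum(w) else rep(1 / length(rest), length(rest)))
    }
    usage_t[[g]] <- ut
  }
  if (floored > 0L) {
    message(floored, " DTU gene(s) had dominant usage below the shift; ",
            "usage floored at 0 with mass redistributed")
  }

  mu0 <- rel * mean(L)
  alpha <- cfg$dispersion_asymptote + cfg$dispersion_scale / mu0
  mu <- outer(rel, L)
  test_cols <- which(grp == "test")
  mu[, test_cols] <- mu[, test_cols] * 2^(lfc %o% rep(1, length(test_cols)))
  counts <- matrix(stats::rnbinom(n * n_s, mu = as.vector(mu),
                                  size = rep(1 / alpha, times = n_s)),
                   nrow = n, dimnames = list(genes, sample_ids))

  iso_ids <- unlist(lapply(seq_len(n), function(g)
    paste0(genes[g], "_iso", seq_len(k_iso[g]))), use.names = FALSE)
  gene_map <- stats::setNames(rep(genes, k_iso), iso_ids)
  iso_counts <- matrix(0, nrow = length(iso_ids), ncol = n_s,
                       dimnames = list(iso_ids, sample_ids))
  row0 <- c(0L, cumsum(k_iso))
  for (g in seq_len(n)) {
    k <- k_iso[g]
    rows <- (row0[g] + 1L):(row0[g] + k)
    if (k == 1L) {
      iso_counts[rows, ] <- counts[g, ]
      next
    }
    for (j in seq_len(n_s)) {
      tot <- counts[g, j]
      if (tot == 0) next
      u <- if (grp[j] == "test") usage_t[[g]] else usage_c[[g]]
      iso_counts[rows, j] <- stats::rmultinom(1L, tot, u)
    }
  }

  dom_iso <- vapply(seq_len(n), function(g) {
    u <- usage_c[[g]]
    paste0(genes[g], "_iso", which.max(u))
  }, character(1L))
  truth <- data.frame(
    gene_id = genes,
    n_isoforms = k_iso,
    is_de = is_de,
    true_lfc = lfc,
    is_dtu = is_dtu,
    dominant_isoform = dom_iso,
    dominant_usage_control = 100 * vapply(usage_c, max, numeric(1L)),
    dominant_usage_test = 100 * vapply(seq_len(n), function(g)
      usage_t[[g]][which.max(usage_c[[g]])], numeric(1L)),
    stringsAsFactors = FALSE
  )

  list(counts = counts,
       iso = isoform_table(iso_counts, gene_map),
       samples = samples,
       truth = truth,
       library_sizes = L,
       config = cfg)
}

#' Write a simulation in RSEM-like per-sample files
#'
#' One `<sample>.genes.results`-style file (gene_id, expected_count) and one
#' `<sample>.isoforms.results`-style file (transcript_id, gene_id,
#' expected_count, IsoPct) per sample, plus `sample_sheet.tsv` and
#' `truth.tsv`. Round-trips through [read_gene_counts()] and
#' [read_isoform_quant()].
#'
#' @param sim output of [simulate_experiment()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the written file paths.
#' @export
write_rsem_like <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gene_files <- character(0); iso_files <- character(0)
  for (s in colnames(sim$counts)) {
    gf <- file.path(out_dir, paste0(s, ".genes.results"))
    utils::write.table(
      data.frame(gene_id = rownames(sim$counts),
                 expected_count = sim$counts[, s]),
      gf, sep = "\t", quote = FALSE, row.names = FALSE)
    iff <- file.path(out_dir, paste0(s, ".isoforms.results"))
    utils::write.table(
      data.frame(transcript_id = rownames(sim$iso$counts),
                 gene_id = unname(sim$iso$gene),
                 expected_count = sim$iso$counts[, s],
                 IsoPct = sim$iso$usage[, s]),
      iff, sep = "\t", quote = FALSE, row.names = FALSE)
    gene_files <- c(gene_files, gf); iso_files <- c(iso_files, iff)
  }
  ss <- file.path(out_dir, "sample_sheet.tsv")
  utils::write.table(sim$samples, ss, sep = "\t", quote = FALSE, row.names = FALSE)
  tf <- file.path(out_dir, "truth.tsv")
  utils::write.table(sim$truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genes = gene_files, isoforms = iso_files,
                 sample_sheet = ss, truth = tf))
}
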