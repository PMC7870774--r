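# Shared setup for the analysis drivers: the emulated study panel.
#
# Five synthetic cell models with the replicate counts of a typical panel
# (2-7 replicates) and increasing transcriptome-wide perturbation (frac_de),
# so the similarity ranking the pipeline should recover is known by
# construction: microtissue > phh > ipsc_hlc > heparg > hepg2.
# Every model is simulated against its own 24-sample reference draw;
# comparisons are per model, as in the pipeline.

library(txsim)

study_models <- function() {
  list(
    microtissue = list(n_test = 2L, frac_de = 0.15, seed = 201L, allow_fewer = TRUE),
    phh         = list(n_test = 6L, frac_de = 0.20, seed = 202L, allow_fewer = FALSE),
    ipsc_hlc    = list(n_test = 3L, frac_de = 0.30, seed = 203L, allow_fewer = FALSE),
    heparg      = list(n_test = 4L, frac_de = 0.35, seed = 204L, allow_fewer = FALSE),
    hepg2       = list(n_test = 7L, frac_de = 0.45, seed = 205L, allow_fewer = FALSE)
  )
}

simulate_model <- function(name, spec) {
  suppressMessages(simulate_experiment(simulation_config(
    n_test = spec$n_test, frac_de = spec$frac_de,
    model_label = name, seed = spec$seed)))
}

liver_gmt <- function() {
  system.file("extdata", "liver_pathways_synthetic.gmt", package = "txsim")
}

results_dir <- "results"
scratch_dir <- "scratch"   # bulky regenerable artifacts live here
comparison_dir <- function(model) file.path(scratch_dir, "comparisons", model)

write_result <- function(df, name) {
  dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(results_dir, name)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", p)
  p
}
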