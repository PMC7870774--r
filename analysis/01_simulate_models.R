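#!/usr/bin/env Rscript
# Simulate the study panel and write it out in RSEM-like per-sample files.
# The raw per-sample files are bulky and fully regenerable from the seeds,
# so they go under scratch/; results/ gets the panel overview.

source("analysis/_common.R")

overview <- do.call(rbind, lapply(names(study_models()), function(name) {
  spec <- study_models()[[name]]
  sim <- simulate_model(name, spec)
  out <- file.path(scratch_dir, "sim", name)
  write_rsem_like(sim, out)
  data.frame(
    model = name,
    n_control = sum(sim$samples$group == "control"),
    n_test_replicates = spec$n_test,
    n_genes = nrow(sim$counts),
    n_isoforms = nrow(sim$iso$counts),
    frac_de_planted = spec$frac_de,
    frac_dtu_planted = sim$config$frac_dtu,
    n_de_planted = sum(sim$truth$is_de),
    n_dtu_planted = sum(sim$truth$is_dtu),
    median_library_size = round(median(colSums(sim$counts))),
    seed = spec$seed
  )
}))

write_result(overview, "01_model_overview.tsv")
cat("\nSimulated panel:\n")
print(overview, row.names = FALSE)
cat("\nPer-sample quantification files are under", file.path(scratch_dir, "sim"),
    "(regenerable; rerun this script).\n")
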