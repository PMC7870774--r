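#!/usr/bin/env Rscript
# Pathway coverage matrices across the panel: how much of each liver
# pathway each model's non-DEGs (and the DTU-refined set, and the DEGs)
# cover. Reads the gene lists written by analysis/03_run_comparisons.R.

source("analysis/_common.R")

read_list <- function(model, file) {
  p <- file.path(comparison_dir(model), file)
  if (!file.exists(p)) stop("missing ", p, "; run analysis/03_run_comparisons.R first")
  utils::read.delim(p)$gene_id
}

models <- names(study_models())
gs <- read_gene_sets(liver_gmt())

for (what in c("non_degs", "nondeg_dtu_minus", "degs")) {
  file <- paste0(what, ".tsv")
  lists <- lapply(models, read_list, file = file)
  names(lists) <- models
  cov <- coverage_matrix(lists, gs, mode = "gene")
  df <- data.frame(pathway_id = rownames(cov),
                   pathway = vapply(gs[rownames(cov)], `[[`, "", "name"),
                   round(cov, 2), check.names = FALSE)
  write_result(df, paste0("05_coverage_", what, ".tsv"))
  cat(sprintf("%-18s mean coverage by model: %s\n", what,
              paste(sprintf("%s=%.1f", colnames(cov), colMeans(cov)),
                    collapse = " ")))
}

cat("\nHigher non-DEG coverage = the model preserves more of the pathway;\n")
cat("DEG coverage shows the opposite trend, and the two need not sum to 100.\n")
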