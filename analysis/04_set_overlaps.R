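#!/usr/bin/env Rscript
# Overlap of the non-DEG (and DEG) sets across models, with exclusive
# UpSet-style intersection cells: models that preserve the same genes share
# liver-like features. Reads the per-model gene lists written by
# analysis/03_run_comparisons.R (run it first).

source("analysis/_common.R")

read_list <- function(model, file, col = "gene_id") {
  p <- file.path(comparison_dir(model), file)
  if (!file.exists(p)) stop("missing ", p, "; run analysis/03_run_comparisons.R first")
  utils::read.delim(p)[[col]]
}

models <- names(study_models())
non_degs <- lapply(models, read_list, file = "non_degs.tsv")
names(non_degs) <- models
degs <- lapply(models, read_list, file = "degs.tsv")
names(degs) <- models

ov_nd <- overlap_sets(non_degs, top_n = 50L)
ov_deg <- overlap_sets(degs, top_n = 50L)

write_result(ov_nd, "04_nondeg_overlap.tsv")
write_result(ov_deg, "04_deg_overlap.tsv")

cat("\nTop non-DEG overlap cells (exclusive):\n")
print(head(ov_nd, 8), row.names = FALSE)
cat(sprintf("\nnon-DEG union %d genes across %d models; all-model core cell: %d genes\n",
            attr(ov_nd, "union_size"), length(models),
            ov_nd$count[ov_nd$combination == paste(models, collapse = "&")][1]))
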