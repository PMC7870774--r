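# Pathway coverage: percentage of a pathway's genes (or protein nodes)
# present in a query gene list. Higher coverage of a liver pathway by the
# non-DEG list means the cell model preserves more of that process.

#' Coverage of one pathway by a gene list
#'
#' Gene mode: `100 * |list intersect pathway| / |pathway|`. Node mode:
#' `100 * (nodes with at least one member in the list) / (number of nodes)`.
#' Node mode exists because pathway mapping tools frequently map more than
#' one gene onto a single protein node, so gene-level coverages of a list
#' and its complement need not add up to 100. The denominator always counts
#' pathway members, never the query-list size.
#'
#' @param gene_list character vector of query gene ids.
#' @param pathway one entry of a [read_gene_sets()] collection.
#' @param mode `"gene"` or `"node"`.
#' @return coverage percentage in \[0, 100\].
#' @export
compute_coverage <- function(gene_list, pathway, mode = c("gene", "node")) {
  mode <- match.arg(mode)
  if (length(pathway$genes) == 0L) stop("pathway has no genes: ", pathway$id)
  gene_list <- unique(gene_list)
  if (mode == "gene") {
    return(100 * length(intersect(gene_list, pathway$genes)) / length(pathway$genes))
  }
  nodes <- pathway$nodes
  if (is.null(nodes)) nodes <- as.list(pathway$genes)  # singletons
  hit <- vapply(nodes, function(nd) any(nd %in% gene_list), logical(1L))
  100 * sum(hit) / length(nodes)
}

#' Coverage matrix: pathways x gene lists
#'
#' One column per query list, one row per pathway, each cell computed by
#' [compute_coverage()]. Rows and columns are ordered by sorted pathway and
#' list ids for deterministic output.
#'
#' @param gene_lists named list of character vectors (one per comparison).
#' @param gene_sets a [read_gene_sets()] collection.
#' @param mode `"gene"` or `"node"`.
#' @return numeric matrix of coverage percentages with pathway ids as
#'   rownames and list names as colnames.
#' @export
coverage_matrix <- function(gene_lists, gene_sets, mode = c("gene", "node")) {
  mode <- match.arg(mode)
  if (length(gene_lists) == 0L) stop("need at least one gene list")
  if (length(gene_sets) == 0L) stop("need at least one pathway")
  if (is.null(names(gene_lists)) || any(names(gene_lists) == "")) {
    names(gene_lists) <- paste0("list", seq_along(gene_lists))
  }
  pids <- sort(names(gene_sets))
  lids <- sort(names(gene_lists))
  m <- matrix(NA_real_, length(pids), length(lids), dimnames = list(pids, lids))
  for (p in pids) {
    for (l in lids) {
      m[p, l] <- compute_coverage(gene_lists[[l]], gene_sets[[p]], mode)
    }
  }
  m
}

#' Write a coverage matrix as TSV
#' @param m coverage matrix from [coverage_matrix()].
#' @param path output path.
#' @export
write_coverage <- function(m, path) {
  df <- data.frame(pathway_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
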