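# Domain types and readers/writers: sample sheets, gene/isoform quantification
# tables (plain TSV matrices or RSEM-style per-sample files), and GMT gene sets.
# All tables are tab-delimited UTF-8 with a header row; ids are opaque strings.

#' Construct and validate a sample table
#'
#' A sample table assigns each sequenced sample to a comparison group
#' (`control` = reference tissue, `test` = cell model), a model label
#' (e.g. "PHH"), a cultivation time point in hours and a replicate id.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character vector, one of `"control"` / `"test"` per sample
#'   (case-insensitive).
#' @param model_label character, the cell-model name; defaults to the group.
#' @param time_point_h non-negative integer hours; default 0.
#' @param replicate_id character replicate labels; default the sample id.
#' @return A `data.frame` with columns `sample_id`, `group`, `model_label`,
#'   `time_point_h`, `replicate_id`.
#' @export
sample_table <- function(sample_id, group, model_label = NULL,
                         time_point_h = 0L, replicate_id = NULL) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) == 0L) stop("no samples")
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  }
  group <- tolower(as.character(group))
  bad <- which(!group %in% c("control", "test"))
  if (length(bad) > 0L) {
    stop("unknown group label '", group[bad[1L]], "' for sample '",
         sample_id[bad[1L]], "' (expected 'control' or 'test')")
  }
  if (is.null(model_label)) model_label <- group
  if (is.null(replicate_id)) replicate_id <- sample_id
  time_point_h <- as.integer(time_point_h)
  if (any(is.na(time_point_h)) || any(time_point_h < 0L)) {
    stop("time_point_h must be non-negative integer hours")
  }
  df <- data.frame(
    sample_id = sample_id,
    group = group,
    model_label = rep_len(as.character(model_label), length(sample_id)),
    time_point_h = rep_len(time_point_h, length(sample_id)),
    replicate_id = rep_len(as.character(replicate_id), length(sample_id)),
    stringsAsFactors = FALSE
  )
  df
}

#' Read a sample sheet
#'
#' Expects a tab-delimited file with a header containing at least
#' `sample_id` and `group`; optional columns `model_label`, `time_point_h`
#' and `replicate_id` are filled with defaults when absent. Group labels are
#' normalized (case-insensitively) to `control`/`test`.
#'
#' @param path path to the sample sheet TSV.
#' @return A validated sample table (see [sample_table()]).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("no samples in ", path, " (", conditionMessage(e), ")")
  )
  if (nrow(df) == 0L) stop("no samples in ", path)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  sample_table(
    sample_id = df$sample_id,
    group = df$group,
    model_label = if ("model_label" %in% names(df)) df$model_label else NULL,
    time_point_h = if ("time_point_h" %in% names(df)) df$time_point_h else 0L,
    replicate_id = if ("replicate_id" %in% names(df)) df$replicate_id else NULL
  )
}

validate_counts_matrix <- function(counts, what = "count") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(what, " matrix must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop(what, " matrix must carry feature rownames and sample colnames")
  }
  if (anyNA(counts)) stop(what, " matrix contains NA values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop("negative ", what, " for feature '", rownames(counts)[neg[1L, 1L]],
         "' in sample '", colnames(counts)[neg[1L, 2L]], "'")
  }
  invisible(counts)
}

strip_version <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Read a gene count matrix
#'
#' Two dialects are supported. `matrix`: a single TSV whose first column
#' holds gene ids and remaining columns one sample each. `rsem_genes`: one
#' `.genes.results`-style file per sample with (at least) `gene_id` and
#' `expected_count` columns; sample names are taken from `names(path)` or
#' derived from the file names. Expected counts may be fractional and are
#' never rounded. Gene id universes must be identical across samples;
#' a mismatch is an error (silent intersection would change non-DEG counts).
#'
#' @param path file path (matrix dialect) or character vector of per-sample
#'   file paths (rsem_genes dialect).
#' @param dialect `"matrix"` or `"rsem_genes"`.
#' @param samples optional sample table; when given, every sample in the
#'   files must be present in it.
#' @param strip_id_version strip trailing ".N" Ensembl-style versions from
#'   gene ids (default off).
#' @return numeric matrix, genes x samples. Library sizes are the column sums.
#' @export
read_gene_counts <- function(path, dialect = c("matrix", "rsem_genes"),
                             samples = NULL, strip_id_version = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    if (!file.exists(path)) stop("count matrix not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    if (any(!file.exists(path))) {
      stop("missing file(s): ", paste(path[!file.exists(path)], collapse = ", "))
    }
    ids_by_sample <- NULL
    cols <- list()
    snames <- names(path)
    if (is.null(snames) || any(snames == "")) {
      snames <- sub("\\.genes\\.results$", "", basename(path))
    }
    for (i in seq_along(path)) {
      df <- utils::read.delim(path[i], stringsAsFactors = FALSE, check.names = FALSE)
      if (!all(c("gene_id", "expected_count") %in% names(df))) {
        stop("file ", path[i], " lacks gene_id/expected_count columns")
      }
      gid <- as.character(df$gene_id)
      if (is.null(ids_by_sample)) {
        ids_by_sample <- gid
      } else if (!setequal(gid, ids_by_sample)) {
        diff <- union(setdiff(gid, ids_by_sample), setdiff(ids_by_sample, gid))
        stop("gene id sets differ across samples; symmetric difference: ",
             paste(sort(diff), collapse = ", "))
      }
      cols[[snames[i]]] <- df$expected_count[match(ids_by_sample, gid)]
    }
    m <- do.call(cbind, cols)
    rownames(m) <- ids_by_sample
  }
  if (strip_id_version) rownames(m) <- strip_version(rownames(m))
  validate_counts_matrix(m, "count")
  if (!is.null(samples)) {
    extra <- setdiff(colnames(m), samples$sample_id)
    if (length(extra) > 0L) {
      stop("sample(s) in count files absent from sample table: ",
           paste(extra, collapse = ", "))
    }
  }
  m
}

#' Construct an isoform table
#'
#' Bundles the isoform-level quantification: a counts matrix
#' (isoforms x samples), the isoform-to-parent-gene map, and per-sample
#' usage percentages (each gene's isoform percentages sum to 100, or are
#' all zero when the gene's total count in that sample is zero). When
#' `usage` is omitted it is computed from the counts.
#'
#' @param counts numeric matrix, isoforms x samples, non-negative.
#' @param gene_map named character vector mapping isoform_id -> gene_id.
#' @param usage optional usage-percentage matrix matching `counts`.
#' @return An object of class `isoform_table` with elements `counts`,
#'   `usage`, `gene`.
#' @export
isoform_table <- function(counts, gene_map, usage = NULL) {
  validate_counts_matrix(counts, "isoform count")
  gene_map <- gene_map[rownames(counts)]
  if (anyNA(gene_map)) {
    stop("gene_map lacks parent gene for isoform(s): ",
         paste(rownames(counts)[is.na(gene_map)], collapse = ", "))
  }
  obj <- structure(
    list(counts = counts, usage = NULL, gene = gene_map),
    class = "isoform_table"
  )
  if (is.null(usage)) {
    obj <- compute_isoform_percentages(obj)
  } else {
    if (!identical(dim(usage), dim(counts))) stop("usage/counts dimension mismatch")
    dimnames(usage) <- dimnames(counts)
    if (any(usage < -1e-9) || any(usage > 100 + 1e-9)) {
      stop("usage percentages must lie in [0, 100]")
    }
    obj$usage <- usage
  }
  obj
}

#' @export
print.isoform_table <- function(x, ...) {
  cat("isoform_table:", nrow(x$counts), "isoforms,",
      length(unique(x$gene)), "genes,", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Subset an isoform table to a set of isoforms (and optionally samples)
#'
#' Usage percentages are carried over as-is, never renormalized.
#' @param iso an `isoform_table`.
#' @param isoforms character vector of isoform ids to keep.
#' @param samples optional character vector of sample ids to keep.
#' @return the subsetted `isoform_table`.
#' @export
subset_isoforms <- function(iso, isoforms, samples = NULL) {
  keep_s <- if (is.null(samples)) colnames(iso$counts) else samples
  structure(
    list(
      counts = iso$counts[isoforms, keep_s, drop = FALSE],
      usage = iso$usage[isoforms, keep_s, drop = FALSE],
      gene = iso$gene[isoforms]
    ),
    class = "isoform_table"
  )
}

#' Compute isoform usage percentages from counts
#'
#' Per gene and sample, usage = 100 x isoform count / parent-gene total.
#' Gene-samples with a zero total get all-zero usage (the RSEM IsoPct
#' convention); such isoforms are removed later by the detection filter.
#' The operation is idempotent and invariant to rescaling a gene-sample's
#' counts by any positive constant.
#'
#' @param iso an `isoform_table` with counts populated.
#' @return the same table with `usage` recomputed from `counts`.
#' @export
compute_isoform_percentages <- function(iso) {
  totals <- rowsum(iso$counts, group = iso$gene, reorder = FALSE)
  tot_per_iso <- totals[match(iso$gene, rownames(totals)), , drop = FALSE]
  usage <- 100 * iso$counts / tot_per_iso
  usage[tot_per_iso == 0] <- 0
  dimnames(usage) <- dimnames(iso$counts)
  iso$usage <- usage
  iso
}

#' Read isoform-level quantification
#'
#' Dialect `rsem_isoforms`: one `.isoforms.results`-style file per sample
#' with columns `transcript_id`, `gene_id`, `expected_count` and optionally
#' `IsoPct`; when `IsoPct` is absent, usage is derived from counts. Dialect
#' `matrix_pair`: `paths` is a list with element `counts` (TSV: isoform_id,
#' gene_id, then one column per sample) and optionally `usage` (same layout).
#'
#' @param paths character vector of per-sample files (rsem_isoforms) or a
#'   list with `counts` and optional `usage` paths (matrix_pair).
#' @param dialect `"rsem_isoforms"` or `"matrix_pair"`.
#' @param strip_id_version strip trailing ".N" versions from both isoform
#'   and gene ids.
#' @return an [isoform_table()].
#' @export
read_isoform_quant <- function(paths, dialect = c("rsem_isoforms", "matrix_pair"),
                               strip_id_version = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix_pair") {
    cdf <- utils::read.delim(paths$counts, stringsAsFactors = FALSE, check.names = FALSE)
    iso_ids <- as.character(cdf[[1L]])
    genes <- as.character(cdf[[2L]])
    cm <- as.matrix(cdf[, -(1:2), drop = FALSE]); storage.mode(cm) <- "double"
    rownames(cm) <- iso_ids
    usage <- NULL
    if (!is.null(paths$usage)) {
      udf <- utils::read.delim(paths$usage, stringsAsFactors = FALSE, check.names = FALSE)
      um <- as.matrix(udf[, -(1:2), drop = FALSE]); storage.mode(um) <- "double"
      rownames(um) <- as.character(udf[[1L]])
      usage <- um[iso_ids, colnames(cm), drop = FALSE]
    }
    gene_map <- stats::setNames(genes, iso_ids)
  } else {
    snames <- names(paths)
    if (is.null(snames) || any(snames == "")) {
      snames <- sub("\\.isoforms\\.results$", "", basename(paths))
    }
    iso_ids <- NULL; gene_map <- NULL
    cm_cols <- list(); um_cols <- list(); have_pct <- TRUE
    for (i in seq_along(paths)) {
      df <- utils::read.delim(paths[i], stringsAsFactors = FALSE, check.names = FALSE)
      if (!all(c("transcript_id", "gene_id", "expected_count") %in% names(df))) {
        stop("file ", paths[i], " lacks transcript_id/gene_id/expected_count")
      }
      tid <- as.character(df$transcript_id)
      if (is.null(iso_ids)) {
        iso_ids <- tid
        gene_map <- stats::setNames(as.character(df$gene_id), tid)
      } else {
        if (!setequal(tid, iso_ids)) {
          diff <- union(setdiff(tid, iso_ids), setdiff(iso_ids, tid))
          stop("isoform id sets differ across samples; symmetric difference: ",
               paste(sort(diff), collapse = ", "))
        }
        this_map <- stats::setNames(as.character(df$gene_id), tid)[iso_ids]
        clash <- names(this_map)[this_map != gene_map]
        if (length(clash) > 0L) {
          stop("isoform(s) mapped to conflicting parent genes: ",
               paste(clash, collapse = ", "))
        }
      }
      ord <- match(iso_ids, tid)
      cm_cols[[snames[i]]] <- df$expected_count[ord]
      if ("IsoPct" %in% names(df)) um_cols[[snames[i]]] <- df$IsoPct[ord]
      else have_pct <- FALSE
    }
    cm <- do.call(cbind, cm_cols)
    rownames(cm) <- iso_ids
    usage <- if (have_pct) {
      um <- do.call(cbind, um_cols); rownames(um) <- iso_ids; um
    } else NULL
  }
  if (strip_id_version) {
    rownames(cm) <- strip_version(rownames(cm))
    gene_map <- stats::setNames(strip_version(unname(gene_map)), rownames(cm))
    if (!is.null(usage)) rownames(usage) <- rownames(cm)
  }
  isoform_table(cm, gene_map, usage = usage)
}

#' Read pathway gene sets from a GMT file
#'
#' GMT lines are `pathway_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' An optional node map (TSV: `pathway_id`, `node_id`, `gene_id`) groups
#' member genes into protein nodes, reflecting that pathway mapping tools
#' frequently map more than one gene onto a single protein node. Genes not
#' listed in the node map become singleton nodes; a node-map gene outside
#' its pathway is an error. A gene may belong to several nodes.
#'
#' @param path GMT file path.
#' @param node_map optional node-map TSV path.
#' @return a named list (one entry per pathway) of
#'   `list(id, name, genes, nodes)`; `nodes` is a list of character vectors.
#' @export
read_gene_sets <- function(path, node_map = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    id <- parts[1L]
    name <- if (length(parts) >= 2L) parts[2L] else id
    genes <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    if (length(genes) == 0L) stop("pathway with zero genes: ", id)
    if (id %in% names(out)) stop("duplicated pathway id: ", id)
    out[[id]] <- list(id = id, name = name, genes = genes, nodes = NULL)
  }
  if (!is.null(node_map)) {
    nm <- utils::read.delim(node_map, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("pathway_id", "node_id", "gene_id")
    if (!all(need %in% names(nm))) {
      stop("node map must have columns ", paste(need, collapse = ", "))
    }
    for (pid in unique(nm$pathway_id)) {
      if (!pid %in% names(out)) stop("node map references unknown pathway: ", pid)
      sub <- nm[nm$pathway_id == pid, , drop = FALSE]
      outside <- setdiff(sub$gene_id, out[[pid]]$genes)
      if (length(outside) > 0L) {
        stop("node map for ", pid, " references gene(s) outside the pathway: ",
             paste(outside, collapse = ", "))
      }
      nodes <- split(sub$gene_id, sub$node_id)
      nodes <- lapply(nodes, unique)
      leftover <- setdiff(out[[pid]]$genes, unlist(nodes))
      nodes <- c(nodes, as.list(leftover))
      out[[pid]]$nodes <- unname(nodes)
    }
  }
  out
}

#' Write a count matrix as TSV (first column = feature id)
#' @param m numeric matrix with rownames/colnames.
#' @param path output path.
#' @param id_col header name of the id column.
#' @export
write_count_matrix <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an isoform table as a counts/usage TSV pair
#' @param iso an `isoform_table`.
#' @param counts_path,usage_path output paths.
#' @export
write_isoform_table <- function(iso, counts_path, usage_path) {
  cdf <- data.frame(isoform_id = rownames(iso$counts),
                    gene_id = unname(iso$gene), iso$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  udf <- data.frame(isoform_id = rownames(iso$usage),
                    gene_id = unname(iso$gene), iso$usage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(udf, usage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, usage_path))
}
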