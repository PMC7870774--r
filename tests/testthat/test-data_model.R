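test_that("sample sheets are read, normalized and validated", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = c(paste0("liver_", 1:24), paste0("PHH_024_", 1:3)),
                   group = c(rep("Control", 24), rep("TEST", 3)),
                   model_label = c(rep("in_vivo", 24), rep("PHH", 3)),
                   time_point_h = c(rep(0, 24), rep(24, 3)))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_sample_table(f)
  expect_equal(nrow(st), 27)
  expect_setequal(unique(st$group), c("control", "test"))
  expect_equal(st$replicate_id, st$sample_id)

  df2 <- df; df2$sample_id[2] <- "PHH_024_1"
  write.table(df2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_table(f), "PHH_024_1")

  df3 <- df; df3$group[5] <- "invitro"
  write.table(df3, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_table(f), "invitro")

  writeLines("sample_id\tgroup", f)
  expect_error(read_sample_table(f), "no samples")
})

test_that("gene count reading validates ids, sign and sample universe", {
  dir <- tempfile(); dir.create(dir)
  genes <- sprintf("g%03d", 1:100)
  set.seed(42)
  paths <- character(3)
  for (i in 1:3) {
    paths[i] <- file.path(dir, paste0("s", i, ".genes.results"))
    write.table(data.frame(gene_id = genes,
                           expected_count = round(rexp(100, 1 / 50), 2)),
                paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  m <- read_gene_counts(paths, "rsem_genes")
  expect_equal(dim(m), c(100L, 3L))
  expect_equal(colnames(m), paste0("s", 1:3))
  expect_true(all(m >= 0))

  # non-identical id sets -> error listing the symmetric difference
  write.table(data.frame(gene_id = c(genes[-1], "gXXX"),
                         expected_count = 1),
              paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_counts(paths, "rsem_genes"), "g001.*gXXX")

  # matrix dialect with a negative cell -> error with coordinates
  f <- file.path(dir, "mat.tsv")
  mm <- data.frame(gene_id = genes[1:5], sA = 1:5, sB = c(1, -2, 3, 4, 5))
  write.table(mm, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_counts(f, "matrix"), "g002.*sB")

  # sample missing from the sample table -> error
  mm$sB <- abs(mm$sB)
  write.table(mm, f, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- sample_table(c("sA", "sC"), c("control", "test"))
  expect_error(read_gene_counts(f, "matrix", samples = st), "sB")
})

test_that("isoform quantification reads both dialects and derives usage", {
  dir <- tempfile(); dir.create(dir)
  p1 <- file.path(dir, "sA.isoforms.results")
  write.table(data.frame(transcript_id = c("T1", "T2"), gene_id = "G1",
                         expected_count = c(30, 70), IsoPct = c(30, 70)),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "sB.isoforms.results")
  write.table(data.frame(transcript_id = c("T1", "T2"), gene_id = "G1",
                         expected_count = c(10, 40), IsoPct = c(20, 80)),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  iso <- read_isoform_quant(c(p1, p2), "rsem_isoforms")
  expect_equal(iso$counts["T1", "sA"], 30)
  expect_equal(iso$usage["T2", "sB"], 80)
  expect_equal(unname(iso$gene["T1"]), "G1")

  # without IsoPct, usage is computed from counts
  write.table(data.frame(transcript_id = c("T1", "T2"), gene_id = "G1",
                         expected_count = c(10, 40)),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(transcript_id = c("T1", "T2"), gene_id = "G1",
                         expected_count = c(30, 70)),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  iso2 <- read_isoform_quant(c(p1, p2), "rsem_isoforms")
  expect_equal(unname(iso2$usage[, "sB"]), c(20, 80))

  # conflicting parent gene -> error naming the isoform
  write.table(data.frame(transcript_id = c("T1", "T2"), gene_id = c("G9", "G1"),
                         expected_count = c(10, 40)),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_isoform_quant(c(p1, p2), "rsem_isoforms"), "T1")
})

test_that("usage percentages follow the definition and its conventions", {
  counts <- rbind(T1 = c(30, 0, 1), T2 = c(70, 0, 1), T3 = c(0, 0, 2))
  colnames(counts) <- paste0("s", 1:3)
  gm <- c(T1 = "G1", T2 = "G1", T3 = "G2")
  iso <- isoform_table(counts, gm)
  expect_equal(unname(iso$usage[, "s1"]), c(30, 70, 0))
  expect_equal(unname(iso$usage[, "s2"]), c(0, 0, 0))   # zero-total convention
  expect_equal(unname(iso$usage["T3", "s3"]), 100)

  counts2 <- rbind(T1 = c(1), T2 = c(1), T3 = c(2))
  colnames(counts2) <- "s1"
  iso2 <- isoform_table(counts2, c(T1 = "G1", T2 = "G1", T3 = "G1"))
  expect_equal(unname(iso2$usage[, 1]), c(25, 25, 50))
})

test_that("usage computation is idempotent, scale-invariant and sums to 100", {
  set.seed(7)
  for (rep in 1:5) {
    counts <- matrix(rpois(60, 40) + 1, nrow = 12,
                     dimnames = list(paste0("T", 1:12), paste0("s", 1:5)))
    gm <- stats::setNames(rep(paste0("G", 1:4), each = 3), paste0("T", 1:12))
    iso <- isoform_table(counts, gm)
    sums <- rowsum(iso$usage, gm)
    expect_true(all(abs(sums - 100) < 1e-6))
    again <- compute_isoform_percentages(iso)
    expect_equal(again$usage, iso$usage)
    scaled <- isoform_table(counts * 7.3, gm)
    expect_equal(scaled$usage, iso$usage, tolerance = 1e-12)
  }
})

test_that("tables round-trip through their writers to 1e-9", {
  set.seed(11)
  m <- matrix(round(rexp(50, 1 / 100), 2), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  f <- tempfile(fileext = ".tsv")
  write_count_matrix(m, f)
  m2 <- read_gene_counts(f, "matrix")
  expect_equal(m2, m, tolerance = 1e-9)

  gm <- stats::setNames(rep(c("G1", "G2"), each = 3), paste0("T", 1:6))
  iso <- isoform_table(matrix(rpois(30, 50), nrow = 6,
                              dimnames = list(paste0("T", 1:6), paste0("s", 1:5))), gm)
  cf <- tempfile(fileext = ".tsv"); uf <- tempfile(fileext = ".tsv")
  write_isoform_table(iso, cf, uf)
  iso2 <- read_isoform_quant(list(counts = cf, usage = uf), "matrix_pair")
  expect_equal(iso2$counts, iso$counts, tolerance = 1e-9)
  expect_equal(iso2$usage, iso$usage, tolerance = 1e-9)
  expect_equal(iso2$gene, iso$gene)
})

test_that("GMT gene sets and node maps are parsed and validated", {
  f <- write_tmp_gmt(c(
    paste(c("P1", "desc", "g1", "g2", "g3"), collapse = "\t"),
    paste(c("P2", "desc", "g2", "g4"), collapse = "\t")
  ))
  gs <- read_gene_sets(f)
  expect_length(gs, 2)
  expect_setequal(gs$P1$genes, c("g1", "g2", "g3"))

  f2 <- write_tmp_gmt(c(paste(c("P1", "desc", "g1"), collapse = "\t"),
                        "P2\tdesc\t"))
  expect_error(read_gene_sets(f2), "P2")

  nm <- tempfile(fileext = ".tsv")
  write.table(data.frame(pathway_id = "P1", node_id = "n1",
                         gene_id = c("g1", "g2")),
              nm, sep = "\t", quote = FALSE, row.names = FALSE)
  gs2 <- read_gene_sets(f, node_map = nm)
  expect_equal(length(gs2$P1$nodes), 2)   # {g1,g2} plus singleton {g3}
  expect_setequal(unlist(gs2$P1$nodes), gs2$P1$genes)

  write.table(data.frame(pathway_id = "P1", node_id = "n1",
                         gene_id = c("g1", "g99")),
              nm, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_sets(f, node_map = nm), "g99")

  # the shipped 20-pathway liver fixture parses
  shipped <- system.file("extdata", "liver_pathways_synthetic.gmt",
                         package = "txsim")
  gs3 <- read_gene_sets(shipped)
  expect_length(gs3, 20)
})
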