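test_that("the filter cascade matches the hand enumeration on the fixture", {
  fx <- make_cascade_fixture()
  res <- run_dtu_cascade(fx$iso, fx$samples, lib_size = fx$lib_size)
  expect_setequal(res$survivors, fx$expected$survivors)
  for (step in names(fx$expected)[names(fx$expected) != "survivors"]) {
    expect_setequal(res$trace$isoform_id[res$trace$step == step],
                    fx$expected[[step]])
  }
  # trace bookkeeping: removals disjoint, union + survivors = starting set
  expect_false(any(duplicated(res$trace$isoform_id)))
  expect_setequal(c(res$trace$isoform_id, res$survivors),
                  rownames(fx$iso$counts))
  # survivors keep their original (un-renormalized) usage values
  expect_equal(res$iso$usage, fx$iso$usage[res$survivors, ])
})

test_that("filter boundaries are handled per the stated conventions", {
  samp <- c(paste0("c", 1:6), paste0("t", 1:6))
  samples <- sample_table(samp, rep(c("control", "test"), each = 6))

  # CPM exactly at the floor is retained (strict <)
  counts <- rbind(X1 = rep(1, 12), X2 = rep(0.999, 12), X3 = rep(50, 12))
  colnames(counts) <- samp
  iso <- isoform_table(counts, c(X1 = "G1", X2 = "G1", X3 = "G2"))
  st <- filter_low_expression(iso, samples, cpm_floor = 1,
                              lib_size = rep(1e6, 12))
  expect_true("X1" %in% st$kept)
  expect_true("X2" %in% st$removed)

  # usage delta exactly 10 removed; 10.5 retained
  u <- rbind(Y1 = c(rep(50, 6), rep(40, 6)),      # delta 10 -> removed
             Y2 = c(rep(50, 6), rep(60, 6)),      # complement, delta 10
             Y3 = c(rep(39.5, 6), rep(50, 6)),    # delta 10.5 -> retained
             Y4 = c(rep(60.5, 6), rep(50, 6)))
  cts <- u * 10; colnames(cts) <- samp
  iso2 <- isoform_table(cts, c(Y1 = "Ga", Y2 = "Ga", Y3 = "Gb", Y4 = "Gb"),
                        usage = u)
  st2 <- filter_similar_usage(iso2, samples)
  expect_setequal(st2$removed, c("Y1", "Y2"))
  expect_setequal(st2$kept, c("Y3", "Y4"))
})

test_that("detection thresholds fire at the documented fractions", {
  ctrl <- paste0("c", 1:24); tst <- paste0("t", 1:3)
  samples <- sample_table(c(ctrl, tst), rep(c("control", "test"), c(24, 3)))
  u <- rbind(
    Z1 = c(rep(0, 5), rep(30, 19), rep(40, 3)),  # 5/24 = 20.8% -> discarded
    Z2 = c(rep(0, 4), rep(30, 20), rep(40, 3)),  # 4/24 = 16.7% -> retained
    Z3 = c(rep(30, 24), 0, 40, 40)               # small-n rule: any zero
  )
  cts <- pmax(u, 0.01) * 10
  colnames(cts) <- colnames(u) <- c(ctrl, tst)
  iso <- isoform_table(cts, c(Z1 = "G1", Z2 = "G2", Z3 = "G3"), usage = u)
  st <- filter_detection(iso, samples)
  expect_setequal(st$removed, c("Z1", "Z3"))
  expect_equal(st$kept, "Z2")
})

test_that("single-isoform pruning applies after synchronization only", {
  samp <- c(paste0("c", 1:6), paste0("t", 1:3))
  samples <- sample_table(samp, rep(c("control", "test"), c(6, 3)))
  # gene {A,B}: B fails CPM -> A pruned; gene {C,D,E}: E fails -> C,D kept
  counts <- rbind(A = c(rep(500, 9)),
                  B = c(rep(500, 6), rep(0.1, 3)),
                  C = c(rep(400, 6), rep(150, 3)),
                  D = c(rep(300, 6), rep(550, 3)),
                  E = c(rep(300, 6), rep(0.1, 3)))
  colnames(counts) <- samp
  iso <- isoform_table(counts, c(A = "G1", B = "G1", C = "G2", D = "G2", E = "G2"))
  res <- run_dtu_cascade(iso, samples, lib_size = rep(1e6, 9))
  expect_setequal(res$survivors, c("C", "D"))
  expect_true("A" %in%
    res$trace$isoform_id[res$trace$step == "single_isoform_prune"])
})

test_that("thresholds act monotonically on the survivor set", {
  sim <- simulate_experiment(small_cfg(seed = 18, frac_dtu = 0.3,
                                       dtu_shift_pct = 25))
  sf <- estimate_size_factors(sim$iso$counts)
  ison <- sim$iso
  ison$counts <- normalize_counts(sim$iso$counts, sf)
  surv <- function(cpm = 1, delta = 10) {
    suppressWarnings(run_dtu_cascade(ison, sim$samples, cpm_floor = cpm,
                                     delta_pct = delta)$survivors)
  }
  base <- surv()
  expect_true(all(surv(delta = 20) %in% base))     # raising delta shrinks
  expect_true(all(base %in% surv(cpm = 0.2)))      # lowering floor grows
})

test_that("two-level ANOVA equals the pooled t-test and handles degeneracy", {
  samp <- c(paste0("c", 1:4), paste0("t", 1:3))
  samples <- sample_table(samp, rep(c("control", "test"), c(4, 3)))
  u <- rbind(I1 = c(50, 52, 48, 50, 20, 22, 21),
             I2 = c(50, 48, 52, 50, 80, 78, 79))
  cts <- u * 10; colnames(cts) <- colnames(u) <- samp
  iso <- isoform_table(cts, c(I1 = "G1", I2 = "G1"), usage = u)
  p <- anova_isoform_usage(iso, samples)
  tt <- t.test(u[1, 1:4], u[1, 5:7], var.equal = TRUE)$p.value
  expect_equal(unname(p["I1"]), tt, tolerance = 1e-10)

  set.seed(23)
  g <- rep(c("control", "test"), c(6, 5))
  samples2 <- sample_table(paste0("s", 1:11), g)
  for (i in 1:200) {
    x <- rnorm(11, 50, 8)
    um <- rbind(W = x, V = 100 - x)
    colnames(um) <- paste0("s", 1:11)
    iso2 <- isoform_table(pmax(um, 0.01), c(W = "G", V = "G"), usage = pmin(pmax(um, 0), 100))
    p2 <- anova_isoform_usage(iso2, samples2)
    oracle <- t.test(x[1:6], x[7:11], var.equal = TRUE)$p.value
    expect_equal(unname(p2["W"]), oracle, tolerance = 1e-10)
  }

  # degenerate: identical values -> p = 1; constant but different -> p = 0
  u3 <- rbind(K1 = rep(50, 7), K2 = rep(50, 7),
              K3 = c(rep(30, 4), rep(70, 3)), K4 = c(rep(70, 4), rep(30, 3)))
  colnames(u3) <- samp
  iso3 <- isoform_table(u3 * 2, c(K1 = "Gx", K2 = "Gx", K3 = "Gy", K4 = "Gy"),
                        usage = u3)
  p3 <- anova_isoform_usage(iso3, samples)
  expect_equal(unname(p3["K1"]), 1)
  expect_equal(unname(p3["K3"]), 0)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(29)
  n <- 2000
  samp <- c(paste0("c", 1:10), paste0("t", 1:6))
  samples <- sample_table(samp, rep(c("control", "test"), c(10, 6)))
  u <- matrix(rnorm(n * 16, 50, 10), nrow = n,
              dimnames = list(paste0("iso", 1:n), samp))
  u <- pmin(pmax(u, 0), 100)
  iso <- isoform_table(matrix(100, n, 16, dimnames = dimnames(u)),
                       stats::setNames(paste0("g", 1:n), rownames(u)),
                       usage = u)
  p <- anova_isoform_usage(iso, samples)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("DTU calls key on the control-dominant isoform only", {
  samp <- c(paste0("c", 1:4), paste0("t", 1:3))
  samples <- sample_table(samp, rep(c("control", "test"), c(4, 3)))
  u <- rbind(dom = c(60, 61, 59, 60, 58, 61, 60),     # dominant, flat
             min1 = c(25, 24, 26, 25, 5, 4, 6),       # minor, shifted
             min2 = c(15, 15, 15, 15, 37, 35, 34))
  cts <- u * 10; colnames(cts) <- colnames(u) <- samp
  iso <- isoform_table(cts, c(dom = "G1", min1 = "G1", min2 = "G1"), usage = u)
  p <- anova_isoform_usage(iso, samples)
  expect_lt(unname(p["min1"]), 0.01)    # the minor isoform is significant
  call <- call_dtu_genes(iso, p, samples)
  expect_equal(unname(call$dominant["G1"]), "dom")
  expect_false("G1" %in% call$dtu_genes)  # but the gene is not DTU
  expect_false(call$table$dominant_switched[call$table$gene_id == "G1"])

  # now shift the dominant isoform itself
  u2 <- rbind(dom = c(60, 61, 59, 60, 20, 22, 21),
              min1 = c(40, 39, 41, 40, 80, 78, 79))
  cts2 <- u2 * 10; colnames(cts2) <- colnames(u2) <- samp
  iso2 <- isoform_table(cts2, c(dom = "G2", min1 = "G2"), usage = u2)
  call2 <- call_dtu_genes(iso2, anova_isoform_usage(iso2, samples), samples)
  expect_true("G2" %in% call2$dtu_genes)
  expect_true(call2$table$dominant_switched[call2$table$gene_id == "G2"])

  # dominance ties break lexicographically by isoform id
  u3 <- rbind(bbb = c(50, 50, 50, 50, 10, 12, 11),
              aaa = c(50, 50, 50, 50, 90, 88, 89))
  cts3 <- u3 * 10; colnames(cts3) <- colnames(u3) <- samp
  iso3 <- isoform_table(cts3, c(bbb = "G3", aaa = "G3"), usage = u3)
  call3 <- call_dtu_genes(iso3, anova_isoform_usage(iso3, samples), samples)
  expect_equal(unname(call3$dominant["G3"]), "aaa")
})

test_that("the refined non-DEG set is the plain set difference", {
  expect_setequal(derive_nondeg_dtu_minus(c("a", "b", "c"), c("b")), c("a", "c"))
  expect_setequal(derive_nondeg_dtu_minus(c("a", "b"), character(0)), c("a", "b"))
  expect_length(derive_nondeg_dtu_minus(c("a", "b"), c("a", "b", "z")), 0)
  fake <- list(dtu_genes = "b")
  expect_setequal(derive_nondeg_dtu_minus(c("a", "b"), fake), "a")
})
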