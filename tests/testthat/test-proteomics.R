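test_that("Q-value filter applies the one-outlier-per-group rule", {
  groups <- rep(c("a", "b", "c"), each = 4)
  ok <- 1e-5
  bad <- 0.05
  q <- rbind(
    all_pass = rep(ok, 12),
    two_fail_one_group = c(bad, bad, ok, ok, rep(ok, 8)),
    one_fail_each_group = c(bad, rep(ok, 3), bad, rep(ok, 3), bad, rep(ok, 3)),
    na_counts_as_failure = c(NA, bad, rep(ok, 10)))
  keep <- filter_peptides(q, groups)
  expect_equal(unname(keep), c(TRUE, FALSE, TRUE, FALSE))
  # zero Q-values everywhere: everything retained
  expect_true(all(filter_peptides(matrix(0, 5, 12), groups)))
})

test_that("filter retention is monotone in the q threshold", {
  set.seed(1)
  tbl <- generate_peptide_table(n_proteins = 60, q_fail_prob = 0.2, seed = 1)
  k1 <- filter_peptides(tbl$q, tbl$groups, q_max = 1e-3)
  k2 <- filter_peptides(tbl$q, tbl$groups, q_max = 1e-2)
  expect_true(all(k2[k1])) # larger threshold never drops a retained peptide
  expect_gte(sum(k2), sum(k1))
})

test_that("cyclic loess leaves identical samples untouched and removes scale", {
  set.seed(2)
  x <- matrix(rnorm(2000, 20, 2), 1000, 2)
  x[, 2] <- x[, 1]
  out <- cyclic_loess_normalize(x)
  expect_lt(max(abs(out - x)), 1e-6)
  # sample2 = sample1 * 2 (linear): log2 offset of 1 removed
  y <- cbind(x[, 1], x[, 1] + 1)
  yn <- cyclic_loess_normalize(y)
  expect_lt(abs(median(yn[, 2] - yn[, 1])), 0.05)
  # approximate idempotence
  yn2 <- cyclic_loess_normalize(yn)
  expect_lt(max(abs(yn2 - yn)), 1e-3)
  expect_warning(cyclic_loess_normalize(matrix(rnorm(20), 10, 2)),
                 "fewer than 20 features")
})

test_that("roll-up sums linear peptide areas per protein", {
  areas <- rbind(c(3, 1), c(5, 2), c(2, 3), c(7, 7))
  prot <- c("P1", "P1", "P1", "P2")
  out <- rollup_proteins(areas, prot)
  expect_equal(out["P1", ], c(10, 6))
  expect_equal(out["P2", ], c(7, 7)) # single-peptide protein passes through
  # zero-noise generator: roll-up returns exact planted sums
  tbl <- generate_peptide_table(n_proteins = 10, peptides_per_protein = 2,
                                group_sizes = c(control = 2, case = 2),
                                fraction_de = 0, peptide_log2_sd = 0,
                                sample_log2_sd = 0, seed = 3)
  got <- rollup_proteins(tbl$areas, tbl$proteins)
  manual <- rowsum(tbl$areas, tbl$proteins)
  expect_equal(got, manual)
  expect_equal(unname(got[, 1]), unname(got[, 2]), tolerance = 1e-12)
})

test_that("roll-up then group-mean equals group-mean then roll-up", {
  set.seed(4)
  tbl <- generate_peptide_table(n_proteins = 30, seed = 4)
  prot <- rollup_proteins(tbl$areas, tbl$proteins)
  g <- tbl$groups == tbl$control
  a <- rowMeans(prot[, g])
  b <- rollup_proteins(matrix(rowMeans(tbl$areas[, g]), ncol = 1),
                       tbl$proteins)[, 1]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("moderated t reduces to the ordinary t at d0 = 0", {
  set.seed(5)
  mat <- matrix(rnorm(50 * 10, 20), 50, 10)
  groups <- rep(c("ctrl", "case"), each = 5)
  got <- moderated_t(mat, groups, ref = "ctrl", d0 = 0, s02 = 1)
  ref <- apply(mat, 1, function(x) {
    tt <- t.test(x[6:10], x[1:5], var.equal = TRUE)
    c(unname(tt$statistic), tt$p.value)
  })
  expect_equal(got$t, ref[1, ], tolerance = 1e-10)
  expect_equal(got$p, ref[2, ], tolerance = 1e-10)
})

test_that("moderated t uses the prior variance alone at d0 = Inf", {
  set.seed(6)
  mat <- matrix(rnorm(20 * 8, 10), 20, 8)
  groups <- rep(c("ctrl", "case"), each = 4)
  s02 <- 2.5
  got <- moderated_t(mat, groups, ref = "ctrl", d0 = Inf, s02 = s02)
  m <- rowMeans(mat[, 5:8]) - rowMeans(mat[, 1:4])
  expect_equal(got$t, m / sqrt(s02 * (1 / 4 + 1 / 4)), tolerance = 1e-10)
})

test_that("fitted hyperparameters agree with the reference eBayes fit", {
  set.seed(7)
  n <- 500
  truevar <- 0.04 * rchisq(n, 5) / 5
  mat <- matrix(rnorm(n * 21, 0, sqrt(truevar)), n, 21) + 18
  groups <- rep(c("ctrl", "case"), c(14, 7))
  got <- moderated_t(mat, groups, ref = "ctrl")
  design <- cbind(1, as.integer(groups == "case"))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(attr(got, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(got, "s02"), unname(fit$s2.prior), tolerance = 0.02)
  expect_equal(got$t, fit$t[, 2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(got$p, fit$p.value[, 2], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("null moderated-t p-values are uniform with controlled FDR", {
  set.seed(8)
  mat <- matrix(rnorm(2000 * 21, 20, 0.2), 2000, 21)
  groups <- rep(c("ctrl", "case"), c(14, 7))
  got <- moderated_t(mat, groups, ref = "ctrl")
  expect_lt(suppressWarnings(ks.test(got$p, "punif")$statistic), 0.04)
  expect_lt(mean(got$q < 0.05), 0.05)
})

test_that("median CV matches hand arithmetic", {
  mat <- rbind(c(10, 10, 10), c(8, 10, 12))
  cv <- median_cv(mat, rep("g", 3))
  expect_equal(unname(cv), median(c(0, sd(c(8, 10, 12)) / 10)))
  mat2 <- rbind(c(1, 1, 1, 5, 5, 5), c(1, 2, 3, 5, 6, 7))
  cv2 <- median_cv(mat2, rep(c("a", "b"), each = 3))
  expect_equal(names(cv2), c("a", "b"))
  expect_equal(unname(cv2["a"]), median(c(0, 1 / 2)))
})

test_that("the full chain recovers planted differential proteins", {
  tbl <- generate_peptide_table(n_proteins = 400, fraction_de = 0.1,
                                de_fold = 2,
                                group_sizes = c(control = 14, case = 7),
                                seed = 9)
  pp <- proteomics_pipeline(tbl)
  res <- pp$results$case
  truth_de <- sprintf("P%04d", which(tbl$truth$de[, "case"]))
  called <- res$feature[res$q < 0.05]
  sens <- mean(truth_de %in% called)
  fdr <- if (length(called)) mean(!(called %in% truth_de)) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.1)
  expect_true(all(pp$median_cv < 0.2))
})
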