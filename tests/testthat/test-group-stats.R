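# independent oracle: Welch's F evaluated directly from the formula
welch_oracle <- function(values, groups) {
  groups <- factor(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  k <- length(n)
  A <- sum(w * (m - mw)^2) / (k - 1)
  B <- 2 * (k - 2) / (k^2 - 1) * sum((1 - w / sum(w))^2 / (n - 1))
  F <- A / (1 + B)
  df2 <- 1 / (3 / (k^2 - 1) * sum((1 - w / sum(w))^2 / (n - 1)))
  list(F = F, df1 = k - 1, df2 = df2,
       p = pf(F, k - 1, df2, lower.tail = FALSE))
}

test_that("Welch ANOVA matches direct formula evaluation on toy data", {
  v <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  g <- rep(c("A", "B", "C"), each = 3)
  got <- welch_anova(v, g)
  ora <- welch_oracle(v, g)
  expect_equal(got$F, ora$F, tolerance = 1e-6)
  expect_equal(got$df1, ora$df1)
  expect_equal(got$df2, ora$df2, tolerance = 1e-6)
  expect_equal(got$p, ora$p, tolerance = 1e-6)
})

test_that("with two groups Welch's F equals the squared Welch t", {
  set.seed(1)
  v <- c(rnorm(8, 0, 1), rnorm(12, 1, 3))
  g <- rep(c("A", "B"), c(8, 12))
  got <- welch_anova(v, g)
  tt <- t.test(v[g == "A"], v[g == "B"])
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)
})

test_that("Welch p-values are uniform under the null", {
  set.seed(2)
  p <- vapply(1:400, function(i) {
    v <- rnorm(24)
    welch_anova(v, rep(c("A", "B", "C"), each = 8))$p
  }, numeric(1))
  expect_lt(suppressWarnings(ks.test(p, "punif")$statistic), 0.05)
})

test_that("degenerate groupings are rejected", {
  expect_error(welch_anova(1:4, rep("A", 4)), "2 groups")
  expect_error(welch_anova(c(1, 1, 2, 3), rep(c("A", "B"), each = 2)),
               "zero-variance")
  expect_error(welch_anova(c(-1, 2, 3, 4), rep(c("A", "B"), each = 2),
                           log_transform = TRUE), "positive")
})

test_that("classical option reduces to one-way ANOVA", {
  set.seed(3)
  v <- rnorm(30)
  g <- rep(c("A", "B", "C"), each = 10)
  got <- welch_anova(v, g, classical = TRUE)
  ref <- summary(aov(v ~ g))[[1]]
  expect_equal(got$F, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(got$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("one treatment vs control reduces Dunnett to the plain t-test", {
  set.seed(4)
  v <- c(rnorm(10), rnorm(8, 0.5))
  g <- rep(c("Ctrl", "T"), c(10, 8))
  got <- dunnett_test(v, g, "Ctrl")
  # pooled-variance two-sample t
  tt <- t.test(v[g == "T"], v[g == "Ctrl"], var.equal = TRUE)
  expect_equal(got$p_adjusted, tt$p.value, tolerance = 1e-10)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-10)
})

test_that("Dunnett adjusted p dominates the unadjusted p and is seeded", {
  set.seed(5)
  v <- rnorm(40)
  g <- rep(c("Ctrl", "T1", "T2", "T3"), each = 10)
  a <- dunnett_test(v, g, "Ctrl", seed = 7)
  b <- dunnett_test(v, g, "Ctrl", seed = 7)
  expect_identical(a, b)
  expect_true(all(a$p_adjusted >= a$p_unadjusted))
})

test_that("Dunnett adjusted p agrees with the reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(6)
  v <- c(rnorm(12), rnorm(9, 0.8), rnorm(10, -0.3))
  g <- factor(rep(c("Ctrl", "T1", "T2"), c(12, 9, 10)))
  got <- dunnett_test(v, g, "Ctrl")
  fit <- stats::aov(v ~ g)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(gl)$test$pvalues
  expect_equal(got$p_adjusted, as.numeric(ref), tolerance = 0.002)
})

test_that("Dunnett family-wise error is controlled under the null", {
  set.seed(8)
  rej <- vapply(1:300, function(i) {
    v <- rnorm(32)
    g <- rep(c("Ctrl", "T1", "T2", "T3"), each = 8)
    any(dunnett_test(v, g, "Ctrl", seed = i)$p_adjusted < 0.05)
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("BH step-up matches the hand-applied rule and is order invariant", {
  p <- c(0.01, 0.02, 0.04, 0.20)
  out <- bh_fdr(p)
  expect_equal(out$q, c(0.04, 0.04, 0.04 * 4 / 3, 0.20), tolerance = 1e-10)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p[perm])$q, out$q[perm])
  expect_true(all(bh_fdr(rep(1, 5))$significant == FALSE))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})
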