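#' Welch's heteroscedastic one-way ANOVA
#'
#' The default between-genotype omnibus test: Welch's F with
#' Satterthwaite-type denominator degrees of freedom, which does not assume
#' equal group variances. `classical = TRUE` gives the equal-variance one-way
#' ANOVA instead. Values may be natural-log transformed first (positively
#' skewed quantities such as firing rates); non-positive values then raise an
#' error rather than being offset.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @param log_transform Apply `log()` first.
#' @param classical Use the equal-variance one-way ANOVA.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(values, groups, log_transform = FALSE,
                        classical = FALSE) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  n <- table(groups)
  if (any(n < 2)) stop("each group needs at least 2 observations")
  if (log_transform) {
    if (any(values <= 0)) stop("log transform requires strictly positive values")
    values <- log(values)
  }
  v <- tapply(values, groups, var)
  if (!classical && any(v == 0)) {
    stop("zero-variance group: Welch's ANOVA is undefined")
  }
  ft <- oneway.test(values ~ groups, var.equal = classical)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

#' Dunnett's many-to-one post-test
#'
#' Two-sided Dunnett comparisons of every non-control group against the
#' designated control, as used after the omnibus ANOVA. Contrast t statistics
#' use the pooled variance with `N - k` degrees of freedom; the family-wise
#' adjusted p-value of comparison `j` is
#' `1 - P(max_i |T_i| <= |t_j|)` under the joint multivariate-t distribution
#' of the contrasts, whose correlation structure follows from the group sizes
#' (`rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`). The multivariate-t
#' probability is evaluated by seeded quasi-Monte-Carlo integration
#' (absolute tolerance ~5e-4, well inside +/-0.002 on p); with a single
#' treatment group the procedure reduces to the plain two-sided t-test.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param control Control-group label.
#' @param log_transform Natural-log transform first.
#' @param seed Seed for the quasi-Monte-Carlo integration (default 1;
#'   results are deterministic for a fixed seed).
#' @return Data.frame with one row per non-control group: `group`,
#'   `estimate` (mean difference vs control), `t`, `df`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunnett_test <- function(values, groups, control, log_transform = FALSE,
                         seed = 1) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (!control %in% levels(groups)) stop("control group not found: ", control)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (log_transform) {
    if (any(values <= 0)) stop("log transform requires strictly positive values")
    values <- log(values)
  }
  n <- tapply(values, groups, length)
  if (any(n < 2)) stop("each group needs at least 2 observations")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, var)
  N <- sum(n); k <- nlevels(groups)
  df <- N - k
  s2 <- sum((n - 1) * v) / df
  if (s2 == 0) stop("zero pooled variance")
  trt <- setdiff(levels(groups), control)
  est <- m[trt] - m[control]
  se <- sqrt(s2 * (1 / n[trt] + 1 / n[control]))
  tstat <- est / se
  p_un <- 2 * pt(-abs(tstat), df)
  if (length(trt) == 1) {
    p_adj <- p_un
  } else {
    lam <- sqrt(n[trt] / (n[trt] + n[control]))
    R <- outer(lam, lam)
    diag(R) <- 1
    p_adj <- vapply(abs(tstat), function(q) {
      set.seed(seed)
      pr <- mvtnorm::pmvt(lower = rep(-q, length(trt)),
                          upper = rep(q, length(trt)),
                          df = as.integer(round(df)), corr = R,
                          algorithm = mvtnorm::GenzBretz(maxpts = 100000,
                                                         abseps = 5e-4))
      1 - as.numeric(pr)
    }, numeric(1))
    p_adj <- pmin(pmax(p_adj, p_un), 1)
  }
  data.frame(group = trt, estimate = unname(est), t = unname(tstat),
             df = df, p_unadjusted = unname(p_un),
             p_adjusted = unname(p_adj), row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values with the significance set at the requested FDR
#' level (default 0.05).
#'
#' @param p P-values in `[0, 1]`.
#' @param alpha FDR level for the `significant` flag.
#' @return List with `q` (adjusted values, same order as `p`) and
#'   `significant` (logical, `q < alpha`).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- p.adjust(p, method = "BH")
  list(q = q, significant = q < alpha)
}
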