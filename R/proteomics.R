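#' Filter peptides by identification Q-value
#'
#' A peptide is retained iff, within every sample group, at most
#' `outliers_allowed` samples have `Q > q_max` (the one-outlier-per-group
#' allowance at the stringent 1e-3 confidence threshold). Missing Q-values
#' count as failures.
#'
#' @param q Peptides x samples Q-value matrix.
#' @param groups Per-sample group labels.
#' @param q_max Confidence threshold (default 1e-3; the library standard
#'   would be 1e-2).
#' @param outliers_allowed Failing samples tolerated per group.
#' @return Logical vector: `TRUE` for retained peptides.
#' @export
filter_peptides <- function(q, groups, q_max = 1e-3, outliers_allowed = 1) {
  q <- as.matrix(q)
  stopifnot(length(groups) == ncol(q), q_max > 0, outliers_allowed >= 0)
  fail <- is.na(q) | q > q_max
  keep <- rep(TRUE, nrow(q))
  for (g in unique(groups)) {
    nfail <- rowSums(fail[, groups == g, drop = FALSE])
    keep <- keep & nfail <= outliers_allowed
  }
  keep
}

#' Cyclic loess normalization of log2 abundances
#'
#' Intensity-dependent (MA-trend) normalization across samples, cycled until
#' the largest per-sample median change falls below `tol` or `max_iterations`
#' cycles have run. The default `"fast"` variant fits each sample's loess
#' against the mean of all samples; `"pairs"` cycles over all sample pairs.
#'
#' @param log2_mat Features x samples matrix of log2 abundances.
#' @param method `"fast"` or `"pairs"`.
#' @param max_iterations Cycle cap (default 3).
#' @param tol Convergence tolerance on the per-sample median change.
#' @param span Loess span.
#' @return Normalized matrix of the same shape; attribute `iterations` gives
#'   the number of cycles run.
#' @export
cyclic_loess_normalize <- function(log2_mat, method = c("fast", "pairs"),
                                   max_iterations = 3, tol = 1e-3,
                                   span = 0.7) {
  method <- match.arg(method)
  x <- as.matrix(log2_mat)
  if (ncol(x) < 2) stop("need at least 2 samples")
  if (nrow(x) < 20) {
    warning("fewer than 20 features: loess trend estimates are unreliable")
  }
  it <- 0L
  for (i in seq_len(max_iterations)) {
    xn <- limma::normalizeCyclicLoess(x, method = method, iterations = 1,
                                      span = span)
    it <- i
    delta <- max(abs(apply(xn - x, 2, median)))
    x <- xn
    if (delta < tol) break
  }
  dimnames(x) <- dimnames(log2_mat)
  structure(x, iterations = it)
}

#' Roll peptides up to protein abundances by summation
#'
#' Protein abundance per sample is the sum of the linear-scale normalized
#' peak areas of its retained peptides (summation, not mean or median).
#' Proteins left with no retained peptides are absent from the output.
#'
#' @param areas Peptides x samples matrix of linear-scale areas.
#' @param proteins Per-peptide protein assignment.
#' @return Proteins x samples matrix.
#' @export
rollup_proteins <- function(areas, proteins) {
  areas <- as.matrix(areas)
  stopifnot(length(proteins) == nrow(areas))
  if (nrow(areas) == 0) {
    message("no peptides to roll up")
    return(matrix(numeric(0), 0, ncol(areas),
                  dimnames = list(NULL, colnames(areas))))
  }
  rowsum(areas, group = proteins, reorder = TRUE)
}

# Newton solve of trigamma(y) = x (vectorized), as used by the
# method-of-moments fit of the variance prior.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per-protein pooled residual variances are shrunk toward a common prior by
#' fitting a scaled inverse-chi-square distribution across proteins
#' (hyperparameters: prior degrees of freedom `d0` and prior variance `s02`,
#' estimated by method-of-moments on the log residual variances). The
#' moderated t uses the posterior variance
#' `(d0 * s02 + d * s2) / (d0 + d)` with `d0 + d` degrees of freedom.
#' `d0 = 0` recovers the ordinary two-sample t; `d0 = Inf` uses the prior
#' variance alone. Benjamini-Hochberg q-values are appended.
#'
#' @param mat Features x samples matrix of log2 abundances.
#' @param groups Per-sample labels with exactly 2 levels; the fold change is
#'   level 2 minus level 1 (set `ref` to pick the reference level).
#' @param ref Optional reference (denominator) group.
#' @param d0,s02 Optional fixed hyperparameters (both must be given
#'   together); default: fitted from the data.
#' @return Data.frame (`feature`, `logFC`, `t`, `df`, `p`, `q`) with
#'   attributes `d0` and `s02`. Features with zero residual variance in both
#'   groups are excluded (with a message) from the fit and the output.
#' @export
moderated_t <- function(mat, groups, ref = NULL, d0 = NULL, s02 = NULL) {
  mat <- as.matrix(mat)
  groups <- factor(groups)
  stopifnot(ncol(mat) == length(groups))
  if (nlevels(groups) != 2) stop("moderated_t expects exactly 2 groups")
  if (!is.null(ref)) groups <- stats::relevel(groups, ref = ref)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  x1 <- mat[, groups == levels(groups)[1], drop = FALSE]
  x2 <- mat[, groups == levels(groups)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  d <- n1 + n2 - 2
  s2 <- ss / d
  zero <- s2 <= 0
  if (any(zero)) {
    message(sum(zero), " feature(s) with zero residual variance excluded")
  }
  keep <- which(!zero)
  s2k <- s2[keep]
  if ((is.null(d0) || is.null(s02)) && length(keep) < 2) {
    stop("too few features with positive variance to fit the prior")
  }
  if (is.null(d0) || is.null(s02)) {
    # moments of log(s2): E[log s2] and Var[log s2] under the scaled
    # inverse-chi-square model
    e <- log(s2k) - digamma(d / 2) + log(d / 2)
    ev <- var(e) - trigamma(d / 2)
    if (is.finite(ev) && ev > 0) {
      d0 <- 2 * trigamma_inverse(ev)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(mean(e))
    }
  }
  stopifnot(d0 >= 0, s02 > 0)
  s2_post <- if (is.infinite(d0)) rep(s02, length(keep)) else
    (d0 * s02 + d * s2k) / (d0 + d)
  lfc <- (m2 - m1)[keep]
  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- min(d + d0, 1e6)
  p <- 2 * pt(-abs(tstat), df_total)
  q <- p.adjust(p, method = "BH")
  fn <- rownames(mat)
  if (is.null(fn)) fn <- as.character(seq_len(nrow(mat)))
  structure(data.frame(feature = fn[keep], logFC = unname(lfc),
                       t = unname(tstat), df = df_total, p = unname(p),
                       q = unname(q), row.names = NULL),
            d0 = d0, s02 = s02)
}

#' Per-group median coefficient of variation
#'
#' CV (SD/mean on the linear scale) per feature within each group; the
#' reported figure of merit is the median CV across features per group.
#' Features with non-positive mean in a group are excluded from that group's
#' median.
#'
#' @param mat Features x samples matrix (linear scale).
#' @param groups Per-sample group labels.
#' @return Named numeric vector of per-group median CVs.
#' @export
median_cv <- function(mat, groups) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(groups))
  vapply(unique(groups), function(g) {
    x <- mat[, groups == g, drop = FALSE]
    if (ncol(x) < 2) stop("group ", g, " needs at least 2 samples")
    mu <- rowMeans(x)
    cv <- apply(x, 1, sd) / mu
    median(cv[mu > 0])
  }, numeric(1))
}

#' Full SWATH-style differential-abundance chain
#'
#' Runs the quantification chain on a peptide table: Q-value filtering (one
#' outlier allowed per group), cyclic loess normalization of log2 peptide
#' areas, summation roll-up to proteins, and a moderated-t contrast of each
#' non-control group against the control, with BH correction. Also reports
#' the per-group median protein CV.
#'
#' @param tbl A peptide table as from [generate_peptide_table()] (list with
#'   `areas`, `q`, `proteins`, `groups`, `control`).
#' @param q_max,outliers_allowed Passed to [filter_peptides()].
#' @param fdr FDR level for the significant sets.
#' @param normalize_method Passed to [cyclic_loess_normalize()].
#' @return List with `results` (per non-control group: [moderated_t()]
#'   data.frame), `significant` (per group: feature ids at `q < fdr`),
#'   `median_cv`, `n_peptides_retained`, `n_proteins`, `protein_log2`
#'   (the protein x sample log2 matrix).
#' @export
proteomics_pipeline <- function(tbl, q_max = 1e-3, outliers_allowed = 1,
                                fdr = 0.05, normalize_method = "fast") {
  keep <- filter_peptides(tbl$q, tbl$groups, q_max, outliers_allowed)
  areas <- tbl$areas[keep, , drop = FALSE]
  prot <- tbl$proteins[keep]
  norm_log2 <- cyclic_loess_normalize(log2(areas), method = normalize_method)
  prot_mat <- rollup_proteins(2^norm_log2, prot)
  prot_log2 <- log2(prot_mat)
  trt <- setdiff(unique(tbl$groups), tbl$control)
  results <- lapply(trt, function(g) {
    sel <- tbl$groups %in% c(tbl$control, g)
    moderated_t(prot_log2[, sel, drop = FALSE], tbl$groups[sel],
                ref = tbl$control)
  })
  names(results) <- trt
  list(results = results,
       significant = lapply(results, function(r) r$feature[r$q < fdr]),
       median_cv = median_cv(prot_mat, tbl$groups),
       n_peptides_retained = sum(keep),
       n_proteins = nrow(prot_mat),
       protein_log2 = prot_log2)
}
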