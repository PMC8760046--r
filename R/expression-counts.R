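#' geNorm reference-gene stability
#'
#' For each reference gene j, the stability measure `M_j` is the mean over
#' all other reference genes k of the SD across samples of
#' `log2(count_j / count_k)`; low M means stable expression relative to the
#' panel. The per-sample normalization factor is the geometric mean of the
#' retained reference genes, rescaled to geometric mean 1 across samples.
#'
#' @param ref_counts Reference genes x samples matrix of positive counts.
#' @param iterate Iteratively drop the least stable gene (highest M) until
#'   only 2 remain, recomputing factors from the retained set. Off by
#'   default: the emulated study kept its full reference panel.
#' @return List with `M` (named per-gene stability, full panel), `retained`
#'   (gene names used for the factors), `factors` (per-sample normalization
#'   factor, geometric mean 1).
#' @export
genorm_stability <- function(ref_counts, iterate = FALSE) {
  ref_counts <- as.matrix(ref_counts)
  if (nrow(ref_counts) < 2) stop("geNorm needs at least 2 reference genes")
  if (any(ref_counts <= 0)) stop("geNorm requires strictly positive counts")
  if (is.null(rownames(ref_counts))) {
    rownames(ref_counts) <- paste0("ref", seq_len(nrow(ref_counts)))
  }
  lg <- log2(ref_counts)
  M_of <- function(lgm) {
    vapply(seq_len(nrow(lgm)), function(j) {
      mean(vapply(setdiff(seq_len(nrow(lgm)), j), function(k) {
        sd(lgm[j, ] - lgm[k, ])
      }, numeric(1)))
    }, numeric(1))
  }
  M <- setNames(M_of(lg), rownames(ref_counts))
  keep <- rownames(ref_counts)
  if (iterate) {
    cur <- lg
    while (nrow(cur) > 2) {
      Mi <- M_of(cur)
      cur <- cur[-which.max(Mi), , drop = FALSE]
    }
    keep <- rownames(cur)
  }
  geo <- exp(colMeans(log(ref_counts[keep, , drop = FALSE])))
  factors <- geo / exp(mean(log(geo)))
  list(M = M, retained = keep, factors = factors)
}

#' Normalize codeset counts with control mean set to 1
#'
#' Normalization chain for hybridization-based digital counts: an optional
#' positive-control stage (per-sample geometric mean of positive-control
#' probes rescaled to the cohort mean, the vendor convention), division by
#' the geNorm reference-gene factor, then scaling each gene by its
#' control-group mean so that the control mean equals 1.
#'
#' @param counts Genes x samples matrix of counts.
#' @param roles Per-gene roles: `"target"`, `"reference"` or
#'   `"positive-control"`.
#' @param groups Per-sample group labels.
#' @param control Control-group label.
#' @param use_positive_controls Apply the positive-control stage when such
#'   probes are present.
#' @param genorm_iterate Passed to [genorm_stability()].
#' @return List with `normalized` (genes x samples, control mean 1 per gene),
#'   `genorm` (the [genorm_stability()] result), `positive_factors`.
#' @export
normalize_counts <- function(counts, roles, groups, control,
                             use_positive_controls = TRUE,
                             genorm_iterate = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(length(roles) == nrow(counts), length(groups) == ncol(counts))
  in_ctrl <- groups == control
  if (!any(in_ctrl)) stop("control group is empty")
  pos_factors <- rep(1, ncol(counts))
  x <- counts
  if (use_positive_controls && any(roles == "positive-control")) {
    pos <- counts[roles == "positive-control", , drop = FALSE]
    if (any(pos <= 0)) stop("positive-control counts must be positive")
    geo <- exp(colMeans(log(pos)))
    pos_factors <- geo / mean(geo)
    x <- sweep(x, 2, pos_factors, "/")
  }
  gn <- genorm_stability(x[roles == "reference", , drop = FALSE],
                         iterate = genorm_iterate)
  x <- sweep(x, 2, gn$factors, "/")
  ctrl_mean <- rowMeans(x[, in_ctrl, drop = FALSE])
  if (any(ctrl_mean == 0)) stop("zero control-group mean for some gene")
  x <- sweep(x, 1, ctrl_mean, "/")
  list(normalized = x, genorm = gn, positive_factors = pos_factors)
}

#' Fold change between count aggregates
#'
#' `fold = aggregate(numerator) / aggregate(denominator)`. With
#' `aggregation = "ratio_mean"` the per-line ratios are averaged (numerator
#' and denominator paired element-wise); `"pooled"` sums both sides first.
#' An explicit rounding mode reproduces how worked examples are reported
#' (e.g. integer fold for large overexpression, one decimal near 1).
#'
#' @param numerator,denominator Positive count vectors (paired for
#'   `"ratio_mean"`).
#' @param aggregation `"ratio_mean"` or `"pooled"`.
#' @param digits Optional rounding digits (`0` for integer fold).
#' @return The fold change (numeric scalar).
#' @export
fold_change <- function(numerator, denominator,
                        aggregation = c("ratio_mean", "pooled"),
                        digits = NULL) {
  aggregation <- match.arg(aggregation)
  if (any(denominator <= 0)) stop("denominator counts must be positive")
  fold <- switch(aggregation,
                 ratio_mean = {
                   stopifnot(length(numerator) == length(denominator))
                   mean(numerator / denominator)
                 },
                 pooled = sum(numerator) / sum(denominator))
  if (!is.null(digits)) fold <- round(fold, digits)
  fold
}
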