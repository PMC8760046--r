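#' Generate a ground-truthed codeset count table
#'
#' Negative-binomial counts for a panel of target and reference genes across
#' sample groups, with per-sample library-size factors and planted
#' fold-changes on target genes (reference genes always have fold 1).
#' Defaults mirror the emulated codeset: 12 target and 6 reference genes,
#' a control cohort of 11 and a transgenic cohort of 8.
#'
#' @param n_target,n_reference Number of target / reference genes.
#' @param group_sizes Named sample counts; the first group is the control.
#' @param planted_folds Per-target-gene fold change of each non-control group
#'   vs control: a vector (recycled across target genes; applies to every
#'   non-control group) or a matrix `n_target x (n_groups - 1)`.
#' @param base_median_counts Median baseline expression (counts).
#' @param dispersion Negative-binomial `size` parameter (larger = less
#'   overdispersed); digital counting is near-Poisson, default 50.
#' @param libsize_sdlog Log-scale SD of per-sample library factors.
#' @param seed Optional seed.
#' @return List with `counts` (genes x samples), `roles`, `groups`,
#'   `control`, `truth` (planted folds, library factors, base means).
#' @export
generate_count_table <- function(n_target = 12, n_reference = 6,
                                 group_sizes = c(control = 11, case = 8),
                                 planted_folds = 1,
                                 base_median_counts = 1000,
                                 dispersion = 50,
                                 libsize_sdlog = 0.15,
                                 seed = NULL) {
  stopifnot(n_target >= 1, n_reference >= 2, length(group_sizes) >= 2,
            all(group_sizes >= 1), all(planted_folds > 0), dispersion > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- c("control", paste0("group", seq_len(length(group_sizes) - 1)))
  }
  control <- names(group_sizes)[1]
  n_groups <- length(group_sizes)
  folds <- matrix(planted_folds, nrow = n_target, ncol = n_groups - 1)
  groups <- rep(names(group_sizes), group_sizes)
  n_samples <- length(groups)
  n_genes <- n_target + n_reference
  roles <- c(rep("target", n_target), rep("reference", n_reference))
  genes <- c(sprintf("target%02d", seq_len(n_target)),
             sprintf("ref%02d", seq_len(n_reference)))
  base <- base_median_counts * rlnorm(n_genes, 0, 1)
  lib <- rlnorm(n_samples, 0, libsize_sdlog)
  mu <- matrix(base, n_genes, n_samples)
  for (g in seq_len(n_groups - 1)) {
    cols <- groups == names(group_sizes)[g + 1]
    mu[seq_len(n_target), cols] <- mu[seq_len(n_target), cols] * folds[, g]
  }
  mu <- sweep(mu, 2, lib, "*")
  counts <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = dispersion),
                   n_genes, n_samples,
                   dimnames = list(genes, paste0("s", seq_len(n_samples))))
  list(counts = counts, roles = roles, groups = groups, control = control,
       truth = list(folds = folds, lib_factors = lib, base_means = base))
}

#' Generate a ground-truthed peptide abundance table with Q-values
#'
#' Log-normal peptide peak areas for proteins quantified across sample
#' groups, with planted differential abundance at the protein level,
#' per-sample loading factors, and per peptide-sample identification
#' Q-values of which a configurable fraction exceed the confidence threshold.
#' Default group sizes mirror the emulated design (14 control, 7 + 7
#' transgenic animals).
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Peptides per protein (scalar or per-protein
#'   vector); must be at least 1.
#' @param group_sizes Named sample counts; the first group is the control.
#' @param fraction_de Fraction of proteins differentially abundant in each
#'   non-control group (independent draws per group).
#' @param de_fold Linear fold change planted on DE proteins (direction
#'   random per protein-group).
#' @param peptide_log2_sd Residual peptide-level noise (log2 SD). The default
#'   0.25 with 3 peptides per protein yields protein-level CVs near the
#'   10-13% range typical of the emulated SWATH quantification.
#' @param sample_log2_sd Log2 SD of per-sample loading factors (removed by
#'   normalization).
#' @param q_fail_prob Probability that a peptide-sample Q-value exceeds 1e-3.
#' @param seed Optional seed.
#' @return List with `areas` (peptides x samples, linear scale), `q`
#'   (matching Q-value matrix), `proteins` (per-peptide protein id),
#'   `groups`, `control`, `truth` (logical DE matrix proteins x non-control
#'   groups, signed log2 folds, sample factors).
#' @export
generate_peptide_table <- function(n_proteins = 200, peptides_per_protein = 3,
                                   group_sizes = c(control = 14, sh_wt = 7,
                                                   sh_rx = 7),
                                   fraction_de = 0.1, de_fold = 2,
                                   peptide_log2_sd = 0.25,
                                   sample_log2_sd = 0.2,
                                   q_fail_prob = 0.02, seed = NULL) {
  stopifnot(n_proteins >= 1, all(peptides_per_protein >= 1),
            length(group_sizes) >= 2, all(group_sizes >= 2),
            fraction_de >= 0, fraction_de <= 1, de_fold > 0,
            peptide_log2_sd >= 0, sample_log2_sd >= 0,
            q_fail_prob >= 0, q_fail_prob < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- c("control", paste0("group", seq_len(length(group_sizes) - 1)))
  }
  control <- names(group_sizes)[1]
  npp <- rep(peptides_per_protein, length.out = n_proteins)
  proteins <- rep(sprintf("P%04d", seq_len(n_proteins)), npp)
  n_pep <- length(proteins)
  groups <- rep(names(group_sizes), group_sizes)
  n_samples <- length(groups)
  trt <- names(group_sizes)[-1]

  prot_base <- rnorm(n_proteins, 20, 2)             # log2 protein abundance
  pep_off <- rnorm(n_pep, 0, 1)                     # ionization efficiency
  samp <- rnorm(n_samples, 0, sample_log2_sd)       # loading factors
  de <- matrix(runif(n_proteins * length(trt)) < fraction_de,
               n_proteins, length(trt), dimnames = list(NULL, trt))
  lfc <- matrix(0, n_proteins, length(trt), dimnames = list(NULL, trt))
  lfc[de] <- sample(c(-1, 1), sum(de), replace = TRUE) * log2(de_fold)

  pidx <- rep(seq_len(n_proteins), npp)
  log2a <- matrix(prot_base[pidx] + pep_off, n_pep, n_samples)
  log2a <- sweep(log2a, 2, samp, "+")
  for (g in trt) {
    cols <- groups == g
    log2a[, cols] <- log2a[, cols] + lfc[pidx, g]
  }
  if (peptide_log2_sd > 0) {
    log2a <- log2a + rnorm(n_pep * n_samples, 0, peptide_log2_sd)
  }
  q <- matrix(10^runif(n_pep * n_samples, -8, -4), n_pep, n_samples)
  fail <- runif(n_pep * n_samples) < q_fail_prob
  q[fail] <- 10^runif(sum(fail), -2.9, -1)
  sn <- paste0(groups, ".", stats::ave(seq_len(n_samples), groups, FUN = seq_along))
  dimnames(q) <- list(NULL, sn)
  areas <- 2^log2a
  dimnames(areas) <- list(NULL, sn)
  list(areas = areas, q = q, proteins = proteins, groups = groups,
       control = control,
       truth = list(de = de, log2_folds = lfc, sample_log2 = samp))
}
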