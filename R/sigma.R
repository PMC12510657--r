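#' Equipartition sigma score for one gene
#'
#' Rescales a gene's mutational energy to a dimensionless per-residue score
#' relative to the group-wide average:
#' \deqn{\sigma_i = \frac{L \, E_i}{L_i \, E}}
#' where \eqn{E_i} is the gene's energy, \eqn{L_i} its protein length in
#' residues, \eqn{E} the total energy over all genes in the group and
#' \eqn{L} the total proteomic length. Under equipartition -- mutational
#' energy uniform per residue -- every gene scores exactly 1.
#'
#' @param E_i Gene energy (>= 0).
#' @param L_i Gene length in residues (>= 1).
#' @param E Total group energy (> 0).
#' @param L Total proteomic length (>= L_i).
#' @return Dimensionless sigma score.
#' @examples
#' sigmaScore(10, 100, 20, 400)  # 2
#' @export
sigmaScore <- function(E_i, L_i, E, L) {
  if (any(E <= 0)) stop("group has zero total energy")
  stopifnot(all(L_i >= 1), all(L >= L_i), all(E_i >= 0))
  (L * E_i) / (L_i * E)
}

# sigma profile for a set of sample columns; G is genes x samples energy
sigma_profile <- function(G, cols, L_i, L) {
  E_i <- Matrix::rowSums(G[, cols, drop = FALSE])
  E <- sum(E_i)
  if (E <= 0) stop("group has zero total energy")
  (L * E_i) / (L_i * E)
}

#' Case/control difference in equipartition sigma scores
#'
#' Computes sigma within each arm separately (energies and the total energy
#' are arm-specific; the proteomic length total covers every modelled gene)
#' and returns \eqn{\Delta\sigma_i = \sigma_i^{controls} -
#' \sigma_i^{cases}}. A positive value therefore means *lower* relative
#' burden in cases; the permutation z of [sigmaDiff()] is oriented the
#' opposite way (positive z = higher case burden).
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param mode Energy counting mode, see [geneEnergyMatrix()].
#' @return `data.frame` with `gene_id`, `sigma_cases`, `sigma_controls`,
#'   `delta`.
#' @export
sigmaDelta <- function(cohort, mode = "dosage") {
  G <- geneEnergyMatrix(cohort, mode = mode)
  L_i <- geneLengths(cohort)
  L <- sum(L_i)
  lab <- sampleLabels(cohort)
  if (!any(lab == "case") || !any(lab == "control"))
    stop("both arms must be nonempty")
  sc <- sigma_profile(G, which(lab == "case"), L_i, L)
  sk <- sigma_profile(G, which(lab == "control"), L_i, L)
  data.frame(gene_id = names(L_i), sigma_cases = as.numeric(sc),
             sigma_controls = as.numeric(sk),
             delta = as.numeric(sk - sc), row.names = NULL)
}

#' Sigma-Diff: label-permutation z-scores for differential burden
#'
#' The observed statistic per gene is \eqn{\sigma_i^{cases} -
#' \sigma_i^{controls}}, oriented so that a positive z-score indicates
#' higher mutational burden in cases (potentially causative) and a negative
#' z-score higher burden in controls (potentially protective). Case/control
#' labels are permuted `n_perm` times preserving arm sizes; each gene's z is
#' the observed statistic standardized by the mean and standard deviation of
#' its permutation null, with `p = 2 * pnorm(-|z|)`. An empirical two-sided
#' rank p-value, floored at `1/(n_perm + 1)`, is reported alongside. Genes
#' whose null has zero spread (e.g. no qualifying alleles) are flagged
#' `degenerate` and excluded from significance calls.
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param n_perm Number of label permutations (default 1000; a warning is
#'   issued below 100 where z is unstable).
#' @param seed Integer seed; results are reproducible under a fixed seed.
#' @param z_call Absolute z threshold for the significance call (default 3).
#' @param mode Energy counting mode, see [geneEnergyMatrix()].
#' @return `data.frame` with one row per modelled gene: `gene_id`,
#'   `sigma_cases`, `sigma_controls`, `delta` (stored as controls - cases),
#'   `z`, `p` (two-sided normal tail), `p_emp` (empirical rank),
#'   `significant`, `degenerate`, `n_perm`.
#' @examples
#' sim <- simulateCohort(simParams(n_cases = 60, n_controls = 60,
#'                                 n_genes = 30, seed = 3))
#' head(sigmaDiff(sim$cohort, n_perm = 100, seed = 1))
#' @export
sigmaDiff <- function(cohort, n_perm = 1000, seed = 1, z_call = 3,
                      mode = "dosage") {
  stopifnot(n_perm >= 1)
  if (n_perm < 100)
    warning("n_perm < 100: permutation z-scores will be unstable")
  G <- geneEnergyMatrix(cohort, mode = mode)
  L_i <- geneLengths(cohort)
  L <- sum(L_i)
  lab <- sampleLabels(cohort)
  n_case <- sum(lab == "case"); n_ctrl <- sum(lab == "control")
  if (n_case == 0 || n_ctrl == 0) stop("both arms must be nonempty")
  n <- length(lab)

  tot <- Matrix::rowSums(G)
  stat_from_cases <- function(EC) {
    # EC: genes x k matrix of case energies per relabeling
    EK <- tot - EC
    sC <- sum_guard(Matrix::colSums(EC))
    sK <- sum_guard(Matrix::colSums(EK))
    sweep2 <- (L / L_i) * (sweep(EC, 2, sC, "/") - sweep(EK, 2, sK, "/"))
    sweep2
  }
  sum_guard <- function(s) {
    if (any(s <= 0)) stop("group has zero total energy")
    s
  }

  obs <- stat_from_cases(as.matrix(Matrix::rowSums(G[, lab == "case",
                                                     drop = FALSE])))[, 1]
  null_mat <- local_seed(seed, {
    P <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) P[sample.int(n, n_case), b] <- 1
    as.matrix(G %*% P)
  })
  null_stat <- stat_from_cases(null_mat)
  mu <- rowMeans(null_stat)
  s <- apply(null_stat, 1, sd)
  degenerate <- s == 0 | tot == 0
  z <- ifelse(degenerate, NA_real_, (obs - mu) / s)
  p <- 2 * pnorm(-abs(z))
  p_emp <- (1 + rowSums(abs(null_stat) >= abs(obs))) / (n_perm + 1)
  p_emp[degenerate] <- NA_real_
  d <- sigmaDelta(cohort, mode = mode)
  data.frame(gene_id = d$gene_id,
             sigma_cases = d$sigma_cases,
             sigma_controls = d$sigma_controls,
             delta = d$delta,
             z = z, p = p, p_emp = p_emp,
             significant = !degenerate & !is.na(z) & abs(z) >= z_call,
             degenerate = degenerate,
             n_perm = n_perm, row.names = NULL)
}
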