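#' @importFrom stats pnorm phyper fisher.test p.adjust ks.test rbinom rpois
#'   rnorm runif rbeta rlnorm setNames sd qnorm
NULL

# Evaluate `expr` under a locally seeded RNG, restoring the caller's stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child-seed derivation so any grid cell can be re-run alone.
child_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1000003 + as.numeric(p) + 12289) %% 2147483629
  as.integer(h) + 1L
}

#' Exome-wide Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_genes Number of genes tested (default 18000, the approximate
#'   size of the protein-coding exome).
#' @return `alpha / n_genes`.
#' @examples
#' signif(bonferroniThreshold(), 2)  # 2.8e-06
#' @export
bonferroniThreshold <- function(alpha = 0.05, n_genes = 18000) {
  stopifnot(alpha > 0, n_genes >= 1)
  alpha / n_genes
}

#' Expected false positives per exome-wide scan
#'
#' Under a per-gene significance threshold `p_threshold` applied to
#' `n_genes` null genes, the expected number of false-positive calls is
#' their product.
#'
#' @param p_threshold Per-gene p-value threshold (default 1e-5).
#' @param n_genes Number of genes scanned (default 18000).
#' @return Expected false-positive count.
#' @examples
#' expectedFalsePositives()  # 0.18, i.e. roughly 0.2 per scan
#' @export
expectedFalsePositives <- function(p_threshold = 1e-5, n_genes = 18000) {
  stopifnot(p_threshold > 0, p_threshold < 1, n_genes >= 1)
  p_threshold * n_genes
}

#' Area under the ROC curve by mid-rank ties
#'
#' Mann-Whitney formulation: with `R` the mid-ranks of the positive class
#' among all scores, AUROC = (sum(R) - n1(n1+1)/2) / (n1 n0). When every
#' score is equal this yields exactly 0.5.
#'
#' @param scores Numeric vector; larger = more positive-like.
#' @param positive Logical vector marking the positive class.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: samples within each class dealt round-robin
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  fold
}
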