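#' Cauchy combination test (CCT) for one gene
#'
#' Combines `d` component p-values through the tangent transform
#' \deqn{T = \sum_{i=1}^{d} \omega_i \tan\{(0.5 - p_i)\pi\}, \qquad
#'       p = 0.5 - \arctan(T)/\pi}
#' with nonnegative weights summing to 1 (equal by default). Each
#' transformed term is standard Cauchy under a uniform null, so the tail of
#' `T` stays approximately Cauchy under arbitrary correlation between the
#' components. Input p-values equal to 1 are clipped to `1 - 1e-15` before
#' the transform (permutation p-values can equal 1; the untruncated
#' transform would be -Inf).
#'
#' In 64-bit arithmetic the back-transform cannot produce a value below
#' `2^-54` (about 5.6e-17): smaller true p-values evaluate to zero. Such
#' results are returned with `floored = TRUE`, the numeric value pinned at
#' `2^-54` for ranking, and the display label `"<5.6e-17"`.
#'
#' @param p Numeric vector of component p-values in (0, 1].
#' @param weights Optional nonnegative weights, renormalized to sum to 1;
#'   equal weights when `NULL`.
#' @return List with `T`, `p` (numeric, floored at `2^-54`), `floored`
#'   (logical) and `label` (the p-value as printed, `"<5.6e-17"` when
#'   floored).
#' @examples
#' cauchyCombine(c(0.5, 0.5, 0.5))$p          # 0.5
#' cauchyCombine(0.05)$p                      # 0.05: single p is returned
#' cauchyCombine(rep(1e-20, 3))$label         # "<5.6e-17"
#' @export
cauchyCombine <- function(p, weights = NULL) {
  if (length(p) < 1) stop("no combinable evidence")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("component p-values must lie in (0, 1]")
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  if (length(weights) != length(p) || any(weights < 0))
    stop("weights must be nonnegative, one per p-value")
  weights <- weights / sum(weights)
  p_clip <- pmin(p, 1 - 1e-15)
  T_stat <- sum(weights * tan((0.5 - p_clip) * pi))
  p_out <- 0.5 - atan(T_stat) / pi
  floored <- p_out <= 0
  if (floored) p_out <- 2^-54
  list(T = T_stat, p = p_out, floored = floored,
       label = if (floored) "<5.6e-17" else format(p_out))
}

#' Smallest representable Cauchy-combination p-value
#'
#' Scans the back-transform `p = 0.5 - atan(T)/pi` over increasing `T` in
#' IEEE-754 double precision and returns the smallest strictly positive
#' result. This equals the spacing below 0.5, `2^-54` (about 5.6e-17): any
#' combined p-value smaller than this underflows to zero and is reported as
#' `"<5.6e-17"`.
#'
#' @return The floor as a double (`2^-54`).
#' @export
cctFloor <- function() {
  T_grid <- 10^seq(8, 20, length.out = 5000)
  p <- 0.5 - atan(T_grid) / pi
  min(p[p > 0])
}

#' Combine component p-values across a cohort of genes
#'
#' Applies [cauchyCombine()] per gene over the available component
#' p-values. Masked or missing components (`NA`) are dropped for that gene
#' and the weights renormalized equally over the remainder. Genes with no
#' combinable component are excluded with a warning. Ranks are assigned
#' over all combined genes with minimum-rank ties (all genes at the
#' underflow floor share rank 1).
#'
#' @param components `data.frame` with column `gene_id` and one column per
#'   component p-value (any columns starting with `p_`, e.g. `p_eaml`,
#'   `p_sigma`, `p_network`). `NA` marks an unavailable component.
#' @param mask Character vector of gene ids whose network component is
#'   masked (from [controlMask()]); their `p_network` is dropped before
#'   combination.
#' @param weights Optional named weights per component column; equal over
#'   unmasked components when `NULL`.
#' @return `data.frame` with `gene_id`, `T`, `p` (numeric), `p_label`,
#'   `floored`, `rank`, `masked_network`, `n_combined`.
#' @export
combineComponents <- function(components, mask = character(),
                              weights = NULL) {
  stopifnot(is.data.frame(components), "gene_id" %in% colnames(components))
  pcols <- grep("^p_", colnames(components), value = TRUE)
  if (length(pcols) == 0) stop("no component p-value columns (p_*)")
  P <- as.matrix(components[, pcols, drop = FALSE])
  if ("p_network" %in% pcols && length(mask))
    P[components$gene_id %in% mask, "p_network"] <- NA
  bad <- !is.na(P) & (P <= 0 | P > 1)
  if (any(bad)) stop("component p-values must lie in (0, 1]")
  n_comb <- rowSums(!is.na(P))
  if (any(n_comb == 0)) {
    warning(sum(n_comb == 0), " gene(s) with no combinable evidence excluded")
    keep <- n_comb > 0
    components <- components[keep, , drop = FALSE]
    P <- P[keep, , drop = FALSE]
    n_comb <- n_comb[keep]
  }
  if (nrow(P) == 0) stop("no combinable evidence")
  W <- matrix(rep(if (is.null(weights)) rep(1, length(pcols))
                  else as.numeric(weights[pcols]),
                  each = nrow(P)), nrow(P), length(pcols))
  W[is.na(P)] <- 0
  W <- W / rowSums(W)
  P_clip <- pmin(P, 1 - 1e-15)
  Tn <- W * tan((0.5 - P_clip) * pi)
  Tn[is.na(Tn)] <- 0
  T_stat <- rowSums(Tn)
  p_out <- 0.5 - atan(T_stat) / pi
  floored <- p_out <= 0
  p_out[floored] <- 2^-54
  data.frame(gene_id = components$gene_id,
             T = T_stat, p = p_out,
             p_label = ifelse(floored, "<5.6e-17", format(p_out)),
             floored = floored,
             rank = rank(p_out, ties.method = "min"),
             masked_network = components$gene_id %in% mask,
             n_combined = n_comb, row.names = NULL)
}

#' Significance calls and FDR annotation for combined results
#'
#' Flags genes significant at the exome-wide threshold `p < p_threshold`
#' (strict inequality; underflow-floored genes always count as significant)
#' and appends Benjamini-Hochberg q-values as an auxiliary column.
#'
#' @param results Output of [combineComponents()] (needs columns `p` and
#'   `floored`).
#' @param p_threshold Gene-level significance threshold (default 1e-5).
#' @return `results` with `significant` and `q` columns added.
#' @export
addSignificance <- function(results, p_threshold = 1e-5) {
  stopifnot(all(c("p", "floored") %in% colnames(results)))
  results$significant <- results$p < p_threshold | results$floored
  results$q <- p.adjust(results$p, method = "BH")
  results
}
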