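#' Inverse-rank evidence score from a p-value ranking
#'
#' The best-ranked gene scores 1, the next `(N-1)/N`, and so on:
#' `score = (N - rank + 1) / N`, with minimum-rank ties sharing the higher
#' score (so genes tied at the underflow floor all score 1). At N = 100
#' this reproduces the 1, 0.99, 0.98, ... scheme.
#'
#' @param pvals Named numeric vector of p-values per gene.
#' @return Named score vector in (0, 1\].
#' @export
inverseRankScore <- function(pvals) {
  if (length(pvals) == 0) stop("empty input")
  N <- length(pvals)
  r <- rank(pvals, ties.method = "min")
  stats::setNames((N - r + 1) / N, names(pvals))
}

#' Binary evidence metric
#'
#' Membership indicator: 1 when the gene belongs to the evidence set
#' (e.g. recovered gold standards, colocalized genes, or genes annotated
#' to an enriched term overlapping the true-positive term list).
#'
#' @param genes Character vector of genes to score.
#' @param evidence_set Character vector defining the evidence.
#' @return Named 0/1 vector.
#' @export
binaryMetric <- function(genes, evidence_set) {
  stats::setNames(as.numeric(genes %in% evidence_set), genes)
}

#' Aggregate the ten-metric evidence table into priority scores
#'
#' Sums ten per-gene metrics, each in \[0, 1\], grouped into four evidence
#' categories: robust signal (meta p-value inverse-rank per cohort, 2
#' metrics), genetic (4), pathway (2) and phenotype (2). Missing evidence
#' contributes 0. The total lies in \[0, 10\]; genes are ranked descending
#' with minimum-rank ties.
#'
#' @param metric_table `data.frame` (or matrix) with `gene_id` rownames or
#'   column and one column per metric; values in \[0, 1\] (error
#'   otherwise), `NA` treated as 0.
#' @return `data.frame` sorted by decreasing `total`: `gene_id`, the
#'   metric columns, `total`, `rank`.
#' @export
priorityScores <- function(metric_table) {
  if (is.matrix(metric_table)) metric_table <- as.data.frame(metric_table)
  if ("gene_id" %in% colnames(metric_table)) {
    ids <- metric_table$gene_id
    M <- metric_table[, setdiff(colnames(metric_table), "gene_id"),
                      drop = FALSE]
  } else {
    ids <- rownames(metric_table)
    M <- metric_table
  }
  M <- as.matrix(M)
  M[is.na(M)] <- 0
  if (any(M < 0 | M > 1)) stop("metrics must lie in [0, 1]")
  total <- rowSums(M)
  out <- data.frame(gene_id = ids, M, total = total,
                    rank = rank(-total, ties.method = "min"),
                    row.names = NULL)
  out[order(out$rank, out$gene_id), ]
}
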