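#' Collapse a gene's variants to a carrier 2x2 table
#'
#' A sample is a carrier iff it holds at least one allele copy in the gene
#' with an impact score inside the half-open bin (lower exclusive, upper
#' inclusive) and allele frequency strictly below `af_max`. The bins
#' `(30, 70]` and `(70, 100]` proxy gain- and loss-of-function burden;
#' loss-of-function class variants (score 100) fall in the LOF bin.
#' Homozygous carriers count once (sample-wise collapsing).
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param gene_id Gene to collapse.
#' @param ea_bin `"GOF"` for scores in (30, 70\], `"LOF"` for (70, 100\],
#'   or a numeric `c(lo, hi)`.
#' @param af_max Strict allele-frequency ceiling (default 0.5; rare-variant
#'   reruns use 0.05).
#' @param exclude Variant row names (or indices) to drop before collapsing,
#'   e.g. a single driver allele for sensitivity reruns.
#' @return 2x2 integer matrix: rows carrier/non-carrier, columns
#'   case/control.
#' @export
collapseCarriers <- function(cohort, gene_id, ea_bin = c("GOF", "LOF"),
                             af_max = 0.5, exclude = NULL) {
  if (is.character(ea_bin) || length(ea_bin) == 1)
    ea_bin <- switch(match.arg(ea_bin), GOF = c(30, 70), LOF = c(70, 100))
  rd <- rowData(cohort)
  if (!"impact_score" %in% colnames(rd))
    stop("impact scores not assigned; run assignImpactScores() first")
  keep <- rd$gene_id == gene_id & rd$qualifying &
    !is.na(rd$impact_score) &
    rd$impact_score > ea_bin[1] & rd$impact_score <= ea_bin[2] &
    rd$allele_freq < af_max
  if (!is.null(exclude)) {
    if (is.character(exclude)) keep <- keep & !rownames(cohort) %in% exclude
    else keep[exclude] <- FALSE
  }
  D <- dosage(cohort)[keep, , drop = FALSE]
  carrier <- Matrix::colSums(D) >= 1
  lab <- sampleLabels(cohort)
  tab <- matrix(c(sum(carrier & lab == "case"),
                  sum(!carrier & lab == "case"),
                  sum(carrier & lab == "control"),
                  sum(!carrier & lab == "control")),
                2, 2,
                dimnames = list(c("carrier", "non_carrier"),
                                c("case", "control")))
  storage.mode(tab) <- "integer"
  tab
}

#' Odds ratio, Woolf confidence interval and exact p for a 2x2 table
#'
#' The point estimate is the cross-product ratio `(a*d)/(b*c)` with a
#' Haldane-Anscombe 0.5 continuity correction applied to every cell when
#' any cell is zero (the result is then flagged). The 95% CI uses the
#' Woolf normal approximation on the log odds ratio; the p-value is the
#' two-sided Fisher exact test on the uncorrected table. Tables with an
#' empty margin are undefined and flagged.
#'
#' @param table 2x2 nonnegative integer matrix: rows carrier status,
#'   columns case/control.
#' @return List with `or`, `ci95` (lo, hi), `p`, `corrected`, `undefined`.
#' @examples
#' fisherOr(matrix(c(10, 90, 5, 95), 2, 2))$or  # 2.11
#' @export
fisherOr <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(or = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
                corrected = FALSE, undefined = TRUE))
  corrected <- any(table == 0)
  tc <- if (corrected) table + 0.5 else table
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  se <- sqrt(sum(1 / tc))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  p <- fisher.test(table)$p.value
  list(or = or, ci95 = ci, p = p, corrected = corrected, undefined = FALSE)
}

#' Impact-binned collapsing odds ratios across genes
#'
#' Runs [collapseCarriers()] and [fisherOr()] for each requested gene in
#' both impact bins and applies Benjamini-Hochberg correction separately
#' within each bin via [fdrByBin()].
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param genes Genes to test (default: all modelled genes with at least
#'   one qualifying allele).
#' @param bins Character vector of bins (default both `"GOF"`, `"LOF"`).
#' @param af_max Strict allele-frequency ceiling (default 0.5).
#' @param exclude Variant exclusion list passed through to
#'   [collapseCarriers()].
#' @return `data.frame`: `gene_id`, `ea_bin`, `n_case_carriers`,
#'   `n_control_carriers`, `or`, `ci_lo`, `ci_hi`, `p`, `q`, `corrected`,
#'   `undefined`.
#' @export
effectDirection <- function(cohort, genes = NULL, bins = c("GOF", "LOF"),
                            af_max = 0.5, exclude = NULL) {
  if (is.null(genes)) {
    rd <- rowData(cohort)
    genes <- intersect(geneIds(cohort), unique(rd$gene_id[rd$qualifying]))
  }
  rows <- list()
  for (b in bins) for (g in genes) {
    tab <- collapseCarriers(cohort, g, b, af_max = af_max,
                            exclude = exclude)
    fo <- fisherOr(tab)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = g, ea_bin = b,
      n_case_carriers = tab[1, 1], n_control_carriers = tab[1, 2],
      or = fo$or, ci_lo = fo$ci95[1], ci_hi = fo$ci95[2], p = fo$p,
      corrected = fo$corrected, undefined = fo$undefined)
  }
  fdrByBin(do.call(rbind, rows))
}

#' Benjamini-Hochberg q-values applied separately within each impact bin
#'
#' @param results `data.frame` with columns `ea_bin` and `p`.
#' @return `results` with a `q` column (BH within each `ea_bin`).
#' @export
fdrByBin <- function(results) {
  stopifnot(all(c("ea_bin", "p") %in% colnames(results)))
  results$q <- NA_real_
  for (b in unique(results$ea_bin)) {
    idx <- results$ea_bin == b
    results$q[idx] <- p.adjust(results$p[idx], method = "BH")
  }
  results
}
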