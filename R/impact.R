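#' Assign variant impact scores on the 0-100 Evolutionary Action scale
#'
#' Loss-of-function classes (`stop_gained`, `frameshift`, `stop_lost`,
#' `splice_donor`, `splice_acceptor`) receive the maximal score of 100 even
#' when a raw EA value is annotated: the loss-of-function rule is
#' categorical. Missense variants keep their raw EA score unchanged (already
#' on the 0-100 scale). All other consequence classes (e.g. synonymous) are
#' excluded: their `impact_score` is `NA` and `qualifying` is `FALSE`.
#'
#' @param x A [MevaCohort-class] or a variant `data.frame` with columns
#'   `consequence` and `ea_raw`.
#' @param af_max Allele-frequency ceiling for the qualifying flag; alleles
#'   with `allele_freq > af_max` are non-qualifying regardless of
#'   consequence. The boundary is inclusive (AF equal to `af_max` passes).
#' @return The input with `impact_score` (numeric, `NA` when excluded) and
#'   `qualifying` (logical) added.
#' @examples
#' v <- data.frame(gene_id = "G1", chrom = "1", pos = 1:3,
#'                 consequence = c("stop_gained", "missense", "other"),
#'                 ea_raw = c(NA, 42.5, NA), allele_freq = 0.01)
#' assignImpactScores(v)$impact_score  # 100, 42.5, NA
#' @export
assignImpactScores <- function(x, af_max = 0.5) {
  if (is(x, "MevaCohort")) {
    rd <- as.data.frame(rowData(x))
    rd <- assignImpactScores(rd, af_max = af_max)
    rowData(x)$impact_score <- rd$impact_score
    rowData(x)$qualifying <- rd$qualifying
    return(x)
  }
  stopifnot(is.data.frame(x), all(c("consequence", "ea_raw") %in% colnames(x)))
  score <- rep(NA_real_, nrow(x))
  lof <- x$consequence %in% LOF_CONSEQUENCES
  mis <- x$consequence == "missense"
  score[lof] <- 100
  if (any(mis & is.na(x$ea_raw))) {
    bad <- which(mis & is.na(x$ea_raw))[1]
    id <- if (!is.null(x$gene_id))
      paste0(x$gene_id[bad], ":", x$chrom[bad], ":", x$pos[bad]) else bad
    stop("missense variant without an EA score: ", id)
  }
  if (any(mis) && (any(x$ea_raw[mis] < 0) || any(x$ea_raw[mis] > 100)))
    stop("ea_raw must lie in [0, 100]")
  score[mis] <- x$ea_raw[mis]
  x$impact_score <- score
  x$qualifying <- !is.na(score)
  if (!is.null(x$allele_freq))
    x$qualifying <- x$qualifying & x$allele_freq <= af_max
  x
}

#' Filter variant alleles on frequency and consequence
#'
#' Retains exactly the alternate alleles with `allele_freq <= af_max` and a
#' qualifying consequence class (missense or one of the loss-of-function
#' classes). Each row is one alternate allele, so multiallelic sites --
#' already decomposed per alternate allele by the readers -- are judged
#' independently. Idempotent; an empty result is allowed.
#'
#' @param variants Variant `data.frame` (columns `consequence`,
#'   `allele_freq`).
#' @param af_max Inclusive allele-frequency ceiling (default 0.5). The main
#'   pipeline uses 0.5; rare-variant reruns use a strict `< 0.05` via
#'   [collapseCarriers()].
#' @return The retained subset of `variants`.
#' @export
filterVariants <- function(variants, af_max = 0.5) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0) return(variants)
  keep <- variants$consequence %in% QUALIFYING_CONSEQUENCES &
    variants$allele_freq <= af_max
  variants[keep, , drop = FALSE]
}
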