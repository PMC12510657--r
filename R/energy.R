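#' Per-sample, per-gene mutational energy matrix
#'
#' The mutational energy a sample carries in a gene is the impact-score sum
#' over its qualifying alternate alleles there, each allele copy counting
#' once (so a homozygote contributes twice in `"dosage"` mode). `"carrier"`
#' mode counts each carried allele once regardless of zygosity, exposed for
#' sensitivity analysis.
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param mode `"dosage"` (default, allele-copy weighted) or `"carrier"`.
#' @return Sparse genes x samples matrix of energies; rows cover all
#'   modelled genes (zero rows for genes without qualifying alleles).
#' @export
geneEnergyMatrix <- function(cohort, mode = c("dosage", "carrier")) {
  mode <- match.arg(mode)
  stopifnot(is(cohort, "MevaCohort"))
  rd <- rowData(cohort)
  if (!"impact_score" %in% colnames(rd))
    stop("impact scores not assigned; run assignImpactScores() first")
  genes <- geneIds(cohort)
  keep <- which(rd$qualifying)
  D <- dosage(cohort)
  if (mode == "carrier") {
    D@x <- rep(1, length(D@x))
  }
  # aggregation matrix: genes x variants, entries = impact score
  gi <- match(rd$gene_id[keep], genes)
  A <- Matrix::sparseMatrix(i = gi, j = keep,
                            x = rd$impact_score[keep],
                            dims = c(length(genes), nrow(D)))
  G <- A %*% D
  rownames(G) <- genes
  colnames(G) <- colnames(cohort)
  G
}

#' Gene mutational energy within a sample group
#'
#' E_i = sum over the group's samples of the impact scores of the gene's
#' qualifying alleles, weighted by allele-copy count: a heterozygous carrier
#' of a score-80 allele contributes 80, a homozygote 160.
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param gene_id Gene identifier (must be modelled).
#' @param group `"cases"`, `"controls"`, or `"all"`.
#' @param mode See [geneEnergyMatrix()].
#' @return Non-negative scalar energy.
#' @examples
#' sim <- simulateCohort(simParams(n_cases = 50, n_controls = 50,
#'                                 n_genes = 10, seed = 7))
#' geneEnergy(sim$cohort, geneIds(sim$cohort)[1], "cases")
#' @export
geneEnergy <- function(cohort, gene_id,
                       group = c("all", "cases", "controls"),
                       mode = "dosage") {
  group <- match.arg(group)
  if (!gene_id %in% geneIds(cohort))
    stop("unknown gene_id: ", gene_id)
  G <- geneEnergyMatrix(cohort, mode = mode)
  lab <- sampleLabels(cohort)
  cols <- switch(group,
                 all = seq_along(lab),
                 cases = which(lab == "case"),
                 controls = which(lab == "control"))
  if (group != "all" && length(cols) == 0) stop("group is empty: ", group)
  sum(G[gene_id, cols])
}
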