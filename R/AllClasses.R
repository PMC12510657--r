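#' @importFrom methods setClass setGeneric setMethod setValidity validObject
#'   is new as callNextMethod
#' @import SummarizedExperiment
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
NULL

QUALIFYING_CONSEQUENCES <- c("missense", "stop_gained", "frameshift",
                             "stop_lost", "splice_donor", "splice_acceptor")
LOF_CONSEQUENCES <- c("stop_gained", "frameshift", "stop_lost",
                      "splice_donor", "splice_acceptor")

#' MevaCohort: samples-by-variant container for impact-aware burden testing
#'
#' `MevaCohort` extends [SummarizedExperiment::SummarizedExperiment] with rows
#' indexing alternate alleles at protein-coding sites and columns indexing
#' samples. The single `"dosage"` assay stores allele-copy counts (0/1/2) as
#' a sparse matrix. Row metadata carries the per-allele annotation that drives
#' every downstream statistic: the gene, consequence class, raw Evolutionary
#' Action (EA) score, allele frequency and, once [assignImpactScores()] has
#' run, the 0-100 impact score together with a `qualifying` flag. Column
#' metadata carries the case/control `label`, `sex` and ancestry principal
#' components `PC1`..`PC5`. Gene models (genomic interval plus protein length
#' in residues of the largest transcript) live in the `geneModels` slot as a
#' [GenomicRanges::GRanges].
#'
#' @slot geneModels A `GRanges` with metadata columns `gene_id` and
#'   `length_residues` (protein length of the largest transcript, >= 1).
#'
#' @section Validity:
#' Every variant's `gene_id` must appear in `geneModels`; allele frequencies
#' must lie in \[0, 1\]; `label` must be a factor with levels
#' `c("control", "case")`; the five PC columns must be present and numeric.
#'
#' @seealso [MevaCohort()] for construction, [assignImpactScores()],
#'   [sigmaDiff()], [simulateCohort()]
#' @exportClass MevaCohort
setClass("MevaCohort",
         contains = "SummarizedExperiment",
         representation(geneModels = "GRanges"))

setValidity("MevaCohort", function(object) {
  msg <- character()
  rd <- rowData(object)
  need_rd <- c("gene_id", "consequence", "ea_raw", "allele_freq")
  if (!all(need_rd %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need_rd, collapse = ", ")))
  cd <- colData(object)
  need_cd <- c("label", "sex", paste0("PC", 1:5))
  if (!all(need_cd %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need_cd, collapse = ", ")))
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  gm <- object@geneModels
  if (!all(c("gene_id", "length_residues") %in% colnames(S4Vectors::mcols(gm))))
    msg <- c(msg, "geneModels needs mcols gene_id and length_residues")
  else {
    if (any(S4Vectors::mcols(gm)$length_residues < 1))
      msg <- c(msg, "gene lengths must be >= 1 residue")
    if (anyDuplicated(S4Vectors::mcols(gm)$gene_id))
      msg <- c(msg, "duplicated gene_id in geneModels")
    if ("gene_id" %in% colnames(rd) &&
        !all(rd$gene_id %in% S4Vectors::mcols(gm)$gene_id))
      msg <- c(msg, "every variant gene_id must exist in geneModels")
  }
  if ("allele_freq" %in% colnames(rd)) {
    af <- rd$allele_freq
    if (any(is.na(af)) || any(af < 0) || any(af > 1))
      msg <- c(msg, "allele_freq must lie in [0, 1]")
  }
  if ("label" %in% colnames(cd)) {
    if (!is.factor(cd$label) || !identical(levels(cd$label), c("control", "case")))
      msg <- c(msg, "label must be a factor with levels c('control','case')")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MevaCohort
#'
#' @param variants `data.frame` with one row per alternate allele and columns
#'   `gene_id`, `chrom`, `pos`, `consequence` (one of `missense`,
#'   `stop_gained`, `frameshift`, `stop_lost`, `splice_donor`,
#'   `splice_acceptor`, `other`), `ea_raw` (0-100, `NA` allowed for
#'   non-missense) and `allele_freq`.
#' @param samples `data.frame` with columns `sample_id`, `label`
#'   (`"case"`/`"control"`), `sex`, and `PC1`..`PC5`.
#' @param dosage sparse or dense matrix of allele-copy counts, variants in
#'   rows and samples in columns (values 0, 1, 2).
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `length_residues`.
#'
#' @return A validated [MevaCohort-class] object.
#' @examples
#' cohort <- simulateCohort(simParams(n_cases = 40, n_controls = 40,
#'                                    n_genes = 20, seed = 1))$cohort
#' cohort
#' @export
MevaCohort <- function(variants, samples, dosage, genes) {
  stopifnot(is.data.frame(variants), is.data.frame(samples),
            is.data.frame(genes))
  dosage <- methods::as(methods::as(methods::as(Matrix::Matrix(dosage, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(dosage) != nrow(variants) || ncol(dosage) != nrow(samples))
    stop("dosage dimensions must be variants x samples")
  gm <- GRanges(seqnames = as.character(genes$chrom),
                ranges = IRanges(start = genes$start, end = genes$end),
                gene_id = as.character(genes$gene_id),
                length_residues = as.integer(genes$length_residues))
  rd <- DataFrame(gene_id = as.character(variants$gene_id),
                  chrom = as.character(variants$chrom),
                  pos = as.integer(variants$pos),
                  consequence = as.character(variants$consequence),
                  ea_raw = as.numeric(variants$ea_raw),
                  allele_freq = as.numeric(variants$allele_freq))
  if (!is.null(variants$impact_score)) {
    rd$impact_score <- as.numeric(variants$impact_score)
    rd$qualifying <- !is.na(rd$impact_score)
  }
  lab <- factor(as.character(samples$label), levels = c("control", "case"))
  if (any(is.na(lab))) stop("sample label must be 'case' or 'control'")
  cd <- DataFrame(label = lab, sex = as.character(samples$sex),
                  samples[, paste0("PC", 1:5), drop = FALSE])
  rownames(cd) <- as.character(samples$sample_id)
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowData = rd, colData = cd)
  rownames(se) <- sprintf("var%05d", seq_len(nrow(rd)))
  obj <- new("MevaCohort", se, geneModels = gm)
  validObject(obj)
  obj
}

#' @describeIn MevaCohort Compact display of cohort dimensions and state.
#' @param object A `MevaCohort`.
#' @export
setMethod("show", "MevaCohort", function(object) {
  cd <- colData(object)
  cat("MevaCohort:", nrow(object), "variant alleles x", ncol(object),
      "samples\n")
  cat("  cases:", sum(cd$label == "case"),
      " controls:", sum(cd$label == "control"), "\n")
  cat("  genes with models:", length(object@geneModels), "\n")
  rd <- rowData(object)
  if ("qualifying" %in% colnames(rd)) {
    cat("  qualifying alleles:", sum(rd$qualifying), "of", nrow(rd), "\n")
  } else {
    cat("  impact scores not yet assigned; run assignImpactScores()\n")
  }
})
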