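#' Accessors for MevaCohort
#'
#' @param x A [MevaCohort-class].
#' @name meva-accessors
NULL

#' @rdname meva-accessors
#' @return `dosage()`: the sparse variants x samples allele-copy matrix.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname meva-accessors
#' @export
setMethod("dosage", "MevaCohort", function(x) assay(x, "dosage"))

#' @rdname meva-accessors
#' @return `geneModels()`: `GRanges` of gene intervals with `gene_id` and
#'   `length_residues`.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname meva-accessors
#' @export
setMethod("geneModels", "MevaCohort", function(x) x@geneModels)

#' @rdname meva-accessors
#' @return `sampleLabels()`: factor of case/control labels, one per sample.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname meva-accessors
#' @export
setMethod("sampleLabels", "MevaCohort", function(x) colData(x)$label)

#' @rdname meva-accessors
#' @return `variantData()`: per-allele annotation as a `data.frame`.
#' @export
setGeneric("variantData", function(x) standardGeneric("variantData"))

#' @rdname meva-accessors
#' @export
setMethod("variantData", "MevaCohort", function(x)
  as.data.frame(rowData(x)))

#' @rdname meva-accessors
#' @return `geneIds()`: character vector of all modelled gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname meva-accessors
#' @export
setMethod("geneIds", "MevaCohort", function(x)
  S4Vectors::mcols(x@geneModels)$gene_id)

#' Protein lengths of modelled genes
#'
#' @param x A [MevaCohort-class].
#' @return Named integer vector of residue lengths (largest transcript per
#'   gene), named by `gene_id`.
#' @export
geneLengths <- function(x) {
  stopifnot(is(x, "MevaCohort"))
  gm <- S4Vectors::mcols(x@geneModels)
  stats::setNames(as.integer(gm$length_residues), gm$gene_id)
}
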