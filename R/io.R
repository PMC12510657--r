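#' Write a cohort to the flat TSV dialect
#'
#' Emits four plain-text tables into `dir`: `variants.tsv` (one row per
#' alternate allele: `variant_id`, `gene_id`, `chrom`, `pos`,
#' `consequence`, `ea_raw`, `allele_freq`), `samples.tsv` (`sample_id`,
#' `label`, `sex`, `PC1`..`PC5`), `genes.tsv` (`gene_id`, `chrom`,
#' `start`, `end`, `length_residues`; 1-based inclusive) and `dosage.tsv`
#' (sparse triplets `variant_id`, `sample_id`, `dosage`).
#'
#' @param cohort A [MevaCohort-class].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohortTSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- as.data.frame(rowData(cohort))
  v <- data.frame(variant_id = rownames(cohort),
                  rd[, c("gene_id", "chrom", "pos", "consequence",
                         "ea_raw", "allele_freq")])
  utils::write.table(v, file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(colData(cohort))
  s <- data.frame(sample_id = rownames(cd), cd)
  utils::write.table(s, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gm <- geneModels(cohort)
  g <- data.frame(gene_id = S4Vectors::mcols(gm)$gene_id,
                  chrom = as.character(seqnames(gm)),
                  start = start(gm), end = end(gm),
                  length_residues = S4Vectors::mcols(gm)$length_residues)
  utils::write.table(g, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  D <- methods::as(dosage(cohort), "TsparseMatrix")
  d <- data.frame(variant_id = rownames(cohort)[D@i + 1],
                  sample_id = colnames(cohort)[D@j + 1],
                  dosage = D@x)
  utils::write.table(d, file.path(dir, "dosage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from the flat TSV dialect
#'
#' Counterpart of [writeCohortTSV()].
#'
#' @param dir Directory holding `variants.tsv`, `samples.tsv`,
#'   `genes.tsv`, `dosage.tsv`.
#' @return A [MevaCohort-class] (impact scores not yet assigned).
#' @export
readCohortTSV <- function(dir) {
  rd_tsv <- function(f) utils::read.delim(file.path(dir, f),
                                          stringsAsFactors = FALSE)
  v <- rd_tsv("variants.tsv"); s <- rd_tsv("samples.tsv")
  g <- rd_tsv("genes.tsv"); d <- rd_tsv("dosage.tsv")
  D <- Matrix::sparseMatrix(i = match(d$variant_id, v$variant_id),
                            j = match(d$sample_id, s$sample_id),
                            x = d$dosage,
                            dims = c(nrow(v), nrow(s)))
  MevaCohort(v, s, D, g)
}

#' Read gene models from TSV (optionally BED-style coordinates)
#'
#' Accepts a 4-column table (`gene_id`, `chrom`, `start`, `end`) plus a
#' separate 2-column protein-length table (`gene_id`,
#' `length_residues`), or a single 5-column table. All internal
#' coordinates are 1-based inclusive; with `format = "bed"` the input is
#' treated as 0-based half-open and converted on read.
#'
#' @param file Path to the interval table.
#' @param lengths_file Optional path to the protein-length table.
#' @param format `"tsv"` (1-based inclusive, default) or `"bed"`.
#' @return `data.frame` suitable for [MevaCohort()]'s `genes` argument.
#' @export
readGeneModels <- function(file, lengths_file = NULL, format = c("tsv", "bed")) {
  format <- match.arg(format)
  g <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (format == "bed") {
    g$start <- g$start + 1L   # 0-based half-open -> 1-based inclusive
  }
  if (!is.null(lengths_file)) {
    len <- utils::read.delim(lengths_file, stringsAsFactors = FALSE)
    g <- merge(g, len, by = "gene_id")
  }
  stopifnot(all(c("gene_id", "chrom", "start", "end",
                  "length_residues") %in% colnames(g)))
  g
}

#' Read a cohort from a VCF with per-alt decomposition
#'
#' Reads genotypes and annotations via the VariantAnnotation package,
#' expanding multiallelic records so each alternate allele is judged
#' independently downstream. The EA score, consequence class and gene are
#' taken from INFO keys named by the caller; allele frequencies are
#' computed from the genotypes unless an INFO key is given. Requires the
#' VariantAnnotation package.
#'
#' @param file Path to an (uncompressed or bgzipped) VCF.
#' @param samples `data.frame` of sample metadata as in [MevaCohort()]
#'   (`sample_id` must match the VCF sample names).
#' @param genes Gene-model `data.frame` (see [readGeneModels()]).
#' @param info_ea,info_csq,info_gene,info_af INFO key names for the EA
#'   score, consequence, gene id and allele frequency (`info_af = NULL`
#'   computes AF from the genotypes).
#' @return A [MevaCohort-class].
#' @export
readCohortVCF <- function(file, samples, genes, info_ea = "EA",
                          info_csq = "CSQ", info_gene = "GENE",
                          info_af = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readCohortVCF() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(file)
  vcf <- VariantAnnotation::expand(vcf)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  # expand() emits one row per alternate allele in original ALT order;
  # recover each row's alt index so 0/2-style genotypes dose correctly
  key <- paste(as.character(seqnames(rr)), start(rr),
               as.character(rr$REF))
  alt_idx <- stats::ave(seq_along(key), key, FUN = seq_along)
  D <- matrix(0, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) {
    alleles <- strsplit(gt[, j], "[/|]")
    D[, j] <- mapply(function(a, k) sum(a == as.character(k)),
                     alleles, alt_idx)
  }
  af <- if (is.null(info_af)) rowSums(D) / (2 * ncol(D))
        else as.numeric(info[[info_af]])
  v <- data.frame(gene_id = as.character(info[[info_gene]]),
                  chrom = as.character(seqnames(rr)),
                  pos = start(rr),
                  consequence = as.character(info[[info_csq]]),
                  ea_raw = suppressWarnings(as.numeric(info[[info_ea]])),
                  allele_freq = af)
  samples <- samples[match(colnames(D), samples$sample_id), ]
  MevaCohort(v, samples, D, genes)
}

#' Write a weighted edge list TSV
#'
#' @param graph Weighted `igraph`.
#' @param file Output path (columns `from`, `to`, `weight`).
#' @return `file`, invisibly.
#' @export
writeEdgeList <- function(graph, file) {
  el <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(el, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a weighted edge list TSV into an igraph
#'
#' Expects columns `from`, `to` and `weight` (0-1 confidence weights);
#' self-loops are dropped.
#'
#' @param file Path to the edge-list TSV.
#' @return Weighted undirected `igraph`.
#' @export
readEdgeList <- function(file) {
  el <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "weight") %in% colnames(el)))
  el <- el[el$from != el$to, ]
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  g
}
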