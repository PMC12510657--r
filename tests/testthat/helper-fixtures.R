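# Hand-built 2-gene, 4-sample cohort with known energies.
#
# Qualifying alleles (dosage mode):
#   GA cases:    S1 het v1 (EA 80) = 80, S2 het v2 (EA 30) = 30  -> 110
#   GA controls: S3 hom v1 (EA 80) = 160                         -> 160
#   GB cases:    S2 het v3 (EA 70) = 70, S1 het v4 (LoF 100)     -> 170
#   GB controls: S4 het v3 (EA 70) = 70                          -> 70
# v5 is synonymous (excluded), v6 has AF 0.6 (non-qualifying).
toy_cohort <- function() {
  variants <- data.frame(
    gene_id = c("GA", "GA", "GB", "GB", "GB", "GB"),
    chrom = "chr1",
    pos = c(100, 200, 5100, 5200, 5300, 5400),
    consequence = c("missense", "missense", "missense", "stop_gained",
                    "other", "missense"),
    ea_raw = c(80, 30, 70, NA, NA, 50),
    allele_freq = c(0.1, 0.2, 0.3, 0.05, 0.01, 0.6))
  samples <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    label = c("case", "case", "control", "control"),
    sex = c("M", "F", "M", "F"),
    PC1 = c(0.1, -0.2, 0.15, -0.1), PC2 = 0, PC3 = 0, PC4 = 0, PC5 = 0)
  D <- matrix(0, 6, 4)
  D[1, 1] <- 1; D[2, 2] <- 1; D[1, 3] <- 2
  D[3, 2] <- 1; D[3, 4] <- 1; D[4, 1] <- 1
  D[5, ] <- 1
  D[6, 2] <- 1
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                      start = c(1, 5001), end = c(1000, 6000),
                      length_residues = c(100, 300))
  assignImpactScores(MevaCohort(variants, samples, D, genes))
}

# tiny null cohort generator for calibration-style unit tests
null_sim <- function(n_genes = 100, n = 100, seed = 1) {
  simulateCohort(simParams(n_cases = n, n_controls = n,
                           n_genes = n_genes, seed = seed))$cohort
}

# small weighted graph from an edge matrix
make_graph <- function(edges, weights = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- if (is.null(weights)) 1 else weights
  g
}
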