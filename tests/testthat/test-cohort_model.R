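test_that("impact scoring is categorical for LoF, identity for missense", {
  v <- data.frame(gene_id = c("G", "G", "G", "G"), chrom = "1",
                  pos = 1:4,
                  consequence = c("stop_gained", "missense", "other",
                                  "splice_donor"),
                  ea_raw = c(NA, 42.5, NA, 55),
                  allele_freq = c(0.01, 0.01, 0.01, 0.01))
  out <- assignImpactScores(v)
  expect_equal(out$impact_score, c(100, 42.5, NA, 100))
  expect_equal(out$qualifying, c(TRUE, TRUE, FALSE, TRUE))
  # LoF score forced to 100 even with an annotated EA (row 4)
  expect_equal(out$impact_score[4], 100)
  # missense without EA is an error naming the variant
  bad <- v; bad$ea_raw[2] <- NA
  expect_error(assignImpactScores(bad), "G:1:2")
})

test_that("impact score is monotone in ea_raw for missense", {
  ea <- sort(runif(50, 0, 100))
  v <- data.frame(gene_id = "G", chrom = "1", pos = seq_along(ea),
                  consequence = "missense", ea_raw = ea,
                  allele_freq = 0.01)
  expect_equal(assignImpactScores(v)$impact_score, ea)
})

test_that("variant filtering keeps qualifying alleles at AF <= 0.5 and is idempotent", {
  v <- data.frame(gene_id = "G", chrom = "1", pos = 1:5,
                  consequence = c("missense", "missense", "other",
                                  "frameshift", "missense"),
                  ea_raw = c(10, 20, NA, NA, 30),
                  allele_freq = c(0.60, 0.50, 0.01, 0.05, 0.01))
  f <- filterVariants(v)
  expect_equal(f$pos, c(2, 4, 5))    # AF 0.6 dropped; AF 0.5 kept (inclusive)
  expect_identical(filterVariants(f), f)
  expect_equal(nrow(filterVariants(v[0, ])), 0)
  # multiallelic site decomposed per-allele: each row judged independently
  multi <- data.frame(gene_id = "G", chrom = "1", pos = c(9, 9),
                      consequence = c("missense", "other"),
                      ea_raw = c(50, NA), allele_freq = c(0.1, 0.1))
  expect_equal(nrow(filterVariants(multi)), 1)
})

test_that("gene energy follows the allele-copy convention", {
  co <- toy_cohort()
  # het carrier of score-80 allele: 80; hom carrier: 160
  expect_equal(geneEnergy(co, "GA", "cases"), 110)     # 80 + 30
  expect_equal(geneEnergy(co, "GA", "controls"), 160)  # hom = 2 x 80
  expect_equal(geneEnergy(co, "GB", "cases"), 170)
  expect_equal(geneEnergy(co, "GB", "controls"), 70)
  # union energy equals the sum of group energies
  expect_equal(geneEnergy(co, "GA", "all"),
               geneEnergy(co, "GA", "cases") +
                 geneEnergy(co, "GA", "controls"))
  # carrier mode counts the hom once
  expect_equal(geneEnergy(co, "GA", "controls", mode = "carrier"), 80)
  expect_error(geneEnergy(co, "NOPE", "cases"), "unknown gene_id")
})

test_that("MevaCohort validity catches malformed inputs", {
  co <- toy_cohort()
  expect_s4_class(co, "MevaCohort")
  v <- as.data.frame(rowData(co))[, 1:6]
  s <- cbind(sample_id = colnames(co), as.data.frame(colData(co)))
  g <- data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                  start = c(1, 5001), end = c(1000, 6000),
                  length_residues = c(100, 300))
  D <- as.matrix(dosage(co))
  bad_v <- v; bad_v$gene_id[1] <- "MISSING"
  expect_error(MevaCohort(bad_v, s, D, g), "gene_id")
  bad_v <- v; bad_v$allele_freq[1] <- 1.5
  expect_error(MevaCohort(bad_v, s, D, g), "allele_freq")
  bad_s <- s; bad_s$label <- as.character(bad_s$label)
  bad_s$label[1] <- "weird"
  expect_error(MevaCohort(v, bad_s, D, g), "label")
  expect_error(MevaCohort(v, s, D[1:3, ], g), "dimensions")
})

test_that("TSV round-trip preserves the cohort", {
  co <- toy_cohort()
  dir <- withr::local_tempdir()
  writeCohortTSV(co, dir)
  back <- assignImpactScores(readCohortTSV(dir))
  expect_equal(as.matrix(dosage(back)), as.matrix(dosage(co)),
               ignore_attr = TRUE)
  expect_equal(variantData(back)$allele_freq, variantData(co)$allele_freq)
  expect_equal(geneEnergy(back, "GA", "cases"), 110)
})

test_that("gene-model reader converts BED coordinates at the boundary", {
  dir <- withr::local_tempdir()
  bed <- data.frame(gene_id = "G1", chrom = "chr1", start = 0, end = 100)
  len <- data.frame(gene_id = "G1", length_residues = 33)
  write.table(bed, file.path(dir, "g.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(len, file.path(dir, "len.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- readGeneModels(file.path(dir, "g.bed"),
                      file.path(dir, "len.tsv"), format = "bed")
  expect_equal(g$start, 1)   # 0-based half-open -> 1-based inclusive
  expect_equal(g$end, 100)
})

test_that("VCF reader decomposes per alternate allele", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- system.file("extdata", "toy_cohort.vcf", package = "meva")
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "1",
                      start = c(1, 5001), end = c(1000, 6000),
                      length_residues = c(100, 300))
  samples <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                        label = c("case", "case", "control", "control"),
                        sex = c("M", "F", "M", "F"),
                        PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0, PC5 = 0)
  co <- readCohortVCF(vcf, samples, genes, info_af = "AF")
  # the multiallelic record at pos 300 contributes one row per alt
  expect_equal(sum(variantData(co)$pos == 300), 2)
  co <- assignImpactScores(co)
  rd <- variantData(co)
  expect_equal(rd$impact_score[rd$consequence == "stop_gained"], 100)
  expect_equal(sum(rd$qualifying), 4)
})
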