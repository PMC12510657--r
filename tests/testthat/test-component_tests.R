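test_that("threshold features implement the dominant/recessive indicators", {
  co <- toy_cohort()
  f <- thresholdFeatures(co)
  # S1 carries GA:v1 het (score 80): dominant at 30 and 70, not 100
  m <- geneFeatureMatrix(f, "GA")
  expect_equal(m["S1", ], c(dom_30 = 1, rec_30 = 0, dom_70 = 1,
                            rec_70 = 0, dom_100 = 0, rec_100 = 0))
  # S3 is hom for the score-80 allele: recessive at 30 and 70
  expect_equal(m["S3", ], c(dom_30 = 1, rec_30 = 1, dom_70 = 1,
                            rec_70 = 1, dom_100 = 0, rec_100 = 0))
  # no qualifying alleles -> all zero (S4 carries nothing in GA)
  expect_equal(unname(m["S4", ]), rep(0, 6))
  # hom LoF allele (score 100) switches on all six features
  mb <- geneFeatureMatrix(f, "GB")
  expect_equal(unname(mb["S1", c("dom_100")]), 1)
  # recessive implies dominant at every threshold
  for (t in c(30, 70, 100))
    expect_true(all(m[, paste0("dom_", t)] >= m[, paste0("rec_", t)]))
  expect_error(thresholdFeatures(co, thresholds = c(70, 30, 100)),
               "strictly increasing")
})

test_that("feature test attains its permutation floor on a separating gene and flags constants", {
  # build a cohort where one gene's LoF carriers are exactly the cases
  n <- 40
  variants <- data.frame(gene_id = c("GSEP", "GCONST"), chrom = "chr1",
                         pos = c(10, 2010),
                         consequence = c("stop_gained", "missense"),
                         ea_raw = c(NA, 50), allele_freq = c(0.25, 0.01))
  D <- matrix(0, 2, n)
  D[1, 1:(n / 2)] <- 1   # all cases carry, no control does
  samples <- data.frame(sample_id = sprintf("S%02d", 1:n),
                        label = rep(c("case", "control"), each = n / 2),
                        sex = "M", PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0,
                        PC5 = 0)
  genes <- data.frame(gene_id = c("GSEP", "GCONST"), chrom = "chr1",
                      start = c(1, 2001), end = c(2000, 4000),
                      length_residues = c(200, 200))
  co <- assignImpactScores(MevaCohort(variants, samples, D, genes))
  r <- eamlLikeTest(thresholdFeatures(co), n_perm = 99, seed = 1)
  expect_equal(r$p[r$gene_id == "GSEP"], 1 / 100)
  expect_true(r$constant[r$gene_id == "GCONST"])  # nobody carries it
  expect_equal(r$p[r$gene_id == "GCONST"], 1)
  r2 <- eamlLikeTest(thresholdFeatures(co), n_perm = 99, seed = 1)
  expect_identical(r, r2)
})

test_that("feature-test p-values are roughly uniform under the null", {
  co <- null_sim(n_genes = 150, n = 80, seed = 41)
  r <- eamlLikeTest(thresholdFeatures(co), n_perm = 150, seed = 2)
  p <- r$p[!r$constant]
  expect_gt(length(p), 100)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("network differential test scores planted modules and handles edge cases", {
  genes <- sprintf("G%04d", 1:40)
  module <- genes[1:8]
  planted <- data.frame(gene = module[1:4], mechanism = "LOF_risk",
                        effect = 4)
  sim <- simulateCohort(simParams(n_cases = 120, n_controls = 120,
                                  n_genes = 40, seed = 17,
                                  planted = planted))
  net <- simulateNetwork(genes[1:30], modules = list(module),
                         p_in = 0.8, p_out = 0.05, seed = 3)
  r <- networkDiffTest(sim$cohort, net, n_perm = 50, seed = 1)
  scored <- r[!r$unscored, ]
  # planted-module genes outrank the median non-member
  expect_gt(mean(rank(scored$score)[scored$gene_id %in% module[1:4]]),
            nrow(scored) * 0.6)
  # genes outside the network are unscored with p = 1
  expect_true(all(r$p[r$unscored] == 1))
  expect_equal(sum(r$unscored), 10)
  expect_error(networkDiffTest(sim$cohort,
                               igraph::make_empty_graph(directed = FALSE)),
               "empty network")
  # identical arms give all-zero distances
  cases <- sim$cohort[, sampleLabels(sim$cohort) == "case"]
  dup <- cases
  colnames(dup) <- paste0(colnames(dup), "d")
  colData(dup)$label <- factor(rep("control", ncol(dup)),
                               levels = c("control", "case"))
  both <- cbind(cases, dup)
  r0 <- networkDiffTest(both, net, n_perm = 5, seed = 1)
  expect_equal(max(r0$score, na.rm = TRUE), 0)
})

test_that("control-vs-control mask is deterministic and empty for homogeneous controls", {
  co <- null_sim(n_genes = 30, n = 60, seed = 51)
  net <- simulateNetwork(geneIds(co)[1:20], seed = 5, p_in = 0.5,
                         p_out = 0.1)
  m1 <- controlMask(co, net, n_splits = 2, n_perm = 30, seed = 7,
                    fdr = 0.01)
  m2 <- controlMask(co, net, n_splits = 2, n_perm = 30, seed = 7,
                    fdr = 0.01)
  expect_identical(m1, m2)
  expect_length(m1, 0)
})

test_that("masking never alters the other components' p-values", {
  co <- null_sim(n_genes = 25, n = 50, seed = 61)
  sig <- sigmaDiff(co, n_perm = 100, seed = 1)
  eml <- eamlLikeTest(thresholdFeatures(co), n_perm = 100, seed = 1)
  comp <- componentPValues(sig, eml)
  set.seed(2)
  comp$p_network <- runif(nrow(comp))
  # mask genes that still have burden/feature evidence of their own
  maskable <- comp$gene_id[!is.na(comp$p_sigma) & !is.na(comp$p_eaml)]
  mask <- maskable[1:5]
  out_masked <- combineComponents(comp, mask = mask)
  comp_free <- combineComponents(comp)
  expect_true(all(out_masked$masked_network[out_masked$gene_id %in% mask]))
  # sigma and feature-test p-values are untouched inputs by construction;
  # unmasked genes combine identically
  keep <- !out_masked$gene_id %in% mask
  expect_equal(out_masked$p[keep],
               comp_free$p[match(out_masked$gene_id[keep],
                                 comp_free$gene_id)])
})
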