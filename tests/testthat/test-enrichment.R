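test_that("hypergeometric overlap matches exhaustive enumeration", {
  # frozen example: universe 10, |a| = 3, |b| = 4, k = 2 -> p = 1/3
  u <- sprintf("g%02d", 1:10)
  r <- hypergeomOverlap(u[1:3], c(u[2:3], u[5:6]), u)
  expect_equal(r$k, 2)
  expect_equal(r$p, 1 / 3)
  # enumeration oracle over all draws of |b| genes, universes <= 12
  set.seed(2)
  for (rep in 1:5) {
    N <- sample(6:12, 1)
    u <- sprintf("g%02d", seq_len(N))
    a <- sample(u, sample(2:(N - 2), 1))
    b <- sample(u, sample(2:(N - 2), 1))
    k <- length(intersect(a, b))
    draws <- combn(N, length(b))
    tail_p <- mean(apply(draws, 2, function(ix)
      length(intersect(u[ix], a)) >= k))
    expect_equal(hypergeomOverlap(a, b, u)$p, tail_p)
  }
  expect_equal(hypergeomOverlap(u[1:2], u[5:6], u)$p, 1,
               tolerance = 1e-12)  # k = 0
  expect_equal(hypergeomOverlap(u, u[1:3], u)$p, 1)  # overlap forced
  expect_error(hypergeomOverlap(c(u, "zz"), u[1:2], u), "subsets")
})

test_that("colocalization respects the distance window and chromosome", {
  genes <- GenomicRanges::GRanges("chr7",
                                  IRanges::IRanges(1000000, 1100000),
                                  gene_id = "G1")
  expect_equal(colocalize(genes,
                          data.frame(chrom = "chr7", pos = 1400000))$n_coloc,
               1)  # 300 kb away
  expect_equal(colocalize(genes,
                          data.frame(chrom = "chr7", pos = 1700000))$n_coloc,
               0)  # 600 kb > window
  expect_equal(colocalize(genes,
                          data.frame(chrom = "chr8", pos = 1050000))$n_coloc,
               0)  # wrong chromosome
  expect_equal(colocalize(genes,
                          data.frame(chrom = "chr7", pos = 1050000))$n_coloc,
               1)  # overlapping: distance 0
})

test_that("Fisher exact p matches tail enumeration on small tables", {
  enum_two_sided <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    ks <- max(0, k - n):min(m, k)
    pr <- dhyper(ks, m, n, k)
    p_obs <- dhyper(tab[1, 1], m, n, k)
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  tables <- list(matrix(c(8, 2, 10, 20), 2, 2, byrow = TRUE),
                 matrix(c(3, 7, 9, 1), 2, 2, byrow = TRUE),
                 matrix(c(0, 12, 8, 15), 2, 2, byrow = TRUE),
                 matrix(c(5, 5, 5, 5), 2, 2, byrow = TRUE))
  for (tab in tables)
    expect_equal(fisherOr(tab)$p, enum_two_sided(tab), tolerance = 1e-10)
})

test_that("diffusion conserves mass and matches the direct linear solve", {
  # 5-node path, seed at one end, restart 0.5: closed-form via solve()
  g <- make_graph(cbind(1:4, 2:5))
  igraph::V(g)$name <- paste0("n", 1:5)
  s <- diffuse(g, "n1", restart = 0.5)
  expect_equal(sum(s), 1, tolerance = 1e-10)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  Wn <- sweep(W, 2, colSums(W), "/")
  e <- c(1, 0, 0, 0, 0)
  s_direct <- solve(diag(5) - 0.5 * Wn, 0.5 * e)
  expect_equal(unname(s), as.numeric(s_direct), tolerance = 1e-9)
  # symmetric star with centre seed: all leaves tie exactly
  star <- make_graph(cbind(1, 2:6))
  igraph::V(star)$name <- paste0("s", 1:6)
  st <- diffuse(star, "s1")
  expect_equal(length(unique(round(st[2:6], 12))), 1)
  # isolated node is unreachable
  iso <- igraph::add_vertices(g, 1, name = "lonely")
  expect_equal(unname(diffuse(iso, "n1")["lonely"]), 0)
  expect_error(diffuse(g, character(0)), "empty seed")
  # random weighted graphs <= 50 nodes vs direct solve
  set.seed(3)
  for (rep in 1:3) {
    n <- sample(10:50, 1)
    gg <- igraph::sample_gnp(n, 0.15)
    igraph::V(gg)$name <- paste0("v", seq_len(n))
    igraph::E(gg)$weight <- runif(igraph::ecount(gg), 0.2, 1)
    seeds <- sample(igraph::V(gg)$name, 3)
    s <- diffuse(gg, seeds, restart = 0.5)
    W <- as.matrix(igraph::as_adjacency_matrix(gg, attr = "weight"))
    cs <- colSums(W)
    Wn <- sweep(W, 2, pmax(cs, 1e-300), "/")
    dang <- which(cs == 0)
    if (length(dang)) Wn[cbind(dang, dang)] <- 1
    e <- as.numeric(igraph::V(gg)$name %in% seeds) / 3
    s_direct <- solve(diag(n) - 0.5 * Wn, 0.5 * e)
    expect_equal(unname(s), as.numeric(s_direct), tolerance = 1e-8)
  }
})

test_that("AUROC equals the pairwise Mann-Whitney oracle and handles ties", {
  pairwise_auroc <- function(scores, pos) {
    sp <- scores[pos]; sn <- scores[!pos]
    tot <- 0
    for (a in sp) for (b in sn)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    scores <- sample(round(runif(n), 1))   # deliberate ties
    pos <- seq_len(n) %in% sample(n, max(2, n %/% 4))
    expect_equal(auroc(scores, pos), pairwise_auroc(scores, pos))
  }
  expect_equal(auroc(rep(1, 10), c(rep(TRUE, 3), rep(FALSE, 7))), 0.5)
  # targets occupying the top ranks give AUROC exactly 1
  expect_equal(auroc(10:1, c(rep(TRUE, 3), rep(FALSE, 7))), 1)
})

test_that("diffusion AUROC z-test recovers planted targets", {
  genes <- sprintf("g%03d", 1:60)
  module <- genes[1:12]
  g <- simulateNetwork(genes, modules = list(module), p_in = 0.9,
                       p_out = 0.15, seed = 9)
  seeds <- module[1:6]; targets <- module[7:12]
  r <- diffusionAurocZ(g, seeds, targets, n_random = 50,
                       degree_matched = FALSE, seed = 1)
  expect_gt(r$auroc, 0.8)
  expect_true(r$significant)
  r2 <- diffusionAurocZ(g, seeds, targets, n_random = 50,
                        degree_matched = FALSE, seed = 1)
  expect_identical(r, r2)
  expect_error(diffusionAurocZ(g, seeds, seeds[1], n_random = 5),
               "disjoint")
})

test_that("first-neighbor z-test detects planted candidate-gold links", {
  genes <- sprintf("g%03d", 1:80)
  gold <- genes[1:10]; cand <- genes[11:20]
  # homogeneous-degree background plus planted candidate-gold edges, so
  # degree-matched nulls are drawn from comparable nodes
  set.seed(13)
  bg <- igraph::sample_gnp(80, 0.12)
  igraph::V(bg)$name <- genes
  planted_edges <- cbind(cand, c(gold, gold[1:5], gold[6:10])[1:20])
  planted_edges <- rbind(planted_edges,
                         cbind(cand, rev(gold)[c(1:10, 1:10)][1:20]))
  g <- igraph::add_edges(bg, t(planted_edges))
  g <- igraph::simplify(g)
  igraph::E(g)$weight <- 0.95
  r <- firstNeighborZ(cand, gold, g, n_random = 100, seed = 1)
  expect_gt(r$z, 2)
  expect_true(r$significant)
  # no edges above an impossible threshold -> observed 0
  r0 <- firstNeighborZ(cand, gold, g, min_weight = 1.01, n_random = 10,
                       seed = 1)
  expect_equal(r0$observed, 0)
})

test_that("count-binned enrichment flags degenerate nulls and planted excess", {
  genes <- sprintf("g%03d", 1:200)
  counts <- setNames(rep(0L, 200), genes)
  r0 <- matchedCountEnrichment(counts, genes[1:20], n_random = 20,
                               seed = 1)
  expect_equal(r0$observed, c(0, 0))
  expect_true(all(r0$flagged))
  counts[genes[1:20]] <- 100L
  r1 <- matchedCountEnrichment(counts, genes[1:20], n_random = 100,
                               seed = 1)
  expect_equal(r1$observed[r1$bin == ">=50"], 20)
  expect_gt(r1$z[r1$bin == ">=50"], 2)
})

test_that("annotation enrichment flags a term planted on the candidate set", {
  genes <- sprintf("g%03d", 1:120)
  cand <- genes[1:15]
  onto <- simulateOntology(n_terms = 25, depth = 2, genes = genes,
                           annotation_rate = 0.05,
                           enriched_terms = list(T0020 = cand), seed = 5)
  r <- annotationEnrichment(onto$gene_terms, cand, n_random = 300,
                            seed = 1)
  row <- r$terms[r$terms$term == "T0020", ]
  expect_equal(row$observed, 15)
  expect_true(row$significant)
  expect_error(annotationEnrichment(onto$gene_terms, character(0)),
               "empty candidate")
  # term annotating (nearly) all genes is unenriched
  gt2 <- rbind(onto$gene_terms,
               data.frame(gene_id = genes, term = "TALL"))
  r2 <- annotationEnrichment(gt2, cand, n_random = 100, seed = 1)
  expect_equal(abs(r2$terms$z[r2$terms$term == "TALL"]), 0)
})

test_that("MCL separates components and merges cliques", {
  # two disconnected triangles -> exactly 2 clusters
  tri2 <- make_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                           c(4, 5), c(5, 6), c(4, 6)))
  igraph::V(tri2)$name <- paste0("t", 1:6)
  cl <- mclCluster(tri2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:3])), 1)
  # complete graph K6 -> a single cluster
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("k", 1:6)
  igraph::E(k6)$weight <- 1
  expect_equal(length(unique(mclCluster(k6))), 1)
  # barbell: two K5 joined by one bridge above the weight filter
  edges <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)), c(5, 6))
  bar <- make_graph(edges, weights = c(rep(1, 20), 0.75))
  igraph::V(bar)$name <- paste0("b", 1:10)
  clb <- mclCluster(bar)
  expect_equal(length(unique(clb)), 2)
  expect_equal(length(unique(clb[1:5])), 1)
  expect_equal(length(unique(clb[6:10])), 1)
})

test_that("per-cluster enrichment applies BH within each cluster", {
  clusters <- setNames(rep(c(1, 2), each = 4), paste0("g", 1:8))
  term_sets <- list(A = paste0("g", 1:4), B = paste0("g", 5:8))
  r <- clusterEnrichment(clusters, term_sets)
  expect_true(r$significant[r$cluster == 1 & r$term == "A"])
  expect_true(r$significant[r$cluster == 2 & r$term == "B"])
  expect_false(r$significant[r$cluster == 1 & r$term == "B"])
  # q within a cluster is a BH step-up of that cluster's p only
  for (cl in 1:2) {
    sub <- r[r$cluster == cl, ]
    expect_equal(sub$q, p.adjust(sub$p, method = "BH"))
  }
})

test_that("randomized enrichment nulls are centred under no enrichment", {
  genes <- sprintf("g%03d", 1:150)
  counts <- simulateCounts(genes, base_rate = 3, seed = 8)
  zs <- vapply(1:25, function(i) {
    cand <- local({set.seed(100 + i); sample(genes, 25)})
    matchedCountEnrichment(counts, cand, bins = 1, n_random = 60,
                           seed = i)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.35)
})
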