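#' One-tailed hypergeometric overlap between two gene sets
#'
#' Tests whether the observed intersection of two sets drawn from a common
#' universe is larger than expected: `p = P(X >= k)` with `X ~
#' hypergeometric(|universe|, |a|, |b|)`.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List with `k` (overlap count) and `p`.
#' @examples
#' hypergeomOverlap(letters[1:3], letters[2:5], letters[1:10])
#' @export
hypergeomOverlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  list(k = k, p = p)
}

#' Colocalization of genes with associated loci
#'
#' A gene colocalizes with a locus list when any part of its interval lies
#' within `window` bases of a locus position on the same chromosome
#' (distance 0 if overlapping). Enrichment of colocalization among
#' candidates relative to background genes is assessed by a one-tailed
#' Fisher exact test.
#'
#' @param genes `GRanges` of candidate gene intervals (1-based inclusive)
#'   with `mcols()$gene_id`.
#' @param loci `data.frame` with columns `chrom` and `pos` (1-based).
#' @param window Maximum distance in bp (default 5e5, i.e. 0.5 Mbp).
#' @param background Optional `GRanges` of background genes for the Fisher
#'   test; skipped when `NULL`.
#' @return List with `colocalized` (logical per candidate), `n_coloc`,
#'   `fraction`, and `fisher_p` (NA without background).
#' @export
colocalize <- function(genes, loci, window = 5e5, background = NULL) {
  stopifnot(is(genes, "GRanges"), all(c("chrom", "pos") %in% colnames(loci)))
  hit_fun <- function(gr) {
    if (length(gr) == 0) return(logical(0))
    vapply(seq_along(gr), function(i) {
      same <- loci$chrom == as.character(seqnames(gr)[i])
      if (!any(same)) return(FALSE)
      s <- start(gr)[i]; e <- end(gr)[i]
      pos <- loci$pos[same]
      d <- ifelse(pos < s, s - pos, ifelse(pos > e, pos - e, 0))
      any(d <= window)
    }, logical(1))
  }
  hits <- hit_fun(genes)
  fisher_p <- NA_real_
  if (!is.null(background)) {
    bg_hits <- hit_fun(background)
    tab <- matrix(c(sum(hits), sum(!hits), sum(bg_hits), sum(!bg_hits)),
                  2, 2)
    fisher_p <- fisher.test(tab, alternative = "greater")$p.value
  }
  list(colocalized = hits, n_coloc = sum(hits),
       fraction = if (length(hits)) mean(hits) else NA_real_,
       fisher_p = fisher_p)
}

# degree-decile bins over the vertices of a graph
degree_bins <- function(graph, n_bins = 10) {
  deg <- igraph::degree(graph)
  br <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) < 2) rep(1L, length(deg))
         else cut(deg, breaks = br, include.lowest = TRUE, labels = FALSE)
  stats::setNames(bin, igraph::V(graph)$name)
}

# draw one random node set matching the degree-bin profile of `nodes`,
# sampling from `pool`; nearest-bin fallback when a bin is exhausted
degree_matched_set <- function(nodes, bins, pool) {
  tab <- table(bins[nodes])
  out <- character()
  pool_bins <- bins[pool]
  for (b in names(tab)) {
    want <- tab[[b]]
    cand <- pool[pool_bins == as.integer(b) & !pool %in% out]
    if (length(cand) < want) {
      warning("degree bin ", b, " exhausted; nearest-bin fallback")
      ord <- order(abs(pool_bins - as.integer(b)))
      cand <- setdiff(pool[ord], out)
    }
    out <- c(out, sample(cand, want))
  }
  out
}

#' First-neighbor connectivity z-test against degree-matched nulls
#'
#' Counts high-confidence edges (weight > `min_weight`) joining exclusive
#' candidate genes (gold-standard members removed first) to a
#' gold-standard set, and standardizes the count against `n_random`
#' degree-matched random candidate sets (degree-decile bins). z > 2 is
#' flagged significant.
#'
#' @param candidates,gold Character vectors of gene ids.
#' @param graph Weighted `igraph`.
#' @param min_weight Confidence cutoff on edge weight (default 0.9).
#' @param n_random Null sets (default 100).
#' @param seed Integer seed.
#' @return `data.frame`: `observed`, `null_mean`, `null_sd`, `z`, `p`,
#'   `significant`, `n_null`.
#' @export
firstNeighborZ <- function(candidates, gold, graph, min_weight = 0.9,
                           n_random = 100, seed = 1) {
  g <- igraph::subgraph_from_edges(
    graph, igraph::E(graph)[igraph::E(graph)$weight > min_weight],
    delete.vertices = FALSE)
  nodes <- igraph::V(graph)$name
  candidates <- setdiff(intersect(candidates, nodes), gold)
  gold <- intersect(gold, nodes)
  count_links <- function(set) {
    if (length(set) == 0) return(0)
    sub <- igraph::E(g)[set %--% gold]
    length(sub)
  }
  observed <- count_links(candidates)
  bins <- degree_bins(g)
  pool <- setdiff(nodes, gold)
  nulls <- local_seed(seed, vapply(seq_len(n_random), function(b)
    count_links(degree_matched_set(candidates, bins, pool)),
    numeric(1)))
  mu <- mean(nulls); s <- sd(nulls)
  z <- if (s > 0) (observed - mu) / s else NA_real_
  data.frame(observed = observed, null_mean = mu, null_sd = s, z = z,
             p = if (is.na(z)) NA_real_ else pnorm(-z),
             significant = !is.na(z) && z > 2, n_null = n_random)
}

#' Restart-walk network diffusion from seed nodes
#'
#' Iteratively propagates signal from seed nodes over the column-normalized
#' weighted adjacency with restart: `s <- restart * e + (1 - restart) * W
#' %*% s`, `e` uniform over the seeds, iterated to a fixed point (sup-norm
#' tolerance 1e-12). Scores sum to 1 and are deterministic; nodes
#' unreachable from any seed score 0. Dangling nodes retain their mass via
#' an implicit self-loop.
#'
#' @param graph Weighted undirected `igraph` (or an ontology DAG converted
#'   with [ontologyGraph()]).
#' @param seeds Character vector of seed node names (nonempty, present in
#'   the graph).
#' @param restart Restart probability in (0, 1\] (default 0.5).
#' @return Named numeric score vector over all nodes.
#' @export
diffuse <- function(graph, seeds, restart = 0.5) {
  nodes <- igraph::V(graph)$name
  if (length(seeds) == 0) stop("empty seed set")
  if (!all(seeds %in% nodes)) stop("seeds must be present in the graph")
  W <- igraph::as_adjacency_matrix(
    graph, attr = if ("weight" %in% igraph::edge_attr_names(graph))
      "weight" else NULL, sparse = TRUE)
  W <- methods::as(W, "CsparseMatrix") * 1.0
  cs <- Matrix::colSums(W)
  dangling <- cs == 0
  Wn <- W %*% Matrix::Diagonal(x = ifelse(dangling, 0, 1 / pmax(cs, 1e-300)))
  e <- stats::setNames(numeric(length(nodes)), nodes)
  e[seeds] <- 1 / length(seeds)
  s <- e
  for (it in seq_len(10000)) {
    s_new <- restart * e + (1 - restart) *
      (as.numeric(Wn %*% s) + ifelse(dangling, s, 0))
    if (max(abs(s_new - s)) < 1e-12) { s <- s_new; break }
    s <- s_new
  }
  stats::setNames(as.numeric(s), nodes)
}

#' Diffusion-ranking AUROC with degree-matched null z-test
#'
#' Diffuses signal from `seeds`, ranks all non-seed nodes by received
#' score, and computes the AUROC at which `targets` are recovered
#' (mid-rank ties; all-equal scores give exactly 0.5 and are flagged). The
#' AUROC is standardized against `n_random` random target sets, degree
#' matched by decile by default; z > 2 is flagged significant.
#'
#' @param graph Weighted `igraph`.
#' @param seeds Seed node names.
#' @param targets Target node names, disjoint from seeds.
#' @param n_random Null target sets (default 100).
#' @param degree_matched Match null targets on degree decile (default
#'   TRUE; uniform draws otherwise).
#' @param seed Integer seed.
#' @param restart Restart probability (default 0.5).
#' @return `data.frame`: `auroc`, `null_mean`, `null_sd`, `z`, `p`,
#'   `significant`, `flat` (all scores equal), `n_null`.
#' @export
diffusionAurocZ <- function(graph, seeds, targets, n_random = 100,
                            degree_matched = TRUE, seed = 1,
                            restart = 0.5) {
  nodes <- igraph::V(graph)$name
  targets <- intersect(targets, nodes)
  if (length(intersect(seeds, targets)))
    stop("targets must be disjoint from seeds")
  s <- diffuse(graph, seeds, restart = restart)
  eligible <- setdiff(nodes, seeds)
  sc <- s[eligible]
  flat <- max(sc) == min(sc)
  a <- auroc(sc, eligible %in% targets)
  bins <- degree_bins(graph)
  nulls <- local_seed(seed, vapply(seq_len(n_random), function(b) {
    rt <- if (degree_matched)
      degree_matched_set(targets, bins, eligible)
    else sample(eligible, length(targets))
    auroc(sc, eligible %in% rt)
  }, numeric(1)))
  mu <- mean(nulls); sdv <- sd(nulls)
  z <- if (sdv > 0) (a - mu) / sdv else NA_real_
  data.frame(auroc = a, null_mean = mu, null_sd = sdv, z = z,
             p = if (is.na(z)) NA_real_ else pnorm(-z),
             significant = !is.na(z) && z > 2, flat = flat,
             n_null = n_random)
}

#' Count-binned enrichment against uniform random gene sets
#'
#' For each count bin (default: genes with >= 1 and with >= 50 counts,
#' mirroring literature co-mention binning), compares the number of
#' candidate genes meeting the bin to the distribution over `n_random`
#' uniformly drawn gene sets of equal size.
#'
#' @param counts Named nonnegative integer vector over the gene universe.
#' @param candidates Character vector of candidate genes.
#' @param bins Numeric thresholds defining the `>=` bins (default
#'   `c(1, 50)`).
#' @param n_random Null sets (default 100).
#' @param seed Integer seed.
#' @return `data.frame`, one row per bin: `bin`, `observed`, `null_mean`,
#'   `null_sd`, `z`, `p`, `flagged` (degenerate null), `n_null`.
#' @export
matchedCountEnrichment <- function(counts, candidates, bins = c(1, 50),
                                   n_random = 100, seed = 1) {
  universe <- names(counts)
  if (!all(candidates %in% universe))
    stop("candidates must be covered by the count table")
  nulls <- local_seed(seed, replicate(n_random,
    sample(universe, length(candidates))))
  do.call(rbind, lapply(bins, function(b) {
    obs <- sum(counts[candidates] >= b)
    nv <- apply(nulls, 2, function(set) sum(counts[set] >= b))
    mu <- mean(nv); s <- sd(nv)
    z <- if (s > 0) (obs - mu) / s else NA_real_
    data.frame(bin = paste0(">=", b), observed = obs, null_mean = mu,
               null_sd = s, z = z,
               p = if (is.na(z)) NA_real_ else pnorm(-z),
               flagged = s == 0, n_null = n_random)
  }))
}

#' Per-term annotation enrichment with representation-matched nulls
#'
#' For each annotation term, the number of candidate genes annotated to it
#' is standardized against `n_random` random gene sets matched for
#' representation: genes are binned by how many annotations (e.g. mouse
#' models) each carries, and null sets reproduce the candidates' bin
#' profile. z is converted to a two-sided p and Benjamini-Hochberg q;
#' q < 0.05 is called significant. Terms annotating fewer than 2 genes are
#' skipped. When `true_terms` is supplied, the significant terms are
#' compared to it by [hypergeomOverlap()].
#'
#' @param gene_terms `data.frame` with columns `gene_id` and `term`.
#' @param candidates Character vector (must intersect the annotation
#'   universe; absent genes are dropped with a warning).
#' @param n_random Null sets (default 5000).
#' @param n_bins Representation bins (default 10).
#' @param seed Integer seed.
#' @param true_terms Optional character vector of true-positive terms.
#' @return List with `terms` (per-term `data.frame`: `term`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p`, `q`, `significant`) and
#'   `true_term_overlap` (NULL or [hypergeomOverlap()] output over the
#'   term universe).
#' @export
annotationEnrichment <- function(gene_terms, candidates, n_random = 5000,
                                 n_bins = 10, seed = 1, true_terms = NULL) {
  stopifnot(all(c("gene_id", "term") %in% colnames(gene_terms)))
  if (length(candidates) == 0) stop("empty candidate set")
  universe <- unique(gene_terms$gene_id)
  dropped <- setdiff(candidates, universe)
  if (length(dropped)) {
    warning(length(dropped), " candidate(s) missing from the annotation ",
            "universe dropped")
    candidates <- intersect(candidates, universe)
  }
  if (length(candidates) == 0) stop("empty candidate set")
  n_models <- table(gene_terms$gene_id)[universe]
  br <- unique(stats::quantile(n_models, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(as.numeric(n_models), breaks = br, include.lowest = TRUE,
             labels = FALSE)
  names(bin) <- universe
  term_genes <- split(gene_terms$gene_id, gene_terms$term)
  term_genes <- term_genes[vapply(term_genes,
                                  function(g) length(unique(g)) >= 2,
                                  logical(1))]
  cand_bins <- table(bin[candidates])
  null_sets <- local_seed(seed, lapply(seq_len(n_random), function(b) {
    out <- character()
    for (bb in names(cand_bins)) {
      cand <- universe[bin == as.integer(bb)]
      out <- c(out, sample(cand, min(cand_bins[[bb]], length(cand))))
    }
    out
  }))
  res <- do.call(rbind, lapply(names(term_genes), function(tm) {
    tg <- unique(term_genes[[tm]])
    obs <- length(intersect(candidates, tg))
    nv <- vapply(null_sets, function(set) length(intersect(set, tg)),
                 numeric(1))
    mu <- mean(nv); s <- sd(nv)
    z <- if (s > 0) (obs - mu) / s
         else if (obs == mu) 0 else NA_real_
    data.frame(term = tm, observed = obs, null_mean = mu, null_sd = s,
               z = z, p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)))
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$q) & res$q < 0.05 & res$z > 0
  overlap <- NULL
  if (!is.null(true_terms)) {
    term_universe <- names(term_genes)
    overlap <- hypergeomOverlap(res$term[res$significant],
                                intersect(true_terms, term_universe),
                                term_universe)
  }
  list(terms = res, true_term_overlap = overlap)
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Filters the graph to edges above `min_weight`, adds unit self-loops,
#' column-normalizes the adjacency and alternates expansion (matrix
#' squaring) with inflation (element-wise power `inflation` followed by
#' column renormalization), pruning entries below 1e-8, until the maximum
#' column change falls below 1e-6 or `max_iter` iterations (returning the
#' current partition with a warning on non-convergence). Clusters are the
#' connected components of the converged flow matrix's support.
#'
#' @param graph Weighted `igraph`.
#' @param inflation Inflation exponent (default 1.5).
#' @param min_weight Edge-weight filter (default 0.7).
#' @param max_iter Iteration cap (default 100).
#' @return Named integer vector: cluster id per retained node.
#' @export
mclCluster <- function(graph, inflation = 1.5, min_weight = 0.7,
                       max_iter = 100) {
  g <- igraph::subgraph_from_edges(
    graph, igraph::E(graph)[igraph::E(graph)$weight > min_weight],
    delete.vertices = FALSE)
  nodes <- igraph::V(g)$name
  M <- graph_adjacency(g)
  diag(M) <- 1
  norm_cols <- function(A) sweep(A, 2, pmax(colSums(A), 1e-300), "/")
  M <- norm_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M_new <- norm_cols(M %*% M)           # expansion
    M_new <- norm_cols(M_new^inflation)   # inflation
    M_new[M_new < 1e-8] <- 0
    M_new <- norm_cols(M_new)
    if (max(abs(M_new - M)) < 1e-6) { M <- M_new; converged <- TRUE; break }
    M <- M_new
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter, " iterations")
  support <- (M > 1e-8) | t(M > 1e-8)
  comp_graph <- igraph::graph_from_adjacency_matrix(support,
                                                    mode = "undirected")
  cl <- igraph::components(comp_graph)$membership
  stats::setNames(as.integer(cl), nodes)
}

#' Per-cluster term enrichment for an MCL partition
#'
#' Runs [hypergeomOverlap()] of each cluster against each term's gene set
#' and applies Benjamini-Hochberg correction separately within each
#' cluster (FDR < `fdr`).
#'
#' @param clusters Named cluster membership from [mclCluster()].
#' @param term_sets Named list of character gene sets.
#' @param universe Gene universe (default: the clustered nodes).
#' @param fdr Per-cluster FDR threshold (default 0.05).
#' @return `data.frame`: `cluster`, `term`, `k`, `p`, `q`, `significant`.
#' @export
clusterEnrichment <- function(clusters, term_sets,
                              universe = names(clusters), fdr = 0.05) {
  out <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    members <- names(clusters)[clusters == cl]
    rows <- do.call(rbind, lapply(names(term_sets), function(tm) {
      hg <- hypergeomOverlap(members,
                             intersect(term_sets[[tm]], universe), universe)
      data.frame(cluster = cl, term = tm, k = hg$k, p = hg$p)
    }))
    rows$q <- p.adjust(rows$p, method = "BH")
    rows
  }))
  out$significant <- out$q < fdr
  out
}

#' Directed ontology DAG as an igraph for diffusion
#'
#' Builds an undirected unit-weight graph from parent-child term edges so
#' that signal can diffuse across the ontology structure.
#'
#' @param edges `data.frame` with columns `parent` and `child`.
#' @return Undirected `igraph` with `weight = 1` edges.
#' @export
ontologyGraph <- function(edges) {
  stopifnot(all(c("parent", "child") %in% colnames(edges)))
  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     directed = FALSE)
  igraph::E(g)$weight <- 1
  g
}
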