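#' EA-thresholded dominant/recessive feature matrices
#'
#' For each impact-score threshold `t` in `thresholds` and each gene, two
#' binary per-sample features are defined: *dominant* -- the sample carries
#' at least one allele copy with impact score >= t in the gene -- and
#' *recessive* -- it carries at least two such copies (a homozygote or a
#' compound heterozygote). Six features per gene per sample with the
#' default threshold triple. Recessive implies dominant at the same
#' threshold by construction.
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param thresholds Strictly increasing numeric triple (default
#'   `c(30, 70, 100)`, aligning with the gain/loss-of-function impact
#'   bins).
#' @return Object of class `ThresholdFeatures`: a list with `thresholds`,
#'   `counts` (one sparse genes x samples matrix of qualifying allele-copy
#'   counts per threshold), `genes`, and `labels`.
#' @export
thresholdFeatures <- function(cohort, thresholds = c(30, 70, 100)) {
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  rd <- rowData(cohort)
  if (!"impact_score" %in% colnames(rd))
    stop("impact scores not assigned; run assignImpactScores() first")
  genes <- geneIds(cohort)
  D <- dosage(cohort)
  counts <- lapply(thresholds, function(t) {
    keep <- which(rd$qualifying & rd$impact_score >= t)
    gi <- match(rd$gene_id[keep], genes)
    A <- Matrix::sparseMatrix(i = gi, j = keep, x = 1,
                              dims = c(length(genes), nrow(D)))
    C <- A %*% D
    dimnames(C) <- list(genes, colnames(cohort))
    C
  })
  names(counts) <- paste0("t", thresholds)
  structure(list(thresholds = thresholds, counts = counts, genes = genes,
                 labels = sampleLabels(cohort)),
            class = "ThresholdFeatures")
}

#' Extract the six binary features for one gene
#'
#' @param features A `ThresholdFeatures` object.
#' @param gene_id Gene identifier.
#' @return samples x 6 binary matrix, columns `dom_<t>` / `rec_<t>`.
#' @export
geneFeatureMatrix <- function(features, gene_id) {
  stopifnot(inherits(features, "ThresholdFeatures"))
  if (!gene_id %in% features$genes) stop("unknown gene_id: ", gene_id)
  out <- do.call(cbind, lapply(seq_along(features$thresholds), function(k) {
    cnt <- as.numeric(features$counts[[k]][gene_id, ])
    cbind(as.integer(cnt >= 1), as.integer(cnt >= 2))
  }))
  colnames(out) <- as.vector(rbind(paste0("dom_", features$thresholds),
                                   paste0("rec_", features$thresholds)))
  rownames(out) <- colnames(features$counts[[1]])
  out
}

# fixed linear scorer over the six features: weight t/100 for the dominant
# indicator and 2t/100 for the recessive one, so stringent thresholds and
# biallelic genotypes weigh more. Fully specified, no training step.
feature_scores <- function(features) {
  S <- NULL
  for (k in seq_along(features$thresholds)) {
    t <- features$thresholds[k]
    C <- features$counts[[k]]
    contrib <- (t / 100) * ((C >= 1) + 2 * (C >= 2))
    S <- if (is.null(S)) contrib else S + contrib
  }
  as.matrix(S)
}

#' EA-threshold feature test per gene (EAML-style component)
#'
#' A calibrated stand-in for ensemble-classifier gene scoring: each gene's
#' six EA-thresholded dominant/recessive features are collapsed by a fixed
#' linear scorer (dominant weight t/100, recessive 2t/100), the
#' discrimination statistic is the mean held-out AUROC over stratified
#' cross-validation folds, and the p-value comes from a case/control
#' label-permutation null of the same statistic (permutations shared across
#' genes). Genes whose features are constant across samples are flagged and
#' assigned p = 1. The smallest attainable p is `1/(n_perm + 1)`.
#'
#' @param features A `ThresholdFeatures` from [thresholdFeatures()].
#' @param labels Optional factor of case/control labels (defaults to the
#'   labels stored in `features`).
#' @param cv_folds Number of stratified folds (default 10).
#' @param n_perm Number of label permutations (default 200).
#' @param seed Integer seed.
#' @return `data.frame` with `gene_id`, `stat` (mean fold AUROC), `p`,
#'   `constant`.
#' @export
eamlLikeTest <- function(features, labels = NULL, cv_folds = 10,
                         n_perm = 200, seed = 1) {
  stopifnot(inherits(features, "ThresholdFeatures"))
  if (is.null(labels)) labels <- features$labels
  y <- labels == "case"
  n <- length(y)
  if (!any(y) || all(y)) stop("both classes required")
  S <- feature_scores(features)
  constant <- apply(S, 1, function(r) max(r) == min(r))
  G_n <- nrow(S)

  local_seed(seed, {
    fold <- stratified_folds(ifelse(y, "case", "control"), cv_folds)
    Yp <- matrix(FALSE, n, n_perm)
    for (b in seq_len(n_perm)) Yp[sample.int(n, sum(y)), b] <- TRUE

    obs_sum <- numeric(G_n); null_sum <- matrix(0, G_n, n_perm)
    obs_k <- 0; null_k <- numeric(n_perm)
    for (f in seq_len(cv_folds)) {
      H <- which(fold == f)
      R <- t(apply(S[, H, drop = FALSE], 1, rank, ties.method = "average"))
      yH <- y[H]
      n1 <- sum(yH); n0 <- sum(!yH)
      if (n1 > 0 && n0 > 0) {
        obs_sum <- obs_sum +
          (as.numeric(R %*% yH) - n1 * (n1 + 1) / 2) / (n1 * n0)
        obs_k <- obs_k + 1
      }
      YH <- Yp[H, , drop = FALSE]
      n1b <- colSums(YH); n0b <- length(H) - n1b
      ok <- n1b > 0 & n0b > 0
      A <- R %*% YH
      A <- sweep(A, 2, n1b * (n1b + 1) / 2, "-")
      A <- sweep(A, 2, n1b * n0b, "/")
      null_sum[, ok] <- null_sum[, ok] + A[, ok, drop = FALSE]
      null_k[ok] <- null_k[ok] + 1
    }
    stat <- obs_sum / obs_k
    null_stat <- sweep(null_sum, 2, null_k, "/")
    p <- (1 + rowSums(null_stat >= stat)) / (n_perm + 1)
    p[constant] <- 1
    data.frame(gene_id = features$genes, stat = stat, p = p,
               constant = constant, row.names = NULL)
  })
}

# base adjacency of an igraph as a symmetric dense matrix over its nodes
graph_adjacency <- function(graph) {
  W <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  as.matrix(W)
}

# energy-weighted diffusion profile matrix for one arm: column g is the
# restart-walk vector started at node g on the arm-weighted network
arm_profiles <- function(W0, m, restart) {
  ms <- outer(m, m, "+")
  W <- W0 * ms
  cs <- colSums(W)
  Wn <- sweep(W, 2, ifelse(cs > 0, cs, 1), "/")
  dangling <- which(cs == 0)
  if (length(dangling)) Wn[cbind(dangling, dangling)] <- 1
  n <- nrow(W)
  restart * solve(diag(n) - (1 - restart) * Wn)
}

#' Network differential-burden test (network propagation component)
#'
#' Stand-in for embedding-based differential network scoring. Edge weights
#' of the protein-interaction graph are multiplied, within each arm, by the
#' sum of the two endpoint genes' per-sample mean mutational energies,
#' giving a case-weighted and a control-weighted network. Each network-gene
#' is scored by the L1 distance between its restart-walk diffusion profiles
#' (restart probability `restart`) in the two arm networks; p-values come
#' from a case/control label-permutation null of the same score. Genes
#' absent from the network receive p = 1 with an `unscored` flag.
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param graph Weighted undirected `igraph`; vertex names must be a subset
#'   of the cohort's modelled genes.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed.
#' @param restart Restart probability of the walk (default 0.5).
#' @return `data.frame` over all modelled genes: `gene_id`, `score`, `p`,
#'   `unscored`.
#' @export
networkDiffTest <- function(cohort, graph, n_perm = 100, seed = 1,
                            restart = 0.5) {
  if (igraph::vcount(graph) == 0 || igraph::ecount(graph) == 0)
    stop("empty network")
  nodes <- igraph::V(graph)$name
  genes <- geneIds(cohort)
  if (!all(nodes %in% genes))
    stop("network nodes must be a subset of the gene universe")
  G <- geneEnergyMatrix(cohort)[nodes, , drop = FALSE]
  lab <- sampleLabels(cohort)
  W0 <- graph_adjacency(graph)[nodes, nodes]
  n <- length(lab); n_case <- sum(lab == "case")

  score_for <- function(case_idx) {
    mc <- Matrix::rowSums(G[, case_idx, drop = FALSE]) / length(case_idx)
    mk <- Matrix::rowSums(G[, -case_idx, drop = FALSE]) /
      (n - length(case_idx))
    Sc <- arm_profiles(W0, mc, restart)
    Sk <- arm_profiles(W0, mk, restart)
    colSums(abs(Sc - Sk))
  }
  obs <- score_for(which(lab == "case"))
  null_mat <- local_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) score_for(sample.int(n, n_case)),
           numeric(length(nodes)))
  })
  p_net <- (1 + rowSums(null_mat >= obs)) / (n_perm + 1)
  out <- data.frame(gene_id = genes, score = NA_real_, p = 1,
                    unscored = TRUE, row.names = NULL)
  idx <- match(nodes, genes)
  out$score[idx] <- obs
  out$p[idx] <- p_net
  out$unscored[idx] <- FALSE
  out
}

#' Control-versus-control mask for network hub artifacts
#'
#' Network differential scoring can up-rank high-degree hub genes for
#' reasons unrelated to disease. To detect them, the controls are split at
#' random into two pseudo-arms and [networkDiffTest()] is run on each
#' split; genes reaching the component significance threshold
#' (Benjamini-Hochberg FDR <= `fdr`) in any control-only run are returned
#' for masking in [combineComponents()]. Deterministic under a fixed seed.
#'
#' @param cohort A [MevaCohort-class]; only its controls are used (at least
#'   4 required).
#' @param graph Weighted `igraph` as in [networkDiffTest()].
#' @param n_splits Number of random half-splits (default 2).
#' @param fdr BH threshold flagging a gene in a control-only run (default
#'   0.1).
#' @param n_perm Permutations per split (default 100).
#' @param seed Integer seed.
#' @return Character vector of gene ids to mask (typically empty for
#'   homogeneous controls).
#' @export
controlMask <- function(cohort, graph, n_splits = 2, fdr = 0.1,
                        n_perm = 100, seed = 1) {
  ctrl <- cohort[, sampleLabels(cohort) == "control"]
  n <- ncol(ctrl)
  if (n < 4) stop("need at least 4 controls to split")
  half <- floor(n / 2)
  masked <- character()
  for (s in seq_len(n_splits)) {
    idx <- local_seed(child_seed(seed, s), sample.int(n, half))
    lab <- factor(ifelse(seq_len(n) %in% idx, "case", "control"),
                  levels = c("control", "case"))
    colData(ctrl)$label <- lab
    res <- networkDiffTest(ctrl, graph, n_perm = n_perm,
                           seed = child_seed(seed, s, 7L))
    scored <- res[!res$unscored, ]
    q <- p.adjust(scored$p, method = "BH")
    masked <- union(masked, scored$gene_id[q <= fdr])
  }
  sort(masked)
}

#' Assemble the per-gene component p-value table
#'
#' Collects the three component tests into the table consumed by
#' [combineComponents()]. Degenerate sigma genes, constant-feature genes
#' and network-unscored genes contribute `NA` (not combinable) rather than
#' an artificial p-value. The sigma z is converted to a two-sided normal
#' tail p, consistent with its |z| >= 3 significance call.
#'
#' @param sigma_res Output of [sigmaDiff()].
#' @param eaml_res Output of [eamlLikeTest()] (optional).
#' @param network_res Output of [networkDiffTest()] (optional).
#' @return `data.frame` with `gene_id`, `p_sigma`, and where supplied
#'   `p_eaml`, `p_network`.
#' @export
componentPValues <- function(sigma_res, eaml_res = NULL,
                             network_res = NULL) {
  out <- data.frame(gene_id = sigma_res$gene_id,
                    p_sigma = ifelse(sigma_res$degenerate, NA_real_,
                                     sigma_res$p))
  if (!is.null(eaml_res)) {
    m <- match(out$gene_id, eaml_res$gene_id)
    out$p_eaml <- ifelse(eaml_res$constant[m], NA_real_, eaml_res$p[m])
  }
  if (!is.null(network_res)) {
    m <- match(out$gene_id, network_res$gene_id)
    out$p_network <- ifelse(network_res$unscored[m], NA_real_,
                            network_res$p[m])
  }
  out
}
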