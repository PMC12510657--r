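#' Parameters for the synthetic cohort generator
#'
#' Collects the generator's knobs with defaults chosen to emulate an
#' exome-wide case/control burden study at desk scale: log-normal protein
#' lengths (median about 430 residues), Poisson variant-site counts per
#' gene, an impact-score mixture with a 10% loss-of-function mass at 100
#' and a Beta-shaped missense EA spectrum on (0, 100), an allele-frequency
#' spectrum mixing rare (85%, Beta) and common (15%, uniform on 0.05-0.5)
#' alleles, Bernoulli sex with exact 1:1 matching across arms, and a
#' shared 5-dimensional Gaussian ancestry PC model. A fraction of variant
#' sites is emitted with non-qualifying consequences so inclusion filters
#' are exercised.
#'
#' @param n_cases,n_controls Samples per arm.
#' @param n_genes Number of modelled genes.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal residue-length
#'   parameters.
#' @param variants_per_gene_rate Poisson mean of variant sites per gene.
#' @param lof_fraction Fraction of qualifying sites that are
#'   loss-of-function class (scored 100).
#' @param other_fraction Fraction of sites with non-qualifying
#'   consequence (excluded by the filters).
#' @param ea_shape1,ea_shape2 Beta parameters of the missense EA spectrum.
#' @param af_rare_frac Mixture weight of the rare-allele component.
#' @param af_rare_shape1,af_rare_shape2 Beta parameters of rare allele
#'   frequencies.
#' @param af_common_min,af_common_max Uniform range of common allele
#'   frequencies.
#' @param planted `data.frame` with columns `gene` (e.g. `"G0001"`),
#'   `mechanism` (`"LOF_risk"`, `"GOF_risk"`, `"protective"`) and `effect`
#'   (multiplier > 0 on the at-risk arm's allele frequency for *rare*
#'   alleles -- baseline AF at most `planted_af_max` -- in the mechanism's
#'   impact bin; common in-bin alleles stay exchangeable, mirroring risk
#'   effects concentrated on the rare end of the spectrum).
#' @param n_planted_variants Guaranteed variant sites per planted gene
#'   inside the mechanism's impact bin.
#' @param planted_af Allele frequency of those guaranteed sites.
#' @param planted_af_max Baseline-AF ceiling for alleles the effect
#'   multiplier applies to (default 0.05).
#' @param sex_ratio Probability of male.
#' @param seed Integer seed.
#' @return A `simParams` list.
#' @export
simParams <- function(n_cases = 1000, n_controls = 1000, n_genes = 2000,
                      gene_length_meanlog = log(430),
                      gene_length_sdlog = 0.6,
                      variants_per_gene_rate = 8,
                      lof_fraction = 0.10, other_fraction = 0.15,
                      ea_shape1 = 0.8, ea_shape2 = 0.8,
                      af_rare_frac = 0.85,
                      af_rare_shape1 = 0.3, af_rare_shape2 = 30,
                      af_common_min = 0.05, af_common_max = 0.5,
                      planted = NULL, n_planted_variants = 3,
                      planted_af = 0.01, planted_af_max = 0.05,
                      sex_ratio = 0.5, seed = 1) {
  p <- as.list(environment())
  if (!is.null(p$planted)) {
    stopifnot(is.data.frame(p$planted),
              all(c("gene", "mechanism", "effect") %in%
                    colnames(p$planted)),
              all(p$planted$effect > 0),
              all(p$planted$mechanism %in%
                    c("LOF_risk", "GOF_risk", "protective")))
  }
  structure(p, class = "simParams")
}

mechanism_bin <- function(mechanism) {
  switch(mechanism,
         LOF_risk = c(70, 100),
         GOF_risk = c(30, 70),
         protective = c(70, 100))
}

# sparse HWE genotype draw for one variant over n samples at frequency af
sim_genotypes <- function(n, af) {
  p_het <- 2 * af * (1 - af); p_hom <- af^2
  k_het <- rbinom(1, n, p_het)
  k_hom <- rbinom(1, n - k_het, p_hom / (1 - p_het))
  idx <- sample.int(n, k_het + k_hom)
  list(i = idx, x = c(rep(1, k_het), rep(2, k_hom)))
}

#' Simulate a case/control cohort with planted gene effects
#'
#' Null genes have exchangeable case/control variant processes; planted
#' genes realize their mechanism by multiplying the allele frequency of
#' in-bin alleles in the at-risk arm (`LOF_risk`: impact (70, 100\] excess
#' in cases; `GOF_risk`: (30, 70\] excess in cases; `protective`:
#' (70, 100\] excess in controls). Each planted gene carries
#' `n_planted_variants` guaranteed in-bin sites so the mechanism is always
#' realizable. Sexes are matched exactly 1:1 across arms and ancestry PCs
#' are drawn from one shared Gaussian. Reproducible under the seed; a
#' ground-truth manifest is returned alongside the cohort.
#'
#' @param params A [simParams()] list.
#' @param assign_impact Run [assignImpactScores()] on the result (default
#'   TRUE).
#' @return List with `cohort` ([MevaCohort-class]) and `manifest` (planted
#'   truth and generator echo).
#' @examples
#' sim <- simulateCohort(simParams(n_cases = 50, n_controls = 50,
#'                                 n_genes = 20, seed = 1,
#'                                 planted = data.frame(gene = "G0001",
#'                                   mechanism = "LOF_risk", effect = 3)))
#' sim$cohort
#' @export
simulateCohort <- function(params = simParams(), assign_impact = TRUE) {
  stopifnot(inherits(params, "simParams"))
  local_seed(params$seed, {
    ng <- params$n_genes
    gene_id <- sprintf("G%04d", seq_len(ng))
    if (!is.null(params$planted) &&
        !all(params$planted$gene %in% gene_id))
      stop("planted genes must lie in the gene universe")
    len <- pmax(50L, as.integer(round(rlnorm(ng, params$gene_length_meanlog,
                                             params$gene_length_sdlog))))
    chrom <- paste0("chr", rep_len(1:22, ng))
    idx_on_chrom <- stats::ave(seq_len(ng), chrom, FUN = seq_along)
    start <- 1e6 + (idx_on_chrom - 1) * 3e6
    genes <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                        end = start + len * 3 - 1, length_residues = len)

    n_sites <- rpois(ng, params$variants_per_gene_rate)
    vg <- rep(gene_id, n_sites)
    nv <- length(vg)
    u <- runif(nv)
    consequence <- ifelse(u < params$other_fraction, "other",
                   ifelse(u < params$other_fraction +
                            (1 - params$other_fraction) * params$lof_fraction,
                          sample(LOF_CONSEQUENCES, nv, replace = TRUE),
                          "missense"))
    ea <- ifelse(consequence == "missense",
                 100 * rbeta(nv, params$ea_shape1, params$ea_shape2),
                 NA_real_)
    rare <- runif(nv) < params$af_rare_frac
    af <- ifelse(rare,
                 pmin(0.5, rbeta(nv, params$af_rare_shape1,
                                 params$af_rare_shape2)),
                 runif(nv, params$af_common_min, params$af_common_max))
    af <- pmax(af, 1e-4)
    variants <- data.frame(gene_id = vg, chrom = genes$chrom[match(vg, gene_id)],
                           pos = NA_integer_, consequence = consequence,
                           ea_raw = ea, allele_freq = af,
                           stringsAsFactors = FALSE)

    # guaranteed in-bin sites for planted genes
    if (!is.null(params$planted)) {
      extra <- do.call(rbind, lapply(seq_len(nrow(params$planted)),
        function(k) {
          pg <- params$planted$gene[k]
          bin <- mechanism_bin(params$planted$mechanism[k])
          m <- params$n_planted_variants
          data.frame(gene_id = pg, chrom = genes$chrom[match(pg, gene_id)],
                     pos = NA_integer_, consequence = "missense",
                     ea_raw = runif(m, bin[1] + 2, bin[2] - 2),
                     allele_freq = rep(params$planted_af, m),
                     stringsAsFactors = FALSE)
        }))
      variants <- rbind(variants, extra)
    }
    nv <- nrow(variants)
    variants$pos <- genes$start[match(variants$gene_id, gene_id)] +
      sample.int(5000, nv, replace = TRUE)

    # arm-specific allele frequencies
    af_case <- variants$allele_freq
    af_ctrl <- variants$allele_freq
    if (!is.null(params$planted)) {
      imp <- ifelse(variants$consequence %in% LOF_CONSEQUENCES, 100,
                    variants$ea_raw)
      for (k in seq_len(nrow(params$planted))) {
        pg <- params$planted$gene[k]
        mech <- params$planted$mechanism[k]
        bin <- mechanism_bin(mech)
        hit <- variants$gene_id == pg & !is.na(imp) &
          imp > bin[1] & imp <= bin[2] &
          variants$allele_freq <= params$planted_af_max
        eff <- params$planted$effect[k]
        if (mech == "protective") af_ctrl[hit] <- af_ctrl[hit] * eff
        else af_case[hit] <- af_case[hit] * eff
      }
      if (any(af_case > 0.5 + 1e-9) || any(af_ctrl > 0.5 + 1e-9))
        stop("infeasible planted rates: effect pushes allele frequency ",
             "beyond 0.5")
    }

    n_case <- params$n_cases; n_ctrl <- params$n_controls
    n <- n_case + n_ctrl
    trip_i <- vector("list", nv); trip_j <- vector("list", nv)
    trip_x <- vector("list", nv)
    for (v in seq_len(nv)) {
      gc <- sim_genotypes(n_case, af_case[v])
      gk <- sim_genotypes(n_ctrl, af_ctrl[v])
      trip_i[[v]] <- rep(v, length(gc$i) + length(gk$i))
      trip_j[[v]] <- c(gc$i, n_case + gk$i)
      trip_x[[v]] <- c(gc$x, gk$x)
    }
    D <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(nv, n))

    sex_case <- ifelse(runif(n_case) < params$sex_ratio, "M", "F")
    sex_ctrl <- sample(rep(c("M", "F"),
                           c(sum(sex_case == "M"), sum(sex_case == "F"))))
    if (n_ctrl != n_case) {
      # unequal arms: controls re-drawn from the same Bernoulli model
      sex_ctrl <- ifelse(runif(n_ctrl) < params$sex_ratio, "M", "F")
    }
    pcs <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("PC", 1:5)))
    samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                          label = rep(c("case", "control"),
                                      c(n_case, n_ctrl)),
                          sex = c(sex_case, sex_ctrl), pcs)

    cohort <- MevaCohort(variants, samples, D, genes)
    if (assign_impact) cohort <- assignImpactScores(cohort)
    manifest <- list(planted = params$planted,
                     n_cases = n_case, n_controls = n_ctrl,
                     n_genes = ng, n_variants = nv, seed = params$seed)
    list(cohort = cohort, manifest = manifest)
  })
}

#' Simulate a weighted interaction network with planted modules
#'
#' Stochastic block graph: node pairs within a planted module connect with
#' probability `p_in`, all other pairs with `p_out` (`p_in > p_out`
#' required); edge weights are uniform on (`w_min`, `w_max`\]. With
#' `p_out = 0` the modules become connected components.
#'
#' @param genes Character vector of node names.
#' @param modules List of character vectors (planted modules).
#' @param p_in,p_out Edge probabilities.
#' @param w_min,w_max Weight range (defaults 0.5, 1).
#' @param seed Integer seed.
#' @return Weighted undirected `igraph`.
#' @export
simulateNetwork <- function(genes, modules = list(), p_in = 0.5,
                            p_out = 0.02, w_min = 0.5, w_max = 1,
                            seed = 1) {
  stopifnot(p_in > p_out, all(unlist(modules) %in% genes))
  local_seed(seed, {
    n <- length(genes)
    mod_id <- stats::setNames(rep(0L, n), genes)
    for (m in seq_along(modules)) mod_id[modules[[m]]] <- m
    pairs <- utils::combn(n, 2)
    same <- mod_id[pairs[1, ]] != 0 &
      mod_id[pairs[1, ]] == mod_id[pairs[2, ]]
    keep <- runif(ncol(pairs)) < ifelse(same, p_in, p_out)
    el <- cbind(genes[pairs[1, keep]], genes[pairs[2, keep]])
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(genes, igraph::V(g)$name)),
                              name = setdiff(genes, igraph::V(g)$name))
    igraph::E(g)$weight <- runif(igraph::ecount(g), w_min, w_max)
    g
  })
}

#' Simulate a tree-like ontology with propagated annotations
#'
#' Builds a random tree of `n_terms` terms over `depth` levels
#' (unit-weight parent-child edges), annotates each gene to leaf terms
#' independently with probability `annotation_rate`, forces designated
#' `enriched_terms` to annotate designated gene sets, and propagates every
#' annotation to all ancestor terms (so a parent's gene set always
#' contains each child's).
#'
#' @param n_terms Number of terms (>= depth + 1).
#' @param depth Tree depth (>= 1).
#' @param genes Character vector of genes.
#' @param annotation_rate Per (gene, leaf term) annotation probability.
#' @param enriched_terms Named list: term name -> character gene set.
#'   Term names must be among the generated terms (`T0001`...).
#' @param seed Integer seed.
#' @return List with `edges` (`parent`, `child`), `gene_terms`
#'   (`gene_id`, `term`) and `graph` (the [ontologyGraph()]).
#' @export
simulateOntology <- function(n_terms = 50, depth = 3, genes,
                             annotation_rate = 0.02,
                             enriched_terms = list(), seed = 1) {
  stopifnot(depth >= 1, n_terms >= depth + 1)
  local_seed(seed, {
    terms <- sprintf("T%04d", seq_len(n_terms))
    level <- c(0, sort(sample(rep_len(seq_len(depth), n_terms - 1))))
    parent <- rep(NA_character_, n_terms)
    for (i in 2:n_terms) {
      pool <- which(level == level[i] - 1)
      parent[i] <- terms[if (length(pool) == 1) pool else sample(pool, 1)]
    }
    edges <- data.frame(parent = parent[-1], child = terms[-1])
    ancestors <- function(tm) {
      out <- character()
      while (!is.na(parent[match(tm, terms)])) {
        tm <- parent[match(tm, terms)]
        out <- c(out, tm)
      }
      out
    }
    leaves <- setdiff(terms, parent)
    ann <- list()
    for (lf in leaves) {
      hit <- genes[runif(length(genes)) < annotation_rate]
      if (length(hit))
        ann[[length(ann) + 1]] <- data.frame(gene_id = hit, term = lf)
    }
    for (tm in names(enriched_terms)) {
      stopifnot(tm %in% terms)
      ann[[length(ann) + 1]] <- data.frame(gene_id = enriched_terms[[tm]],
                                           term = tm)
    }
    gt <- unique(do.call(rbind, c(ann, list(
      data.frame(gene_id = character(), term = character())))))
    if (nrow(gt)) {
      prop <- do.call(rbind, lapply(seq_len(nrow(gt)), function(r) {
        anc <- ancestors(gt$term[r])
        if (length(anc))
          data.frame(gene_id = gt$gene_id[r], term = anc)
        else NULL
      }))
      gt <- unique(rbind(gt, prop))
    }
    list(edges = edges, gene_terms = gt, graph = ontologyGraph(edges))
  })
}

#' Simulate associated loci near a designated gene set
#'
#' Places one locus within `window` of each `near_set` gene (uniformly
#' inside the window around the gene midpoint) and none near the others;
#' because simulated gene models are spaced 3 Mbp apart, all remaining
#' genes sit at least twice the default window from every locus.
#'
#' @param gene_models `GRanges` with `mcols()$gene_id` (e.g.
#'   [geneModels()]).
#' @param near_set Genes to receive a nearby locus.
#' @param window Placement half-width in bp (default 2.5e5).
#' @param seed Integer seed.
#' @return `data.frame` with `chrom` and `pos`.
#' @export
simulateLoci <- function(gene_models, near_set, window = 2.5e5, seed = 1) {
  ids <- S4Vectors::mcols(gene_models)$gene_id
  stopifnot(all(near_set %in% ids))
  local_seed(seed, {
    idx <- match(near_set, ids)
    mid <- (start(gene_models)[idx] + end(gene_models)[idx]) / 2
    data.frame(chrom = as.character(seqnames(gene_models))[idx],
               pos = as.integer(round(mid + runif(length(idx), -window,
                                                  window))))
  })
}

#' Simulate per-gene count tables with an elevated set
#'
#' Poisson counts with background rate `base_rate`, multiplied by
#' `elevated_mult` for genes in `elevated_set` (emulating e.g. literature
#' co-mention counts).
#'
#' @param genes Character vector.
#' @param elevated_set Subset of `genes` with elevated rate.
#' @param base_rate Background Poisson mean (default 2).
#' @param elevated_mult Rate multiplier for the elevated set (default 25).
#' @param seed Integer seed.
#' @return Named integer vector of counts.
#' @export
simulateCounts <- function(genes, elevated_set = character(),
                           base_rate = 2, elevated_mult = 25, seed = 1) {
  stopifnot(all(elevated_set %in% genes))
  local_seed(seed, {
    lam <- ifelse(genes %in% elevated_set, base_rate * elevated_mult,
                  base_rate)
    stats::setNames(rpois(length(genes), lam), genes)
  })
}
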