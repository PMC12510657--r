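#' Run the full impact-aware meta-association pipeline
#'
#' Convenience orchestration of the three component tests and the Cauchy
#' combination: differential equipartition burden ([sigmaDiff()]), the
#' EA-threshold feature test ([eamlLikeTest()]) and, when a network is
#' supplied, the network differential-burden test ([networkDiffTest()])
#' with its control-versus-control hub mask ([controlMask()]). Component
#' p-values are combined per gene with equal weights over the unmasked,
#' available components ([combineComponents()]) and annotated with
#' significance calls at p < 1e-5 and BH q-values ([addSignificance()]).
#'
#' @param cohort A [MevaCohort-class] with impact scores assigned.
#' @param network Optional weighted `igraph` over a subset of the
#'   modelled genes.
#' @param n_perm_sigma,n_perm_eaml,n_perm_network Permutation counts per
#'   component.
#' @param apply_mask Run the control-versus-control mask (default TRUE
#'   when a network is supplied).
#' @param seed Integer master seed (component seeds derived from it).
#' @param p_threshold Gene-level significance threshold (default 1e-5).
#' @return List with `combined` (ranked, annotated results), `components`
#'   (the p-value table), `sigma`, `eaml`, `network`, `mask`.
#' @examples
#' sim <- simulateCohort(simParams(n_cases = 80, n_controls = 80,
#'                                 n_genes = 40, seed = 2))
#' res <- runMeva(sim$cohort, n_perm_sigma = 100, n_perm_eaml = 100,
#'                seed = 1)
#' head(res$combined)
#' @export
runMeva <- function(cohort, network = NULL, n_perm_sigma = 1000,
                    n_perm_eaml = 200, n_perm_network = 100,
                    apply_mask = !is.null(network), seed = 1,
                    p_threshold = 1e-5) {
  sig <- sigmaDiff(cohort, n_perm = n_perm_sigma,
                   seed = child_seed(seed, 1L))
  feats <- thresholdFeatures(cohort)
  eaml <- eamlLikeTest(feats, n_perm = n_perm_eaml,
                       seed = child_seed(seed, 2L))
  net <- NULL; mask <- character()
  if (!is.null(network)) {
    net <- networkDiffTest(cohort, network, n_perm = n_perm_network,
                           seed = child_seed(seed, 3L))
    if (apply_mask)
      mask <- controlMask(cohort, network, n_perm = n_perm_network,
                          seed = child_seed(seed, 4L))
  }
  comp <- componentPValues(sig, eaml, net)
  combined <- addSignificance(combineComponents(comp, mask = mask),
                              p_threshold = p_threshold)
  list(combined = combined, components = comp, sigma = sig, eaml = eaml,
       network = net, mask = mask)
}

#' Gene p-value ranking from the pipeline (for the robustness harness)
#'
#' Returns a `rankFun` suitable for [robustnessGrid()] that runs either
#' the full pipeline or the differential-burden component alone and
#' extracts the named p-value vector.
#'
#' @param method `"sigma"` (fast, default) or `"meva"` (all components).
#' @param network Network for `method = "meva"`.
#' @param n_perm Permutations for the underlying tests.
#' @return `function(cohort, seed)` -> named p-value vector.
#' @export
mevaRankFun <- function(method = c("sigma", "meva"), network = NULL,
                        n_perm = 300) {
  method <- match.arg(method)
  function(cohort, seed) {
    if (method == "sigma") {
      res <- sigmaDiff(cohort, n_perm = n_perm, seed = seed)
      p <- ifelse(res$degenerate, 1, res$p)
      stats::setNames(p, res$gene_id)
    } else {
      res <- runMeva(cohort, network = network, n_perm_sigma = n_perm,
                     n_perm_eaml = n_perm, seed = seed)
      stats::setNames(res$combined$p, res$combined$gene_id)
    }
  }
}
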