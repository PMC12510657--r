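#' Stratified case/control subsample with ancestry matching
#'
#' Draws `n` cases and `n` controls such that the two arms have exactly
#' equal sex counts and, for each of the five ancestry principal
#' components, a two-sample Kolmogorov-Smirnov p-value above `ks_p`
#' between arms. Sampling is retried up to `max_retry` times; if the KS
#' criterion is never met the best attempt (largest minimum KS p) is
#' returned with attribute `ks_ok = FALSE` and a warning. Deterministic
#' under a fixed seed.
#'
#' @param cohort A [MevaCohort-class].
#' @param n Samples per arm (must be available in both arms).
#' @param seed Integer seed.
#' @param ks_p KS acceptance threshold (default 0.05).
#' @param max_retry Retry cap (default 50).
#' @return A [MevaCohort-class] with `2n` samples and attributes `ks_ok`
#'   and `ks_min_p`.
#' @export
stratifiedSubsample <- function(cohort, n, seed = 1, ks_p = 0.05,
                                max_retry = 50) {
  lab <- sampleLabels(cohort)
  cases <- which(lab == "case"); ctrls <- which(lab == "control")
  if (n > length(cases) || n > length(ctrls))
    stop("n exceeds available samples per arm")
  sex <- colData(cohort)$sex
  pcs <- as.matrix(colData(cohort)[, paste0("PC", 1:5)])
  draw <- function() {
    ci <- sample(cases, n)
    sex_tab <- table(sex[ci])
    ki <- integer()
    for (sx in names(sex_tab)) {
      pool <- ctrls[sex[ctrls] == sx]
      if (length(pool) < sex_tab[[sx]])
        stop("not enough controls of sex ", sx, " for 1:1 matching")
      ki <- c(ki, sample(pool, sex_tab[[sx]]))
    }
    list(ci = ci, ki = ki)
  }
  local_seed(seed, {
    best <- NULL; best_p <- -Inf
    for (try in seq_len(max_retry)) {
      d <- draw()
      ks <- vapply(1:5, function(j)
        suppressWarnings(ks.test(pcs[d$ci, j], pcs[d$ki, j])$p.value),
        numeric(1))
      if (min(ks) > best_p) { best <- d; best_p <- min(ks) }
      if (min(ks) > ks_p) break
    }
    ok <- best_p > ks_p
    if (!ok)
      warning("KS matching criterion not met after ", max_retry,
              " draws (best min p = ", signif(best_p, 3), ")")
    out <- cohort[, c(best$ci, best$ki)]
    attr(out, "ks_ok") <- ok
    attr(out, "ks_min_p") <- best_p
    out
  })
}

#' Down-sampling robustness grid
#'
#' Re-runs a gene-ranking procedure on stratified sub-cohorts over a grid
#' of arm sizes and repetitions and scores each run against the full-cohort
#' reference: (a) overlap of the top `top_n` genes with the full-cohort
#' top `top_n` plus its hypergeometric p, (b) overlap of the top `top_n`
#' with a gold-standard set plus hypergeometric p, and (c) AUROC of the
#' gold set over the run's full ranking. A `size = NA` row records the
#' full-cohort run itself (self-overlap is `top_n` by construction).
#' Per-cell child seeds are derived deterministically from the master seed
#' so any cell can be re-run in isolation.
#'
#' @param cohort Full [MevaCohort-class].
#' @param sizes Integer arm sizes (default
#'   `c(500, 1000, 5000, 10000, 15000, 20000)`).
#' @param reps Repetitions per size (default 5, drawn independently).
#' @param seed Master integer seed.
#' @param rankFun `function(cohort, seed)` returning a named p-value
#'   vector over genes (smaller = more significant).
#' @param gold Character vector of gold-standard genes.
#' @param top_n Size of the head list (default 100; if fewer genes are
#'   ranked, all are used with a warning).
#' @return List with `grid` (`data.frame`: `size`, `rep`, `overlap_full`,
#'   `p_full`, `overlap_gold`, `p_gold`, `auroc_gold`, `ks_ok`) and
#'   `occurrence` (per-gene count of top-`top_n` appearances across runs).
#' @export
robustnessGrid <- function(cohort, sizes = c(500, 1000, 5000, 10000,
                                             15000, 20000),
                           reps = 5, seed = 1, rankFun, gold,
                           top_n = 100) {
  stopifnot(is.function(rankFun))
  ref <- rankFun(cohort, seed)
  universe <- names(ref)
  if (length(universe) < top_n) {
    warning("fewer than ", top_n, " ranked genes; using all")
    top_n <- length(universe)
  }
  top_of <- function(p) names(sort(p))[seq_len(top_n)]
  ref_top <- top_of(ref)
  gold <- intersect(gold, universe)
  occurrence <- stats::setNames(numeric(length(universe)), universe)
  score_run <- function(p, size, rep, ks_ok) {
    tp <- top_of(p)
    occurrence[tp] <<- occurrence[tp] + 1
    of <- hypergeomOverlap(tp, ref_top, universe)
    og <- hypergeomOverlap(tp, gold, universe)
    data.frame(size = size, rep = rep,
               overlap_full = of$k, p_full = of$p,
               overlap_gold = og$k, p_gold = og$p,
               auroc_gold = auroc(-p, universe %in% gold),
               ks_ok = ks_ok)
  }
  rows <- list(score_run(ref, NA_integer_, 0L, TRUE))
  for (si in seq_along(sizes)) for (r in seq_len(reps)) {
    cs <- child_seed(seed, si, r)
    sub <- stratifiedSubsample(cohort, sizes[si], seed = cs)
    p <- rankFun(sub, cs)
    rows[[length(rows) + 1]] <- score_run(p[universe], sizes[si], r,
                                          attr(sub, "ks_ok"))
  }
  list(grid = do.call(rbind, rows), occurrence = occurrence)
}
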