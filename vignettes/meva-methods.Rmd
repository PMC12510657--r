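---
title: "Impact-aware meta-analytic gene-disease association with meva"
author: "meva authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impact-aware meta-analytic gene-disease association with meva}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meva)
```

## The problem

Conventional gene-based case/control association tests treat every
qualifying allele as equivalent. When most of a gene's burden signal is
carried by a handful of functionally severe alleles, that choice costs
power. `meva` implements a meta-analytic framework for *impact-aware* gene
discovery: every protein-coding alternate allele carries a 0-100 functional
impact score (an Evolutionary Action score for missense variants; the
maximal score 100 for loss-of-function classes), three complementary
gene-level tests are run on the scored cohort, and their p-values are
merged per gene with the Cauchy combination test. A battery of validation
statistics, an effect-direction module, a prioritization score and a
down-sampling harness complete the pipeline. Because the framework is
designed for large cohort data that typically cannot be redistributed, the
package
ships first-class synthetic generators for every input it consumes.

## Data model

A cohort is a `MevaCohort`, extending `SummarizedExperiment`:

* rows are alternate alleles (multiallelic sites decomposed, one row per
  alt), annotated with gene, consequence class, raw EA score and allele
  frequency;
* the single `dosage` assay holds sparse allele-copy counts (0/1/2);
* columns are samples with a case/control label, sex and five ancestry
  principal components;
* gene models (interval plus protein length of the largest transcript)
  live in a `GRanges` slot.

Inclusion rules: an allele qualifies when its consequence is missense or a
loss-of-function class (stop-gained, frameshift, stop-lost, splice-donor,
splice-acceptor) and its allele frequency is at most 0.5 (boundary
inclusive). `assignImpactScores()` scores qualifying alleles: missense
keeps its EA value unchanged, loss-of-function classes are forced to 100
even if an EA value is annotated — the rule is categorical. All
coordinates are 1-based inclusive; BED input is converted at the reader.

## The equipartition burden statistic

For gene $i$ with protein length $L_i$, group energy
$E_i = \sum_{\text{samples}} \sum_{\text{alleles}} \text{score} \times
\text{copies}$ (a homozygote contributes twice; a carrier-mode switch is
exposed for sensitivity analysis), total group energy $E$ and total
proteomic length $L$:

$$\sigma_i = \frac{L\,E_i}{L_i\,E}$$

Under equipartition — mutational energy uniform per residue — every gene
scores exactly 1, and $\sum_i \sigma_i L_i E / L = E$ (energy
conservation, asserted in the tests). The case/control contrast is
$\Delta\sigma_i = \sigma_i^{\text{controls}} - \sigma_i^{\text{cases}}$,
with $\sigma$ computed within each arm separately (arm-specific energies
and totals; the length total covers every modelled gene, including those
with no observed variants). Significance comes from permuting labels
(default 1,000 times, arm sizes preserved): the observed
$\sigma_i^{\text{cases}} - \sigma_i^{\text{controls}}$ is standardized by
the null's mean and standard deviation, so a *positive* z means higher
case burden, and $p = 2\Phi(-|z|)$. An empirical rank p, floored at
$1/(B+1)$, is reported alongside; genes whose null has zero spread are
flagged degenerate and excluded from calls. The significance call is
$|z| \ge 3$.

Two presentation choices deserve a note. First, the statistic is stored as
printed ($\Delta\sigma$ = controls − cases) while the z is oriented
cases − controls; both conventions circulate and the orientation of z is
what the significance call uses. Second, z comes from null moments rather
than the empirical rank, because 1,000 permutations cannot resolve the
tail beyond $10^{-3}$ while the moment-based z extrapolates smoothly — the
rank p is kept for readers who prefer it.

## Component tests

**EA-threshold feature test** (`eamlLikeTest`). For thresholds
$(30, 70, 100)$ each sample × gene pair yields six binary features:
*dominant* (≥ 1 allele copy with score ≥ t) and *recessive* (≥ 2 copies)
per threshold. A fixed linear scorer collapses them — weight $t/100$ for
dominant, $2t/100$ for recessive, so stringent thresholds and biallelic
genotypes weigh more. The statistic is the mean held-out AUROC over
stratified cross-validation folds (default 10), calibrated by a
case/control label-permutation null shared across genes. We deliberately
use a fixed, fully specified scorer instead of a trained classifier
ensemble: the meta-layer needs *calibrated* component p-values, and a
fixed scorer makes the permutation null exact and cheap. The threshold
triple mirrors the gain/loss-of-function impact bins; it is a configurable
assumption, not an estimated quantity.

**Network differential-burden test** (`networkDiffTest`). Edge weights of
a protein-interaction graph are multiplied, per arm, by the sum of the two
endpoint genes' per-sample mean energies; each network gene is scored by
the L1 distance between its restart-walk diffusion profiles (restart 0.5)
in the case- and control-weighted networks, with a label-permutation p.
This is a transparent stand-in for learned node-embedding distances; the
combination layer accepts externally computed p-values
(`componentPValues`) so genuine external results can be plugged in. Genes
absent from the network are `unscored` and contribute no evidence (they
are *not* assigned p = 1 for combination — see below). Because this class
of score can up-rank hubs, `controlMask()` splits the controls in half at
random, reruns the test control-vs-control, and returns genes reaching
BH FDR ≤ 0.1 in any split for masking.

A structural property worth knowing: the diffusion operator column-
normalizes the arm-weighted adjacency, so a *uniform* energy elevation
across a module largely cancels. The network component is therefore
sensitive to energy *contrast* along edges — e.g. a gene adjacent to
strongly burdened partners — which is exactly the guilt-by-association
signal it exists to contribute.

## The Cauchy combination

Per gene, the unmasked available component p-values are combined with

$$T = \sum_{i=1}^{d} \omega_i \tan\{(0.5 - p_i)\pi\}, \qquad
p = 0.5 - \arctan(T)/\pi,$$

equal weights over available components (user-overridable; there is no
principled basis for unequal weights). Each term is standard Cauchy under a uniform
null, and the tail of $T$ stays approximately Cauchy under arbitrary
dependence — the reason this combiner is safe for three tests run on the
same variants. Numerical choices:

* p-values of exactly 1 (possible for permutation p's) are clipped to
  $1 - 10^{-15}$ before the tangent;
* in double precision the back-transform cannot produce a value below
  $2^{-54} \approx 5.6 \times 10^{-17}$ (the spacing below 0.5);
  underflowed genes are flagged, pinned at the floor for ranking, and
  displayed as `"<5.6e-17"`; `cctFloor()` recomputes the floor by scanning
  $T$ upward;
* ranks use minimum-rank ties, so all floored genes share rank 1;
* degenerate sigma genes, constant-feature genes and network-unscored
  genes contribute `NA`, and weights are renormalized over the remainder —
  an artificial p = 1 would act as strong evidence *against* association
  under the tangent transform.

Significance is called at $p < 10^{-5}$ (strict; floored genes count),
with BH q-values as an auxiliary column. At ~18,000 genes this threshold
implies ~0.18 expected false positives per scan, while the Bonferroni
bound would be $2.8\times10^{-6}$; both constants are exposed as
`expectedFalsePositives()` and `bonferroniThreshold()`.

## Validation battery

`hypergeomOverlap` (one-tailed overlap against a universe), `colocalize`
(gene within 0.5 Mbp of an associated locus; one-tailed Fisher against
background), `firstNeighborZ` (high-confidence edges, weight > 0.9, from
candidates to a gold set vs 100 degree-matched random sets; degree
deciles, nearest-bin fallback), `diffuse` / `diffusionAurocZ`
(restart-walk ranking of targets, mid-rank AUROC, degree-matched null,
z > 2 significant), `matchedCountEnrichment` (count bins ≥ 1 and ≥ 50 vs
uniform random sets), `annotationEnrichment` (per-term z against 5,000
representation-matched sets, BH q < 0.05, optional comparison to a
true-positive term list), `mclCluster` (expansion = matrix squaring,
inflation 1.5, prune $10^{-8}$, converge at $10^{-6}$ max column change,
cap 100 iterations; unit self-loops; clusters = components of the
converged flow's support) and `clusterEnrichment` (BH separately within
each cluster, FDR < 0.05). Wherever "FDR" appears it is Benjamini-
Hochberg. The diffusion implementation is iterative; the tests check it
against a direct linear solve, AUROC against the pairwise Mann-Whitney
form, and the exact tests against enumeration on small universes.

## Effect direction

`collapseCarriers` collapses a gene sample-wise: a carrier holds ≥ 1
allele copy with impact in a half-open bin — gain-of-function proxy
$(30, 70]$, loss-of-function proxy $(70, 100]$, so score-100 alleles fall
in the LOF bin — at allele frequency strictly below the ceiling (0.5 by
default; 0.05 for rare-variant reruns; an exclusion list supports
dropping a single driver allele). `fisherOr` reports the cross-product
odds ratio with a Haldane-Anscombe 0.5 correction when a cell is zero, a
Woolf log-normal 95% CI (a conventional choice where no single
standard exists), and the two-sided exact p. `fdrByBin` applies BH within each
impact bin separately.

## Prioritization and robustness

`priorityScores` sums ten per-gene metrics in $[0,1]$ grouped as robust
signal (2: inverse-rank of the meta p per cohort), genetic (4), pathway
(2) and phenotype (2); `inverseRankScore` gives the best gene 1, the next
$(N-1)/N$ and so on with minimum-rank ties (at $N = 100$: 1, 0.99, ...),
and `binaryMetric` is a membership indicator. Missing evidence scores 0;
totals live in $[0, 10]$.

`stratifiedSubsample` draws n cases and n controls with exactly matched
sex counts and two-sample KS p > 0.05 on each of the five ancestry PCs
(up to 50 redraws, then the best attempt is returned flagged — the
matching criterion is part of the method; the retry procedure is an
implementation choice).
`robustnessGrid` re-runs a ranking over sizes × repetitions (defaults
500-20,000 per arm, 5 independent repetitions) and scores top-100 overlap
with the full-cohort ranking, top-100 overlap with a gold set, and gold
AUROC over the full ranking, with per-cell child seeds derived
deterministically from the master seed so any cell can be re-run alone.

## Synthetic data: what it emulates and what it does not

`simulateCohort` draws log-normal protein lengths (median ≈ 430
residues), Poisson variant sites per gene (mean 8), a consequence mix
with 15% non-qualifying sites and a 10% loss-of-function mass scored 100,
Beta(0.8, 0.8)-shaped missense EA on (0, 100), and an allele-frequency
spectrum of 85% rare (Beta(0.3, 30)) plus 15% common (uniform on
0.05-0.5) alleles under Hardy-Weinberg genotypes. Sexes are matched
exactly 1:1 and the five PCs come from one shared Gaussian, so arms are
exchangeable by construction. Planted genes multiply the at-risk arm's
allele frequency for *rare* in-bin alleles (baseline AF ≤ 0.05) — a
multiplier on common alleles would be infeasible and unrealistic — with
three guaranteed in-bin sites per planted gene; mechanisms are LOF-risk
(excess case carriers in $(70, 100]$), GOF-risk ($(30, 70]$) and
protective (control excess). A ground-truth manifest is emitted so every
recovery property can assert against it. `simulateNetwork` (stochastic
blocks, weights in (0, 1]), `simulateOntology` (random tree, annotations
propagated to ancestors), `simulateLoci` and `simulateCounts` cover the
remaining inputs.

Not emulated: linkage disequilibrium, coalescent site-frequency spectra,
ancestry structure beyond Gaussian PCs, sequencing artefacts, relatedness
and genotype error. Passing recovery tests therefore demonstrate the
statistical machinery under clean exchangeable nulls with planted
effects; they do not certify behaviour under real-cohort confounding,
which the upstream QC the package deliberately excludes is meant to
handle.

## Problem sizes used by the shipped checks

The packaged checks run, per scenario: null calibration on 2,000 genes at
1,000 samples per arm with 1,000 permutations; planted-gene recovery and
the split-mechanism property on 2,000 genes at 2,000 per arm over five
fixed seeds (a 300-node network; 1,000/200/100-200 permutations for the
three components); odds-ratio recovery at 5,000 per arm over 50 seeds;
and the down-sampling grid on 1,000 genes with arms 500/1,000/5,000 ×
5 repetitions against a 5,000-per-arm reference. These sizes were chosen
so the full battery runs on a laptop in minutes while keeping Monte-Carlo
error well inside the asserted tolerances.

In the split-mechanism scenario, "detectable only by the network
component" is realized as guilt-by-association: the network half carries
sub-threshold burden (allele-frequency multiplier 1.3, individually below
the $|z| \ge 3$ call in expectation) and shares a tight module with the
strongly burdened half, so only propagation ranks it highly; the burden
half is absent from the network. As noted above, a uniformly elevated
module is nearly invisible after column normalization, so association
contrast — not aggregate module burden — is the designed signal.

## Known limitations

* The EAML-like and network components are transparent stand-ins, not
  reimplementations of the published classifier ensemble or node-embedding
  method; `componentPValues` accepts external p-values precisely so the
  genuine tools can take their place.
* The Cauchy combiner treats a component p near 1 as evidence against; a
  gene strongly supported by one component can be demoted by an extreme
  null draw in another. This is inherent to the tangent transform and is
  why unavailable evidence enters as `NA`, never as p = 1.
* Permutation z from moments assumes the permutation null is roughly
  normal per gene; genes dominated by one common high-impact allele can
  deviate — the degenerate flag and the empirical rank p are the guard
  rails.
* The restart-walk and MCL parameters (restart 0.5, inflation 1.5) are
  standard literature settings; neither is tuned per dataset.
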