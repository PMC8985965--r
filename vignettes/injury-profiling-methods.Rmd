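---
title: "Methods: latent class injury profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent class injury profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
measurement model and its assumptions, the numerical choices inside the
EM fitter, the model-selection and diagnostic statistics, the injury
coding conventions, what the synthetic-cohort generator does and does not
emulate, and the design decisions taken where the methodology left a
genuine choice.

## The measurement model

A cohort is an N × J binary table: casualty i has indicator
$x_{ij} = 1$ when at least one of their injuries falls in Barell matrix
cell j. The latent class model is a K-component mixture of independent
Bernoulli items,

$$P(x_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J}
  \rho_{jk}^{x_{ij}} (1 - \rho_{jk})^{1 - x_{ij}},$$

with mixing proportions $\pi_k$ (class prevalences) and conditional item
probabilities $\rho_{jk}$. Its assumptions are worth stating plainly:

* **Local independence.** Given class membership, indicators are
  independent. Co-occurrence of injuries is explained entirely by class;
  residual dependence (e.g. mechanistically linked wounds within a class)
  is not modeled and will inflate the apparent number of classes.
* **Casualty events are exchangeable rows.** A person injured twice
  contributes two independent rows.
* **No covariates in the measurement model.** Covariates are compared
  *across* fitted profiles afterwards; they do not inform class
  membership (no concomitant-variable extension).

## EM fitting

`fit_lca()` maximizes the observed-data log-likelihood by
expectation–maximization:

* **E-step.** Responsibilities
  $t_{ik} \propto \pi_k \prod_j \rho_{jk}^{x_{ij}}(1-\rho_{jk})^{1-x_{ij}}$
  are computed in log space. Because items are binary the per-class
  log-densities collapse to a single matrix product,
  $\log f_k(x_i) = x_i^\top(\mathrm{logit}\,\rho_k) + \sum_j \log(1-\rho_{jk})$,
  followed by a row-wise log-sum-exp; no probability is ever formed on
  the raw scale.
* **M-step.** $\pi_k$ is the mean responsibility and $\rho_{jk}$ the
  responsibility-weighted item mean, clipped to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$. Clipping
  prevents $\log 0$ and absorption at the boundary; at cohort scale its
  likelihood effect is far below the convergence tolerance. A class whose
  total responsibility collapses to numerical zero aborts the run (a
  restart signal), rather than continuing with an empty component.
* **Initialization and restarts.** Each restart draws row-stochastic
  responsibilities from a flat Dirichlet and starts with an M-step. The
  default is 20 restarts; the best final log-likelihood wins. The
  restart count and tolerance are package choices — standard practice
  for mixture likelihoods with many local optima.
* **Convergence.** Relative log-likelihood improvement below $10^{-8}$
  or 5,000 iterations. EM's ascent property is asserted in the test
  suite over randomized instances.
* **Canonical order and ties.** Mixture likelihoods are invariant to
  label permutation, so classes are reported in a canonical order:
  descending $\pi_k$, ties broken by the first item's probability. Hard
  assignment is the maximum-probability rule with ties going to the
  lowest class index. Both rules are arbitrary but fixed, which makes
  runs reproducible.
* **K = 1.** The model has a closed form (item marginal frequencies);
  the EM path reaches it in one effective iteration and the equality is
  tested exactly.

## Choosing the number of classes

`scan_lca()` fits each K in a range and tabulates, with
$p = KJ + (K-1)$ free parameters:

| criterion | penalty |
|---|---|
| BIC | $p \ln N$ |
| SABIC | $p \ln\frac{N+2}{24}$ |
| AIC | $2p$ |
| CAIC | $p(\ln N + 1)$ |

The SABIC and CAIC penalty dialects matter: with these forms, the
criteria recomputed from a published fit table's log-likelihoods
reproduce that table's printed values to its rounding, which is how the
dialect was confirmed. The automatic selection is the CAIC minimum — the
stated quantitative basis of the published analysis — but the full table
is always reported, because "coherent, interpretable classes" is a human
judgement the package deliberately does not automate.

Classification quality is summarized two ways:

* **Relative entropy**
  $E = 1 - \sum_i \sum_k (-t_{ik} \ln t_{ik}) / (N \ln K)$, in $[0,1]$,
  with $0\ln 0 := 0$; reported as missing for K = 1 rather than defined
  as 1. Values above 0.80 are conventionally read as good
  classification. The standardized (relative) form is used because it is
  the form bounded in $[0,1]$.
* **Classification diagnostics**: the K × K matrix of mean posterior
  probabilities by assignment group. Diagonals above 0.70 with
  off-diagonals at or below 0.05 mark well-separated classes; empty
  assignment groups are flagged, not dropped silently.

## Profile labeling and comparisons

A class's defining items are those with $\rho_{jk} \ge 0.30$, boundary
inclusive, listed in descending probability; the threshold is the
conventional labeling rule for this analysis and is tunable. Naming the
resulting profiles is analyst-supplied — thresholded item lists are
evidence, not names.

Covariates are compared across profiles with Pearson chi-square tests
(no continuity correction) on the level × class count table, and with
pairwise two-proportion chi-square tests for every pair of classes,
Holm-adjusted. Two conventions deserve note, both flagged in output:

* **The Holm family is one level of one variable** — the
  $\binom{K}{2}$ pairwise tests behind one report row. The alternative
  (all levels of a variable jointly) is defensible; the per-level family
  matches the row-wise superscript presentation standard in
  characteristics tables and is the convention here.
* **"Unknown" categories are displayed but not tested** (e.g. unknown
  combat posture). They are explicit categories, not missing data, but
  pairwise significance marks on an unknown row would compare data
  completeness, not epidemiology.

Percentages in reports are rounded half-up to one decimal — the printed
convention of epidemiological tables, not R's round-half-even — and tests
always use unrounded counts.

## Injury coding and severity

`classify_injury()` resolves record-level (region, nature) codes to cells
of the extended Barell matrix through a bundled dialect table that covers
all 36 × 13 cells and accepts either dialect keys or human-readable
names. Fracture records must carry an open/closed flag (or an explicit
"fracture (open)"-style nature); routing to the split fracture columns is
part of classification, not display. The indicator matrix records
presence, never multiplicity, and by default keeps only populated cells,
in deterministic row-major Barell order.

ISS is the sum of squared maxima of AIS over the three most severely
injured of the six standard ISS body regions, with severity bands
serious 9–15, severe 16–24, critical ≥ 25. Three conventions are
declared explicitly because the standard leaves them to the implementer:

* **The Barell-row → ISS-region bridge** ships as the `iss_region`
  column of `barell_regions()` and can be replaced by the caller. The
  assignment of spine rows (cervical to head/neck, thoracic to chest,
  lumbar/sacral to abdomen) and of the bony pelvis to extremities
  follows common ISS practice, but no published crosswalk accompanies
  the matrix, so the bridge is a convention, not a reproduction.
* **AIS 6 sets ISS to 75**, the standard convention; survivor cohorts
  rarely exercise it.
* **Ties among region maxima need no rule**: the sum of the three
  largest squared maxima is tie-invariant, which the tests verify
  against brute-force subset maximization.

## The synthetic cohort generator

The generator exists because the registry data behind the published
7-profile analysis is restricted. It emulates exactly the structure the
model assumes: classes drawn from mixing proportions, items set
independently given class, covariates drawn from class-conditional
categorical distributions.

Defaults are the published study conditions wherever those are stated:

* **Class shares** come from the published class sizes
  (981, 742, 353, 804, 1036, 387, 924 of 5,227), which form an exact
  simplex; the rounded percentage form does not.
* **The 26 signal items** carry the published conditional item
  probabilities for all seven classes (`profile_item_probabilities()`).
* **All other items get a background rate of 0.05** — the published
  solution reports only above-threshold items, so sub-threshold
  probabilities are unknown; a single low constant keeps the generator
  simple and the true class count recoverable in well-separated designs.
* **The covariate model** uses the published class-wise category counts
  for age group, sex, service branch, combat location, year period,
  injury mechanism, and combat posture, with "unknown" posture as an
  explicit category. One published count (year period 2009–2019 in the
  Type 2 TBI class) is internally inconsistent with its class size and
  its printed percentage; the value satisfying both margins (533) is
  used.
* **The AIS severity model** for record expansion defaults to
  (0.60, 0.30, 0.085, 0.013, 0.002) over AIS 1–5 for every cell, chosen
  once so that expanded cohorts are dominated by serious-to-severe
  ISS with a small below-threshold fraction, qualitatively like survivor
  registries. It is not calibrated to any registry's severity
  distribution and is fully overridable per cell.
* **Seeding**: one master seed; each sampling stage (classes, items,
  covariates, severities) uses a deterministically derived child seed,
  so any stage can be replayed alone and full runs are byte-identical.

For class counts other than seven, the generator builds a block template
(each class elevates its own block of items to 0.8 against the 0.05
background, equal mixing). This well-separated design is what the
class-count recovery study uses: 3 classes, 30 items, N = 2,000, scanned
over K = 1..5 with 5 restarts, replicated 20 times — sizes chosen to
make the CAIC minimum a sharp, quickly computable check.

### What the emulation does not claim

The default template carries class signal **only in the 26 published
items**; the other 155 indicators are noise by construction. In the real
registry the sub-threshold items evidently also carry class information,
so the synthetic cohorts are *harder to classify* than the real data:
the Bayes-optimal classifier under the true generating parameters —
computable here precisely because the truth is known — attains only
moderate assignment agreement and relative entropy below the 0.80
convention at N = 5,000. Consequences to keep in mind:

* Recovery of the signal-item probabilities is excellent (mean absolute
  error ≈ 0.02 at N = 5,000 in the acceptance run), and diagnostics
  diagonals clear 0.70 — parameter estimation is not the bottleneck.
* Hard-assignment agreement (adjusted Rand index) and entropy on these
  cohorts sit well below the values the published solution reports for
  real data, and *no fitted model can close that gap*, because the
  limit is the generating model's own separability.
* Penalized criteria at these conditions can prefer fewer than seven
  classes, merging weakly separated profiles; this is correct behavior
  of the criteria on these data, not a fitting failure.

Passing tests on synthetic cohorts therefore demonstrate correctness of
the machinery and recoverability of well-separated structure — they do
not certify performance on any real registry.

## Degenerate inputs and numerical edges

* Empty cohorts: indicator construction returns a zero-row,
  zero-column-beyond-id table with a warning; fitting refuses them.
* Items constant in the data: estimates clip at
  $\varepsilon = 10^{-6}$, never 0 or 1.
* Zero-margin rows or columns in comparison tables are dropped with a
  warning; expected counts below 5 flag the chi-square approximation.
* A covariate level absent from both classes of a pair is skipped, and
  the Holm family size shrinks accordingly.
* All probabilities and simplexes are validated at configuration time;
  mixing proportions must sum to 1 within $10^{-12}$.

## Problem sizes in the test and acceptance runs

The suite's simulation sizes are chosen to make each property sharp at
desk scale: generator marginals and independence at N = 20,000;
parameter recovery and classification diagnostics at the published
study conditions (K = 7, J = 181, N = 5,000, 20 restarts); class-count
recovery on 20 replicates of the 3-class design; oracle equivalences on
hundreds to a thousand randomized small instances. The acceptance script
(`scripts/acceptance.R`) re-runs the recovery fit and the selection study
from scratch under a caller-supplied seed.

## Known limitations

* Local independence is an approximation; real injury data exhibit
  within-class dependence (ballistic trajectories, blast geometry) that
  the model attributes to extra classes.
* The ICD-to-Barell dialect bundled here is a self-contained convention
  sufficient for the package's coding granularity; it is not the
  official ICD-9-CM crosswalk, and no ICD-10 support is provided.
* No standard errors on $\pi$ or $\rho$, no bootstrap likelihood-ratio
  test for K, and no covariate-adjusted (regression-based) class
  comparisons.
* The ISS region bridge is editable precisely because it is a
  convention; analyses sensitive to the bridge should vary it.
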