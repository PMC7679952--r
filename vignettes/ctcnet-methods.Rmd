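---
title: "Models and conventions behind ctcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind ctcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcnet)
```

`ctcnet` analyses the cerebello-thalamo-cortical (CTC) network — bilateral
cerebellar Crus I/II, thalamus, dorsolateral prefrontal cortex (DLPFC) and
precuneus — in survivor cohorts, from regional time courses through
functional-connectivity graphs, permutation inference, effective
connectivity (Bayesian networks), and cohort statistics. This vignette is
the package's own account of its models, assumptions, conventions and
limitations. It states no empirical claim that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The functional connectivity model

Per subject, regional signals are Pearson-correlated and Fisher-transformed,
$z_{ij} = \operatorname{atanh}(r_{ij})$, with $r$ clipped to
$\pm(1 - 10^{-7})$ so degenerate (perfectly correlated) pairs stay finite.
Graphs are built by **proportional density thresholding**: at density $d$,
the $\lceil d \cdot n(n-1)/2\rceil$ largest *positive* entries become binary
undirected edges.

Conventions worth making explicit, because different connectomics pipelines
choose differently:

* **Negative correlations are never admitted as edges.** Anticorrelation has
  no agreed graph-theoretic interpretation in small a-priori networks; this
  is the common connectomics default.
* **Graphs are analysed as binary** after thresholding. Weighted efficiency
  would mix the thresholding decision with edge strength; the binary form
  keeps "density" and "topology" orthogonal.
* **Ties** in the ranking of entries are broken by the fixed lexicographic
  region-pair order, so thresholding is exactly reproducible and the edge
  set at a lower density is always a subset of the edge set at a higher
  one.
* **Per-subject thresholding** is the default (each subject's matrix is
  thresholded on its own ranking). Whether a study thresholds per subject or
  on group means is an open choice; group-level work can pass a group-mean
  matrix through the same functions.
* The operational meaning of "removing false-positive connections" is the
  **minimum-density search** (`find_minimum_density()`): scan an ascending
  grid (default 0.05–0.50 by 0.01) and return the smallest density at which
  no region is isolated. A subject for whom no grid density achieves this is
  *fragmented*; efficiency is still computed (unreachable pairs contribute
  zero) and the subject is flagged and reported separately, mirroring how
  fragmented subjects are tabulated apart in cohort summaries.

## Graph metrics

Global efficiency is the standard binary definition
$E = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}$ on hop-count shortest paths,
with $1/\infty = 0$; it is 0 for an edgeless graph and 1 for a complete one.
Shortest paths are computed by boolean walk expansion, which is exact and
essentially free at 6–8 nodes; the test suite verifies it against a
Floyd–Warshall oracle on *every* graph with up to 6 nodes and against
`igraph::distances()` on random graphs.

The within-module degree z-score uses the **population (divide-by-n) SD**
within each module, with $z = 0$ whenever a module's within-degrees have
zero SD (including singleton modules). The bilateral network is analysed as
one graph with **hemispheric modules** (left/right) by default; any named
partition can be supplied.

## Permutation inference

Group differences in subject-level metrics are tested by shuffling group
labels across subjects — the subject is the exchangeable unit — and the
one-sided p-value is the proportion of permutation mean differences greater
than or equal to the observed one, out of `n_perm = 2000` by default. This
literal rule can return $p = 0$; a `plus_one` flag gives the
$(b+1)/(B+1)$ variant, and `sided = "two"` compares absolute values. The
95% band of the null distribution is reported alongside, since "observed
difference outside the null interval" is the decision rule this style of
analysis prints. Exhaustive enumeration over all
$\binom{n}{n_1}$ assignments replaces sampling when requested, and the type-I
error of the sampled test is verified by simulation to sit near the nominal
5%.

## Effective connectivity

### Score

Structure learning is score-based over linear-Gaussian DAG models. Per node
$j$ with parent set $P_j$, ordinary least squares with intercept gives
$\mathrm{RSS}_j$, and

$$\mathrm{score}(j) = -\tfrac{n}{2}\log(\mathrm{RSS}_j/n)
  - \tfrac{|P_j|+2}{2}\log n,$$

counting $|P_j|$ coefficients, an intercept, and a residual variance. The
total score sums over nodes (decomposability), is invariant to column order,
and is computed from the ML covariance matrix, so its cost is independent of
the number of samples once the covariance is formed. The score family is a
design choice: "score-based" does not pin down Gaussian BIC, but it is the
natural penalized-likelihood score for continuous, approximately Gaussian
regional time courses; a Bayesian Gaussian equivalent (BGe) score would slot
into the same search.

### Search

`hill_climb_structure()` is greedy hill-climbing over single-edge add /
delete / reverse moves, accepting the best strictly improving acyclic move.
Two standard refinements matter in practice:

* a bounded **tabu phase**: when no improving move exists, the best
  non-improving move is accepted (never undoing one of the last 10 moves),
  up to 15 consecutive non-improving steps, and the best structure seen is
  returned. Pure greedy search reliably sticks in collider-orientation local
  optima on this network family; with the tabu phase, the search attains the
  true structure's score in every seeded replicate the suite runs.
* **random restarts** (default 10): the first climb starts from the empty
  graph; later starts alternate between perturbations of the incumbent and
  fresh random sparse DAGs. The result can therefore never score below the
  empty graph. Everything is deterministic given `seed`; move ties break in
  a fixed operator/edge order; per-node score caching cannot change results
  because the score decomposes.

On 3- and 4-node problems the search is verified against exhaustive
enumeration of all 25 / 543 DAGs.

### Equivalence classes, not over-claimed arrows

Gaussian likelihoods cannot distinguish Markov-equivalent DAGs: a two-node
edge's direction is unidentifiable, and only skeletons plus v-structures
(colliders) are. `ctcnet` therefore reports stratified comparisons at both
the raw DAG level and the **CPDAG** level (`cpdag()`, `markov_equivalent()`,
`structural_hamming(..., equivalence = TRUE)`), and `structure_recovery()`
separates *recall* of the identifiable structure (every true skeleton edge
and v-structure found) from exact equivalence-class identity, which
additionally forbids false-positive edges. At 500 timepoints BIC admits a
spurious edge with probability of roughly 1% per candidate pair, so exact
identity fails in a substantial minority of replicates even when the search
is perfect — a property of the score, not a defect of the optimizer.

### Stratified and common models

Subjects are pooled within each sex × impairment stratum by z-scoring each
region's time course per subject and concatenating rows. Whether a study
pools or models subjects hierarchically is rarely stated in this literature;
pooling with per-subject standardization is the simplest scheme that removes
subject-level scale differences, and it is stated prominently here because
it affects effective sample size (timepoints × subjects). The common model
is learned the same way on the whole cohort; per-subject **edge weights**
are then the least-squares coefficients of each child on its common-model
parents. Standardized coefficients (default) feed the ANOVA; raw-scale
coefficients (`standardize = FALSE`) are what recover the generating weights
in simulation, and the two scales differ whenever node variances are not 1.

The sex × impairment **interaction ANOVA** on the cerebellum–DLPFC edge
(either orientation; left hemisphere preferred, matching where group
differences concentrate) uses `lm()` with Type II sums of squares via
`car::Anova()` — the appropriate choice for unbalanced cells, and identical
to the textbook decomposition when the design is balanced (verified against
a direct sums-of-squares oracle).

## Cohort statistics

* **Impairment**: a measure is impaired when its age-adjusted z is *strictly*
  below −1.3 (the 10th percentile of the reference distribution); a subject
  is executively impaired when any of the six executive measures
  (number-letter switch, color-word switch, verbal fluency, digit backward,
  Rey–Osterrieth copy, 20 questions) is impaired.
* **Proportion intervals** are Wald, $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$,
  reported in percent to two decimals — this closed form reproduces the
  published impairment tables cell for cell, which is how the interval type
  was identified; a Wilson option exists for users who prefer boundary-safe
  intervals. At $k \in \{0, n\}$ the Wald interval collapses to a point and a
  warning is raised.
* **Morphometry–exposure–cognition models** are sex-stratified least squares
  with the *morphometric measure as the response* and the neurocognitive
  z-score, dexamethasone AUC, methotrexate AUC and intrathecal count as
  predictors, adjusting for age at diagnosis, age at assessment and
  intracranial volume. This orientation is what makes the published
  coefficient units (mm³ per 1-SD z, mm³ per g·hr/L, mm³ per intrathecal
  count) dimensionally coherent. One-sided p-values are available by flag.
* **FDR** control is Benjamini–Yekutieli (harmonic-factor step-up, valid
  under arbitrary dependence) by default, with Benjamini–Hochberg as the
  alternative, via `stats::p.adjust`.

## The synthetic cohort: what it emulates, and what it does not

The generator exists so that every pipeline stage, and every test, runs on
data whose ground truth is known.

**Ground-truth network.** The common structure has, per hemisphere,
cerebellum → thalamus (0.6), precuneus → thalamus (0.4), cerebellum → DLPFC
(0.5) and precuneus → DLPFC (0.5), with unit innovation SD. The two
colliders per hemisphere make *every* common edge compelled, so the common
equivalence class has a unique member — group comparisons of learned raw
DAGs are then well defined. Impaired female survivors get the planted group
difference: the precuneus → DLPFC edges are removed and the
cerebellum → DLPFC edges are reversed *and strengthened* (DLPFC → cerebellum
at 0.8), a difference in both direction and strength, which is what the
interaction ANOVA is designed to detect. The reversed edge sits in a chain,
so its direction is deliberately *not* identifiable — the package's
CPDAG-level reporting is exercised, not bypassed, by its own test data. The
language control network (bilateral BA 40/44/45) has weak within-hemisphere
edges (0.25) and no group differences.

**Time series.** Panels are drawn from the contemporaneous linear-Gaussian
structural model — children are weighted sums of parents plus Gaussian
noise, evaluated in topological order — optionally with variance-preserving
AR(1) innovation smoothing. The default 174 timepoints is derived from a
6-minute eyes-open resting acquisition at TR 2.06 s
($\lfloor 360/2.06 \rfloor$); the retained-volume count after scrubbing is
never printed in this literature, so the value is configurable. Per-subject
edge-weight jitter (SD 0.05) provides inter-individual variation in
connectivity strength.

**Subjects and scores.** Morphometry is drawn per sex with the published
survivor means and SDs (cerebellar and thalamic volumes, precuneus and DLPFC
thickness), correlated ~0.5 with intracranial volume. Exposure scales
(dexamethasone AUC ~500, methotrexate AUC ~1500, 13–25 intrathecal
administrations) are free parameters — published analyses report
coefficients, not exposure distributions — chosen once so configured slopes
are numerically stable. Neurocognitive z-scores are linear-Gaussian:
sex-specific baseline means/SDs matching the published cohort table, an
executive deficit shift (−1.0) for the latent impaired group, and optional
slopes on covariates. The latent impairment indicator is Bernoulli per sex
(default prevalence 0.35 — single-measure impairment rates in this
population range from ~8% to ~63%, and the latent group here represents the
subset with a qualitatively different network, not everyone crossing any
single threshold). With `enforce_labels = TRUE` (default) executive scores
are drawn by rejection sampling conditional on the label, so
`classify_impairment()` exactly rederives it; this conditioning necessarily
shifts marginal moments, so moment-fidelity checks use
`enforce_labels = FALSE`.

**What passing tests do and do not show.** The synthetic data are Gaussian,
stationary, contemporaneous and unconfounded. Real resting-state signals
have hemodynamic autocorrelation, motion artefacts, non-Gaussian tails,
shared nuisance signals and unmeasured confounders; none of these are
emulated, and no voxel-level, hemodynamic or pharmacokinetic simulation is
attempted. Tests passing on this generator demonstrate that the estimators
are correctly implemented and calibrated under their own assumptions — not
that those assumptions hold in any particular fMRI dataset. In particular,
published subject-level results (specific efficiency values, the printed
mean difference, the printed interaction F) depend on undeposited data and
are targeted only qualitatively: the pipeline plants an effect of the same
*kind* (higher efficiency and a sex × impairment edge-weight interaction)
and verifies detection, calibration, and parameter recovery.

## Numerical choices and degenerate inputs

* Correlation clipping at $1 - 10^{-7}$ before `atanh`; zero-variance
  regions are a named error, not a silent NaN.
* Thresholding with fewer positive entries than requested keeps all positive
  entries, records the achieved density and warns.
* Residual variances at or below machine epsilon, and singular parent
  designs, abort scoring with the offending node named.
* Strict score improvement uses a $10^{-9}$ tolerance; restart winners must
  beat the incumbent by the same margin, so ties keep the earlier
  (deterministic) model.
* Constant metrics in the permutation test return a zero difference with a
  warning rather than an error, since downstream summaries may still want
  the record.
* Problem sizes in the test suite are chosen to keep the full run in tens of
  seconds per file: exhaustive oracles run at ≤6 nodes (graphs) and ≤4 nodes
  (DAGs), calibration uses 1000 null replicates with 500 permutations,
  recovery uses 50 replicates at 500 timepoints, and power uses 100
  study-scale replicates with 3 search restarts.

## Interfaces

All user-facing functions take a data frame first and return tibbles; fitted
objects (`ctc_permtest`, `ctc_dag`, `ctc_anova`, `ctc_glm`) have `tidy()`,
`glance()` and `autoplot()` methods. `run_pipeline()` orchestrates the six
stages from one config (YAML-loadable via `read_config()`), derives
per-stage seeds from the global seed by stage-name hashing so stages can be
rerun in isolation, and writes every numeric output as CSV/JSON plus a
manifest with the config hash and seed table; rerunning a config reproduces
identical files. The package deliberately ships no shell entry point: it is
an analysis library, and the R functions, the pipeline driver and this
vignette are its interface.

## Known limitations

* Effective-connectivity direction claims are bounded by Markov equivalence;
  only colliders orient edges, and the package says so in its outputs.
* BIC's false-positive edge rate at a few hundred timepoints means learned
  models can carry an extra edge; consumers should prefer
  `structure_recovery()` / CPDAG comparisons over exact edge-set equality.
* The Wald interval is degenerate at the boundaries and anti-conservative at
  small $n$; it is the default only because it is the published convention
  this package reproduces.
* The permutation test assumes exchangeability under the null; metrics with
  strong covariate structure should be residualized first.
* No missing-data machinery: panels must be complete; per-measure cohort
  denominators are taken as given.
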