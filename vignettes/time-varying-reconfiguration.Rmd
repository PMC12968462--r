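---
title: "Time-varying brain network reconfiguration: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying brain network reconfiguration: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Resting-state functional connectivity is usually summarised as one
correlation matrix per scan, but the coupling between brain regions
fluctuates within a scan. This package quantifies those fluctuations at
the level of *network membership*: how often, and in what company, each
region leaves its canonical resting-state network for another. The
resulting node metrics (promiscuity, flexibility, cohesion,
disjointedness) can then be related to behavioural scores — the design
case is fatigue in multiple sclerosis cohorts — with conventional
covariate-adjusted statistics.

The pipeline is:

1. **Sliding windows.** A parcellated BOLD series (regions × timepoints,
   repetition time TR in seconds) is cut into overlapping windows of
   `window_seconds` (default 60 s) advanced by `step_seconds` (default
   10 s). Lengths are converted to samples by rounding, starts are
   $0, S, 2S, \dots$, and trailing samples not covered by a full window
   are dropped, so a 300-volume scan at TR = 1 s yields exactly
   $\lfloor(300-60)/10\rfloor + 1 = 25$ windows (26 with the 44 s
   variant).
2. **Windowed connectivity.** Within each window, all pairwise Pearson
   correlations are clipped to $[-(1-10^{-7}),\,1-10^{-7}]$ and mapped
   to nonnegative edge weights $w_{ij} = |\operatorname{atanh}(r_{ij})|$
   (absolute Fisher r-to-z). The diagonal is zero.
3. **Per-window community detection.** Regions are seeded with
   literature-based network labels (seven cortical resting-state
   networks plus one deep grey matter group, eight communities in
   total). Iteratively, the region with the lowest *assignment quality*
   is reallocated to the community with which it has maximal mean
   connectivity, until the same region is selected in two consecutive
   iterations, a reallocation changes nothing, or an iteration cap is
   reached. Every window is detected independently from the same seed
   labels, producing a regions × windows assignment matrix.
4. **Reconfiguration metrics** on that matrix, per node, aggregated
   globally and per network.
5. **Surrogate nulls** by Fourier phase randomization, and **group
   statistics** (Bonferroni-corrected Pearson correlations, ANCOVA,
   hierarchical ENTER regression).

# The detection rule, precisely

For region $i$ with current label $c_i$ and one window's weight matrix
$W$, define the mean connectivity of $i$ to community $k$ as the mean of
$W_{ij}$ over members $j \ne i$ of $k$ (undefined communities, or the
own community when $i$ is its only member, count as $-\infty$). The
assignment quality is

$$q_i \;=\; \bar W_{i,c_i} \;-\; \max_{k \ne c_i} \bar W_{i,k},$$

the margin by which the region prefers its own community over the best
alternative. Selection takes the minimum-$q$ region (ties: lowest
index); reallocation takes the maximal-mean community (ties: keep the
current label if tied, else lowest index). Because a region's mean
connectivity to any community never involves its own edges, a
reallocation cannot decrease the moved region's quality — the test suite
asserts this monotonicity from the recorded trace.

Two points here were genuinely open design choices:

* **The quality function.** Only "lowest assignment quality" and
  "maximal connectivity" are constrained by the method this
  re-implements; we pair them so that selection and reallocation are two
  views of the same margin $q_i$. The referenced original script may
  differ in detail, so the quality function is isolated in one internal
  surface (`assignment_quality()` / `community_means()`); this is the
  principal fidelity risk of the re-implementation.
* **Mean, not sum.** Connectivity to a community is its *mean* edge
  weight so that large networks do not systematically swallow
  borderline regions.

Other conventions: labels are only ever drawn from the initial label
set (no new communities; an emptied community simply becomes an unused
label, which keeps the promiscuity denominator stable at $K = 8$);
stopping adds a no-op-move stop and a hard cap of 1000 iterations on
top of the repeated-selection rule, because the latter alone does not
provably terminate on adversarial inputs.

# The four metrics

For a node's label row $a_1,\dots,a_T$ over $T$ windows and $K$
communities:

* **Promiscuity** $= |\{a_t\}| / K$: the fraction of all communities
  visited at least once. The denominator is the full $K$ (8), not the
  number of communities a subject happens to use; a never-switching
  node scores $1/K$.
* **Flexibility** $= (\#\{t: a_t \ne a_{t+1}\}) / (T-1)$: the fraction
  of transitions with a switch.
* **Cohesion** and **disjointedness** split each switch exactly once: a
  switch at $t \to t+1$ is *cohesive* (mutual) iff at least one other
  node moves at the same transition from the same source to the same
  destination community, else *disjoint* (independent). Both are
  reported as fractions of transitions, so
  $\text{flexibility} = \text{cohesion} + \text{disjointedness}$ holds
  exactly per node. Requiring identical source *and* destination is what
  makes the decomposition exact, and published group means for these
  metrics are consistent with that reading. Pairwise partner identities
  are retained in the classification object for export, but the metric
  itself is the fraction, not a partner-weighted sum.

Aggregates are unweighted means over nodes — globally, and per network
using the *static* atlas membership (networks must be a stable grouping
for group statistics; time-resolved membership would make the grouping
itself stochastic). A network with no member regions yields `NA`, never
a silent 0.

These definitions are verified against naive brute-force
re-implementations: exhaustively over every label row with $T \le 4$,
$K \le 3$ and every adjacent-column pattern with $n \le 4$ nodes (the
two decompositions that together cover the full small-matrix space),
plus complete enumeration of the smaller full spaces.

# Surrogate nulls

`phase_randomize()` adds uniform random phases to the positive-frequency
Fourier bins of each region, enforces conjugate symmetry, leaves DC
untouched and flips the Nyquist bin by a random sign (even lengths), so
each region's amplitude spectrum is preserved exactly. The default
`multivariate_common_phase` mode shares one phase vector across regions,
which preserves all cross-spectra and hence the static correlation
matrix to machine precision — the null keeps static connectivity and
destroys only its temporal organisation, which is exactly what a null
for *time-varying* reconfiguration should do. `independent_phase` is
available when the null should also destroy cross-correlations.

Whether "the average over 50 randomization runs" means averaging the
surrogate *series* and running the pipeline once, or running the
pipeline per surrogate and averaging the *metrics*, is ambiguous in the
method this re-implements; both are provided (`average_series` is the
literal default) and the mode is a mandatory, recorded field of
`surrogate_spec()` — never a silent choice.

On the package's own synthetic data the null flexibility sits *above*
the real value: phase randomization discards the generator's latent
identifiability constraint (next section), so the surrogate's
noise-driven switching floor exceeds the planted switching rate. The
one-sided null-vs-real test asserts that direction.

# What the synthetic generator emulates — and what it does not

`plant_truth()` builds a ground-truth assignment matrix from the atlas
labels plus *sojourns*: a set of nodes leaves its home network at one
transition and returns a few transitions later (out-and-back, lengths
4–8 transitions, guard band of 3 between a node's sojourns). Cohesive
events move 2–3 nodes with identical source/destination/transition;
disjoint events move exactly one node, and event
(transition, source, destination) triples are kept unique so the planted
kinds are exactly what the classifier must find. Defaults are 12
cohesive and 25 disjoint sojourns per subject over 25 windows.

Three generator choices deserve justification:

* **Switch propensity as a stable node trait.** Event nodes are drawn
  with fixed per-node weights (`switch_propensity()`): association
  (fronto-parietal, attention) networks high, primary visual zero, with
  a deterministic within-network gradient. Real cohorts show node
  flexibility as a spatially structured, reliable trait with exactly
  this gradient; making it a fixed function of the atlas means a
  simulated cohort shares one spatial profile, so profile recovery is a
  meaningful target.
* **Latent identifiability constraint.** Each community's latent signal
  is band-limited to 0.01–0.1 Hz (matching the standard high-pass
  regime of resting-state preprocessing). A 60 s window of such a
  signal carries only ~11 effective degrees of freedom, so two
  unconstrained latents transiently correlate strongly in some windows —
  and in those windows the planted labels are *objectively wrong* as a
  description of the generated data, making "recovery" ill-defined.
  Latents are therefore redrawn until no pair exceeds a windowed
  correlation of `max_latent_cor = 0.6` (chosen once, below the
  within-community coupling, so membership is always identifiable).
* **Signal model.** Region $i$ at time $t$ emits
  $\sqrt{\rho}\,g_{c_i(t)}(t) + \sqrt{1-\rho}\,\varepsilon_i(t)$ with
  unit-variance band-limited latent $g_k$ and noise $\varepsilon_i$, so
  $\rho$ (default 0.8) is the within-community correlation. Membership
  changes at the sample midway between the centres of the two windows
  adjacent to the planted transition, which makes each window's
  majority content match its truth column.

The phenotype generator draws demographics, disability, treatment
categories and brain volumes from distributions matching published
cohort descriptions, and fatigue scores on the FSMC scale (total ≤ 100,
subscales ≤ 50) constructed so the declared metric has the declared
standardized association with each scale in the patient group only.
Clipping to the scale limits attenuates the realised correlation
slightly; the tests *measure* this (the mean recovered correlation must
fall inside the 95% sampling interval of the declared effect) rather
than assuming it absent.

What the generator does **not** emulate: hemodynamics, head motion,
scanner noise, spatial autocorrelation within parcels, non-stationary
variance, or any voxel-level property. Passing recovery tests therefore
show that the pipeline's algorithmic chain is correct and
well-calibrated on data satisfying its own assumptions — not that those
assumptions hold in any real scan.

# Statistics layer

* Pearson correlations per group × metric × fatigue scale, two-sided p
  from the t transform on $n-2$ df, Bonferroni adjustment
  $p_\text{adj} = \min(1, m\,p)$ with an *explicit* family size $m$ —
  the appropriate family is a declaration of the analysis, not something
  to infer from a table's shape.
* ANCOVA: `metric ~ group + age + sex + education`, nested-model F for
  the group term (identical to the squared t for a two-level group),
  Bonferroni over the metric family. Collinear covariates are an error
  naming the offending column.
* Hierarchical ENTER regression: blocks demographics (age, sex,
  education) → clinical (EDSS, disease duration, DMT as 8 dummies with
  "none" reference) → structural (normalized brain volume, T2 lesion
  load) → the reconfiguration metric; OLS refit at each entry, adjusted
  R² per step, and the metric's standardized β from a final fit with
  the response and continuous predictors z-scored (binary sex and the
  DMT dummies stay on their own scale). Listwise deletion with the
  dropped count reported.

Calibration is tested by simulation: type-I error of the group ANCOVA
within [0.03, 0.07] at α = 0.05 over 500 null replicates (n = 100), and
unbiased recovery of a planted standardized β = 0.2 at n = 155 (500
replicates, mean within 2 standard errors).

# Numerical choices and degenerate inputs

* Correlation clipping at $1 - 10^{-7}$ keeps Fisher z finite for
  duplicated signals; identical regions get the maximal finite weight
  $\operatorname{atanh}(1-10^{-7}) \approx 8.4$.
* Constant signals are tolerated at read time (with a warning) and
  rejected at correlation time, naming region and window — failure
  happens where the arithmetic actually breaks.
* Coverage exclusion is literal about its boundaries: a region fails a
  subject only if coverage is *strictly below* 0.30, and is excluded
  only if it fails in *strictly more than* 10% of subjects.
* Seconds→samples conversion rounds to the nearest integer; at TR = 1 s
  all the standard geometries are exact.
* All tie-breaks in detection are by lowest index, with
  "keep the current label" preferred on reallocation ties, making the
  whole pipeline deterministic given its inputs; every stochastic
  component (generator, surrogates) is driven by an explicit seed.

# Problem sizes in the shipped tests

The test-suite simulations use the geometry the pipeline is designed
for — 200 regions × 300 timepoints × 25 windows — for the 20-subject
recovery study and single-subject checks, and smaller geometries
(24–100 regions, 7 windows) where only mechanics are exercised. The
statistical calibration uses 500 replicates at n = 100 (type-I error)
and n = 155 (β recovery), and 20 replicate cohorts for the planted
fatigue effect. `scripts/acceptance.R` re-runs the same computations
from scratch at comparable sizes.

# Known limitations

* The iterative detection is a local, greedy refinement; it inherits the
  original method's lack of a global objective, and its exact quality
  function is a reconstruction (see above).
* Windows are detected independently; there is no temporal regularisation
  (no multilayer coupling parameter), so single-window label noise
  propagates directly into flexibility. On synthetic data this noise
  floor is visible as spurious switches; recovery of the *spatial
  profile* of flexibility across a cohort is excellent, while
  single-subject switch counts are noisy — a property of the method
  class, not of this implementation.
* The FSMC-scale clipping slightly attenuates planted brain–behaviour
  effects (measured, not corrected).
* `average_series` nulls inherit the variance shrinkage of averaging 50
  surrogate series; this is the literal reading of the validated
  procedure and is flagged, with `average_metrics` as the alternative.
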