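# netreconfig

Time-varying brain network reconfiguration from sliding-window
functional connectivity.

## What it is for

Static functional connectivity summarises a whole resting-state fMRI
scan as one correlation matrix, but regions drift between functional
networks *within* a scan, and that drift is behaviourally meaningful —
in multiple sclerosis cohorts, less stable network membership has been
linked to fatigue severity. `netreconfig` is an R implementation of the
full analysis chain for quantifying this instability from parcellated
BOLD time series:

1. **Sliding windows** — 60 s windows stepped by 10 s (a 300-volume,
   TR = 1 s scan gives exactly 25 windows; `floor((N - L)/S) + 1` in
   samples).
2. **Windowed connectivity** — edge weights
   `w_ij = |atanh(r_ij)|`, the absolute Fisher r-to-z transform of the
   within-window Pearson correlation (clipped at `1 - 1e-7`).
3. **Per-window community detection** — regions start at their
   literature-based resting-state network (DMN, FPN, DAN, VAN, VN, SMN,
   LN + deep grey matter, K = 8); the lowest-quality region
   (own-community mean connectivity minus best-other-community mean) is
   iteratively reallocated to its maximal-connectivity community until
   the same region is selected twice in a row. The result is a
   regions × windows assignment matrix.
4. **Reconfiguration metrics** per node, over T windows:
   * promiscuity = distinct communities visited / K
   * flexibility = switches / (T − 1)
   * cohesion = mutual switches / (T − 1) (same source, destination and
     transition as ≥ 1 other region)
   * disjointedness = independent switches / (T − 1)

   so that flexibility = cohesion + disjointedness exactly, with global
   and per-network (static atlas grouping) means.
5. **Validation and statistics** — Fourier phase-randomization surrogate
   nulls (common-phase mode preserves the static correlation matrix
   exactly), Bonferroni-corrected metric–fatigue Pearson correlations,
   ANCOVA group comparisons (age, sex, education adjusted), and
   hierarchical ENTER regression with demographic / clinical /
   structural covariate blocks.

Because cohort imaging data of this kind are not openly shareable, the
package includes a first-class synthetic generator
(`plant_truth()`, `generate_subject()`, `generate_cohort()`) that
produces band-limited BOLD-like signals with *planted* community
sojourns and phenotype tables with declared metric–fatigue effect
sizes, so every stage is testable end-to-end against known ground
truth.

## Worked example

```r
library(netreconfig)

atlas <- example_atlas(200)                 # 200 regions over 8 networks
truth <- plant_truth(atlas, seed = 42)      # planted switching events
bold  <- generate_subject(truth, seed = 43) # 200 x 300 BOLD-like series

fit <- reconfig(bold, atlas)                # windows -> detection -> metrics
summary(fit)
```

```
Time-varying reconfiguration fit: subject 'sim'
  200 regions x 25 windows, 8 communities (window 60 s, step 10 s)
  Global metrics:
   promiscuity    flexibility       cohesion disjointedness 
         0.195          0.040          0.016          0.023 

  Per-network means:
    promiscuity flexibility cohesion disjointedness
DMN       0.220       0.053    0.025          0.028
FPN       0.210       0.050    0.020          0.030
DAN       0.225       0.055    0.023          0.032
VAN       0.290       0.092    0.033          0.058
VN        0.150       0.017    0.005          0.012
SMN       0.165       0.025    0.017          0.008
LN        0.175       0.025    0.007          0.018
DGM       0.125       0.000    0.000          0.000

  Detection: 15.8 iterations/window on average, 25/25 windows converged
```

The global flexibility of 0.040 says the average region changed
network at 4% of the 24 window transitions; its split into cohesion
(0.016) and disjointedness (0.023) separates joint from solo moves.
The per-network rows reflect the generator's built-in propensity
profile (association networks switch most, primary visual and deep
grey matter are anchors). Checking recovery against the planted truth:

```r
mean(fit$assignments == truth$assignments)
#> [1] 0.968
```

For whole-cohort runs, `simulate_fixture()` writes a complete input
directory (series, atlas, coverage, phenotypes, ground truth) and
`run_pipeline(pipeline_config(...))` executes every stage — coverage
exclusion, per-subject fits, surrogate nulls, group statistics — with
logged, checksummed, seed-deterministic outputs. Surrogate nulls for a
single subject are available directly via `build_null()`, and the
statistics layer via `correlate_metrics_fatigue()`,
`group_comparison_ancova()` and `hierarchical_regression()`.

See `vignettes/time-varying-reconfiguration.Rmd` for the model details,
generator assumptions and design decisions.

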