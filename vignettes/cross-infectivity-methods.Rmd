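---
title: "Methods: cross-infectivity phenotypes and infection-network structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-infectivity phenotypes and infection-network structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhinet)
```

`vhinet` analyses full-factorial virus–host challenge panels of the kind
used to map infection networks in the *Emiliania huxleyi*/EhV system:
every host strain is incubated with every virus strain (plus uninfected
controls) in replicate, and cells and virions are enumerated at the
start and end of the incubation. This vignette documents the models and
conventions behind each stage, the tunable parameters, and what the
synthetic-data validation does and does not establish.

## The data model

The primary input is a tidy count table with one row per
(host, challenge, replicate, timepoint): `cell_conc` in cells/mL,
`virus_conc` in particles/mL, with the reserved challenge token
`CONTROL` marking the uninfected series. Keeping controls in the same
table (rather than a parallel file) lets validation enforce the design
in one place: both timepoints per well series, at least one control
series per host, finite non-negative concentrations, and `virus_conc`
missing only in control wells. All downstream results are invariant to
row order. Concentrations are stored per mL and never rescaled silently.

## Phenotypes

**Growth rate.** `mu = ln(N2/N1)/t` per day, from the control series.
`t` is expressed in days (a 72-h incubation is `t = 3`), because growth
rates in this literature are reported per day. Each control replicate
yields one rate; the host's `mu` is their mean and `mu_sd` their
standard deviation. A noise-free exponential series is recovered exactly
(to floating point), which the tests assert.

**Resistance R1.** Per virus, the surviving-cell ratio
`min(1, infected_final / control_final)` on replicate means; per host,
the unweighted mean over the virus panel. The ratio form (rather than a
raw difference) keeps R1 on a bounded [0, 1] scale interpretable as the
fraction of cells not lysed; clipping at 1 acknowledges that an
infected well denser than its control carries no evidence of lysis.

**Resistance R2 and host range.** Binary calls per pair:

- *lysis*: 1 when mean infected final cells fall below `theta` × the
  control mean. Default `theta = 0.75`: with triplicates and ~10%
  measurement CV, a 25% drop is far outside counting noise while still
  catching partial lysis. The rule uses replicate means and makes no
  distributional assumption, which is about all three replicates can
  support.
- *progeny*: 1 when mean final virions reach at least `rho` × the
  measured initial count. Default `rho = 1.5`: a 50% increase exceeds
  plausible counting error but is far below a genuine burst (tens-fold).
  The measured t0 virion count is used as the baseline, falling back to
  the nominal inoculum (1e6/mL) only when no t0 virus count exists.

`R2` is the row sum of the progeny-call matrix; a virus's host range is
the column sum of the lysis-call matrix. Both thresholds are exposed and
monotone: raising `theta` can only add lysis calls, raising `rho` can
only remove progeny calls (a property test). Because lysis is observed
cell-side and progeny virus-side, both matrices are produced; the
network analysis defaults to the lysis matrix, since "0 = no lysis,
1 = lysis" is the operational definition of the infection network here.
Generalists and specialists are the top/bottom `k` viruses by host range
(default `k = 5`), with lexicographic tie-breaks so the split is
deterministic.

**Viral production.** `Vp = v_final − v_initial` per pair, a plain
signed difference: negative values (net decay on resistant hosts) are
retained in averages rather than truncated, because truncation would
bias per-virus means upward on resistant panels. Summaries are the
per-virus mean and maximum over hosts and the per-host maximum over
viruses.

## Association screens

`pearson()` and `one_way_anova()` are implemented from their
definitions — the sample correlation with the two-sided t-transform
`t = r sqrt((n−2)/(1−r²))`, and `F = MS_between/MS_within` with
`(k−1, n−k)` degrees of freedom — and are checked against
`stats::cor.test()` and `anova(lm(...))` to 1e-10, plus a 2000-run
calibration of the ANOVA type-I error rate. No multiple-testing
correction is applied: the screen is a fixed, declarative battery of
ten named comparisons, reported together so the reader can judge them
jointly.

The isolation-period split assigns the cutoff year itself (default
2009) to the *younger* group; strains without a recorded year are
excluded and listed. The cutoff is a parameter, not a constant.

## NODF nestedness

For every ordered pair of rows with marginal sums `k_i > k_j > 0` the
paired term is the overlap `|columns shared|/k_j`; likewise over column
pairs; NODF is the total divided by `n(n−1)/2 + m(m−1)/2`. Conventions:

- *strict decreasing fill*: pairs with tied marginals contribute zero —
  so the all-ones matrix scores 0 and the strict staircase scores
  exactly 1 (both are tests);
- empty rows/columns contribute zero to terms but stay in the pair
  count, keeping the denominator a pure function of shape;
- the score is reported on the 0–1 scale (a `"percent"` flag gives the
  0–100 convention of the older literature);
- because pairing is by marginal comparison, the score is invariant to
  row/column permutation and to transposition — both property-tested.

The implementation is vectorised (overlap via `tcrossprod`); its oracle
in the tests is a literal pair-by-pair enumeration, plus an agreement
check against `vegan::nestednodf`.

## Barber modularity and module detection

`Qb = (1/m) Σ_ij (A_ij − k_i d_j/m) · [g_i = h_j]`. The one-module
partition scores exactly 0 for every matrix (the degree expectation sums
to `m`), which anchors the detector: it never returns Qb < 0.

`detect_modules()` builds the Barber matrix `B = A − k dᵀ/m` once and
recursively bisects: within a candidate module it takes the dominant
left/right singular vectors of the restricted block of `B` (the
bipartite analogue of the leading-eigenvector method), splits rows and
columns by sign, fine-tunes the proposed bisection by greedy single-node
toggles, and accepts the split only if Qb strictly improves (tolerance
1e-12). Two BRIM alternation runs (rows↔columns assignment to
convergence, seeded from singleton modules on either side) provide
alternative candidate partitions; every candidate gets a final local
refinement pass (single-node reassignments, rows then columns in label
order), and the best Qb wins, first candidate on ties. Determinism is
by construction: the SVD sign is canonicalised (largest-magnitude entry
of the left vector positive), all sweeps run in fixed label order, and
ties break to the smallest label — `seed` is accepted for interface
parity and ignored.

The correctness reference is `brute_force_modules()`, an exhaustive
search over restricted-growth assignments (≤ 12 nodes), not any external
implementation: the acceptance tests require the detector to reach at
least 95% of the brute-force optimum across a random small-matrix
corpus, and stress runs on 200 additional matrices met the same bound.

## Null models and significance

The equiprobable null keeps only the fill: the `m` ones are re-placed
on a uniformly random subset of cells ("interactions uniformly
permuted" taken literally), so marginals are free to vary. Significance
uses `n_null = 100` by default, reporting the null mean/sd, a z-score,
and a one-tailed empirical p with the `(r+1)/(n+1)` correction — the
hypotheses (nestedness present, modularity present) are directional,
and the correction avoids reporting p = 0 from a finite ensemble; a
two-sided option exists. Each Qb null is scored by a fresh detector run.
With a degenerate null distribution (sd = 0, e.g. a full matrix) the
z-score is reported as `NA` while the empirical p remains valid. The
ensemble is reproducible from one master seed (RNG state is isolated
via `withr::with_seed`); calibration — p approximately uniform when the
observed matrix is itself a null draw — is tested with 200 replicate
analyses.

## The synthetic-data generator

`simulate_experiment()` emulates the two-timepoint plate design, not
infection dynamics. Controls grow exponentially; an infected well either
lyses (final cells at `lysis_survival` of the control expectation,
virions at `virus_init` × a per-pair burst fold) or tracks the control
while the inoculum decays. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| panel | 49 × 13, triplicate, 72 h | the reference cross-infectivity design |
| `cell_init`, `virus_init` | 1e5 /mL, 1e6 /mL | VHR of 10, as in the reference design |
| `mu_range` | 0.12–1.11 /d | span observed across host strains |
| `fill` | 0.40 | mid-range connectance typical of these panels |
| `lysis_survival` | 0.1 | near-complete lysis at 72 h |
| `burst_fold` | 50 (lognormal, sdlog 0.5) | order of magnitude of lab lysates vs inoculum; heterogeneity lets production–resistance correlations emerge |
| `decay_fold` | 0.9 | mild passive virion loss on resistant hosts |
| `meas_cv` | 0.10 | typical flow-cytometry counting spread |
| years | uniform 1990–2015 | spans the 2009 domestication boundary |

Measurement noise is multiplicative lognormal with unit mean —
cytometry counts are strictly positive with roughly constant CV — and
`meas_cv = 0` yields bit-exact expectations, making "the pipeline is a
left inverse of the generator at zero noise" a testable identity. The
nested generator draws a host susceptibility ranking and virus range
sizes (distinct where the shape allows, nudged to the target fill) so
each virus infects a prefix of the ranking: supports are totally ordered
by inclusion. The modular generator plants balanced blocks with
within/between interaction probabilities. `flip_noise` perturbs the
realised matrix away from the clean structure; ground truth (realised
and pre-flip matrices, rates, bursts, years) is returned alongside the
counts so recovery can be scored exactly. An optional
`young_burst_fold` plants a viral-production shift across the year
boundary for testing the domestication screen.

What passing tests show: the estimators undo the generator's known,
well-behaved distortions (lognormal noise, single lysis regime) at the
stated design size. What they do not show: robustness to semi-lytic
outcomes, latent periods, multi-cycle growth, MOI dependence,
plate-position effects, or non-lognormal outliers — none of which the
generator emulates (deliberately: it targets the two-timepoint design
only).

## Pipeline and reproducibility

`run_all()` chains simulate/read → phenotypes → screen → network →
nulls → report, writes CSV/JSON outputs plus a markdown report stating
the five classical hypotheses with computed statistics and directional
verdicts, and aborts on any stage error after removing partial outputs.
A seed is mandatory whenever a stochastic step is configured; a rerun
with the same configuration is byte-identical (no timestamps in
outputs). The package's functions are the interface; the pipeline is a
library call rather than a shell tool.

Problem sizes in the test suite are chosen to exercise each property at
the smallest scale where it is meaningful: exact oracles run on
matrices up to 8×8 (500 cases), the brute-force modularity comparison
on ≤ 12-node matrices, calibration on 200 replicate analyses of a 6×5
matrix with 100 nulls each, and ground-truth recovery on the full
49 × 13 design.

## Known limitations

- Binary calls discard partial-lysis information; a graded (e.g.
  survival-fraction) network is out of scope.
- The equiprobable null is the only null model; degree-preserving
  (fixed–fixed, curveball) ensembles would test a sharper hypothesis
  and are a natural extension point.
- The leading-eigenvector detector is a heuristic; its near-optimality
  is verified only on small matrices, where exhaustive search is
  feasible.
- With `n_null = 100`, the smallest attainable empirical p is
  1/101 ≈ 0.0099; raise `n_null` for finer resolution.
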