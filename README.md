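# vhinet

Analysis of full-factorial virus–host cross-infectivity panels, built
around the model system of the coccolithophore *Emiliania huxleyi* and
its lytic giant viruses (EhV). Given flow-cytometry-style enumerations
of cells and virions at the start and end of a two-timepoint incubation,
`vhinet` computes per-strain phenotypes, screens them against the
classical hypotheses of marine virus–host ecology, and quantifies the
structure of the resulting binary infection network.

## Who this is for

Microbial ecologists and virologists running challenge panels ("every
host strain × every virus strain, in replicate") who want a reproducible
path from raw well counts to network-level statements such as "this
infection network is significantly nested". Everything also runs on
simulated data, so the pipeline can be validated end to end before any
wet-lab data exist.

## What it computes

**Phenotypes** (per host strain, from the counts):

- growth rate `mu = ln(N2/N1)/t` (per day), from the uninfected controls;
- resistance `R1`: the surviving-cell ratio `min(1, N_infected/N_control)`
  per virus, averaged over the virus panel;
- resistance `R2`: the number of virus strains that successfully produced
  progeny on the host (low `R2` = high resistance);
- viral production `Vp`: final minus initial viral concentration per
  host–virus pair, with per-virus averages/maxima and the per-host maximum.

**Association screens**: Pearson correlations (R1~mu, R2~mu, Vp~R1,
maxVp~R2, Vp~mu), a one-way ANOVA of viral production between generalist
and specialist viruses, and ANOVAs across isolation periods
(before/after a cutoff year, default 2009). Both tests are implemented
from their definitions and verified against the base-R references to
1e-10 in the test suite.

**Network structure** of the binary lysis matrix `A` (1 = lysis):

- **NODF** nestedness: for each ordered pair of rows with marginal sums
  `k_i > k_j > 0` the paired term is `|shared columns| / k_j`; same over
  column pairs; the sum is normalised by the total pair count, giving a
  score in [0, 1] where 1 is a perfect staircase.
- **Barber bipartite modularity**
  `Qb = (1/m) * sum_ij (A_ij − k_i d_j / m) · [g_i = h_j]`, optimised by a
  leading-eigenvector detector (recursive SVD bisection of the Barber
  matrix with local refinement, plus BRIM alternation candidates). An
  exhaustive brute-force optimiser serves as the correctness oracle on
  small matrices.
- **Significance** against the equiprobable null model: `n_null` (default
  100) matrices with the same shape and fill but uniformly re-placed 1s;
  z-score and one-tailed empirical p with the (r+1)/(n+1) correction.

**Synthetic data**: `simulate_experiment()` generates the full plate
experiment (default 49 hosts × 13 viruses, triplicates, 0 h/72 h,
1e5 cells/mL and 1e6 particles/mL inocula, growth rates 0.12–1.11/d)
from a nested, modular or random ground-truth interaction matrix, with
lognormal measurement noise, so that recovery of the truth by the
pipeline is a testable property.

## Worked example

```r
library(vhinet)

sim <- simulate_experiment(sim_config(seed = 42))  # 49 x 13 panel
ph  <- phenotype_table(sim$counts)                 # theta = 0.75, rho = 1.5
ph
#> phenotypes: 49 hosts x 13 viruses (theta = 0.75, rho = 1.50)
#>   mu range 0.131-1.13 /d; lysis fill 0.40; progeny fill 0.40

nodf(ph$lysis)
#> NODF = 0.5917 (49 x 13 matrix, fill 255)

significance(ph$lysis, "NODF", n_null = 100, seed = 43)
#> NODF = 0.5917 vs 100 equiprobable nulls (mean 0.4129, sd 0.0163)
#>   z = 10.95, empirical p (greater) = 0.0099

head(screen(ph, sim$metadata), 4)
#>   comparison  test    statistic df1 df2        p  n
#> 1 R1_vs_mu    pearson   -0.1004  47  NA 4.92e-01 49
#> 2 R2_vs_mu    pearson    0.0845  47  NA 5.64e-01 49
#> 3 Vp_vs_R1    pearson   -0.9520  47  NA 8.50e-26 49
#> 4 maxVp_vs_R2 pearson    0.7799  47  NA 4.01e-11 49
```

Reading the output: the recovered lysis matrix (fill 0.40) is strongly
nested — its NODF of 0.59 sits almost 11 null standard deviations above
the equiprobable expectation of 0.41, with an empirical p of 0.0099
(the smallest value 100 nulls can resolve). The screen finds no
resistance–growth trade-off (R1~mu, p = 0.49) but a strong negative
Vp~R1 correlation: hosts that resist more produce fewer virions. On this
seeded simulation the recovered matrix equals the ground truth exactly
and the growth-rate estimates correlate with the generating rates at
r = 0.995.

`run_all(run_config(simulate = sim_config(), seed = 1))` runs every
stage and writes the phenotype/screen CSVs, the network and null-model
JSONs, and a markdown report that states each of the five classical
hypotheses (cost of resistance, growth–production coupling,
growth–susceptibility coupling, resistance–production trade-off,
specialist advantage) with its computed statistic and verdict. Reruns
with the same configuration are byte-identical.

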