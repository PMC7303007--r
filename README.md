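# bivargwas

Cross-phenotype GWAS meta-analysis from summary statistics alone.

Depression GWASs have long been underpowered relative to the trait's
heritability, while bipolar disorder and schizophrenia — which share a large
part of depression's common-variant architecture — have much larger
well-powered scans. `bivargwas` implements the strategy of combining a
depression GWAS with a genetically correlated psychiatric GWAS at the level
of per-SNP Z-scores, so that shared loci clear genome-wide significance that
neither scan reaches alone. Only summary statistics are needed at every
step; the intended users are statistical geneticists working with published
GWAS results.

## The method

Given two harmonized per-SNP Z-scores `z1`, `z2` with null correlation `s`
(estimated genome-wide, sample-overlap aware), the package computes:

- **O'Brien's combined test**
  `T_OB = (1' S⁻¹ z) / sqrt(1' S⁻¹ 1) = (z1 + z2) / sqrt(2(1+s))`,
  with `S = [[1, s], [s, 1]]`;
- the **direct linear combination (dLC)**
  `T_dLC = (w1 z1 + w2 z2) / sqrt(w1² + w2² + 2 s w1 w2)`,
  with `w = sqrt(N)` by default;
- the **bivariate p-value** `p_biv = min(p_OB, p_dLC)`.

A finding is declared only if `p_biv < 5e-8`, `p_biv ≤ min(p1, p2)/10`,
both univariate `p < 1e-3`, and the effects agree in direction. Findings are
clumped into loci (`r² > 0.10`, ±1 Mb, greedy lead selection), replicated in
an independent cohort (one-sided `p < 0.05`, directional consistency,
combined dLC meta-analysis more significant than discovery) and audited
post hoc by Benjamini–Hochberg FDR.

Upstream of the scan, `fit_h2()`/`fit_rg()` implement univariate and
bivariate LD score regression (`E[χ²] = 1 + N h² l / M`;
`E[z1 z2] = ρ_g sqrt(N1 N2) l / M + overlap`), with block-jackknife standard
errors, and `compute_ld_scores()` builds the ±1 Mb LD scores from a
reference panel. A summary-statistics simulator with AR(1) LD blocks, known
heritabilities, genetic correlation and sample overlap makes the whole
pipeline testable without consortium data.

## Worked example

The package ships the published 23-row discovery/replication table of the
four bivariate depression analyses (broad depression paired with
self-reported MDD, recurrent MDD, bipolar disorder and schizophrenia) as a
fixture, and re-derives its locus bookkeeping from the printed p-values and
effect directions:

```r
library(bivargwas)
audit <- audit_discovery_table()
audit$n_independent_loci   # 20  loci across the four analyses
audit$n_replicated_unique  # 13  pass the three replication criteria
audit$n_novel              # 8   of those are novel for depression
max(audit$fdr$q)           # 0.0214  -- all 13 replication FDR q < 0.05
```

On simulated data the full pipeline runs in seconds:

```r
cfg <- sim_config(M = 20000, n_blocks = 200, block_size = 100,
                  h2_1 = 0.3, h2_2 = 0.3, rg_true = 0.5, seed = 1)
sim <- simulate_sumstats(cfg)
pairs <- harmonize_pair(sim$t1, sim$t2)
fit_rg(pairs, sim$truth$ld, M = cfg$M)
#> Bivariate LD score regression fit
#>   gcov = 0.2087
#>   rg = 0.6409 (SE 0.1970, p = 0.00114)
#>   cross intercept = -0.3652
#>   h2: 0.3016 / 0.3515 over 20000 SNPs (M = 20000)
```

The estimate recovers the simulated `rg = 0.5` within its jackknife SE.
Single-draw estimates at this desk scale are noisy — the SE is honest about
that — and the recovery experiments (`rg_recovery_experiment()`, also run as
part of the test suite) show the estimator is unbiased with calibrated
intervals over 100 such simulations.
The numbered scripts under `analysis/` run the complete workflow — simulate,
genetic correlation, bivariate discovery with clumping, the published-table
replication audit, and the evaluation experiments (type-I error,
negative-control false positives, rg recovery) — writing their tables under
`results/`.

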