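# epitrial

In silico clinical trials for epitope-based vaccines over HLA-genotyped
cohorts.

## The problem

The immune response rate (IRR) of a therapeutic vaccine trial — the
fraction of subjects mounting measurable CD8+ T-cell responses — has
proved stubbornly hard to predict from epitope–HLA binding alone:
matching a single HLA allele (even when trials enrol only carriers of
that allele) badly overestimates responses. `epitrial` implements the
alternative: score each subject of a fully HLA class I genotyped model
population by the vaccine epitopes predicted to bind **multiple distinct
autologous alleles**, and read off the predicted population response
rate.

For a subject with distinct allele set *G* and a vaccine scanned into
overlapping 9-mers, let

  c(e) = #{ a ∈ G : rank(e, a) ≤ 2 }

be the number of the subject's own alleles predicted to bind epitope
*e* (percentile rank ≤ 2, the strong-binder convention; an IC50 < 150 nM
policy is selectable). The in silico IRR under threshold *n* is the
fraction of subjects with at least one epitope with c(e) ≥ n; the
multi-epitope variant requires two such epitopes, and the multi-antigen
variant requires two from distinct antigens. `run_trial_battery()`
evaluates all twelve estimators (three variants × n = 1..4). A
statistics layer compares predictions with measured trial rates: Pearson
r with the t-based p-value (df = n−2), a perpendicular
(total-least-squares) trend line with bootstrap 0.95 bands, the "n−1"
chi-squared two-proportion test, pairwise-match summaries, and ROC/AUC
sweeps over trial-success thresholds. Seeded generators synthesize
genotyped populations, antigens, promiscuous binding tables and noisy
trial outcomes, so the whole pipeline is testable offline.

## Worked example

A synthetic 100-subject model population, a two-antigen vaccine
restricted to HLA-A*02 carriers, and a sampled binding table:

```r
library(epitrial)
pop <- sample_population(100, seed = 42)
ags <- sample_antigens(2, lengths = c(60, 45), seed = 42)
vx  <- vaccine("demo", ags, restriction = hla_restriction("A02"))
tbl <- sample_binding_table(scan_peptides(ags)$peptide,
                            population_alleles(pop), seed = 42)
enrolled <- stratify_population(pop, vx$restriction)   # 43 subjects
run_trial_battery(enrolled, vx, tbl)
```

```
       estimator hla_threshold numerator denominator       rate flag
1            irr             1        43          43 1.00000000
2            irr             2        42          43 0.97674419
3            irr             3        15          43 0.34883721
4            irr             4         1          43 0.02325581
5  multi_epitope             1        43          43 1.00000000
6  multi_epitope             2        40          43 0.93023256
7  multi_epitope             3         3          43 0.06976744
8  multi_epitope             4         0          43 0.00000000
9       multi_ag             1        43          43 1.00000000
10      multi_ag             2        34          43 0.79069767
11      multi_ag             3         1          43 0.02325581
12      multi_ag             4         0          43 0.00000000
```

Every enrolled subject has some single-allele-binding epitope (the n = 1
row saturates at 100% — the overestimation that single-HLA matching
produces), while 34.9% have an epitope binding ≥ 3 of their own alleles.
Simulating a 50-subject trial whose true rate is the 3×HLA prediction
and comparing measured with predicted:

```r
trials <- simulate_trials(pop, list(vx), tbl, irr_spec(3), 50, seed = 43)
trials$irr_responders / trials$irr_total      # 17/50 = 0.34 measured
chi2_nminus1(c(17, 50), rate_point(15, 43))
```

```
"n-1" chi-squared: statistic = 0.0079 (1 df, N = 93), p = 0.9291
```

p > 0.05: the measured and predicted rates match in the pairwise sense.

A command-line entry point wrapping these functions (subcommands `scan`,
`battery`, `per-peptide`, `coverage`, `represent`, `meta`, `roc`,
`simulate`) is installed at `system.file("exec", "epitrial", package =
"epitrial")`.

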