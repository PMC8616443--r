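---
title: "The in silico trial model: multi-allele epitopes and population response rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The in silico trial model: multi-allele epitopes and population response rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitrial)
```

## The model

Therapeutic vaccines deliver protein antigens or peptides whose epitopes —
here 9-mer fragments — must be presented by a patient's HLA class I
molecules before CD8+ T-cells can respond. Every person carries six class
I allele slots (two each at HLA-A, -B and -C), and the same epitope can be
presented by more than one of them. The central modelling idea of this
package is that an epitope's *promiscuity across a subject's own alleles*
— not merely binding to one preselected allele — is what predicts whether
a trial cohort will mount measurable immune responses.

The in silico trial works as follows. A model population (MP) of fully
genotyped subjects stands in for the unknown trial cohort. Each vaccine
antigen is scanned with overlapping 9-mers; a binding-prediction table
maps (peptide, allele) pairs to percentile ranks; and for every subject we
count, per epitope, the number of *distinct* autologous alleles whose
prediction passes the binder cutoff. A subject is a predicted responder
under an estimator defined by three axes:

* the HLA threshold `n`: an epitope qualifies when it binds at least `n`
  of the subject's distinct alleles (`n` = 1..4 is the reporting grid);
* the minimum number of qualifying epitopes (1, or 2 for the
  multi-epitope variant);
* the minimum number of distinct source antigens among them (1, or 2 for
  the multi-antigen variant).

The in silico immune response rate (IRR) under an estimator is the
fraction of MP subjects qualifying; `run_trial_battery()` evaluates the
full 3 x 4 grid in one pass. When a trial enrolled only carriers of a
given allele (HLA preselection), the MP is stratified the same way —
but, deliberately, *all six alleles* of the retained subjects still count
toward thresholds: preselection restricts who is enrolled, not which
molecules present peptides.

## Parameters and defaults

* `k = 9` — the scanned epitope length. Administered 10-mer peptides are
  handled by scanning their 9-mer windows.
* Binder cutoff: percentile rank `<= 2.0`, the conventional strong-binder
  operating point (a rank-2 binder is, by the definition of percentile
  rank, in the top 2% of random peptides for that allele). An alternative
  IC50 `< 150` nM policy is selectable where affinities are available.
  The cutoff is an explicit, logged parameter of `binding_table()`
  because predicted rates depend on it directly.
* HLA thresholds `1..4`. Thresholds 5 and 6 are computable but flagged
  out-of-grid: epitopes binding five or six autologous alleles are so
  rare (well below one per subject in our synthetic populations, as in
  real cohorts) that rates there are mostly zero.
* Homozygous alleles count **once**. The "binds `n` autologous alleles"
  count uses the distinct allele set of the genotype, because a
  homozygous allele presents the same peptide repertoire regardless of
  copy number. This is a documented modelling choice; the alternative
  (counting slots) would inflate thresholds for homozygotes.
* Epitope identity is the pair (peptide sequence, antigen of origin): a
  9-mer repeated inside one antigen counts once, while the same 9-mer in
  two antigens counts once per antigen, which is what makes the
  multi-antigen estimator well defined.
* Per-peptide mode: trials that report immunogenicity per administered
  peptide can be mirrored either by treating each antigen entry as one
  peptide (`mode = "antigen"`, the default, matching how peptide vaccines
  list their components) or by reporting every scan window
  (`mode = "window"`). Both are provided because published per-peptide
  tables are ambiguous about which was meant.

## The statistics layer

Measured trial rates are compared with predicted rates as data pairs,
each a (responders, total) fraction on both sides.

* `pearson_with_p()` — product-moment correlation with the two-sided
  p-value from Student's t with `n - 2` degrees of freedom.
* `perpendicular_fit()` — the trend line minimizing squared
  *perpendicular* distances (total least squares), appropriate because
  measured and predicted rates are equally "noisy" and the fit should be
  symmetric in the axes; swapping axes yields the reciprocal slope. The
  0.95 confidence and prediction bands are computed by a seeded pairs
  bootstrap (default 2000 resamples): confidence bands from the bootstrap
  spread of the fitted line, prediction bands from fitted values plus
  resampled vertical residuals. A bootstrap was chosen because no
  closed-form band for TLS lines is standard; the scheme is documented
  and reproducible under `seed`.
* `chi2_nminus1()` — the "n-1" chi-squared two-proportion test: the
  Pearson statistic of the 2x2 responder table scaled by `(N-1)/N`,
  recommended over both the uncorrected and the continuity-corrected
  chi-squared for small trials. No continuity correction is applied. A
  zero table margin (both rates 0 or both 1) makes the comparison
  vacuous; p = 1 by convention. Two rates "match" when p > 0.05.
* `pairwise_match_summary()` — the fraction of pairs matching, either by
  the test above or by |measured - predicted| <= 0.10. The 10% margin is
  read as absolute percentage points with an inclusive boundary.
* `roc_for_threshold()` / `auc_sweep()` — trials are labelled successes
  when the measured rate reaches a success threshold (swept over 30–80%
  to avoid one-sided labellings); the predicted rate is the
  classification score, cutoffs swept over its distinct values with ties
  grouped into a single ROC vertex; AUC by the trapezoid rule, which on
  tied data equals the tie-corrected rank-sum statistic
  `U/(n_pos * n_neg)`.
* `group_location_test()` — rank-based (Mann-Whitney, normal
  approximation with tie correction) or mean-based (Welch t) two-group
  comparison; published analyses report medians in one place and means in
  another without naming tests, so both kinds are provided and the choice
  is configuration.
* No multiple-testing adjustment is applied anywhere: the pairwise
  p-values are descriptive summaries, not a family of hypotheses.

Representativeness of a cohort is assessed two ways:
`allele_coverage()` sums catalog frequencies over the population's
distinct allele set, and `per_position_binder_frequency()` /
`mean_epitope_count()` profile the cohort's epitope-binding capability
along an antigen, so two cohorts can be correlated position by position.
The mean epitope count equals the sum of the per-position frequencies
exactly (exchange of summation), which the tests assert.

## The synthetic-data generators

Nothing in this package requires external databases: seeded generators
emulate every input.

* `sample_population()` draws two alleles per locus independently from a
  per-locus renormalized frequency catalog. The built-in catalog
  (`default_allele_catalog()`) is synthetic: real common allele names
  with plausible global frequencies, a dozen common plus eight rare
  alleles per locus, each locus summing to 1/3. Loci are sampled
  independently — real HLA loci are in strong linkage disequilibrium,
  which the generator deliberately omits for simplicity; coverage and
  frequency-recovery checks do not depend on LD, but genotype-level
  statistics of real cohorts would differ.
* `sample_antigens()` draws uniform residues over the 20-letter
  alphabet. Real proteomes have compositional bias and homology between
  antigens; none of that is emulated.
* `sample_binding_table()` plants promiscuity explicitly: every
  (peptide, allele) pair is a seed binder with probability
  `base_binder_rate = 0.02` (the rank-2 operating point), and peptides
  with at least one binder recruit further alleles at
  `base_binder_rate * promiscuity_boost` with `promiscuity_boost = 3`.
  With six-allele genotypes this makes roughly a quarter of a subject's
  binding epitopes bind two or more autologous alleles — the
  multi-allele fraction observed in large genotyped cohorts — which is
  why 3 was fixed as the default. Binder ranks are uniform below the
  cutoff; non-binders are simply absent (sparse-table convention:
  absence = no prediction = non-binder).
* `simulate_trials()` draws measured responder counts binomially around
  the in silico rate of a chosen "truth" estimator, giving trial records
  with known ground truth.
* One master seed fans out to per-component child seeds via
  `child_seed()` (a fixed arithmetic hash of seed and component tag), so
  adding a generator never perturbs existing streams, and every
  generator restores the caller's RNG state.

Because binder events are independent across peptides and alleles (apart
from the planted promiscuity), passing tests on synthetic data shows the
*bookkeeping and statistics* are right, not that any particular real
vaccine is well predicted: real binding predictions are correlated along
the sequence (motif overlap between windows) and across structurally
similar alleles, and real measured rates carry assay heterogeneity far
beyond binomial noise.

## The planted-signal recovery experiment

`recover_hla_threshold()` is the package's self-consistency experiment:
trial outcomes are simulated from the in silico rate at threshold
`n = 3`, and the full grid is then correlated back against the noisy
measured rates. The defaults — 10 replicates of 40 single-antigen
vaccines over a 100-subject population with cohorts of 200 — were chosen
so each replicate runs in about two seconds while leaving binomial noise
clearly visible; antigen lengths 15–80 aa make predicted rates vary
across vaccines at *every* threshold (long antigens saturate the
single-allele threshold at 100%, which is itself informative: it
reproduces the known overestimation by single-HLA matching, visible as
the low mean r at `n = 1`).

```{r recovery, eval = FALSE}
recover_hla_threshold(seed = 1, n_seeds = 3)
#>    threshold    mean_r n_seeds
#> n1         1 0.3991828       3
#> n2         2 0.7447738       3
#> n3         3 0.9748726       3
#> n4         4 0.5980512       3
```

The acceptance script (`scripts/acceptance.R`) reruns this experiment at
full size, together with the worked 9-mer-count example, the
zero-responder binomial bound, a 433-subject coverage computation, and a
59-trial comparison battery, and writes all results as JSON.

## Numerical choices and degenerate inputs

* Rates are kept as exact integer (numerator, denominator) pairs;
  division happens only at presentation.
* A vertical perpendicular-fit line (all variance in y) is returned as an
  explicit `vertical = TRUE` result with the line's x position, never an
  overflow. An isotropic point cloud (zero covariance, equal variances)
  has no unique TLS direction; slope 0 is returned.
* Degenerate ROC labellings (single class) return `auc = NA` with a
  `degenerate` flag rather than a number; `auc_sweep()` skips them and
  reports the min/max over the rest.
* Empty post-stratification populations are an error: there is no
  denominator to report, and silently returning 0/0 would corrupt
  downstream pooling.
* Unknown allele spellings are an error naming the offending token, not a
  guess; incomplete genotypes (a missing HLA-C slot) are rejected because
  thresholds of 3+ alleles are meaningless on partial genotypes.
* Windows containing non-standard residues (`X`) are scanned but flagged
  unscorable and never receive predictions.

## Problem sizes

Unit tests run on populations of 4–20 subjects and antigens of 15–120 aa
with brute-force oracle recounts; the oracle-equivalence suite covers 100
seeded instances and the monotonicity suite 50. The acceptance script
uses a 433-subject synthetic MP for coverage and the 59-pair trial
battery, and 10 x 40 vaccines for recovery. These sizes were chosen as
the smallest at which every behaviour of interest (saturation at `n = 1`,
informative variation at `n = 3..4`, stable bootstrap bands) is clearly
expressed.

## Limitations

The model predicts genetic *capability* to present epitopes; it carries
no information about antigen expression, vaccine formulation, dosing,
prior treatment, assay choice or T-cell receptor recognition — all known
to move measured rates. The default scorer (`scoring_matrix()` +
`score_peptides()`) is a transparent position-specific-scoring-matrix
stand-in intended for testing and teaching; for real analyses, import a
table of predictions from a production epitope predictor via
`read_binding_table()`.
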