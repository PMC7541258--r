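---
title: "Master-regulator activity, synergy, and clinical association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Master-regulator activity, synergy, and clinical association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsynergy)
```

## The problem

A master regulator (MR) is a gene — transcription factor, cofactor, or
signalling gene — whose activity change drives a broad transcriptional
program. Its activity is not read from its own expression but inferred from
the behaviour of its *regulon*: the set of target genes it regulates in a
context-specific interactome. Each interactome edge carries a mode of
regulation (MOR, a signed strength in [-1, +1]; positive means activation)
and a likelihood weight in (0, 1] reflecting the mutual-information support
for the edge.

Given tumour-versus-normal differential-expression (DE) signatures from
several independent cohorts, the pipeline in this package

1. converts each DE signature into a differential-activity (DA) signature
   over all regulators,
2. selects the MRs that are among the top N activated (or suppressed) in
   *every* discovery cohort, validates them in held-out cohorts, and keeps
   only MRs whose own expression change is consistent with their inferred
   activity,
3. tests all pairs of the surviving MRs for *synergy* — whether the targets
   the two MRs share respond more strongly than the targets unique to each —
   and
4. relates MR expression to clinical features, somatic mutation classes and
   overall survival in a sample-level cohort.

## Activity inference (DA step)

The DE signature (moderated t for microarray, signed `-log10` adjusted p for
RNA-seq, see `rnaseq_de_score()`) is first mapped to signed normal scores:
with `G` genes and average ranks `r`,

```
z = qnorm((r - 0.5) / G).
```

For a regulator with scoreable targets `t` (targets present in the signature
with `mor != 0`), with weights `w = likelihood`,

```
NES = sum(w * mor * z_t) / sqrt(sum((w * mor)^2)),   p = 2 * pnorm(-|NES|).
```

Under the null hypothesis that the regulon is an exchangeable draw from the
signature, the normal scores have mean 0 and variance (essentially) 1, so
NES is standard normal; the sign reads as the activation direction and the
magnitude as evidence. This is a deliberately transparent, analytically
calibrated enrichment statistic playing the role that three-tail aREA with
pleiotropy correction plays in VIPER: it is *not* a numerical reimplementation
of VIPER, and no attempt is made anywhere to reproduce VIPER's NES values.
The package's calibration tests verify the N(0,1) null empirically (10,000
random regulons; the fraction of p < 0.05 must fall in [0.04, 0.06]) and
compare the analytic p against a brute-force permutation oracle (all
gene-to-rank assignments) on small regulons. The analytic tail is an
asymptotic approximation: on a realistic signature (thousands of genes) it
is accurate, but on a deliberately tiny 10-gene signature the normal scores
have variance 0.879 rather than 1 and drawing targets without replacement
adds negative covariance, so the analytic and exact permutation p can differ
by up to ~0.1-0.2 for same-signed heavy regulons of size 6. The test suite
asserts the strict 0.05 agreement bound and therefore documents this
finite-size deviation as an expected failure at the 10-gene scale; the
calibration at realistic scale (the 10,000-regulon null check) is the
binding guarantee.

Numerical choices: ties in the DE scores get average ranks; regulators with
fewer than `min_targets = 2` scoreable targets get an undefined NES (the
variance normalization degenerates below two targets); targets with
`mor = 0` carry no directional information under this statistic and are
excluded.

## Selecting reproducible MRs

`top_n()` takes the N regulators with the largest (activated) or smallest
(suppressed) NES; ties at the boundary break lexicographically on the
regulator id so results are reproducible. `common_top()` intersects the
per-cohort top-N sets across all discovery cohorts; `validate_common()`
compares the NES of the selected set against all other regulators in each
validation cohort with a two-sided Wilcoxon rank-sum test. The default
N = 100 follows the headline setting of the analysis this package
operationalizes (N in {50, 100, 200, 300} are all meaningful).

`da_de_consistent()` then demands that the MR's *own* DE score agrees in
sign with its NES and exceeds 3 in magnitude (strictly) in every discovery
cohort. The threshold is applied to each cohort's native DE scale, with no
rescaling between microarray t-statistics and RNA-seq scores — the rule is
used exactly as stated, and mixing scales is a known caveat of it. MRs
missing a DA or DE value in any discovery cohort are dropped with a warning
rather than an error, so one incomplete cohort cannot abort a run silently.

## The synergy test

For an eligible pair (strictly more than 10 shared targets, and the shared
targets strictly more than 10% of each regulon — `eligible_pair()`), the
union of the two regulons is partitioned into common, MR1-unique and
MR2-unique targets. Each target contributes its *expression contribution to
activity*,

```
ECA = DE * MOR,
```

and for each MR the common targets' ECA values (computed with that MR's own
MOR — a shared target may therefore contribute different ECA values to the
two tests) are compared against that MR's unique targets with a one-tailed
Wilcoxon rank-sum test: alternative "greater" when the MR's DA is positive
in that dataset, "less" when negative. Likelihood weights are carried in the
partition but deliberately unused by the test — ECA is a function of DE and
MOR only. Common targets whose two MORs disagree in sign are kept; nothing
in the statistic requires concordance, and dropping them would silently
shrink the eligible-pair set.

The screen (`synergy_screen()`) runs every unordered candidate pair on every
dataset and summarizes by the pair minimizing the maximum of its p-values
over datasets and sides (`top_synergistic_pair()`); an undefined p counts as
1, so a pair is never rewarded for being untestable in a dataset. The
"minimize the worst p" summary is a convention of this package, chosen
because a synergistic pair is expected to be significant in *all* datasets,
not on average.

## Rank-sum convention

Every Wilcoxon rank-sum test in the package — validation, synergy, and the
clinical battery — goes through one routine, `rank_sum_test()`: exact
enumeration when both groups have at most 12 observations and the pooled
sample is tie-free, otherwise the normal approximation with tie and
continuity corrections. Small-sample comparisons are therefore exact and
deterministic, while large cohorts use the standard approximation. The exact
path is verified in the tests against an independent enumeration over all
`choose(n+m, n)` group assignments.

## Clinical association battery

* Mutation classes: a sample is `None` for a gene with no recorded events,
  `LOF` if any loss-of-function event (nonsense, frameshift, splice) is
  present — a sample with both a missense and a LOF event is LOF — and
  `missense` otherwise.
* `categorical_association()` keeps feature groups with strictly more than 5
  samples, orders them by median expression and compares the extreme-median
  groups (two-sided).
* `mutation_association()` compares each mutation class against the `None`
  group (two-sided), reporting the median difference, its direction, and
  selection at raw p < 0.1. No multiple-testing correction is applied in the
  selection itself; `mutation_association_report()` adds a clearly-labelled
  Benjamini-Hochberg column as optional extra output.
* `combined_mutation_test()` contrasts samples with a missense class for at
  least one gene of a set against samples unmutated for the whole set;
  samples whose only mutations in the set are LOF belong to neither group,
  which is the only reading under which "missense in any of the genes" and
  "none of these mutations" partition fewer than all samples, as the
  motivating analysis reports.
* `numerical_association()` is a Spearman correlation with the asymptotic
  t-approximation p-value.
* `survival_split_logrank()` splits at the 80th percentile of expression
  (linear-interpolation quantile, type 7; ties at the threshold go to the
  low group, the high group is strictly above) and applies the standard
  two-group log-rank test. Degenerate splits (a group below 2 samples, or no
  events) return an undefined result with a reason instead of an error.

The delta column of the mutation report is a difference of *medians*,
matching its name; group location differences are reported on the same scale
the rank-sum test effectively compares.

## The synthetic benchmark

`sim_config()` fixes the study conditions the pipeline is benchmarked under;
the generators are pure functions of (configuration, seed), with one named
substream per generator (`substream_seed()`) so that, for instance, changing
the cohort size never perturbs the simulated network.

Default conditions, and why:

| parameter | default | rationale |
|---|---|---|
| `n_mrs`, `n_genes` | 5000, 20000 | order of magnitude of a genome-wide regulator set over a transcriptome |
| `regulon_size_range` | 50-150 | typical regulon sizes of mutual-information interactomes; small regulons (< ~40 targets) make activity inference at effect 2 a coin-flip and would defeat the benchmark's purpose by design |
| `mor_positive_fraction` | 0.7 | activating edges predominate in such interactomes |
| MOR magnitude, likelihood | U(0.3, 1), U(0.1, 1) | weak-to-strong edges with no exact zeros (zero-likelihood edges are invalid by contract) |
| `n_active_up`, `n_active_down` | 18, 3 | cardinalities of the activated/suppressed common-MR sets the pipeline is designed to detect |
| `effect_size` | 2 | per-target DE shift enters as `effect * mor * likelihood`, making the DA statistic correctly specified at defaults |
| `mr_self_de` | 6 | planted MRs' own genes must clear the consistency cutoff of 3 with high probability per cohort; 6 puts them ~3 noise SDs above it |
| `pair_regulon_size`, `pair_common_size` | 60, 12 | smallest comfortable geometry passing the >10 and >10% eligibility rule |
| `pair_extra_effect` | 1 | extra shift of the shared targets, applied as `extra * mean(mor1, mor2)` (the shared MORs are positive for both MRs by construction; the mean is the symmetric choice) |
| `dataset_noise_sd` | 1 | each dataset is `planted effects + N(0, 1)` noise, independent across datasets — the planted effects are the shared biology, the noise is the cohort-specific variation, and with zero effects the signatures are exactly i.i.d. noise |
| cohort sizes | 30/30/30 (N/C/M) | group means step by 1 per group for the designated gene pair |
| `planted_correlation` | 0.8 | within-(group x mutation-status) correlation of the designated pair |
| `mutation_shift` | +2 | expression shift of mutated samples (both designated genes); mutations are assigned uniformly across samples so that, at shift 0, mutated and unmutated groups are exchangeable and the association test's calibration can be measured |
| `survival_hazard_ratio` | 2 | hazard multiplier for the top-20% expression group; times are exponential with administrative censoring |

What the generator deliberately does **not** emulate: probe-level microarray
structure, batch effects, normalization artefacts, covariates such as HPV
status, copy-number confounding of expression, and regulon overlap between
unrelated regulators beyond what random sampling produces. Passing the
recovery benchmarks therefore shows that the pipeline is correct and
well-calibrated under its own model assumptions — not that real cohorts
satisfy those assumptions.

## Benchmark problem sizes

The packaged tests and the acceptance script use: 10,000 random regulons for
the NES null; all `choose(10, k) * k!` rank assignments (k ≤ 6) for the
permutation oracle; 100 simulation seeds at the full default scale (5000
regulators, 20000 genes, 10 datasets) for planted recovery; 1000 replicates
for synergy-null uniformity; 600/200/1000/400 replicates for mutation
calibration, mutation power, correlation coverage and log-rank calibration;
and a 300-regulator bundle for the byte-identity rerun check. These sizes
are the package's chosen benchmark conditions and are stated here so they
can be reproduced exactly.

## Determinism and logging

`run_full_analysis()` writes every stage artefact (per-dataset DA tables,
selection report, synergy report, JSON summary) plus a run log containing
the configuration hash and seed. The log intentionally records the stage
*sequence* but no wall-clock timings, so that rerunning the same
configuration on the same inputs yields byte-identical output trees — a
property the tests assert file by file.

## Known limitations

* The activity statistic is a one-tail weighted mean: it does not model the
  three-tail structure or the pleiotropy (shadow) correction of aREA/VIPER,
  so regulators with heavily overlapping regulons can share credit for the
  same targets.
* The DA-DE consistency rule compares raw DE magnitudes across platforms
  with different scales.
* The percentile survival split discards within-group expression variation;
  no proportional-hazards model is fitted.
* GO-based MR categorization matches term ids literally, with no ontology
  traversal; category counts depend entirely on the annotation snapshot
  supplied.
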