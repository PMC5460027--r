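---
title: "Mining mutation-specific synthetic lethality from Boolean implications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining mutation-specific synthetic lethality from Boolean implications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misl)
```

## The idea

Two genes form a synthetic-lethal (SL) pair when losing either alone is
tolerated but losing both kills the cell. In a tumour that carries a
driver mutation `X`, an SL partner `B` of `X` is a drug target: inhibiting
`B` should kill only the mutant cells. `misl` infers candidate partners
directly from primary-tumour genomics, on the premise that selection
leaves footprints in the joint distribution of somatic alterations:

* **Deletion arm (mutual exclusion, HI-LO).** If `X`-mutant cells cannot
  tolerate loss of `B`, tumours carrying `X` should essentially never also
  carry a deletion of `B`. The Boolean implication "`X` mutated ⇒ `B` NOT
  deleted" holds: the (X = 1, B\_del = 1) quadrant of the 2×2 table over
  samples is statistically empty.
* **Amplification arm (subset, HI-HI).** If mutant cells depend on `B`,
  extra copies of `B` are selected for specifically in `X`-mutant tumours:
  "`B` amplified ⇒ `X` mutated", with the (B\_amp = 1, X = 0) quadrant
  empty.

Both relationships are mined over a pooled pan-cancer sample union, then
filtered by two expression tests that anchor the copy-number signal in
function.

## The implication test

Every alteration is a Boolean variable per sample: gene-level mutation
presence (with optional per-type variables), gene amplification and gene
deletion calls derived from segmented copy number (|segment mean| > 0.3,
≥ 5 markers, tumour segments covered > 50% by matched-normal alterations
removed, ≥ 1 bp gene overlap).

A directed implication between two variables must pass two gates:

1. **Dependence.** Two-sided Fisher exact test on the 2×2 table,
   `p < fisher_cutoff` (the cutoff is itself constrained below 0.05).
2. **Sparse quadrant.** The forbidden quadrant must be almost empty.
   With `a` points in the sparse quadrant, `r` the other cell in its row
   and `c` the other cell in its column, the error rate is the averaged
   conditional violation probability

   `e = 0.5 * (a / (a + r) + a / (a + c))`,

   required to be `< 0.1`. `a = 0` gives `e = 0`; an empty margin fails
   closed (`e = 1`).

Because a handful of alterations are present in nearly every tumour
sample, the HI-HI search first appends *artificial normal* samples —
all-negative columns — to the alteration matrices; otherwise the
mutation margin is degenerate and Fisher's test is powerless. The count
defaults to the pooled tumour sample count (`artificial_normal_k =
"auto"`); somatic alteration matrices can absorb this because germline
events are assumed removed upstream. Expression matrices are never
augmented.

**Cutoff calibration.** `calibrate_fdr()` estimates, for a grid of Fisher
cutoffs, the ratio of the mean implication count after independently
permuting each variable's sample labels (100 permutations by default,
seeded) to the observed count, and chooses the largest cutoff with
estimated FDR < 0.05. Forward runs are meant to use this calibrated
cutoff; `misl_config()`'s default of 0.05 is the hard upper bound, not
the recommended operating point. We permute each variable independently
(rather than jointly) because the null of interest is independence
between the pair; a joint permutation would preserve their dependence
and estimate nothing.

## The forward pipeline (`run_misl`)

For a mutation `X` and a cancer of interest:

1. **Recurrence gate.** Only cancers where `X` is mutated in ≥ 2.5% of
   samples (inclusive) contribute samples.
2. **Arms.** HI-LO implications over partner deletions and HI-HI
   implications over partner amplifications, each computed on one pooled
   2×2 table per partner.
3. **Passenger filter.** Large chromosomal events drag passengers along.
   A partner's cohort contributes samples only if its alteration is
   *non-passenger* there: carriers show concordant differential
   expression (Welch two-sided t-test p < 0.05 and fold difference
   `2^|Δ log2 mean|` > 1.2, lower for deletions, higher for
   amplifications). Genes with fewer than two carriers, or missing
   expression, are passengers by convention.
4. **Mutant overexpression.** Surviving partners must be differentially
   overexpressed in `X`-mutant versus wild-type samples of the cancer of
   interest (Welch p < 0.05 with the mutant mean higher). This removes
   partners that are irrelevant in the target context and false positives
   from convergent evolution.

Design choices worth stating explicitly, because the method description
leaves them open:

* **Pooling, not voting.** Implications are computed on the union of
  samples from eligible, non-passenger cancers — a single 2×2 table —
  rather than per-cancer calls intersected afterwards. The pan-cancer
  union is what gives rare alterations statistical mass.
* **Same-chromosome partners** are *not* excluded in the forward mode
  (a flag exists); the reverse biomarker mode always excludes them,
  where proximity to the drug target is a known false-positive source.
* **Cohorts without copy-number data** (an AML-like situation)
  contribute mutation and expression evidence only; partner CNA evidence
  comes from the other cancers while the final expression filter still
  runs in the cancer of interest.
* **Welch everywhere.** Every "t-test" is the unequal-variance Welch
  test, two-sided, with directionality enforced by the sign of the mean
  difference rather than a one-sided p.
* **Amp/del conflicts** within one (gene, sample) are ambiguous and set
  to FALSE on both sides.
* **Ties and determinism.** Outputs are sorted by (Fisher p, error rate,
  partner symbol); all stochastic stages consume explicit seeds.

`targetable_summary()` aggregates runs: the fraction of recurrent
mutations with ≥ 1 candidate, the fraction of samples carrying a
targetable mutation, and (mutation, partner) pairs shared across
cancers.

## Reverse mode: biomarkers of drug sensitivity

`predict_biomarkers()` inverts the roles. For each gene `Y` inhibited by
a drug (from a drug–gene interaction table), it scans for alterations
`X` with "`X` ⇒ `Y` NOT deleted" or "`Y` amplified ⇒ `X`", pooling
cancers where `Y`'s alteration is non-passenger intersected with cancers
where `X` is recurrent — the role-swapped image of the forward pooling
rule. Alterations on `Y`'s chromosome are removed, and `Y` must be
overexpressed in `X`-altered samples of the cancer of interest.
`evaluate_sensitivity()` scores predictions against pharmacology:
"truly sensitive" cell lines are those in the first quartile of IC50
(inclusive linear-interpolation quantile, ties included); drug families
pool lines on the per-line minimum IC50 across member drugs; overlap
between predicted and truly sensitive lines is a two-sided Fisher test.

## Screen-based validation statistics

* `call_dropout_hits()` — pooled shRNA dropout screens. Constructs with
  baseline reads < 100 are removed, genes with < 3 surviving constructs
  are removed; a construct qualifies at > 20% read reduction
  (ratio < 0.8) and a gene is a hit when ≥ 2 constructs qualify *and*
  their mean drop-out ratio is < 0.6. The two gates are conjunctive,
  each independently relaxable.
* `score_mutation_essentiality()` — per-cell-line essentiality scores.
  Per construct a Welch test of mutated vs wild-type lines; per gene the
  construct with the smallest p; gene score
  `-log10(p) × (mean_wildtype − mean_mutated)`, so genes preferentially
  depleted in mutant lines score strongly positive. Ranking descending,
  ties broken by symbol.
* `preranked_enrichment()` — weighted Kolmogorov–Smirnov running-sum
  enrichment of a gene set in that ranking (weight 1, 2000 label
  permutations by default). The normalised score divides the ES by the
  mean magnitude of same-sign null scores. The nominal p is computed
  against the *same-sign portion* of the null — the standard preranked
  convention — which makes null p-values uniform on (0, 1); computing it
  against all permutations would cap p near 0.5 and break calibration.
  Overlaps below 25 genes are refused by default because the running-sum
  statistic is unstable there (the floor is a parameter).
* `overlap_test()` / `same_pathway_enrichment()` — Fisher and
  hypergeometric set enrichment; pathway tests are restricted to
  pathways containing the mutated gene with ≤ 500 members, and redundant
  results are pruned (identical overlap sets keep the smaller p;
  overlap sets strictly contained in another's are dropped).

## The synthetic-cohort generator

All tests run without external data. `generate_cohorts()` plants the
exact statistical structure the miner assumes, and emits the ground
truth for recovery scoring:

* HI-LO pairs: partner deletions only in mutation-wild-type samples
  (15% of them by default; `leak_rate = 0` forces an empty sparse
  quadrant); HI-HI pairs: partner amplifications only within mutant
  samples (60%).
* Background alterations are independent Bernoulli draws (5% per gene);
  anchor mutations hit 15% of samples; 20 extra background mutations at
  5% provide recurrent non-planted anchors.
* Expression is Gaussian log2 (baseline 5.0, sd 0.4); every
  non-passenger copy-number call shifts its carrier by ±1.0 log2 units;
  the 50 passenger genes carry calls (10% of samples) with *no*
  expression shift; planted partners are overexpressed by 1.0 in mutant
  samples of the cancer of interest (the final-filter signal, removable
  with `mutant_overexpression = FALSE` for ablation studies).
* Planted partner CNAs are placed in every cohort *except* the cancer of
  interest, mirroring a cohort whose copy-number evidence must come from
  other cancers (the AML situation) — this also keeps the final-filter
  signal orthogonal to the CNA-concordance signal, so ablations isolate
  exactly one filter.
* Every artifact draws from its own stream derived deterministically
  from the master seed, so adding artifacts never perturbs existing
  ones; generation is byte-reproducible.

The standard conditions are 3 cancers × 200 samples, 500 genes, 10
planted pairs per arm, 50 passengers, seed 7. What the generator does
*not* emulate: realistic mutational signatures, GISTIC-like CNA length
distributions, count-level RNA-seq noise, gene–gene expression
correlation. Recovery results on these fixtures therefore demonstrate
that the statistics and filters behave as designed, not that real-tumour
power matches them.

`generate_screen()`, `generate_score_screen()` and
`generate_pharmacology()` derive dropout screens (planted partners at
drop-out ratio 0.4, null genes near 1 with log-normal noise ×1.15),
per-cell-line score screens (planted genes depressed by 1.0 in mutant
lines) and IC50 tables (biomarker lines log-normal around 1 µM, others
around 6 µM) from the same truth record.

## Numerical notes and test scales

* `fisher_p()` enumerates the hypergeometric support directly (with the
  conventional 1 + 1e-7 relative tolerance when summing tables no more
  likely than observed) and returns 1 for any degenerate margin; it
  agrees with `stats::fisher.test` to 1e-10 and is cheap enough to call
  hundreds of thousands of times in scans and permutation nulls.
* Welch tests over many genes are computed in closed form over matrices
  (means/variances via row sums); zero-variance rows fall back to
  p = 1 when means agree and p = 0 otherwise.
* Degenerate inputs: empty mutation tables give empty matrices; genes
  missing from the expression matrix or with < 2 carriers are passengers
  by convention; tumour samples without matched normals keep their
  segments, logged.
* The test suite runs the scan-vs-brute-force equivalence on 1,000
  random fixtures (≤ 20 variables × ≤ 100 samples), the Fisher oracle on
  10,000 tables (total ≤ 60), null-calibration on 200 single-cancer
  null cohorts (200 samples × 300 genes), recovery and ablation on the
  standard fixture, enrichment-p uniformity on 500 random sets, and
  essentiality ranking on 20 independent 1,000-gene screens — sizes
  chosen so each property is measured with comfortable statistical
  margin.

## Command-line interface

The `misl` launcher (`system.file("cli", "misl", package = "misl")`)
wires the subcommands `synth`, `booleanize`, `implications`, `run`,
`biomarkers`, `evaluate-sensitivity`, `screen-hits`,
`rank-essentiality`, `gsea` and `pathway-enrich` over the same exported
functions, writes outputs atomically, and drops a JSON manifest (tool
version, config snapshot, input digests, seed, per-stage counts) next to
every result. Reruns with identical inputs and seed are byte-identical.

## Limitations

Gene identity is the uppercased symbol string (no alias resolution);
coordinates are 0-based half-open internally with conversion only in the
readers; there is no liftover, no VCF/MAF full parsing, no GISTIC-style
recurrence peaks, and no dose–response curve fitting. The implication
taxonomy is restricted to the two classes the SL argument needs (HI-HI,
HI-LO); equivalence and LO-LO relations are out of scope.
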