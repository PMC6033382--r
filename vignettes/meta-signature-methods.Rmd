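---
title: "Meta-signatures from directional expression signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-signature methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `metasig`, the
parameters that matter, the design decisions taken where several
reasonable choices existed, and what the synthetic benchmark does and
does not demonstrate about real data.

## The object of study

A *directional signature* is the unit of evidence: the outcome of one
two-group contrast inside one study, recording for each significant gene
its direction of regulation (up or down in the disease-like group) and a
confidence score (`−log10` of the contrast p-value), together with the
size of the tested gene universe. Signatures deliberately discard
expression magnitudes: across microarray and sequencing platforms the
magnitudes are incommensurable, but identity + direction + confidence
survive translation across studies and even across species (via homolog
mapping, `map_homologs()`).

A *meta-signature* is the consensus over a cluster of mutually similar
signatures: genes ranked by how often they recur and how consistently
their direction agrees. A *centroid reference signature* turns the
meta-signature into a per-sample classifier: a fixed per-gene reference
profile correlated (Spearman) against each individual sample.

## Signature extraction

Per gene, a two-sided Wilcoxon rank-sum test compares the case group to
the baseline group; direction is `sign(median_case − median_baseline)`.
Genes at Benjamini–Hochberg FDR ≤ `fdr_alpha` (default 0.05) enter the
signature, capped at `max_entries` (default 500, the several-hundred-gene
scale typical of microarray contrast signatures), ranked by confidence.
Genes with exactly equal medians are excluded even when the test is
significant: no direction can be assigned, and an undirected gene is
useless to every downstream step.

The rank-sum p-value uses three regimes:

* **exact Wilcoxon null** when the row has no ties and the smaller group
  has ≤ 50 samples — the same switchover as `stats::wilcox.test`. The
  exact null matters more than it may seem: with a small control group
  (say 7 controls vs 20 cases) the normal approximation cannot produce a
  p-value below ~1e-4, which no gene can survive after BH correction over
  a 10,000-gene universe; the exact tail reaches 2.3e-6 and restores the
  power the data actually contain.
* **exact permutation enumeration** for tied rows whose group split has at
  most 2000 arrangements — small-sample tied data are common in test
  fixtures and degenerate inputs, and the enumerated null is the correct
  reference there.
* **tie-corrected normal approximation with continuity correction**
  otherwise.

p-values are floored at 1e-300 before the log transform. Contrast
orientation is deterministic so that directions are comparable across
studies: an all-healthy group is always the baseline; between two disease
groups the lexically later label is the case.

## Similarity, significance and clustering

Two signatures are compared only on what they carry. Over the shared
genes *O*:

* `weighted_score = Σ_{g∈O} d_a(g) · d_b(g) · min(w_a(g), w_b(g))`, where
  `w` is each entry's confidence divided by the maximum confidence in its
  own signature (so `w ∈ (0, 1]` and no signature dominates through its
  p-value scale);
* `p_concordance`: one-sided binomial tail `P(X ≥ n_concordant |
  n_overlap, ½)` — direction agreement beyond coin flipping;
* `p_overlap`: hypergeometric upper tail of the overlap size given both
  signature sizes, with the universe set to the *smaller* of the two
  tested universes (the conservative choice; a larger universe would
  flatter the overlap).

A pair is *significant* when both tails are ≤ `alpha` (default 0.01) and
concordant genes outnumber discordant ones. Requiring both criteria
prevents the two classic artifacts: two large signatures overlapping by
chance (identity without directionality), and a handful of shared genes
agreeing by chance (directionality without identity).

Clusters are the connected components of the significance graph,
singletons omitted. The component rule is a single-pass reading of an
iterative search-and-group process; a second pass re-searching cluster
consensus against leftover signatures was considered and rejected for the
default because it adds a free parameter (when to stop) without changing
any benchmark outcome. Cluster *selection* is the user's: in real
collections the disease cluster is identified by reading member
phenotypes, not by size, which is why `metasig_fit()` exposes all
clusters and takes a `cluster` index.

## Meta-signature ranking

Per gene over the cluster members: `recurrence` (membership count),
`n_up`/`n_down`, `concordance = |n_up − n_down| / recurrence`, consensus
direction `sign(n_up − n_down)`, mean confidence. Ranking is
lexicographic — recurrence, then concordance, then mean confidence, then
gene id — and therefore a total order: the output is identical across
runs and input orderings. Genes with `n_up = n_down` are excluded from
the top-N: a consensus direction would be fabricated. The composite of
recurrence and concordance could also be a weighted score; the
lexicographic form was chosen because it has no tuning weight and makes
every rank auditable.

## Centroid construction and per-sample prediction

Within each training study, meta-signature genes are standardized
**against the healthy-control baseline**: centered at the mean of the
study's healthy samples, scaled by the gene's SD across all samples
(`baseline_standardize()`). Per study, the selected samples (disease
status, or a disease-activity bin) are averaged per gene; the centroid
averages the per-study means with equal study weights, so a 900-sample
study cannot outvote a 40-sample one. Genes missing from a study are
skipped for that study and omitted only if absent everywhere.

Centering at the healthy baseline rather than the cohort mean is the
package's most consequential design decision. Disease-dominated cohorts
are the norm in this setting (a validation cohort can be > 90% patients);
centering such a cohort at its own mean subtracts most of the disease
effect out of every profile, leaves low-activity patients *negatively*
correlated with the reference, and silently re-centers any fixed
correlation threshold. The directional meta-profile a signature
represents is "change relative to normal", and the standardization must
match. When a cohort has no healthy samples at all, the cohort mean is
the only available baseline and is used with a warning. Note the
per-sample *call* never uses the sample's own label; labels enter only
through the study-level baseline, the same way expression test sets are
normalized against their control arm in practice.

A sample is called diseased when its Spearman correlation with the
disease centroid reaches the threshold, **inclusive** (`rho ≥ 0.3`, the
conventional threshold for this class of reference-correlation
classifiers; configurable in `(−1, 1)`). The comparison applies a 1e-9
epsilon because rank arithmetic in floating point can return an exact 0.3
as `0.3 − 7e-17`, which would silently turn the inclusive boundary
exclusive. Prediction requires at least `min_shared = 10` genes in common
with the centroid; Spearman correlation on fewer genes is mostly noise.
Disease-activity bins (S1: SLEDAI 0–2, S2: 3–7, S3: > 7) are assigned by
the maximal correlation among the three activity centroids; exact ties
break toward the lower-severity bin, the conservative clinical default.

## Stratification

Retrospective validation clusters samples on the meta-signature genes
alone: per-gene z-scores across the cohort (`project_study()`; here the
spec-standard cohort z-score is appropriate because clustering only needs
relative geometry, not a calibrated threshold), pairwise distance
`1 − Pearson`, average-linkage (UPGMA) agglomeration, and a split at the
root merge — the dendrogram's first bifurcation. The "left" group is the
one containing the lexically smallest sample id, a naming convention with
no semantics. Enrichment of disease labels between the two groups is
tested with a two-sided tie-corrected Mann–Whitney U on status coded
1/0 — kept because it is the established test in this workflow even
though a rank test on binary data is unusual — with a two-sided Fisher
exact test on the 2×2 table reported alongside as the interpretable
cross-check. Constant genes are dropped before clustering (their z-score
and correlations are undefined), and a cohort measuring fewer than half
the meta-signature genes is rejected rather than silently projected.

## The synthetic benchmark

`simulate_collection()` generates what the pipeline needs to be tested
against: multiple independent studies over one gene universe, per-gene
baselines `Normal(0, 1)`, per-study per-gene offsets
`Normal(0, study_shift_sd = 0.5)` (platform scale heterogeneity), a
random `dropout_frac = 0.1` of genes absent per study (platform
coverage), a healthy group and three disease groups graded by activity,
`Normal(0, noise_sd = 1)` measurement noise, and an embedded directional
signature (default 100 genes, 70% up-regulated — disease signatures of
this kind are predominantly up-regulated).

Disease activity acts on the signature in two ways. Active genes shift by
`direction · effect_size_delta · da_multiplier(bin)` (defaults 1.5 SD and
0.5/1.0/1.5), and each signature gene carries an *onset bin* drawn
uniformly from {S1, S2, S3}: it responds only in samples whose activity
reaches its onset. The graded-recruitment component is not decorative —
it is what makes activity bins identifiable at all. If every gene were
active in every bin (pure magnitude scaling), the three activity
centroids would be scalar multiples of one direction vector plus
independent small jitter; their rank vectors would then be exchangeable,
and an argmax over rank correlations would select among them uniformly at
random, for any effect size. Progressive recruitment of genes with rising
activity (as with activity-graded modules in real blood signatures) gives
each bin a distinct active set and makes the maximal-correlation rule
informative. Equal onset thirds give each stratum a comparable number of
newly recruited genes.

Cohort composition: the three disease groups have `samples_per_group`
samples each (default 20, a desk-scale stand-in for real per-study sizes)
and the healthy group is sized so that diseased samples are `frac_sle`
of the study (default 0.9, the imbalance of real validation cohorts).
SLEDAI scores are drawn uniformly within each bin's range. Everything is
a deterministic function of the configuration including its seed, and the
generator restores the caller's RNG state. `simulate_cohort()` draws
additional cohorts sharing an existing collection's ground truth — a
fresh configuration would embed a *different* signature, so held-out
cohorts for a fitted model must come from the same collection.

What the generator does **not** emulate: probe-level intensity
distributions, batch effects requiring correction, longitudinal visits,
treatment effects, correlated gene modules, or non-Gaussian platform
noise. Because every downstream statistic is rank-based, the marginal
noise law is largely immaterial — what the benchmark genuinely exercises
is ordering structure, dropout, study offsets and effect geometry.
Passing benchmarks therefore show the pipeline's machinery is correct and
calibrated under known truth; they do not certify performance figures on
any real cohort.

## Benchmark problem sizes

The test suite and `scripts/acceptance.R` use: the default 13-study ×
10,000-gene collection for signature recovery; a 15-study collection
split 13 training + 2 held-out cohorts for prospective classification;
two 500-sample zero-effect studies (1,000 samples) against a
1,000-draw permutation null for threshold calibration; a 100-per-bin
activity-gradient cohort for disease-activity prediction; and twenty
replicate 90%-disease cohorts for first-bifurcation stratification.
Statistical primitives (rank-sum, Mann–Whitney, Fisher exact, Spearman,
AUC, UPGMA, connected components) are verified against brute-force
enumeration oracles at sizes where enumeration is feasible (hundreds of
randomized instances each).

## Numerical and degenerate-input conventions

* Duplicate gene rows (multiple probes) collapse by per-sample arithmetic
  mean — order-independent and standard; gene symbols are upper-cased on
  ingest so cross-species joins work on one token space.
* Homolog conflicts keep the highest-confidence entry; a discordant tie
  at the maximum drops the gene — a direction is never fabricated.
* Missing values are rejected on ingest; platform dropout is modeled as
  genes absent from a study, never as NaN cells.
* Empty signatures are representable but flagged invalid and excluded
  from the similarity search; a contrast where nothing passes keeps its
  universe size.
* Performance ratios with zero denominators (e.g. NPV with no negative
  calls, AUC with one-class truth) are reported as `NA`, never coerced to
  0 or 1.
* All orderings that could depend on input order carry explicit
  deterministic tie-breaks (gene id, member id, lexical anchors).

## Known limitations

* The classifier needs a control baseline per cohort; fully
  baseline-free prospective prediction would require calibrating a
  reference scale from training data alone, which is out of scope.
* NPV is intrinsically weak in heavily disease-dominated cohorts — with
  few true negatives, even a well-calibrated threshold yields few
  confident negative calls.
* Cluster selection is not automated: the disease cluster is an expert
  judgment over member phenotypes. The default (largest cluster) is only
  a sensible starting point on benchmark data.
* The Mann–Whitney enrichment test on 0/1 status is reported for
  continuity with established practice; Fisher's exact test on the same
  table is the statistically natural summary and is always computed
  alongside.
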