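---
title: "Methods: the organelle proteome landscape pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the organelle proteome landscape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olscape)
```

`olscape` turns protein-level abundance matrices from panels of knockout
(KO) cell lines into organelle-resolved summaries: which subcellular
compartments a mutation reshapes, how similarly two mutations reshape them,
and where inside the cell the redistribution happens. This vignette is the
package's methods account: the statistical model of each stage, the
conventions adopted where several reasonable ones exist, what the synthetic
data generator does and does not emulate, and the known limitations.

## Data model and preprocessing

The pipeline starts at protein-level quantities (no spectra, no peptide
inference). An `abundance_matrix` is a proteins-by-samples table with an
explicit scale flag (`raw_intensity` or `log2`); a `study_design` records
genotype, cell type (`iN`, `iDA`, `HeLa`), fraction (`whole_cell`, `soma`,
`projection`, `lysoip`), replicate and, for LysoIP samples only, tag status.
An `annotation_catalog` maps annotation labels to possibly overlapping
protein sets (nesting such as OXPHOS inside mitochondria is expected),
groups annotations into families, and maps genotypes to disease classes.

Missing values are first-class and are **never imputed**: every downstream
statistic uses pairwise-complete observations. Proteomic missingness in real
data is partially intensity-dependent; modelling that dependence is out of
scope here, and the no-imputation policy keeps every estimate an honest
function of observed values only.

Normalisation is per-sample median centring in log2 space
(`normalize_median`), the single supported normalisation; total-intensity
scaling is the same operation after summation in log space. It is idempotent
and leaves each column with median 0 to within 1e-9. `row_z` standardises
rows for heatmap-style display, mapping zero-variance rows to zeros (rather
than missing) so displays stay dense. QC (`qc_metrics`) reports per-group
protein counts and median relative standard deviation; RSD is computed on
**linear** intensities, matching its standard definition, so a matrix on the
log2 scale must be exponentiated first.

## Differential abundance

`compute_contrast` computes, per protein, log2FC = mean(test) − mean(ref)
over present values and a two-sided two-sample t-test. The default is the
Student pooled-variance t; Welch is available behind a flag. Conventions for
degenerate rows, chosen to be deterministic and documented rather than NaN:

* both groups constant and equal → p = 1; constant and unequal → p = 0
  (the limits of the t statistic as the pooled variance vanishes);
* fewer than 2 replicates in a group → p missing, log2FC still reported when
  both means are computable; proteins absent from both groups are dropped
  with a logged count.

Multiple testing uses Benjamini–Hochberg step-up within each contrast
(`bh_adjust`, delegating to `stats::p.adjust`); missing p-values pass
through without counting as tests. BH is applied per volcano (per contrast),
not across contrasts. No moderation or shrinkage is applied to fold changes
or variances — the landscape statistics consume plain means, and annotation-
level aggregation provides the variance pooling that moderated t-tests would
otherwise contribute.

Effect sizes follow Cohen's d with the pooled, Bessel-corrected SD; zero
pooled SD yields a signed infinite sentinel (0 when the means also agree).

## The correlation landscape

The core statistic asks: restricted to one annotation's proteins, how
correlated are two conditions' fold-change profiles? `annotation_correlation`
computes pairwise-complete Pearson r between every pair of conditions
(a condition is a genotype × cell type; the control is never a condition
because fold changes are relative to it). Pearson is the correlation
throughout, matching the convention of reporting "Pearson scores (r)" on
link diagrams; Spearman is deliberately not a default anywhere. Cells
resting on fewer than `min_proteins` (default 10) pairwise-complete proteins
are reported missing — correlations on fewer points are noise — and missing
cells are excluded from all means, never zero-filled.

One interpretive caveat is worth stating: every condition's fold changes
are computed against the *same* control replicates, so the control's
measurement noise is a shared component of all profiles. At triplicate
scale with equal group variances this induces a baseline correlation of
about +0.5 between entirely unrelated conditions. The positive link
threshold (r > 0.7) sits above this floor, and negative correlations are
correspondingly strong evidence of opposite remodelling; but raw
correlation magnitudes should not be read as if profiles were independent
measurements.

The **organelle correlation** scalar of a condition is the mean of its
pairwise correlations to all other conditions of the same cell type over the
annotation (`organelle_correlation`). Mean-vs-peers is the minimal
convention that produces one scalar per condition from the pairwise matrix;
an alternative (correlating against a pooled rest-of-dataset profile) would
weight peers by their protein coverage and is not implemented. The
**composite map** (`composite_map`) assembles these scalars into a
condition × annotation matrix, tagged `mean-pairwise-within-celltype` so
alternative summaries can be swapped in and recognised downstream.
Cross-cell-type comparisons (`cross_celltype_correlation`) always pair the
*same* genotype's two cell-type conditions; peers never mix cell types.

`class_variance` summarises composite entries per disease class (mean,
sample SD, n), `filter_links` retains condition pairs beyond the display
thresholds r < −0.2 or r > 0.7 (upper triangle only, never self-links, with
an optional origin filter for the focused link diagrams), and
`hcluster_correlations` clusters profile rows under the distance
1 − Pearson r with average (default) or complete linkage via
`stats::hclust`, excluding rows with fewer than 3 informative entries.

The **impact score** ranks how strongly each condition perturbs a group of
annotations. The published description names the score without printing a
formula, so this package defines and documents one: for each annotation in
the group, the mean |log2FC| over its proteins is z-scored across the cell
type's conditions; a condition's impact is the mean z over the group, ranked
descending with ties broken by genotype label. Mean |log2FC| ignores
direction deliberately — the score measures the *extent* of perturbation —
and z-scoring puts annotations of different baseline variability on one
scale before averaging. The convention is recorded in the result's `method`
attribute.

## LysoIP co-enrichment

Lysosome immunopurification yields three groups: untagged background cells,
tagged control and tagged KO. Enrichment is the tagged-vs-untagged contrast
on the `lysoip` fraction (`enrichment_vs_untagged`); analyses without the
untagged background are refused rather than silently recentred on another
reference. The **co-enrichment threshold** is the mean enrichment of
quantified lysosome-annotated proteins, computed *within each tagged group
separately* — per-group thresholds are the only choice under which the
control/KO comparison of co-enrichment profiles is meaningful. A protein is
co-enriched when its enrichment is at or above the threshold (inclusive
boundary, exactly as the "≥" reads); per-annotation counts then ask which
compartments co-purify with lysosomes.

Organelle shifts between KO and control IPs are tested per annotation with a
two-sided Wilcoxon/Mann-Whitney rank-sum test and BH correction across
annotations. For combined samples of up to 12 values the p-value is exact by
full enumeration of group assignments over midranks (correct under ties,
where the classical exact distribution does not apply); beyond that, the
normal approximation with tie and continuity correction is used. The
crossover is configurable.

## Spatial proteomics by ratio of ratios

For the whole-cell / soma / projection design, each genotype's fraction
ratio is mean log2(projection) − mean log2(whole_cell) per protein
(`fraction_log_ratio`). The **ratio of ratios** subtracts the control's
ratio from the KO's (`ratio_of_ratios`): any compartment composition shared
by both genotypes cancels exactly, isolating genotype-specific spatial
redistribution. Because all samples sit in one TMT plex, replicates are
paired by index within genotype (replicate i projection with replicate i
whole-cell) to form replicate-level ratios, and the RoR p-value is a Student
t on KO vs control replicate ratios (3 vs 3 in the reference design);
classification uses q ≤ 0.05 with an optional |RoR| floor (default 0). At
triplicate scale the per-protein RoR test is underpowered for sub-unit
shifts; the powered readout is the annotation level.

`annotation_effect_ranking` scores each annotation by delta mean (annotation
mean RoR minus the mean over its complement among quantified proteins — the
complement, not the whole proteome, so the background reflects what was
measured), Cohen's d of the same comparison, and mean |RoR| over the
annotation. The overall rank is the mean of the three per-metric descending
ranks (unweighted — the three metrics are named jointly without a
combination rule, and an unweighted mean is the neutral aggregation), ties
broken by label; each annotation is additionally tested against its
complement by rank-sum with BH.

## The synthetic data generator

`simulate_landscape`, `simulate_lysoip` and `simulate_spatial` stand in for
the deposited mass-spectrometry data. The model: protein baselines are drawn
Normal(`baseline_mean` = 25, `baseline_sd` = 2) in log2 (typical nDIA/TMT
log2-intensity scale); a sample value is baseline + planted shift +
Normal(0, `noise_sd`) in log2 — i.e. log-normal replicate intensities, the
standard proteomics noise assumption; entries are masked missing completely
at random at `missing_rate`. Defaults mirror the reference study's
conditions: a 24-genotype panel (23 LSD knockouts in three disease classes
plus control), two neuronal cell types, biological triplicates, ~5,000
proteins, and a 20-annotation catalog with realistic sizes and nesting
(OXPHOS ⊂ mitochondria, SynapseSV ⊂ synapse, ...). `noise_sd` defaults to
0.25 log2 units (≈ 15% linear RSD — slightly more conservative than a
well-running instrument, so recovery results are not flattered) and
`missing_rate` to 0.05.

Planted effects are per-(genotype, cell type, annotation) mean log2 shifts;
a protein in several affected annotations receives the sum; duplicate deltas
for one key are rejected as contradictory. Two generator features deserve
explanation:

* **`effect_sd`** (default 0): with `effect_sd` = 0 every member of an
  annotation shifts by exactly delta, which makes noiseless recovery exact —
  but two genotypes sharing such a constant effect have *uncorrelated*
  fold-change profiles over the annotation, because a constant carries no
  protein-level structure. Real organelle remodelling is heterogeneous
  across proteins, and that shared heterogeneity is precisely what the
  correlation landscape measures. With `effect_sd` > 0 each annotation draws
  a per-protein responsiveness profile once (shift = delta × (1 +
  N(0, `effect_sd`))), shared by every condition affected through that
  annotation. The correlation-recovery experiments use `effect_sd` = 0.5,
  at which the expected profile correlation between two genotypes sharing a
  unit effect is r ≈ δ²σ_h² / (δ²σ_h² + 2σ_noise²/n_rep) ≈ 0.86 under the
  default noise — comfortably inside the r > 0.7 link regime without being
  trivial. The realized per-annotation mean shift is recorded in the planted
  truth, so recovery is always judged against what was actually planted.
* **`disjoint`** (default FALSE): by default annotation members are sampled
  independently, so sets overlap by chance exactly as real catalogs do — and
  planted effects legitimately leak into overlapping sets. Specificity
  experiments ("no unplanted annotation is flagged") need a layout where
  leakage is impossible, so `disjoint = TRUE` carves top-level annotations
  from a random permutation without overlap.

Everything is deterministic given the seed: each draw (catalog, baselines,
effect heterogeneity, noise, missingness) runs on a sub-stream derived by a
stable hash of (purpose, seed), and the caller's RNG state is untouched.

What the generator does **not** emulate: intensity-dependent missingness,
batch effects, peptide-level variation and protein-inference ambiguity, TMT
channel interference, correlated noise between co-complex proteins, and
biological covariance beyond the planted annotation structure. Passing
recovery tests therefore demonstrates that the statistics measure what they
claim under their own model assumptions — not that those assumptions hold in
any particular real dataset.

## Validation experiments and problem sizes

The `experiment_*` family reruns the pipeline on planted ground truth; the
test suite asserts on the outputs and `scripts/acceptance.R` re-reports
them. Sizes were chosen to match the reference design where it matters and
to keep a desk-scale run:

* delta recovery: full scale (5,000 proteins × 144 samples), six planted
  effects on annotations of 300-800 proteins; worst error ~0.012 against a
  ±0.05 pass band;
* null calibration: 20 simulations of 2,000 proteins × 6 genotypes (mean
  fraction of q < 0.05 calls ≤ 0.05); p-value uniformity: 10 simulations of
  5,000 proteins, mean KS distance < 0.02;
* correlation recovery: 100 seeds, shared/opposite unit effects on a
  300-protein annotation, judged at the display thresholds r > 0.7 and
  r < −0.2;
* impact ranking: 100 seeds, 20 genotypes × 2 cell types, a 5-annotation
  group with one dominant genotype (0.8 vs 0.3 log2 units);
* RoR: 100 seeds, planted −0.75 projection depletion of 300 proteins
  (recovered mean within ±0.1, Cohen's d sign correct) plus 20 seeds of
  genotype-shared profiles (mean RoR within 3 SEM of 0);
* co-enrichment: exhaustive recomputation on a 1,000-protein LysoIP
  instance; determinism: byte-identical serialization, lossless round-trips,
  permutation-stable rankings.

## Numerical and formatting choices

Text I/O is UTF-8, tab-separated with "." decimals and unquoted
identifiers; abundance values are written with 17 significant digits so
write/read round-trips reproduce doubles exactly, and missing entries are
empty cells. Threshold rules for set membership are strict (>, <), matching
the printed "log2FC > −0.75"; the co-enrichment boundary is inclusive (≥),
matching its printed form. Euler analysis computes exact region counts only
(k ≤ 6 sets); diagram geometry is presentation. All rankings are total and
deterministic: descending score, ties by label.

## Limitations

Beyond the generator's simplifications listed above: the composite map's
orientation (conditions × annotations via mean-vs-peers) is one reading of
an ambiguous published description — the alternative (annotation ×
annotation correlation of mean-FC profiles across conditions) is noted but
not implemented; the impact score formula is this package's stated
convention, not a published equation; and fold-change contrasts assume
groups are exchangeable replicates — no batch correction is attempted.
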