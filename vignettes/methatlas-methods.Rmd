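---
title: "Methods: segmentation and comparative analysis of breast methylomes"
author: "methatlas"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`methatlas` re-implements, as a tested R workflow, the computational core
of a comparative breast-methylome study: whole-genome bisulfite sequencing
(WGBS) tracks of a normal breast, a benign tumour, invasive carcinomas and
breast cell lines are segmented into hypomethylated regions (HMRs) and
partially methylated domains (PMDs); the per-sample HMRs are merged into a
reference atlas that is clustered across samples; HMR width dynamics,
regulatory potential, methylation-expression coupling and loss of
X-chromosome inactivation (XCI) are then analysed on top of that atlas.
Because raw WGBS runs and patient data are not redistributable, the
package ships a synthetic-methylome generator that plants all of the
structure the downstream stages are designed to find, so every stage can
be validated against known truth.

The numbered scripts under `analysis/` run the stages in order on the
default simulated study; all computation lives in the package functions
they call.

# The synthetic methylome generator

`generate_genome()` builds a small stand-in genome: a few chromosomes
(one X-like), CpG positions from a piecewise-constant Poisson process
(defaults: 1 CpG/100 bp background, 10 CpG/100 bp in islands,
0.4 CpG/100 bp in gene deserts), genes whose promoters (TSS ± 1 kb) are
guaranteed at least 5 CpGs, promoter CpG islands, gene-desert blocks that
serve as PMD candidates, and planted HMR sites in the three genomic
location classes. Each site carries one of eight cluster archetypes per
class (24 in total). Planted sites are kept at least 2 kb apart so that
each is its own truth region for recovery scoring.

`generate_methylome()` turns a genome plus a sample archetype into a
per-CpG track. The planted level function is piecewise constant:
background (~0.75–0.8), PMD blocks (~0.45), and each planted site at its
archetype's target from the 24-row profile table
(`default_cluster_profiles()`). Count noise follows the simplest model
consistent with WGBS data: reads per CpG ~ Poisson(depth), methylated
reads ~ beta-binomial via a Beta(μs, (1−μ)s) draw with
s = (1−ρ)/ρ. Defaults: depth 19 (matching the ~19× design the study
archetypes assume) and ρ = 0.08. The within-HMR variance of real data
varies by platform and tissue and has no canonical value, so ρ is an
explicit free parameter, documented rather than fitted. Setting ρ = 0 and depth = ∞
gives the exact noiseless limit used by the boundary-recovery tests.

Sample archetypes encode the study design: `normal` and `benign` have
essentially no PMDs, `invasive` ~10% of the genome, `cell_line` ~30%
(recruited greedily from the desert candidates to approximate the target
fraction). XCI is modelled at X-linked promoters: ~0.5 (allelic) in
XCI-intact females, low in male-like or XCI-lost samples, while the
designated XIST stand-in gene moves in the opposite direction
(hypermethylated and silenced when XCI is lost).

`generate_expression()` draws negative-binomial counts whose expected
log2 mean decreases linearly (default slope 5 per unit methylation) with
promoter methylation for genes in the designated repressed clusters
(A-3, A-6, A-8 by default), and is independent of methylation otherwise.
`generate_paired_cohort()` plants exactly
`round(n_patients × xci_loss_fraction)` affected patients (default 36 of
78) whose tumours shift X promoters by −0.3 (noise SD 0.05), silence
XIST, and over-express a configurable subset of X genes by 1.5 log2
units. Truth labels are returned as sidecar objects and written to
sidecar files only, never embedded in the data formats.

# Segmentation

`call_hmrs()` and `call_pmds()` re-implement two-state
hidden-Markov-model segmentation in the family of the methpipe-style
callers. Design choices:

* **Emissions.** HMR calling works per CpG on (methylated reads, total
  reads) with beta-binomial emissions at fixed precision (default 10);
  PMD calling works on coverage-weighted 1 kb bin means (bins with < 3
  CpGs masked) with Gaussian emissions whose state SDs are estimated.
* **Initialisation and fitting.** EM with a deterministic histogram
  split: the low state starts at the mean of observations below the
  midpoint of the observed range, the high state above. Transitions and
  state means are re-estimated; there is no random initialisation, so
  segmentation is exactly reproducible.
* **Decoding.** Posterior (forward-backward) decoding at 0.5.
* **Gap rules.** Chromosomes are fragmented *before* decoding at CpG
  gaps over 1 kb (HMR) / 20 kb (PMD), so no emitted region can span a
  desert larger than its class limit.
* **Degenerate guards.** If the fitted state means are closer than a
  floor (0.2 for HMRs, 0.15 for PMD bins) the track is declared free of
  the low state; this keeps a uniform fully-methylated track from being
  split on noise. Emitted HMRs must additionally have mean level < 0.5,
  PMDs a mean inside (0.15, 0.7) — partially methylated, neither
  HMR-like nor fully methylated.
* **PMD post-processing.** Decoded low runs that are themselves
  PMD-like are merged across gaps ≤ 4 kb (one or two noisy bins must not
  split a megabase domain into discardable fragments), boundaries are
  polished by a per-CpG likelihood changepoint within ±8 kb (so a
  boundary can land inside a masked bin), and domains shorter than
  100 kb are discarded. `min_cpg` (4) for HMRs and `min_domain`
  (100 kb) have no single canonical value in the field and are exposed
  as parameters.

Exact numeric agreement with any particular external caller is a
non-goal; recovery of planted truth is the correctness criterion (≥ 90%
of planted HMRs at reciprocal overlap 0.8 with ≤ 5% spurious calls;
PMD boundaries within ±2 kb at 1 kb bins).

# The reference-HMR atlas

`build_atlas()` merges all per-sample HMRs (`mergeBed` semantics:
overlapping or book-ended intervals coalesce), re-scores every reference
region in every sample as the coverage-weighted mean CpG level (missing
when fewer than `min_cpg` CpGs are assessable), classifies each region
with priority promoter (overlap with TSS ± 1 kb) > intragenic >
intergenic, and clusters each class separately with Gower dissimilarity
and Ward linkage, cut at k = 8 (exposed as a parameter; eight clusters
per class matches the structure the profile table plants). Cluster
numbers are assigned by ascending mean methylation, so "A-1" is always
the most hypomethylated promoter cluster.

Missingness is handled Gower-style: entries missing in a sample are
excluded pairwise, and rows missing in more than half the samples are
dropped (with a report) before clustering. Ward runs on the precomputed
dissimilarity via the Lance–Williams update with the lowest-index tie
rule, making labels invariant to row order. All-pairs dissimilarity is
quadratic in rows; above a configurable cap (50,000 rows) the tree is
built on an evenly spaced subsample and the remaining rows join the
nearest cluster mean profile — results above the cap are an
approximation, stated prominently here.

# Width dynamics, regulatory potential, integration

`match_widths()` compares the normal-breast HMRs to another sample:
`matched_width` sums *all* overlapping other-sample HMR widths (an HMR
split into pieces has not contracted in covered bases; max-overlap would
say it had). `classify_width_change()` bins |log2 FC| at 0.19 / 1 / 3
into small / large / extreme changes; the conventional "between a ~ b"
statement of these bins is ambiguous at the edges, so the package fixes
the rule that boundary values land in the higher-|change| bin, and this rule is tested exhaustively. Zero
overlap is "lost".

`count_feature_overlaps()` counts distinct feature *sets* (not
elements) intersected; `regulatory_potential()` calls High at ≥ 4 of 8.
`top_quantile_flags()` flags scores at or above the (1−q) type-7
quantile, so all-equal scores all flag (ties at the cut are kept).
`state_enrichment()` builds the per-(cluster, state) 2×2 tables and uses
two-sided Fisher's exact tests with Benjamini–Hochberg adjustment (the
default; the method is a parameter). The two-proportion z-test uses the pooled variance.

`cohens_d()` uses the (n−1)-weighted pooled SD with the tumour − normal
sign convention (positive = hypermethylated in tumour) and magnitude
bins 0.2 / 0.5 / 0.8. `simple_de_test()` is explicitly plumbing — a
Welch t-test on log2(CPM + 0.5) with BH FDR ≤ 0.05 — standing in for a
count-model DE step that is out of scope; externally produced DE labels
can be supplied wherever a label vector is accepted. Group-comparison
t-tests default to Welch; a `student` flag switches to the
pooled-variance test. Promoter methylation deltas are computed at the
region level (weighted mean over TSS ± 1 kb) rather than per CpG and
then averaged — both are defensible; the region-level choice is fixed
here.

# XCI analysis

`x_promoter_deltas()` averages tumour − normal promoter methylation over
X-linked genes, excluding XIST (it moves in the opposite direction).
`classify_xci_status()` must turn a bimodal-looking delta distribution
into two patient populations without a canonical rule for doing so; the
package fits a
one-dimensional two-component Gaussian mixture and labels the lower-mean
component dysregulated, with a minimum component-separation floor
(default 0.1) under which *no* patient is called — this makes the null
cohort produce zero calls — and a simple threshold mode as a fallback.
The split depends only on the gaps between deltas, so it is invariant to
a common shift. `call_escapee_like()` requires the conjunction: promoter
methylation significantly lower *and* expression significantly higher in
the dysregulated group, both at p < 0.01.

# Problem sizes and numerical choices

The bundled simulation studies (`benchmark_*`) use: a 5 Mb chromosome
with ~25,000 CpGs and ~100 planted HMRs for HMR recovery; an ~11 Mb
genome with 10 planted PMDs for domain recovery; 2,400 reference HMRs
(24 archetypes × 100) over 7 samples for atlas clustering across 20
seeds; 40 seeds of a 6-methylome, 130-gene study for the
methylation-expression asymmetry; and the 78-patient cohort for XCI.
These sizes keep each study in the seconds-to-two-minutes range on one
desktop core while leaving every recovery criterion well-powered.
All randomness flows from explicit seeds; generators restore the
caller's RNG state, and repeated runs are byte-identical.

# What the synthetic data does and does not show

The generator reproduces the *structure* the pipeline assumes —
mostly-methylated background, island-anchored HMRs, megabase partial
domains, archetype cluster patterns, methylation-linked repression, an
XCI-loss subpopulation — with idealised piecewise-constant levels and a
single overdispersion parameter. It does not emulate read-mapping
artefacts, bisulfite conversion failure, copy-number effects on
coverage, cell-type mixtures within a sample, or spatially correlated
noise. Passing the recovery tests therefore demonstrates that the
implementations are correct and well-calibrated on data satisfying their
model assumptions; it does not by itself establish performance on real
tumour methylomes, where boundary sharpness and cluster separations are
less generous.

# Known limitations

* The HMR emission precision is fixed, not estimated; heavily
  overdispersed real data may need it lowered.
* Ward on Gower dissimilarities is a heuristic (Ward's criterion is
  defined for squared Euclidean distances); it is used here because it
  is the established practice for this analysis.
* The clustering cap trades exactness for tractability above 50,000
  rows.
* The DE stand-in is not a count model and should not be used for real
  differential expression.
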