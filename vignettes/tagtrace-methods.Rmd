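---
title: "tagtrace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tagtrace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The setting

`tagtrace` analyzes single-cell RNA-seq experiments on chimeric mouse kidney
in which conditional inactivation of the *Vhl* tumor suppressor is
structurally coupled to a tdTomato reporter: reporter-positive cells are
recombined (*Vhl*-null in KO animals, haplosufficient in Controls), while
reporter-negative neighbors retain the unrecombined allele. Sorted
positive/negative fractions from Control and KO animals at an early
(weeks) and a late (months) time point, from mice of both sexes, give a
2×2×2×2 design. The package implements the full inference chain for this
design — quality control, normalization, per-sex correction, clustering,
marker-module cell typing, discovery of the anticorrelated proximal-tubule
(PT) "Class A/B" gene-module pair, contrast-specific Wilcoxon differential
expression, identification of de-differentiated "PT-like" cells, preranked
gene-set enrichment, and HIF/ccRCC module scoring — plus a synthetic-data
generator that emulates the design with planted ground truth so each stage
is verified by parameter recovery rather than by eyeballing.

## Quality control

Cells are kept iff all three of the following hold, with strict
inequalities: detected genes > 200; mitochondrial read fraction < 0.5
(kidney tubular epithelium is mitochondria-rich, hence the permissive
bound); detected genes < 3× the median detected genes of the cell's
sample. The per-sample median is computed on the pre-filter cells, so the
rule set is applied jointly in a single pass; given the stored thresholds a
second pass is a no-op. Mitochondrial genes are recognized by the mouse
`mt-` symbol prefix (the synthetic data labels them explicitly); no
gene-level filtering is performed.

## Normalization, sex correction, clustering

Counts are log-normalized as `ln(1 + S·c/libsize)` with scale factor
`S = 10,000` (a config knob; the community default of the toolchain this
field uses). The top 2,000 genes by variance of log-normalized expression
(n−1 denominator, ties broken by symbol) are standardized to mean 0 / SD 1
*within each sex separately* and recombined. This per-sex standardization
removes additive and multiplicative per-gene sex offsets by construction;
it deliberately stands in for anchor-based reciprocal-PCA integration,
which is a published third-party method and not re-implemented here — the
interface accepts any externally integrated matrix in its place. PCA keeps
the top 30 components (truncated SVD via irlba, seeded; exact SVD for
small problems); an exact k-nearest-neighbor graph (k = 20, including
self) on the PCs is weighted by the Jaccard index of neighbor sets, pruned
below 1/15, and partitioned by Louvain modularity optimization at
resolution 1. k, the pruning bound, the resolution and all seeds are
config-exposed; k and the pruning bound follow common toolchain defaults,
since no principled value exists for them. The 2-D embedding (first two PCs by default,
UMAP optionally) is for visualization only — no quantitative logic reads
it.

## Cell typing by marker-module scores

A marker module is scored per cell as the mean log-normalized expression
of its genes minus the mean over expression-matched control genes: all
genes are ranked by average expression over the scored cells and split
into 100 equal-frequency bins; for each module gene, 50 control genes are
drawn without replacement from its bin (module genes excluded; if a bin
holds fewer than 50 eligible genes the whole bin is used), and the control
pool is deduplicated. Control sampling is seeded and the seed recorded, so
scores are reproducible. Module genes not detected in any scored cell are
excluded first; scoring the intersected module is provably identical. If a
module covers every detected gene, the control pool is empty and the score
falls back to the module mean minus the grand mean, flagged degenerate.
Scores are invariant to adding a constant to the whole matrix, since both
terms shift equally.

Each cell receives the type of its highest-scoring eligible module;
eligibility honors sex restriction (sex-specific S2/S3 PT modules are
scored only for cells of the matching sex). Exact ties resolve to the
lexicographically first module name and are logged. Reference markers can
also be derived from labelled cells: a marker of type T must have log2
fold change > 1.0 versus all other cells pooled, be expressed in > 50% of
T cells and in < 20% of non-T cells — all strict.

## The PT Class A/B dichotomy

Within PT cells of Control samples, the 1,200 most variable genes (sample
variance of log-normalized expression; constant genes excluded) enter a
1,200×1,200 Spearman correlation matrix (average ranks for ties; a
zero-variance gene's correlations are set to 0 and flagged). Genes are
clustered by `hclust` on distance 1 − ρ with complete linkage (R's
default; average linkage is config-exposed) and the dendrogram cut into
k = 8 clusters. Among clusters of at least 20 genes, the pair with the
most negative mean cross-correlation is selected; if no pair is negative,
the result is an explicit "no dichotomy detected". In practice such block
pairs are curated visually from the correlation heatmap; the selection is
therefore refined by a deterministic surrogate of that curation:
a gene stays in a module iff its mean correlation with the opposing
module is at least half as negative as the current pair mean, iterated to
a fixed point. Bystander genes that the dendrogram glued onto a block
dilute the pair mean at first; as they drop out the bound tightens, and
on a clean two-block matrix the refinement keeps everything. The larger
module is named A unless anchor genes are supplied (exemplar-gene
anchoring mirrors how the modules are named in practice). PT cells are
then scored for both modules (100 bins / 50 controls) and a cell is Class
A iff its Module A score exceeds 0.15 — strictly; non-PT cells are never
assigned a class.

## Differential expression and the four specificity schemes

Per gene, a two-sided Wilcoxon rank-sum test on log-normalized expression:
exact null distribution when both groups have ≤ 25 cells and no ties are
present, otherwise the normal approximation with average ranks, tie
correction and continuity correction. The fold change is
`log2((mean(expm1 x₁)+ε)/(mean(expm1 x₂)+ε))` on normalized, unscaled
expression with ε = 1e-9 (the legacy pseudocount of 1 is config-exposed,
since older toolchain versions used it). P values are Bonferroni-corrected
over the genes tested in that contrast; a gene is regulated iff
|log2FC| > 0.25 and adjusted p < 0.01, both strict. Identity-stratified
contrasts run only when each condition has strictly more than 100 cells of
that identity; skipped contrasts are logged with the group sizes, never
silent.

The four schemes are pure set logic over these tables. (1) Early
Vhl-specific: regulated in the positive-fraction KO-vs-Control contrast
and *not regulated in the same direction* in the negative-fraction
companion — a sub-threshold same-sign trend in the companion does not
exclude. (2) Time-specific: same rule for KO-positive late-vs-early
against the Control-positive companion. (3) Identity-specific: regulated
in the focal identity, in no other tested identity in the same direction,
and with |log2FC| exceeding every other identity's by strictly more than
0.2 (the same rule with Class B as the single "other" serves the Class A
scheme). (4) Cross-identity geometry: identities are embedded by PCA of
their per-gene fold-change vectors over the union of regulated genes,
centered and scaled per gene; constant columns are dropped. Replicate
concordance computes, for each KO-positive sample, fold changes of the
Vhl-specific genes against the pooled sex-matched Control-positive cells
and reports pairwise Spearman correlations.

## PT-like cells, enrichment, and scores

Clusters of the reporter-positive samples in which strictly more than 80%
of cells carry a PT type assignment are PT clusters; cells inside them
assigned a non-PT type are PT-like. The positive-sample clustering is
computed by the same preprocess path, separately from the global one.
Preranked enrichment uses the weighted Kolmogorov–Smirnov running-sum
statistic (weight exponent 1 on |statistic|) with a seeded gene-set
permutation null. Exact magnitude ties between the positive and negative
running-sum extremum resolve to the positive deviation. The permutation p
conditions on the sign of the observed score: p = (1 + #{null of matching
sign with |ES_null| ≥ |ES|}) / (1 + #{null of matching sign}). The
unconditional variant (all permutations in the denominator) is biased
toward 0.5 and fails calibration under random sets; the conditional
estimator is the standard construction and is verified uniform in the
tests. NES divides ES by the mean |null ES| of matching sign. When the
family is small an exhaustive mode enumerates every same-size set.
Bonferroni across gene sets uses the number of sets in the call as the
family. "Cycling" means a raw count of the proliferation marker (Mki67)
strictly above 0 — the weakest defensible reading of "cells expressing";
the threshold is exposed.

## The synthetic-data generator

Counts are negative binomial via gamma–Poisson: per-gene base means are
log-normal (median 0.5 counts, log-sd 1.2, capped at 30), multiplied by a
log-normal per-cell size factor (sd 0.35) and a mean-1 gamma factor with
dispersion 0.1, then Poisson-sampled. The default design is one sample per
arm of the 2×2×2×2 design at 750 cells each — 12,000 cells by 2,000 genes.
Sixteen renal cell types (three PT segments, loop-of-Henle segments, DCT,
CNT, collecting-duct principal and intercalated cells, podocytes,
endothelium, fibroblasts, two immune types, and a zero-baseline "Injured
PT" state) have distinct compositions in the negative (whole-kidney) and
positive (tubule-enriched) fractions; the focal identities are deliberately
abundant enough in the positive fraction to clear the >100-cell rule the
analysis imposes. Planted structure, all recorded as ground truth:

* **Markers.** 10 genes per type at 8× their (low) base mean, plus two
  male-only and two female-only extra markers for each of PT S2 and S3 to
  exercise the sex-restricted modules.
* **Class A/B.** Each PT cell is Class A with probability 0.5 (a Bernoulli
  latent — the dichotomy is treated as two populations, not a continuum);
  Class A cells elevate the 60 Module A genes and Class B the 60 Module B
  genes by 2^1.2, each module carrying a shared per-cell log-normal
  activity factor (log-sd 0.25) that gives within-module correlation. This
  effect size is set so class-driven elevation stays under the marker
  rule's log2FC > 1 bound and cannot leak into derived marker sets.
* **Vhl program.** 30 core genes upregulated in all recombined epithelial
  identities (center 1.5 log2, per-gene spread ±40% — a program spans a
  range of effect sizes, which is also what gives replicate fold-change
  vectors their correlatable structure), amplified a further 0.5 log2 at
  the late time point (the hypoxic program deepens with time, making the
  HIF fixture set genuinely enriched in the late-vs-early ranking);
  15-gene CDIC- and PT S3-specific programs (spread floor 0.8× — a
  "specific" gene below the Wilcoxon+Bonferroni detection floor of a
  ~130-vs-130-cell contrast could not test the set logic it is planted
  for); 25 + 25 time-up/-down genes in recombined cells.
* **PT-like state.** Each late KO-positive PT cell de-differentiates with
  probability 0.10: its segment markers' means are attenuated to 15–50% of
  their elevated level (≥ 50% attenuation), it gains a 10-gene injury
  program with per-cell log-normal intensity, elevated Mki67, and it
  *retains* its class-module program — which is what keeps these cells
  inside PT neighborhoods in expression space. The fraction is kept at
  10% because the identification rule presumes de-differentiated cells
  are a minority of their cluster; a much larger fraction flips its own
  cluster below the 80% bound and the phenomenon, as defined, ceases to
  exist.
* **Proliferation.** Mki67 mean boosted 6× in early recombined epithelium
  (a transient burst), 4× in PT-like cells.
* **Nuisance structure.** 13 mitochondrial genes sized to an 8% mean mito
  fraction with per-cell variation; 30 genes shifted 2× in males (the
  target of the per-sex correction); 2% of KO-negative cells resampled
  from the KO-positive generative process (imperfect negative sorting).

The generator is a deterministic function of its config, including the
seed. What it does **not** emulate: ambient RNA, doublets, batch/chemistry
effects, read-level artifacts, continuous differentiation trajectories,
and any correlation between programs beyond the planted ones. Passing
recovery tests therefore demonstrates that the inference chain is correct
under the stated statistical structure, not that it is robust to every
artifact of real droplet data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the default 12,000 × 2,000
simulation end to end (about 1.5 minutes on one CPU); unit tests use toy
fixtures and reduced designs (700 genes, 150–250 cells per sample). The
determinism check reruns the reduced pipeline twice and compares output
tables byte for byte. All boundary comparisons in the pipeline are strict,
matching the stated rules (QC bounds, marker rules, the 0.15 class
threshold, the 0.25/0.01 regulation thresholds, the 0.2 specificity
margin, the 80% PT-cluster bound, the >100-cell rule). Degenerate inputs
are pinned: zero-library cells normalize to zero, zero-variance genes are
excluded from variable-gene selection and zeroed in correlation matrices,
a module with no detected genes is an error naming the module, an
all-covering module falls back to a flagged grand-mean score, and "no
dichotomy" is a result, not a crash.

## Known limitations

Per-sex standardization removes per-gene sex offsets but, unlike anchor
integration, cannot align sex-specific population structure; the sex
recovery test targets exactly the planted global shift. The PT-like
identification is a cluster-level rule, so its recall
depends on how Louvain tiles the PT population — the per-condition
proportions are the stable readout. Wilcoxon DE ignores batch and
pseudo-replication; it is a cell-level test, with replicate concordance as
the complementary sample-level check.
The dichotomy search targets a single anticorrelated pair; more than two
modules would require a different selection rule.
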