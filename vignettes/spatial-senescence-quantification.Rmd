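---
title: "Quantifying spatial senescence signatures in binned skin transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial senescence signatures in binned skin transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinspace)
library(dplyr)
```

## The problem

UV stress drives skin cells toward senescence, and interventions that
replete NAD⁺ are expected to attenuate that shift. In binned spatial
transcriptomics of skin explants (Visium-HD-style data, square bins of
16 μm edge), the question "how much senescence signal is there, and where"
can be answered without cell segmentation by counting, for each gene of a
senescence/DNA-damage panel, the **gene-positive bins** — in-tissue,
QC-passing bins with detectable expression — and normalizing that count by
the tissue area to get a **positive-bin density per mm²**. This package
implements that quantification end to end, together with the bin-level QC
that precedes it, marker-based annotation of the epidermal layers, pairwise
rank-sum differential expression, and a seeded simulator of layered skin
data that makes the whole pipeline testable without access to the original
tissue sections.

## The quantification model

For a gene $g$ and a condition $c$ with sections $s = 1, \dots, S$:

* **Positivity.** A bin is positive for $g$ when its normalized expression
  is strictly greater than zero. The normalization used here (below) is
  zero-preserving, so this is exactly the bins with raw count $\ge 1$.
* **Area.** Each bin covers $(e/1000)^2$ mm² for bin edge $e$ in μm:
  0.000256 mm² at $e = 16$. The tissue area of a section is that constant
  times its number of tissue bins.
* **Pooling.** Condition-level metrics pool spatial bins across the
  condition's sections: positives and areas are summed first,
  $d_{g,c} = \sum_s n^{+}_{g,s} \big/ \sum_s A_s$. This is the bins-pooled
  estimator, not the mean of per-section densities; `pool_by_condition()`
  documents the difference and the per-section table is always available.
* **Directional consistency.** Replicate agreement between two conditions
  is summarized as the fraction of cross-section pairs whose density
  difference has the same sign as the pooled difference (`sign(0)` agrees
  only with 0). This is a constructed statistic: it formalizes the
  qualitative criterion of same-direction effects across independent
  sections with the smallest possible definition, and it is labelled as
  such wherever it is reported.

## Quality control and normalization

A bin is retained when all four hold: it overlaps tissue
(`in_tissue = 1`), it has strictly positive total counts and detected
genes, and its mitochondrial content is strictly below 15%
(`percent.mt < 15`; a bin at exactly 15.0 is removed). Mitochondrial
content is the percentage of counts from genes whose name carries the
exact, case-sensitive prefix `MT-`. Zero-total bins are given
`percent.mt = 0` rather than 0/0 and are then removed by the count rule —
same outcome, no special case. Bins whose normalized column would be
all-zero are removed once in the same pass and statistics are recomputed,
which makes `apply_qc()` idempotent.

Normalization is the depth-scaled log transform
$x \mapsto \ln(1 + 10^4 \, c / t)$ of a count $c$ in a bin with total $t$.
This is a deliberate substitution for regularized negative-binomial
(SCTransform-style) normalization and for anchor-based slide integration,
neither of which is re-implemented here. The substitution is safe for this
package's downstream metrics because positive-bin counting depends only on
the zero/non-zero pattern, which every monotone zero-preserving transform
shares — a property the test suite asserts directly by recomputing
densities under two scale factors — and because condition pooling happens
on metrics, not on embeddings. Consumers who need residual-based values
for other purposes should not read them off this transform.

## Layer annotation

Bins are annotated directly from canonical markers — TP63 (basal),
KRT10/KRTDAP (spinous), FLG (granular), COL1A1/TIMP1 (fibroblast) — rather
than through an intermediate clustering: each marker gene is z-scaled
across the bins of its section (zero-variance genes contribute 0), a
label's score is the mean z-score of its genes, and a bin takes the
argmax label when that maximum is strictly positive and unique, otherwise
`unassigned`. Annotating without clustering avoids inventing a clustering
algorithm and resolution where none is specified, and produces the same
deliverable (a per-bin layer label). Spatial position is deliberately not
an input to assignment; depth concordance can be inspected post hoc from
the annotated bin table, which retains array coordinates. `unassigned` is
an explicit fifth class, not an error: with dropout there are always bins
carrying no marker signal at all, and silently forcing them into a layer
would bias composition summaries.

## Differential expression

`find_markers()` compares two bin groups per gene with the two-sided
Wilcoxon rank-sum test on normalized values — exact enumeration when the
pooled sample is ≤ 10 and tie-free, otherwise the tie-corrected normal
approximation with continuity correction. Genes are tested when detected
in at least 1% of either group (`min_pct = 0.01`) with no fold-change
cutoff (`logfc_threshold = 0`), both directions kept; `MT-` genes are
excluded before testing. The log2 fold change is
`log2((mean(expm1(x₁)) + ε) / (mean(expm1(x₂)) + ε))` with ε = 1e-9, the
common single-cell convention. Adjustment is Benjamini–Hochberg over the
tested genes by default: the FDR interpretation matches how gene-level
screens of this kind are read, and Bonferroni is available via
`p_adjust = "bonferroni"` for users who want the family-wise convention of
the common upstream tooling.

## What the simulator emulates — and what it does not

`generate_dataset()` draws one dataset per condition × section from a
single seeded RNG stream. Its defaults define the reference study
conditions used throughout the tests:

* **Geometry.** A 64 × 64 bin grid (4,096 bins per section; large enough
  for stable rank-sum behavior) cut into horizontal bands: background 20%
  of rows, then granular 8%, spinous 16%, basal 16%, dermis 40% — i.e.
  tissue fractions GC 0.10 / SC 0.20 / BC 0.20 / FB 0.50, a plausible
  dermis-dominated section profile. Horizontal bands are the simplest
  geometry that preserves epidermal stratification order.
* **Counts.** Negative binomial with size θ = 2 (moderate overdispersion,
  typical of binned spatial counts) around a mean that multiplies a
  layer-specific per-gene baseline, the condition fold, a mean-one
  log-normal per-bin depth factor (σ = 0.3), and a per-section depth
  scalar (1.0, 0.85) that stands in for technical-replicate variation —
  one scalar per section is the smallest model that exercises the
  cross-section consistency logic.
* **Panel.** Six layer markers at mean 10 counts/bin in their own layer
  versus 0.05 elsewhere. Ten means roughly a tenth of a bin's counts,
  matching the dominance of defining transcripts like COL1A1 or KRT10 in
  their layers, and keeps within-layer marker dropout near 3–4%: the
  generator is required to produce *strongly expressed, disjoint* markers,
  and a weaker setting would contradict that contract rather than test
  annotation. Ten senescence genes at baselines 0.1–1.0 counts/bin
  (CDKN1A at 0.2), multiplied by `uv_fold = 4` under UV and
  `icon_fold = 1.5` under treatment, in all tissue layers. Thirteen `MT-`
  genes calibrated to 5% of counts, with 10% of bins spiked 6-fold so QC
  has something to remove. 171 filler genes on a fixed log-spaced ladder
  of means (0.05–2) — deterministic by construction, so the panel does not
  consume RNG state.

The simulator does **not** emulate: spatial autocorrelation beyond the
band structure (bins are conditionally independent), cell-type mixtures
within a bin, probe-set artifacts, slide-level batch effects richer than a
depth scalar, segmentation errors in the tissue mask, or condition-driven
changes in tissue composition. Passing tests therefore demonstrate that
the pipeline's logic is correct under a faithful count model — not that
the biological effect sizes in real UV-stressed skin equal the defaults,
which no public dataset for this design pins down.

## Numerical choices and degenerate inputs

* Exact ties in marker scores give `unassigned`; no random tie-breaking
  anywhere, which keeps every stage deterministic.
* Zero-variance marker genes contribute 0 to scores (neutral), not NaN.
* `percent.mt` of an empty bin is 0 by convention; the bin is removed
  anyway.
* The rank-sum exactness cutoff (pooled n ≤ 10, tie-free) keeps full
  enumeration at ≤ 252 combinations — negligible cost, and it doubles as
  an internal oracle for the approximation.
* The logistic lifespan fit starts from `K₀ = 1.05 × max(count)`, `t₀` at
  the half-maximum time, and a logit-linearized slope for `r`, then
  refines by Levenberg–Marquardt, which converges cleanly even on
  zero-residual (noiseless) curves; `t95 = t₀ + ln(19)/r` is closed-form.
  Non-convergence is an error, never a silent default.
* Mitochondrial morphology boundaries: < 3 μm fragmented, ≥ 8 μm
  elongated; 3 μm itself falls to intermediate (the closed lower bound is
  the only free choice given the printed outer thresholds).
* The olive tail moment is computed as tail-DNA % *divided by* tail moment
  length. The conventional definition multiplies the tail fraction by the
  tail-centroid distance; the ratio form is retained deliberately to match
  the upstream quantification this package accompanies, and the
  documentation of `olive_tail_moment()` flags the discrepancy instead of
  silently correcting it.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `bin_edge_um` | 16 | μm | binned resolution; sets the 0.000256 mm² bin area |
| `max_percent_mt_exclusive` | 15 | % | QC ceiling on mitochondrial content, strict |
| `scale_factor` | 10⁴ | — | depth scaling before log1p; densities are invariant to it |
| `min_pct` | 0.01 | fraction | detection filter for DE testing |
| `uv_fold` / `icon_fold` | 4 / 1.5 | fold | senescence induction under UV / treatment |
| `area_population` | `qc_passed` | — | area denominator population (see below) |

The area denominator defaults to the QC-passing bins so numerator and
denominator describe the same population; `area_population = "in_tissue"`
switches to the pre-QC tissue mask for users who read "tissue area" as the
mask area. Both are computed from the same per-section table, so the
choice is auditable.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(sim_config(seed = 1), out_dir = tempfile("skinspace_run"))

res$density |> filter(gene == "CDKN1A")
res$consistency$icon_vs_ctrl
res$de$icon_vs_ctrl |> slice_head(n = 5)
plot_density_bars(res$density)
```

The run writes a QC audit, the annotated bin table, composition and
density tables, consistency tables for both condition contrasts, the two
DE tables, and a manifest (seed, config hash, stage tallies — no
timestamps), so rerunning with the same config reproduces every output
byte for byte.

## Known limitations

* The normalized values are a monotone transform of within-bin
  proportions, not variance-stabilized residuals; analyses that depend on
  residual magnitudes (not the zero pattern or ranks) need a different
  transform.
* Technical-replicate sections are treated as exchangeable; with only two
  sections per condition the consistency statistic takes coarse values
  (0, ¼, ½, ¾, 1).
* Annotation assumes the marker panel is discriminative in the data at
  hand; in tissues where a marker is broadly expressed, scores should be
  inspected (`marker_scores()`) before trusting composition summaries.
* DE p-values treat bins as independent sampling units, as rank-sum DE on
  spatial bins conventionally does; spatial autocorrelation in real
  tissue makes them anti-conservative to an unknown degree.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the simulator at its
default 64 × 64 grid (six sections, ≈ 24.6k bins, 200 genes) for the
recovery checks, ten replicate seeds for null calibration, and five for
effect-direction and annotation recovery — sizes at which the pooled
metrics are stable to well under the tolerances being asserted.
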