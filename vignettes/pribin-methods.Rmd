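---
title: "Bin-based pattern analysis of cytometry data: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based pattern analysis of cytometry data: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Most high-dimensional cytometry analysis clusters cells and compares
cluster frequencies. That works well when subpopulations are phenotypically
crisp, and poorly when they are similar or overlapping. The approach
implemented here — pattern recognition of immune cells (PRI) — takes a
different route: it keeps two markers as interpretable axes, cuts the x–y
plane into many small fixed-size "mini-gates" (bins), and summarizes a
third marker z inside every bin. The result is a semi-continuous,
reproducible picture of three-marker combinatorics: a heat map in which
each bin is colored by a statistic of z, plus scalar per-sample features
read off the same grids that can be compared between groups with ordinary
non-parametric tests.

Concretely, for a sample of \(n\) cells with transformed intensities
\(x_e, y_e, z_e\):

* each event is assigned to bin
  \((i, j) = (\lfloor x_e / w \rfloor, \lfloor y_e / w \rfloor)\) with bin
  width \(w\) (default 0.2 asinh units);
* per bin, the package records the cell count, the **MSI** (mean of \(z\)
  over all cells in the bin), and — given a positivity threshold \(t_z\) —
  the z⁺ count, the **MSI⁺** (mean of \(z\) over cells with
  \(z \ge t_z\)), and the z⁺ frequency;
* per quadrant of the plane (split at analyst-set thresholds \(t_x, t_y\)),
  it records the percentage of all cells (the black numbers on plots) and
  the percentage of the quadrant's cells that are z⁺ (the red numbers);
* per sample, it extracts features: the maximum and minimum bin-MSI over
  displayed bins (threshold-independent — exactly the endpoints of a
  dynamic color legend) and the eight quadrant percentages
  (threshold-dependent).

Two-group comparisons of these features use the two-sided Mann–Whitney U
test on per-sample values, with group medians reported.

## Transforms and conventions

**arcsinh cofactor.** Intensities are transformed as
\(\operatorname{asinh}(c \cdot x)\) with cofactor \(c = 0.1\) by default,
i.e. the linear-to-logarithmic transition sits near \(1/c = 10\) raw
counts, appropriate for mass cytometry's dim-signal regime. The phrase
"cofactor" is used both ways in the field; the alternative convention
\(\operatorname{asinh}(x / c)\) is available via
`transform_spec(direction = "divide")`. A table can be transformed exactly
once; the flag travels with the object so double transformation is a
caught state error.

**Bin grid anchor.** The grid is anchored at 0 in transformed space
(`floor(v / w)`), not at the data minimum. This makes bin indices
reproducible across samples and runs without any data-dependent origin,
at the cost of bins not being centered on the data range — irrelevant for
statistics that are computed per bin. Negative indices simply occur for
negative asinh values.

**Ties on thresholds.** Events exactly on a quadrant or positivity
threshold count as high/positive (closed comparison, \(\ge\)). Any fixed
convention works; this one makes `z_threshold = -Inf` degenerate cleanly
(MSI⁺ ≡ MSI, all red percentages 100%), which the test suite exploits.

**The five-cell display rule.** All events always enter the stored grid;
bins with fewer than `min_cells_per_bin = 5` cells are merely flagged
`displayed = FALSE`. Display and feature extraction respect the flag; the
data never do. For MSI⁺ plots a second flag (`displayed_pos`) marks bins
with at least five z⁺ cells; displayed bins below that are drawn gray
rather than dropped, so the viewer can distinguish "few z⁺ cells" from "no
cells". The per-sample intensity features (`max_bin_msi`,
`bin_msi_range`) are taken over displayed bins only, i.e. they equal the
dynamic color-scale endpoints a reader sees on the plot legend. Taking
them over all bins instead would let a single 1-cell bin dominate the
feature; the display-rule semantics is both more robust and consistent
with what the visualization shows.

**Quadrant layout.** Q1 = low-x/low-y, Q2 = low-x/high-y, Q3 =
high-x/high-y, Q4 = high-x/low-y. The literature rarely defines this
layout explicitly, so it is a documented convention here; all quadrant
statistics name their quadrant, and the mapping is trivial to permute
downstream if a different house style is needed.

**Color scale.** Piecewise-linear interpolation through blue → yellow →
red with 50 quantization levels, values clamped to the scale. *Dynamic*
scaling uses one grid's displayed-bin extrema (best for pattern discovery
within a sample); *common* scaling pools extrema over a panel of grids
(required for visual comparison between samples — equal values render as
equal colors). A degenerate scale (`v_min == v_max`, e.g. a single
displayed bin) maps everything to the palette midpoint rather than
dividing by zero. Quadrant percentages are printed with one decimal,
rounding half away from zero.

## Statistics

The Mann–Whitney U statistic is computed from midranks. For untied data
with \(n_a + n_b \le 20\) the two-sided p-value is exact (the full
permutation distribution via `stats::pwilcox`); `mode = "exact"` on tied
data enumerates all \(\binom{n_a+n_b}{n_a}\) labelings explicitly;
otherwise the normal approximation with tie correction *and* continuity
correction is used — the continuity correction is a deliberate,
documented choice (it is what mainstream implementations default to, and
it is conservative at the cohort sizes this tool targets). A feature that
is constant across all samples has zero rank variance and is reported as
p = 1. Star codes follow the conventional thresholds (\*, \*\*, \*\*\*,
\*\*\*\* at 0.05, 0.01, 0.001, 0.0001).

Unadjusted p-values are the primary output: the method's convention is one
test per engineered feature with the feature count visible to the reader.
Because that convention invites multiplicity concerns, `compare_groups()`
additionally emits a Benjamini–Hochberg column (`p_adj`) clearly labeled
as an extension; it never alters the primary values.

## Quality control

Sample-level QC works on **median expression profiles** (exact per-marker
medians of the transformed intensities; midpoint of the central order
statistics for even counts). Two views are provided: classical (Torgerson)
**MDS** of the pairwise Euclidean distances between profiles, and **Ward
hierarchical clustering** of the same distances (`ward.D2`, the variant
that applies Ward's variance criterion to the distances themselves).

The **non-redundancy score** ranks markers by unique information content:
per sample, PCA of the centered cell-by-marker matrix, then
\(\mathrm{NRS}(m) = \sum_{k=1}^{K} \lambda_k \, |v_{mk}|\) over the top
\(K = 3\) components (\(\lambda_k\) eigenvalues, \(v\) loadings), averaged
across samples and ranked. \(K\) is configurable because published
variants differ; 3 components is the common choice for ~40-marker mass
cytometry panels. NRS is intentionally not scale-invariant — it must see
transformed data, which is why the package refuses untransformed tables
upstream.

Exclusion is advisory by design. `qc_report()` flags samples below a cell
count threshold (default 1000) or whose MDS position sits farther from the
group centroid than 3× the median within-group centroid distance; the
pipeline drops flagged samples only when `qc: exclude_flagged: true` is
set, and warns loudly otherwise. Automated silent exclusion is exactly the
kind of irreproducibility this tool exists to avoid.

## The synthetic cohort generator

The generator exists so every claim the package makes can be tested end to
end without any external download. It models a CD4⁺ T-helper sample as a
Gaussian mixture **in asinh space** with diagonal covariance: four
populations (naive 45%, memory 35%, activated 15%, regulatory 5%) over a
9-marker panel (CD90, CD44, CD86, CD27, Ki67, Tbet, Foxp3, KLRG1, PDL1),
means between 0.4 and 3.4 asinh units and common standard deviation 0.35 —
values a practitioner would recognize for asinh(0.1·x)-transformed mass
cytometry data. The default cohort is 6 vs 6 samples of 50,000 events.
The effective-treatment group shifts the activated (CD44⁺CD90-high)
population by +0.8 asinh in CD86 and +0.5 in Ki67; every other marker is
group-null, providing known positives and known negatives. Each event
carries its population index as a truth channel, so any downstream
statistic can be verified per population. Sample-level seeds derive
deterministically from (seed, group, index): generation is reproducible
event for event, and cohort FCS files are written raw-scale
(`sinh(v)/cofactor`) so the standard read → transform → gate → bin
pipeline runs on them unmodified.

What the generator does **not** emulate: marker–marker correlation within
populations (diagonal covariance; full covariance could be added without
interface changes), instrument artifacts (spillover, bead drift,
doublets), zero-inflation of mass cytometry counts, and batch effects.
Passing tests on synthetic cohorts therefore demonstrate correctness of
the computations and sensitivity to planted mean shifts of the stated
size — not robustness to every pathology of real acquisitions.

## Validation strategy and problem sizes

The test suite checks every statistic against an independent
re-derivation: per-event loop oracles for bin and quadrant statistics
(102 random tables up to 10⁴ events, exact or 1e-9 relative), full
enumeration for exact Mann–Whitney p (all group-size pairs with
\(n_a+n_b \le 12\)), brute-force Lance–Williams agglomeration for Ward,
double-centering eigendecomposition for MDS, covariance
eigendecomposition for NRS, and conservation laws (bin counts sum to the
event count; black percentages sum to 100) on every fixture. The planted
+0.8 asinh CD86 shift is recovered with p ≤ 0.05 by the
CD90/CD44/CD86 max-bin-MSI feature across 20 replicate cohorts while the
untouched CD27 feature stays null; `scripts/acceptance.R` recomputes this
study from scratch. Pipeline determinism is asserted byte for byte on the
CSV outputs of repeated runs.

## Known limitations

* Gates are axis-aligned rectangles; polygon gates (common in manual
  workflows) are out of scope, and gating thresholds are always
  analyst-supplied — the package ships a CD4 gating template with
  placeholder thresholds, not magic numbers.
* The FCS writer emits list-mode float32 FCS 3.1 only; the reader handles
  FCS 3.0/3.1 with datatypes F, D and uniform-width I, which covers modern
  exports but not legacy integer files with mixed bit widths.
* Binning is limited to two axes by design; higher-order combinatorics are
  expressed through side-by-side z panels and two-z co-expression
  statistics, not >2-dimensional grids.
* Quadrant and positivity thresholds are manual. That is a feature of the
  method (interpretability), but it means threshold-dependent features
  inherit the analyst's choices; the threshold-independent max-bin-MSI
  features exist precisely to complement them.
* With few cells per sample, few bins pass the five-cell rule and the
  bin-level features become noisy; the method is intended for samples of
  at least a few thousand cells in the gated population.
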