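---
title: "Methods: networked self-organising maps for health-system KPIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: networked self-organising maps for health-system KPIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnet)
```

## The data model

`somnet` analyses a *minimum metadata set* (MMS): one row per small
catchment area, 64 KPIs grouped into three input datasets — service
availability (`A1`–`A12`, clinical teams per 100,000 inhabitants),
placement capacity (`P1`–`P13`, beds and places per 100,000) and
workforce capacity (`W1`–`W33`, full-time equivalents per 100,000) — and
one output dataset, resource utilisation (`U1`–`U6`; discharges, treated
prevalence/incidence and visit frequency per 1,000 inhabitants, length
of stay in days, re-admissions per 100 discharges). The bundled
three-region registry covers Catalonia (74 areas), Biscay (19) and
Gipuzkoa (13); their printed populations sum to about 9.4 million.
Structural validation treats the workforce identity
`W3 >= W1 + W2` as a warning, not an error, because the "other
professionals" term of the total is non-negative but unrecorded.

Each dataset is min–max normalized per indicator before mapping.
Degenerate (constant) indicators normalize to 0.5, are flagged, and are
excluded from all distance computations: this avoids a divide-by-zero
while keeping column alignment, and a constant column carries no
similarity information anyway. Denormalization is the exact inverse for
non-degenerate indicators (round-trip identity within 1e-9 is a tested
property).

## Self-organising maps

One SOM per dataset, on a pointy-top hexagonal offset grid whose
nearest-neighbour planar distance is exactly 1. Training is **batch**
Kohonen learning rather than online updating: the batch rule is
independent of sample order, which makes runs exactly reproducible from
the seed and parameters — a requirement for a decision-support tool whose
outputs are reviewed by domain experts.

Parameters and defaults:

* **Grid size** (`grid = NULL`, automatic): about `5 * sqrt(n)` neurons;
  the rows:cols aspect follows the square root of the ratio of the two
  leading data-covariance eigenvalues (capped at 4), the usual linear
  heuristic for matching the map shape to the data's principal plane.
* **Epochs** (30): batch training on these problem sizes (~100 areas,
  6–33 indicators) converges well before this.
* **Neighbourhood radius**: Gaussian, shrinking linearly from a third of
  the grid diameter to 0.5. A final radius of 0 degenerates to the
  k-means update; on tiny maps this fixed point is tested against
  `stats::kmeans`.
* **Initialization** (`"pca"`): the codebook spans the data's first two
  principal axes (deterministic, with a fixed eigenvector sign
  convention); `"random"` initialization is available behind the seed.

Missing entries are handled by **masked distance**: squared differences
are summed over observed dimensions only, and the batch update
accumulates only observed values. With no missing data this reduces
exactly to Euclidean distance (tested). Values are never imputed.

BMU ties break to the lowest neuron index. Quality is summarized by the
quantization error (mean masked distance to the BMU) and topographic
error (fraction of areas whose two best units are not grid neighbours;
neighbourhood is planar distance 1 with a 1e-4 tolerance).

Neurons with two or more assigned areas are reported as *unit clusters*
of closely similar areas; cluster region purity against planted ground
truth is part of the acceptance suite.

## Networking maps and conditional queries

The association between an input map and the output map is learned from
the shared areas by kernel-smoothed BMU co-activation:
`M[j,k] = Σ_a h_in(j, BMU_in(a)) · h_out(k, BMU_out(a))`, with `h` a
Gaussian kernel over grid distance (radius 1 grid unit by default;
radius 0 gives hard co-occurrence counts). Rows with support are
normalized to sum to one. This is the minimal construction consistent
with weight association over shared samples; the kernel smoothing
spreads each area's evidence over the topological neighbourhood of its
BMU, which stabilizes small maps. It is a documented package convention
rather than a uniquely determined formula.

A query proceeds as activation → propagation → region selection →
estimation:

* **Activation** (`sigma = 0.1` on the normalized scale): per
  constraint, a Gaussian kernel compares the constraint value to the
  codebook column; joint constraints multiply (independent-evidence
  reading of joint conditioning). 0.1 of the normalized range is narrow
  enough to discriminate category levels (which are 0.2 wide) and broad
  enough to keep several neurons active.
* **Propagation**: input-driven fields are `activation %*% M`,
  output-driven fields use the transpose; fields are max-normalized.
  Propagation with no support raises an error rather than returning an
  all-zero field.
* **Region selection** (`q = 0.8`): the mask keeps neurons at or above
  the `q`-quantile of the field weights (ties included, never empty).
  The most-weighted region stands in for the visual "reddish region"
  selection an analyst would make; the quantile is configurable because
  that choice is inherently judgemental.
* **Estimation**: weight-averaged denormalized codebook values over the
  masked region, rather than the argmax neuron — averaging stabilizes
  small-grid behaviour and is the package's convention. Multi-dataset
  input-driven constraints combine their propagated fields
  multiplicatively before selection.

## Categorization

Indicator values are qualitatively categorized on their observed
`[min, max]` range divided into five 20% levels: `low`, `low-medium`,
`medium`, `medium-high`, `high`. Intervals are left-closed/right-open
with the top interval closed; this convention reproduces every published
value/range/label combination in the package's regression suite,
including near-boundary cases (2.59 on [0.41, 5.88] falls just below the
2.598 boundary and is low-medium, while 2.75 is medium). Only three of
the five level names appear in the published table; the remaining two
follow the same naming pattern. Out-of-range values clamp to the end
labels because winsorization and region-averaged estimation can nudge a
value slightly past the observed bounds. Boundaries are computed as
`min + (max − min) · k/5` to keep them exact for decimal ranges.

## Outlier processing

Candidate outliers are flagged per indicator by the robust score
`(x − median) / (1.4826 · MAD)` with a default threshold of 3.5; the
published analysis identified outliers visually, and a reproducible
numeric proxy is required for a scriptable tool. Indicators with zero
MAD are skipped with a note. The decision *which* flagged areas to drop
versus adjust encodes expert knowledge about connectivity with the rest
of the system, so it enters as explicit policy configuration; the
bundled preset drops C63, C64, C74 and B19 and winsorizes U3 for C17,
C25 and C35, leaving 102 of 106 areas. (The source material names the
kept areas inconsistently — C35 in one place, C37 in another; the preset
uses C35.) Winsorization replaces the value by the 97.5th percentile —
linear interpolation between order statistics, i.e. `quantile(type = 7)`
— of the indicator over all non-dropped, non-winsorized areas, the only
reading of "97.5th percentile of the highest value from the other
areas" that yields a well-defined number. Dropped areas are removed from
all four datasets to keep them row-aligned. After outlier processing the
pipeline retrains **all four** maps, reading "newly formed datasets" as
a full retraining rather than selective updates.

## The synthetic generator

No public deposit of the regional health-database extracts exists, so
the package ships a generator that emulates the *structure* the method
needs to demonstrate, with full ground truth:

* three regions of 74/19/13 areas; Biscay and Gipuzkoa tight
  (within-cluster log-sd 0.07) and mutually separated by opposite ±0.35
  log-offsets on every indicator; Catalonia dispersed over five
  sub-cluster centers with evenly spaced log-offsets (±0.45) shared
  across indicators — a small-to-large resource gradient — plus
  within-cluster log-sd 0.10;
* lognormal input marginals (rates are positive and right-skewed), with
  per-indicator base medians on magnitudes comparable to published
  acute-care ranges;
* outputs `U = D · inputs + noise` with a sparse non-negative dependency
  matrix `D` (every output loads positively on `W1`, making input-driven
  monotonicity a planted, testable property) and Gaussian noise of 10%
  of each output's typical magnitude, clipped at zero;
* `W3` rebuilt as `W1 + W2 + other` with a proportional other-staff
  contingent, so the workforce consistency rule holds by construction;
* planted outliers applied last, multiplicatively (×10), so ground truth
  is unambiguous: three Catalonia areas extreme on availability
  indicators and one Biscay area extreme on `U4`/`U5`/`U6`.

Two structural choices deserve a note. Sub-cluster centers are *bounded
and evenly spaced* (not independently drawn per indicator): independent
heavy-tailed center draws can collapse an indicator's pooled median
absolute deviation or create spurious extreme values in linear
combinations of indicators, which would confound planted-outlier
recovery; a bounded common gradient keeps the dispersed region's spread
realistic and non-degenerate under every linear combination. Similarly,
the two tight regions take opposite nonzero offsets on every indicator
so that no indicator's pooled spread collapses onto a single tight
cluster.

What passing tests on this generator do **not** show: the generator
makes no attempt to match real regional KPI magnitudes beyond published
ranges, contains no spatial autocorrelation, no longitudinal structure,
and its input–output dependency is linear by construction. Recovery
results demonstrate the machinery is correct, not that real systems are
this well behaved.

## Determinism and numerical conventions

* One global seed drives everything; the pipeline derives per-stage
  seeds by hashing the stage name into the global seed (so stages can be
  re-run in isolation), and all artifacts — SOM JSON, report JSON, SVG
  figures — are byte-identical across reruns of the same configuration.
* SVG output is written directly with fixed three-decimal coordinate
  formatting and no timestamps; hexagons are pointy-top in offset
  layout, and every rendering embeds neuron indices so planes, label
  maps, glyphs and weight fields align visually.
* Region-selection quantile thresholds use a 1e-8 relative tolerance so
  ties at the threshold are included despite floating-point
  interpolation.
* Degenerate cases error early with diagnostics: empty tables,
  all-missing rows or vectors, empty constraint sets, all-zero
  propagated fields, empty region masks.

## Problem sizes in the test and acceptance suites

The shipped suites train maps of roughly 50–60 neurons on 102–106 areas
for 30 epochs, use 10 seeded synthetic systems for the
parameter-recovery properties (outlier recovery at robust-z threshold 5,
unit-cluster purity, Spearman monotonicity of input-driven estimates
over 5 probe values, category-level round-trip agreement), grids up to
4×4 for brute-force oracle equivalence, and 300 areas per region for
mean-recovery checks. These sizes were chosen to exercise the method at
the bundled system's scale while keeping the full suite fast enough for
routine development runs.

## Known limitations

* Published headline estimates from the original regional analysis
  depend on undeposited data and are not reproduction targets; the
  package reproduces the workflow and the exactly checkable
  categorization surface.
* The association construction is a documented interpretation of weight
  association over shared samples, not a restatement of a published
  formula.
* No U-matrix clustering, growing/hierarchical map variants,
  probabilistic calibration of estimates, spatial-connectivity
  modelling, or interactive visual analytics; selection of the weighted
  region is by quantile (or explicit policy), and figures are static
  SVG.
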