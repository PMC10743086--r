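---
title: "Methods: four-population MDR scoring, dose-response and induction calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-population MDR scoring, dose-response and induction calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrhcs)
```

## The assay

Mixed cultures from resected non-small-cell lung tumors contain carcinoma
cells and stromal fibroblasts. The assay images each 384-well plate well in
three fluorescence channels — a nuclear DNA stain (Hoechst 33342), the
epithelial marker CK8/18, and one ABC-transporter MDR marker (ABCB1, ABCC1
or ABCG2) — and cross-classifies every cell into four populations:
cancer/stromal x marker-positive/negative. From the per-well population
counts the pipeline derives two endpoints:

* **cytotoxicity**: per-population viability relative to vehicle controls,
  summarized as a four-parameter logistic IC50 per culture x drug x
  population;
* **marker induction**: the within-population marker-positive percentage per
  concentration, gated into an increase / no-change call.

Every segmented cell counts as Hoechst-positive; there is no second nuclear
intensity gate beyond the segmentation threshold.

## Segmentation

`segment_nuclei()` applies, in order: a global threshold on the nuclear
channel (a fixed intensity, or a between-class-variance optimum computed by
`auto_threshold()`); hole filling; optional splitting of touching objects by
watershed on the distance transform; and a width gate keeping components
whose *equivalent diameter* (diameter of the equal-area circle, a
rotation-invariant reading of "width") lies in
`[nucleus_min_width, nucleus_max_width]`.

Choices worth knowing:

* `auto_threshold()` evaluates the between-class variance exactly over the
  distinct intensity levels (binned to 4096 levels only for near-continuous
  data) and returns the midpoint of the best adjacent pair, so it commutes
  exactly with constant offsets and is fully deterministic (lowest maximizer
  on ties).
* Border-touching nuclei are dropped: their intensity statistics are
  truncated by the field edge.
* Fully overlapped nuclei are not resolved; they produce a single label.
  This mirrors the known failure mode of threshold-based nuclear
  segmentation and is visible in the simulator-based recall figures.
* Width defaults (6–25 µm nucleus, 40 µm cell, at 1.7 µm/px) are
  assay-calibration parameters tuned to the bundled simulator's geometry;
  real assays should calibrate them to their own staining, as the vendor
  workflow does.

`assign_cell_regions()` grows each nucleus into its cell region by
nearest-nucleus geodesic propagation in the 8-connected (Chebyshev) metric:
all regions advance one ring per step, contested pixels go to the
lowest-numbered adjacent region (a deterministic tie-break at the
equidistant boundary), and a region skips any ring that would push its
equivalent diameter above `cell_max_width`. Ring-atomic capping makes an
isolated nucleus an exact Chebyshev dilation of itself, which is what the
test oracles check; regions are disjoint by construction and always contain
their nucleus.

## Cell scoring

Positivity is decided on the **mean cytoplasmic intensity**: the average of
a channel over the cell region excluding the nucleus (cells with no
cytoplasmic pixels fall back to the whole region; an integrated-intensity
variant is available via `intensity_stat = "integrated"` because the vendor
statistic is not documented). A cell is positive when its statistic is
greater than or equal to the channel threshold — ties score positive,
deterministically.

Thresholds may be given as absolute intensities or resolved automatically.
Automatic resolution applies `auto_threshold()` to the distribution of
per-cell statistics, which presumes both positive and negative cells are
present in the scored set; `analyze_plate()` therefore pools statistics
across the whole plate before resolving, so single-class wells (e.g. a pure
stromal culture's epithelial channel) are gated by the plate-wide mixture
rather than split artificially.

The induction statistic is the marker-positive percentage **within** the
CK8/18-defined population (not of the well total), because induction is a
per-compartment question; percentages are flagged undefined (`NA`) when the
population denominator is zero.

## Dose-response

Viability of a treated well is `100 * count / mean(control counts)` for the
same population and culture. Each series with at least four distinct
concentrations is fitted with the 4PL on log10 dose by Levenberg–Marquardt,
with `bottom >= 0`, `top <= 120`, `h > 0`, initialized from the data
(top = max response, bottom = min, midpoint = dose nearest 50%, h = 1).
Replicates enter as individual points rather than means, preserving the
error structure for diagnostics.

The reported IC50 is the concentration where the *fitted curve crosses 50%
of control* (not the 4PL midpoint parameter, which differs whenever
`bottom > 0` or `top < 100`). Reporting rules:

* crossing above the highest tested dose, or no crossing in range with the
  curve above 50% — right-censored, rendered `">cmax"`;
* curve below 50% over the whole range — flagged `below_range` with the
  value pinned at the lowest dose (the design only defines right-censoring;
  such panels need lower doses, and the flag says so);
* curve flat at 50% — flagged `degenerate` (IC50 unidentifiable).

Fold-resistance divides a resistant IC50 by the parental one; a censored
numerator yields a `"> bound"` lower bound, a censored denominator is an
error (the ratio is undefined). Selectivity between two populations flags
the more sensitive member only when the other's IC50 or censoring bound is
strictly greater; two results censored at the same bound are
indistinguishable.

## Dunnett-gated induction calls

Each culture x drug x population x marker series is one family: every
treated concentration is compared with the concentration-0 control by a
pooled-variance t statistic, and family-wise two-sided adjustment uses the
multivariate t with the exact correlation
$\rho_{ij} = \lambda_i\lambda_j$, $\lambda_i = \sqrt{n_i/(n_i+n_0)}$
(0.5 at equal n). The family is per-series because that is the unit at which
the per-concentration comparisons are starred in this assay's figures; no
additional correction is applied across drugs or markers.

The multivariate-t probability $P(\max_j |T_j| \le t)$ is evaluated by
conditioning on the shared control variate $Z_0$ and the pooled scale $S$,
reducing the k-dimensional integral to a product of normal probabilities
under a deterministic 64 x 64 Gauss–Hermite x Gauss–Legendre grid (the
scale axis is integrated on equiprobable chi quantiles). The quadrature
agrees with adaptive quasi-Monte-Carlo references to ~1e-6, is exactly
reproducible, and collapses to `2 * pt(-|t|, df)` at k = 1. Zero pooled
variance is degenerate: p is 0 or 1 by the sign of the mean difference, and
the row is flagged.

A series is called an **increase** when at least one concentration is both
significant (adjusted p < `alpha`, default 0.05) and relevant: the
marker-positive percentage rises by at least `induction_threshold` over the
control mean. The threshold is interpreted as a *relative* 20% by default —
"an increase of at least 20%" read as proportional change of the plotted
percentage — with an absolute-percentage-points alternative
(`induction_metric = "absolute_points"`) because the phrasing is genuinely
ambiguous; a zero control mean forces the absolute metric. Decreases never
produce an increase call.

## The simulator

`simulate_well()` generates the assay's statistical structure with complete
ground truth:

* surviving count ~ Poisson with mean
  $n \cdot 1/(1+(c/\mathrm{IC50_{kill}})^h)$, per population;
* marker positivity among survivors ~ Bernoulli with
  $p(c) = p_0 + (p_{max}-p_0)\,c^h/(c^h+\mathrm{EC50}^h)$. The assay
  observes only the net positive fraction — it cannot separate induction in
  surviving cells from selective survival of positive cells — so the
  simulator models $p(c)$ as that net observable;
* nucleus centres from a hard-core process (minimum spacing 0.8 x the mean
  nuclear diameter), with a field margin of one cell radius so no truth
  cell touches the border (the scorer excludes border-touchers, and without
  the margin truth-based recall would be structurally biased);
* rendering as flat disks (nucleus) and cytoplasmic annuli (epithelial
  channel for cancer cells; marker channel for positives, with a faint
  annulus for negatives), per-cell lognormal brightness, Gaussian PSF blur,
  Poisson shot noise, constant background and Gaussian read noise.

Defaults emulate the assay's study conditions: an expected 1000 cells per
well on a 2048 x 2048 px field at 1.7 µm/px (a 4x widefield objective
covering the well), a 1:1 cancer:stromal co-culture preset, five-point
concentration panels with four replicate wells, and ~10-fold intensity
separation between positive and negative classes. Hill curves were chosen
for the kill and induction models because the assay reports only endpoint
IC50s and percentages — any smooth monotone model would do, and Hill
parameters make recovery testable.

What the simulator does **not** emulate: illumination gradients, realistic
chromatin/cytoplasm texture, strongly overlapping or apoptotic nuclei,
autofluorescence, or 3-D structure. Passing the simulator-based suites
therefore demonstrates the correctness of the computational chain under the
assay's statistical model, not robustness to every real-world imaging
artifact; the segmentation parameters remain calibration inputs on real
data.

## Problem sizes and numerical choices

Test and validation runs use scaled-down fields (192–512 px with
proportionally fewer cells, the simulator's CI presets) so the full suite
and the acceptance script each complete in minutes on one CPU; the
statistical layers (fit recovery, Dunnett calibration, call operating
characteristics) are exercised at the plate design's full replication
(5 concentrations x 4 replicates, 50–2000 simulated families).

The induction operating-characteristics scenario is designed at a 40%
baseline positive fraction with a 30% relative increase at the top dose and
a per-group SEM of 1 percentage point: a 12-point shift against a ~1.4-point
standard error, the comfortably powered regime the relevance rule targets.
Detection power at fixed SEM scales with the absolute shift
(baseline x relative threshold), so low-baseline markers need tighter
within-group SEMs for the same operating characteristics.

Other numerical details: per-well simulation seeds derive from the base
seed and the well's linear plate index (order-independent, < 2^31);
`nls.lm` runs with `ftol = ptol = 1e-14` so noiseless 4PL data is recovered
to better than 1e-6 relative; result tables are written to 6 significant
digits and round-trip through CSV.

## Known limitations

* Threshold-based segmentation merges fully overlapped nuclei and drops
  border-touching cells; counts are slightly conservative at high density.
* Mean-intensity gating mixes signal where neighbouring cytoplasmic annuli
  overlap, the dominant source of rare class errors in dense wells.
* The relative/absolute reading of the 20% relevance threshold is exposed
  as configuration precisely because the choice changes calls for
  low-baseline markers.
* Exposure time (24-h line panels vs 7-day primary panels) is metadata
  only; the pipeline does not model exposure kinetics.
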