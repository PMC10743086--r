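# mdrhcs

High-content scoring of multidrug-resistance (MDR) markers in mixed tumor
cultures.

Non-small-cell lung cancer resections yield short-term cultures that mix
carcinoma cells with stromal fibroblasts. Bulk viability assays cannot tell
which compartment a drug killed, and bulk expression assays cannot tell which
compartment up-regulated an efflux pump. `mdrhcs` implements an open,
image-based assay that resolves both at the single-cell level: nuclei are
segmented from a DNA stain (Hoechst 33342), every cell is classified by
cytokeratin 8/18 (CK8/18, epithelial) and by an ABC-transporter marker
(ABCB1/P-gp, ABCC1/MRP1 or ABCG2/BCRP), and each well is summarized as four
populations — cancer or stromal, marker-positive or marker-negative. The
package targets 384-well plates imaged at low magnification (one field per
well) and is aimed at screening groups who want the vendor-software analysis
chain as auditable, scriptable code.

## What it computes

**Per-cell scoring.** Nuclei: global intensity threshold (absolute or
between-class-variance "auto"), hole filling, optional distance-transform
watershed splitting, and a width gate on the equivalent diameter. Cells:
nearest-nucleus geodesic growth bounded by a maximal cell width. A cell is
positive on a channel when its mean cytoplasmic intensity reaches that
channel's threshold.

**Cytotoxicity.** Per-population viability is the treated cell count as a
percent of the mean control count. Each culture x drug x population series
is fitted with the four-parameter logistic on log10 dose,

    R(c) = bottom + (top - bottom) / (1 + (c / IC50)^h),

and the reported IC50 is the fitted 50%-of-control crossing; panels that
never reach 50% within the tested range are right-censored and reported as
`">cmax"` (e.g. `">100"` at a 100 µM top dose). Fold-resistance is the IC50
ratio of a resistant to a parental line; selectivity flags the more
sensitive of two populations.

**Marker induction.** For each series the marker-positive percentage at each
concentration is compared against control with Dunnett's many-to-one test
(pooled-variance t statistics under the multivariate t with the exact
unequal-n correlation, evaluated by deterministic Gauss quadrature). A
series is called an **increase** only when some concentration is both
significant (adjusted p < alpha, default 0.05) and biologically relevant
(marker-positive percentage up at least 20% relative to control, by
default); otherwise **no change**.

**Synthetic plates.** A simulator renders multi-channel wells (flat-disk
nuclei and cytoplasmic annuli, Gaussian PSF, Poisson shot noise plus
Gaussian read noise) from Hill kill and induction models with complete
ground truth, so every stage of the pipeline is validated against known
answers.

## Worked example

The bundled reference IC50 panel (`inst/extdata/reference_ic50.csv`, µM)
contains the vinorelbine entries 0.03656 (parental NCI-H460) and 0.9902
(resistant NCI-H460/R):

```r
library(mdrhcs)
ref <- read.csv(system.file("extdata", "reference_ic50.csv",
                            package = "mdrhcs"), colClasses = "character")
vin <- ref[ref$drug == "vinorelbine", ]
fold_resistance(vin$ic50[vin$culture == "NCI-H460/R"],
                vin$ic50[vin$culture == "NCI-H460"])
#> 27.08 (~27-fold)
```

The resistant line needs a 27-fold higher vinorelbine dose to reach the same
50% kill. Fitting a simulated five-point vinorelbine panel (true IC50
0.5 µM, 4 replicates, 10% CV noise):

```r
pan <- simulate_viability_panel(ic50 = 5e-7, hill = 1,
         concentrations = c(100, 250, 500, 750, 1000) * 1e-9,
         n_replicates = 4, cv = 0.10, seed = 1)
fit_curve(pan$concentration, pan$response,
          culture = "NCI-H460", drug = "vinorelbine", population = "total")
#> 4PL fit [NCI-H460/vinorelbine/total]: IC50 = 0.5172 uM (hill 1.36, top 92.8, bottom 14.3)
```

The fitted IC50 (0.517 µM) recovers the simulated truth within the noise.
An induction series with a designed jump at the top dose:

```r
set.seed(3)
g <- data.frame(concentration = rep(0:5, each = 4) * 1e-6,
                pct = rnorm(24, rep(c(40, 40, 40, 40, 40, 52), each = 4), 2))
induction_call(g, analysis_config(), marker = "ABCB1",
               culture = "NCI-H460", population = "cancer")
#> induction [ABCB1 | NCI-H460 | cancer]: increase (control mean 38.93%)
#>  concentration     mean       sem        p_adj relative_increase
#>          1e-06 40.71397 0.5110784 3.693028e-01       0.045929822
#>          ...
#>          5e-06 50.30451 0.6235700 2.234262e-09       0.292307939
```

Only the top dose is both significant (Dunnett-adjusted p = 2.2e-9) and
relevant (+29% relative), so the series is called an increase.

End-to-end runs go through `cmd_simulate()` / `cmd_analyze()` (or the
`inst/cli/mdr-hcs` script): simulate or collect per-well TIFFs, then

```sh
Rscript inst/cli/mdr-hcs analyze --images images/ --layout layout.csv \
    --out results/ --seed 1
```

writes `cells.csv`, `wells.csv`, `dose_response.csv`, `induction.csv`,
`calls.csv` and a run manifest.

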