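---
title: "Assessing caries lesion activity from dehydration, OCT and MicroCT imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing caries lesion activity from dehydration, OCT and MicroCT imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariometry)
```

## The measurement problem

Whether a caries lesion is *active* (porous, progressing, in need of
intervention) or *arrested* (remineralized, sealed, safe to monitor) is
decided clinically by look and feel, both unreliable — stain mimics decay,
and tooth-colored restorations hide the margins where secondary lesions
form. A physical alternative is to measure how fast the lesion loses
water. The outer layers of an active lesion are porous and permeable;
an arrested lesion has grown a *transparent surface layer* (TSL) of
near-sound mineral that blocks fluid exchange. Drying a wet tooth with
forced air and filming it therefore separates the two states:

* In **SWIR reflectance** (short-wave infrared, ~1950 nm), water in the
  lesion pores absorbs the incident light. As the lesion dries,
  absorption disappears and the demineralized tissue scatters strongly,
  so the lesion brightens along a sigmoid. Sound enamel barely changes.
* In **thermal imaging**, evaporation cools the surface. A permeable
  lesion keeps feeding water to the surface and cools markedly before
  recovering to ambient; a sealed lesion barely cools.

`cariometry` implements the complete analysis chain for such recordings,
plus cross-sectional morphometry from OCT and MicroCT, the joined
statistical analysis, and a synthetic cohort generator that stands in for
the extracted-tooth data the protocol is designed for.

## Dehydration statistics

Each recording is a stack of frames (default 60 frames at 1 frame/s). A
lesion region of interest (ROI) and a sound control ROI on the same tooth
are averaged frame by frame (`roi_mean_curve()`), and each curve is
reduced to one number:

* SWIR: `delta_I()` computes \(\Delta I = \sum_t (I_t - I_{\min})\), the
  area under the time–intensity curve above its minimum.
* Thermal: `delta_Q()` computes \(\Delta Q = \sum_t (T_{\max} - T_t)\)
  in K·s, the area enclosed below the temperature maximum.

Both use the *global* extremum of the curve, not the first frame: curves
typically start at the extremum (the tooth leaves the water bath wet and
at ambient temperature) but this is not guaranteed, and the global
extremum keeps the statistic non-negative by construction. The sum runs
over all available frames so truncated acquisitions remain analyzable.

Tooth-level effects are removed by contrasting lesion against control
(`contrast_metrics()`): the difference \(L - C\) and the ratio \(L / C\).
The ratio normalizes out multiplicative gain but also compresses genuine
permeability contrast — in practice \(L-C\) tracks the TSL more closely,
and the package reports both.

`integrated_heatmap()` applies the same integral to every pixel's own
time series. Averaging that map over an ROI is *not* the same estimator
as integrating the ROI-mean curve (each pixel takes its own extremum, so
for SWIR the map average dominates the curve estimate); the package
exposes both, uses the ROI-curve estimator for all reported statistics,
and reserves the map for display and ROI placement.

## OCT morphometry

A B-scan resolves the lesion in depth, but in *optical path length*:
light traverses enamel with refractive index 1.6, so every axial distance
is divided by 1.6 before being reported in tissue micrometres. This
correction is applied to lesion depth and TSL thickness and to nothing
else in the package — MicroCT lengths are physical and never divided.
(The package reports TSL thickness on the tissue scale for consistency
with lesion depth; reports that quote optical-scale TSLs will read up to
1.6× larger.)

The chain is:

1. `detect_surface()` — per A-line, the first pixel above a noise
   threshold (mean + 3 sd of the top rows of air), median-smoothed
   across columns; columns without a surface are excluded.
2. `segment_lesion()` — Otsu's threshold over the below-surface pixels,
   largest connected component, followed by a sanity check that the
   candidate body is actually bright (mean intensity ≥ 0.3 on the
   normalized scale). The check matters: Otsu always finds *a* split,
   even in sound tissue, and without it every sound scan would grow a
   phantom lesion.
3. `lesion_depth()` — per column, (deepest body row − surface row) ×
   pitch / 1.6, averaged over columns.
4. `integrated_reflectivity()` — the mean intensity over the lesion
   mask. This saturates around 15% mineral loss (pores connect rather
   than multiply), so it indexes severity only up to that point; the
   generator builds the same saturation into its forward model.
5. `detect_tsl()` — per column, the run of pixels between the surface
   reflection and the first body pixel that stay below 50% of that
   column's body peak; the thickness is the median run × pitch / 1.6,
   and a layer counts as detected only at ≥ 2 axial pixels. The median
   (not the mean) aggregates columns so single dropout columns cannot
   flip the detection flag.

The 50% body-peak criterion and the 2-pixel floor quantify "transparent"
and "detectable", which are otherwise qualitative: at the default 5 µm
optical pitch the floor is 6.25 µm of tissue, comfortably below the
thinnest layers considered clinically meaningful (~16 µm). The rule
assumes a surface-adjacent TSL; a transparent zone fully enclosed by
lesion body would be missed.

## MicroCT morphometry

MicroCT resolves mineral density at true spatial scale (10 µm/px by
default). `line_profile_depth()` reproduces the standard workflow:
median smoothing (`ct_preprocess()`, radius 1 px by default — the
parameter is sometimes loosely called a "sigma", but a rank filter
preserves the step edges the next stage must localize; a Gaussian is
available via `family = "gaussian"`), Sobel edge detection
(`sobel_edges()`), then `n_lines = 5` evenly spaced depth profiles.

Two numerical choices deserve note:

* Boundaries are localized on the *signed* vertical Sobel component,
  with suprathreshold runs split at sign changes and collapsed to
  magnitude-weighted centroids. Thin surface layers put the air→SL and
  SL→body edges on adjacent pixels; without the sign split they merge
  into one run and bias the surface estimate by half a pixel.
* The surface-layer run (density above the midpoint between sound level
  and near-surface peak) is counted on the **raw** profile, not the
  smoothed one: the median filter erases plateaus at the filter scale,
  and a genuine one-pixel surface layer would vanish from the smoothed
  image.

Profiles are drawn inside the lesion's lateral extent, two columns off
its boundary, because the lateral gradient at the lesion edge would
contaminate a depth profile.

## Activity statistics

`run_pipeline()` joins the per-lesion measurements and runs:

* `correlation_report()` — Pearson correlations (via `stats::cor.test`)
  between TSL thickness and each dehydration statistic, depth vs
  reflectivity, and TSL vs the MicroCT surface layer.
* `tsl_band_analysis()` — lesions split at 70 µm of TSL: within-band
  correlations plus between-band Welch t-tests on each statistic. The
  70 µm cut is the arrest threshold: beyond it permeability is ~5% of
  the TSL-free baseline and further thickening changes little.
* `stratify_by_surface()` — the same correlations per surface type.
  Water pools in occlusal/incisal crevice anatomy and inflates thermal
  signals there, so smooth surfaces carry the cleanest correlations.
* `classify_activity()` — no TSL → active; TSL < 70 µm →
  partially-arrested; ≥ 70 µm → arrested. The boundary is assigned
  *inclusively* to "arrested" (descriptions of the threshold alternate
  between "more than 70" and "70 or more"; one convention had to be
  picked and documented).

Further conventions: Welch's unequal-variance t-test is the default
(nothing guarantees equal variances across bands; the pooled Student
variant is a flag away); p-values are two-sided; no multiple-testing
correction is applied by default, matching how such studies are usually
reported (`p.adjust` can of course be applied to any report column);
lesions without a detectable TSL are *excluded* from TSL correlations by
default rather than entered as zeros (`include_undetected = TRUE`
switches modes) — a zero thickness is a different physical statement
than an unmeasurable layer.

## The synthetic cohort generator

No public dataset of secondary-lesion dehydration stacks exists, so the
generator is a first-class module: every analysis stage is validated by
parameter recovery against its ground truth. Its defaults encode the
acquisition protocol the analysis targets: 60 frames at 1 frame/s,
294.15 K ambient, thermal noise at the 50 mK camera sensitivity, 5 µm
optical OCT pitch, 10 µm MicroCT pitch, a surface mix of roughly 13%
occlusal / 81% smooth / 6% incisal, and ~22% of lesions without a
detectable TSL.

The generative core is the permeability law
\(p(\mathrm{TSL}) = p_0 \cdot 0.05^{\mathrm{TSL}/70}\)
(`permeability_from_tsl()`): exponential decay calibrated so a 70 µm
layer leaves 5% of baseline permeability — the arrest regime — while
never reaching exactly zero. Only the 70 µm saturation point is
empirically anchored; the exponential form is the package's own choice
(the simplest monotone law through both constraints).

From a lesion's permeability, mineral loss and pooling fraction the
renderers produce:

* **SWIR stacks** — a normalized logistic rise (`swir_drying_curve()`)
  whose rate and onset follow permeability and whose amplitude scales
  with mineral loss, on top of a small shared "sound drying" term whose
  per-tooth wetness factor (uniform 0.5–1.5) is common to lesion and
  control ROIs: it cancels in \(L-C\) but jitters \(L/C\), reproducing
  the empirical pattern that ratio statistics correlate more weakly.
* **Thermal stacks** — a drop-then-recover double exponential
  (`thermal_cooling_curve()`, time constants 3 s and 15 s) whose peak
  drop sums a uniform surface-water term (~0.3 K; the whole tooth is
  wet when it leaves the bath), an evaporative term ∝ permeability ×
  pore volume (saturating at 15% mineral loss), and a crevice-pooling
  term confined to occlusal/incisal lesions.
* **OCT B-scans** — surface reflection, dark TSL band of optical
  thickness TSL × 1.6, bright body down to depth × 1.6, attenuated
  background, with the 15% reflectivity saturation built in.
* **MicroCT slices** — elevated surface layer, demineralized body,
  sound floor, with gray ordering body < sound < SL by construction.
  The SL is drawn as `15 + 0.35·TSL + N(0, 28)` µm (clamped to
  8–160 µm): the OCT-visible TSL and the MicroCT-visible SL are
  physically related but far from identical — nearly every lesion has
  *some* mineralized surface zone while only the dense ones read as
  transparent in OCT — and this weakly coupled draw reproduces the
  modest positive TSL–SL correlation seen when both are measured. The
  true generative link between the two is unknown; this is an explicit
  modelling assumption.

When a composite restoration is present, a static bright band (SWIR)
with extra thermal water retention is rendered and *excluded from both
ROIs*, mirroring the documented false-positive hazard of letting
composite into an ROI. Determinism is strict: the cohort seed draws one
`render_seed` per lesion, so any lesion renders identically regardless
of processing order, and two pipeline runs with one seed produce
byte-identical reports.

What the generator does **not** emulate: OCT speckle and the system
point-spread function, 3-D volumes (one representative B-scan/slice per
lesion), surface tilt and curvature, stain, gingiva, specular glare, and
beam-hardening. Passing recovery tests therefore demonstrates that the
analysis is correct *given the stated image formation model*, not that
it is robust to every artifact of real instruments.

## Validation problem sizes

The shipped tests validate: statistic oracles on 1,000 random curves and
direct-formula checks of the correlation/t-test wrappers at 1e-12;
noise-free parameter recovery on a 50-lesion cohort (OCT depth and TSL
within one axial pixel / 1.6, MicroCT depth and SL within one 10 µm
pixel); the full sign structure on the default 100-lesion cohort
(negative TSL vs \(\Delta I_{L-C}\) and \(\Delta Q_{L-C}\), significant
below 70 µm and not above, significant between-band t-test); null
soundness of zero-mineral-loss lesions against a 500-repeat Monte-Carlo
noise floor (`contrast_noise_floor()`); and byte-identical reruns.

```{r example, eval = FALSE}
report <- run_pipeline(cohort_config(n_lesions = 100, seed = 1))
report$correlations
report$band
```

## Known limitations

* The arrest-band null ("no correlation at ≥ 70 µm") is a statement
  about small samples: the generator's permeability keeps decaying
  (slowly) past 70 µm, so very large cohorts would eventually resolve a
  residual within-band trend.
* Segmentation assumes a roughly flat, horizontal surface; strongly
  tilted B-scans would need rotation before analysis.
* The TSL detector assumes the transparent zone sits at the surface;
  enclosed transparent zones are not measured.
* MicroCT gray values are treated as relative density only — no
  calibration to mineral content (g/cm³) is attempted.
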