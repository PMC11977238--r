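---
title: "Models and methods behind dualscreen"
author: "dualscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

# The assay and what the package computes

Dual-fluorescent reporter lines couple a signal-driven nuclear Tomato
reporter to a constitutive nuclear EGFP expressed from the same locus.
Dividing Tomato by EGFP per well cancels cell-number, locus and
detection effects, which is what makes the readout robust enough for
plate screening. `dualscreen` implements the downstream analytics for
this readout: image quantification, plate robustness (Z′, fold
change), bimodal activator/inhibitor hit calling, four-parameter
logistic (4PL) EC50 estimation, flow-cytometry percentile gating and
iron-chelation curves — all exercisable on seeded synthetic data with
known ground truth.

# Image quantification

Nuclei are segmented on the EGFP channel: foreground is EGFP at or
above the isodata (iterative intermeans) threshold, components are
8-connected, and each component receives exactly one QC status in
order of precedence:

1. `excluded_border` — any pixel on the image edge;
2. `excluded_abnormal` — area outside `[minArea, maxArea]`
   (defaults 50–2500 px) or solidity below 0.85;
3. `excluded_unseparated` — area above `clusterAreaFactor` (default
   1.6) times the median area of the remaining candidates;
4. `included`.

Unseparated clusters are *excluded*, not split by watershed: the
platform's convention is that nuclei that cannot be separated reliably
are dropped, and at 2000+ nuclei per well the loss is immaterial.
Per-channel MFIs are means over the component mask after subtracting a
per-field background estimate (median of sub-threshold pixels, floored
at zero). The default well-level reporter value is the ratio of well
means (`tom_mean / egfp_mean`), which is less sensitive to dim-nucleus
ratio noise than a mean of per-nucleus ratios; the latter is available
via `ratioMethod = "mean-of-ratios"`. Wells with fewer than
`minNuclei` included nuclei (default 2000; tests use smaller fixtures)
are flagged rather than silently aggregated.

Two numerical caveats are worth knowing. The intermeans threshold
converges to a point midway between the background mean and the mean
of the *dominant* bright class, so a single very large, very bright
object (e.g. an abnormal blob covering thousands of pixels) can pull
the threshold above dim nuclei and drop them — an inherent property of
the rule, visible in the tests only when abnormal objects are planted.
And the unseparated-cluster rule compares areas against a median, so a
pair of unusually small overlapping nuclei can evade it when nucleus
radii vary; exact flag-recovery tests therefore use homogeneous-radius
fixtures, and real-data users should treat cluster exclusion as
approximate.

# Plate robustness

`zprime()` implements the standard separation-window statistic

$$Z' = 1 - \frac{3(\sigma_{c+} + \sigma_{c-})}{|\mu_{c+} - \mu_{c-}|}$$

with sample SDs (n−1). The sum form is used: a difference of sigma
terms is not the screening-window metric and can exceed 1. Z′ is
invariant to scaling and shifting all well values and strictly
decreases in either control SD; `Z' > 0.5` is the conventional
excellent-assay bar. Fold change is the ratio of control means. Both
accept the Tomato/EGFP ratio (default) or raw Tomato MFI
(`value = "tomato"`), since plate robustness is usefully reported for
both readouts.

Kinetic summaries report mean ± SEM per group and timepoint. Onset is
defined operationally as the earliest timepoint from which the induced
mean exceeds the vehicle mean plus three vehicle SDs at that and all
later timepoints. Sustained exceedance avoids single-timepoint noise
triggering the call; three SDs makes the rule scale-free.

# Bimodal screen hit calling

A bimodal screen reads the same compound plates twice: phase 1
unstimulated (activators raise Tomato above basal), then phase 2 after
pathway stimulation (inhibitors attenuate the induced signal).
Compound wells are screened as singlets; replication comes from
repeating the whole screen.

Z-scores are computed per phase and replicate against **all compound
wells** of that phase — with ~1600 compounds and a low true hit rate
the compound population is an excellent null reference, whereas the
handful of plate controls would estimate the scale poorly (a
control-based reference is available via `reference = "controls"`,
and a median/MAD robust mode via `robust = TRUE`). Classification
applies the EGFP artifact exclusion first: any compound whose EGFP MFI
z-score exceeds ±2 is `excluded_fluorescent` regardless of its ratio
z-score, because an apparent ratio change driven by the internal
control is a fluorescence artifact, not transcription. Otherwise
`z_ratio ≥ +2` (phase 1) is an activator and `z_ratio ≤ −2` (phase 2)
an inhibitor; boundaries are closed on the hit side so behaviour at
exactly 2.0 is defined. Hit rates are percent of the library, reported
to one decimal; replicate hit lists are intersected per class, and
replicate consistency is the Pearson correlation of paired z-scores.

One consequence of self-referenced z-scores deserves emphasis: under
pure noise ~4.6% of *all* compounds land outside ±2 EGFP SDs by
chance, so the artifact filter also removes that fraction of genuine
hits per replicate. Recovery/power statements in the tests are
therefore made on the ratio z-scores *before* EGFP exclusion (exactly
as the type-I rate is), and the exclusion's correctness — no compound
with `|z_egfp| > 2` ever reaches a hit list — is asserted separately.

# Dose-response

`minmaxNormalise()` maps each experiment's minimum to 0 and maximum
to 1. `fit4PL()` fits

$$y = d_{min} + \frac{d_{max} - d_{min}}{1 + (EC_{50}/x)^{h}}$$

by least squares in log-dose space: a coarse grid over 15 log-spaced
EC50 candidates × Hill slopes ±{0.5, 1, 2} with the two asymptotes
profiled out linearly (the model is linear in them), followed by
Levenberg–Marquardt refinement of all four parameters. The reported
solution never has a larger residual sum of squares than the best grid
point; fits with fewer than five distinct doses or failed refinement
are returned flagged (`converged = FALSE`) instead of erroring. The
model is invariant under swapping the asymptotes and negating the Hill
slope, so fits are canonicalised to `ceiling ≥ floor`, making a
negative Hill slope read directly as an inhibition curve. Asymptotes
are fitted freely by default even after min/max normalisation —
fixing them at 0/1 would let single extreme wells define the
asymptotes — and `fixLimits = c(0, 1)` provides the constrained
variant. No weighting is applied; replicate wells enter individually.

# Flow gating

The positivity threshold is the empirical 99th percentile
(linear-interpolation quantile) of the paired negative-control Tomato
intensities (`topFraction = 0.01`), recomputed per paired control
rather than shared across an experiment, since autofluorescence drifts
between acquisitions. Percent positive is the fraction of treated
events above it; MFI fold change uses medians by default (robust on
log-scale intensities; arithmetic mean available). Histograms are
binned in log10 intensity and scaled so the modal bin is 1. Scatter
(FSC/SSC) cleanup is not modelled: the synthetic generator emits
pre-cleaned events, and scatter carries no information used by any
statistic here.

# Chelation

Activity is the percent loss of iron-complex absorbance,
`100 (A_control − A_x) / A_control`; negative values (compound
absorbing more than control) are reported but flagged. The best-fit
line is activity on log10(concentration) — the standard scale for
series spanning decades; `scale = "linear"` is available — and the
50%-activity concentration is the line's inversion at 50, reported
only when it falls within one decade of the tested range.

# The synthetic-data generator

The generator defines the study conditions under which everything
above is tested.

**Per-cell intensities** are lognormal (meanlog/sdlog defaults
`log(500)/0.25` for EGFP, `log(80)/0.25` for basal Tomato, arbitrary
units): reporter flow histograms are unimodal on a log axis, which a
lognormal reproduces with two parameters. Induction multiplies the
Tomato of a responder cell by `inductionFold` (default 10, the
characteristic window of a well-behaved clonal line);
`responderFraction` defaults to 1 for clones and ~0.56 emulates a
sorted polyclonal pool.

**Fields** render nuclei as hard pixel-centre disks (radius 6 ± 0.8
px) over a uniform background of 40 AU with optional Gaussian read
noise (default SD 4): optical PSF realism is deliberately out of
scope, and crisp disks make noise-free recovery exact, so the
segmentation oracle tests are sharp. Planted fractions of nuclei touch
the field edge, overlap a partner (centre distance 0.75 of the summed
radii, giving a ~1.9× two-lobe blob that the cluster rule must catch),
or are oversized "abnormal" blobs (5× mean radius). Each cluster
nucleus pairs a distinct partner so merged blobs stay two-lobed.

**Well noise** totals a 10% CV per channel, decomposed into a factor
shared by both channels (85% of the variance — cell density and
seeding, which the internal-control ratio cancels; this is the
platform's point), a common detection factor, and a reporter-specific
factor carried by Tomato alone. The decomposition makes the ratio's
own noise Gaussian with CV ≈ 5.5%, which (a) matches the assumption
under which ±2 SD z-scoring has its nominal 2.28% tail mass, and (b)
yields plate Z′ values in the 0.6–0.9 band typical of excellent
dual-reporter screens at 10-fold induction. `foldForZ()` converts a
target z-score into the multiplicative ratio effect that lands there,
for planting calibrated screen effects.

**Kinetics** hold the induced ratio at baseline until
`kineticsOnsetH` (default 10 h) and then rise as
`1 − exp(−rate·(t−onset))` to the plateau fold (first-order reporter
accumulation after a signalling delay; an infinite rate gives a step).
A symmetric logistic with its midpoint as the "onset" was rejected
because a 3-SD detection rule crosses such a curve hours before the
midpoint, making the onset parameter unrecoverable by construction.

**Dose-response** draws 4PL responses (floor 0, ceiling 1, EC50
0.2 nM, Hill 1) with 5% multiplicative noise; **flow events** are the
lognormal mixture described above, 10,000 events per sample by
convention.

Determinism is a contract: identical configuration and seed reproduce
every output bit-identically.

What passing tests on these data do *not* show: robustness to
illumination gradients, focus drift, segmentation of crowded or
textured nuclei, plate-edge effects, spectral spillover, or
non-Gaussian well noise. The generator's plumbing (truth tables, label
masks) is invented bookkeeping, not a claim about any instrument.

# Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to estimate
each statistic adequately: 10 plates × (6+6) control wells for plate
robustness, 1595-compound screens (10 replicate simulations for the
type-I rate, giving a binomial 99% CI of ±0.3 percentage points around
2.28%), 9 doses × 8 replicates for EC50 recovery, and 10,000 flow
events. The isodata iteration stops when the threshold moves < 0.5
intensity units (intensities are 16-bit counts) or after 100
iterations. The 4PL grid is 15 × 6 start points; ties in hit-calling
are resolved by the closed-boundary convention above.
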