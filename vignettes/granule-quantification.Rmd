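---
title: "Quantifying RTK fusion oncoprotein granules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RTK fusion oncoprotein granules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulekit)
```

## The scientific problem

Receptor tyrosine kinase (RTK) fusion oncoproteins such as EML4-ALK and
CCDC6-RET lack a transmembrane domain yet drive RAS/MAPK signaling.
They do so from micron-scale, membraneless cytoplasmic protein granules
(biomolecular condensates) that locally concentrate upstream signaling
components. Quantifying this biology from live-cell fluorescence
imaging requires a pipeline of small, individually unremarkable steps —
illumination correction, puncta segmentation, object colocalization,
enrichment ratios, FRAP normalization, densitometry ratios, and the
attendant statistics — whose *composition* determines every reported
number. granulekit implements that composition as tested, reusable
code, together with a synthetic-data generator that plants known ground
truth so each stage can be verified quantitatively without access to
raw microscopy data.

## The imaging track

### Image model and correction

An acquired channel is modeled as

\[ I(x) = L(x)\,S(x) + b + \varepsilon(x), \]

where \(S\) is the true fluorescence, \(L\) a smooth multiplicative
illumination field, \(b\) additive autofluorescence/background, and
\(\varepsilon\) shot plus read noise. `estimate_illumination_field()`
fits a low-order polynomial (default order 2) to the log intensities
over the cell mask by iteratively reweighted least squares with Tukey
bisquare weights, so bright puncta are downweighted as outliers; the
exponentiated surface is normalized to mean 1. `correct_image()` then
applies \(\max(I/L - b, 0)\).

Design notes:

* The estimator was chosen for being parameter-light and directly
  testable against the generator's planted fields (recovery within 2%
  RMS in the tests, and within 5% with 5% of pixels replaced by 10x
  outliers). The original study names no correction model.
* `b` is a configured scalar by default; `estimate_autofluorescence()`
  supplies a median-based estimate from control (untransfected) cells
  when such regions exist. Whether the study used a scalar or a spatial
  map is unstated; both are accepted by `correct_image()`.
* Negative corrected intensities are clipped to zero.
* Skipping the correction matters: on planted scenes the fold-enrichment
  estimate is biased by more than 5% without it and unbiased (within 5%)
  with it, which the test suite demonstrates.

### Granule detection

`segment_granules()` reproduces threshold-based feature finding:

1. An Otsu threshold is computed over within-cell pixels — per image by
   default, per cell optionally (the study does not say which; the
   choice is exposed). `otsu_threshold()` maximizes the between-class
   variance \(w_0 w_1 (\mu_0 - \mu_1)^2\) over observed levels, ties
   broken toward the lowest level, and is implemented to be exactly
   scale-equivariant (multiplying the image by a positive constant
   leaves the segmentation pixel-identical).
2. Foreground pixels are grouped into 8-connected components (compiled
   union-find labeling; 8-connectivity matches common feature-finding
   defaults for round spots).
3. Components touching the image border or spanning two cells are
   discarded.
4. Components are gated by equivalent diameter
   \(d = 2\sqrt{A/\pi}\cdot\text{pixel size}\), inclusive bounds,
   default 0.4–2 µm — the conventional physical size window for these
   granules.

Known limitation: threshold-level segmentation of a Gaussian-profiled
spot returns a region whose size depends on where the threshold falls
relative to the peak. Otsu typically lands below the half-maximum, so
measured equivalent diameters run systematically larger than the
planted full-width-at-half-maximum diameter, and very large or very
bright spots can be clipped by the upper gate. No watershed splitting
of touching granules is attempted; the generator therefore plants
well-separated granules, and real images with touching puncta will
undercount.

### Colocalization and enrichment

`match_granules()` performs object-based colocalization: within each
cell, all pairwise centroid distances between channel-A and channel-B
features are computed, and a one-to-one matching greedily accepts the
globally smallest remaining distance up to a cutoff. The cutoff is
**not** stated in the source study; the default 0.5 µm (a quarter of
the maximum gate diameter, i.e. sub-granule-scale proximity) is
configurable and recorded in every output. Greedy matching is used
instead of thresholding the raw distance list so no granule is counted
twice; the test suite checks it against exhaustive optimal matching
(maximum cardinality, then minimum total distance) on all planted 5x5
instances. `colocalization_fraction()` reports 100 x matched/total over
the reference channel, per cell and pooled, excluding (and counting)
cells with no reference granules.

`fold_enrichment()` computes, per granule,

\[ \text{fold} = \frac{\overline{I_B}(\text{granule pixels})}
                      {\overline{I_B}(\text{whole cell area})}, \]

with fold 1 meaning no enrichment. The whole-cell mean includes granule
pixels (that is what "whole cell area" means); an exclusion option
exists but is off by default. Note one consequence of this definition:
in a cell whose recruiting granules raise the whole-cell mean,
*non*-recruiting granules sit genuinely below fold 1 — they are diluted
by their neighbours — so "fold 1 for unenriched granules" holds exactly
only in recruitment-free scenes.

## The phenotype track

* `granule_positive_fraction()`: percent of cells with at least a
  threshold number of granules (default 6, the scanned-field scoring
  criterion), computed per replicate and averaged, SEM across
  replicates. The threshold is a parameter, not a constant, because the
  study states the criterion only for one figure.
* `persistence_ratio()`: per-field after/before granule-count ratio
  around a treatment (e.g. 5 min of 5% 1,6-hexanediol, which dissolves
  liquid-like but not solid-like condensates). Count-based, because the
  study counts persisting granules; fields with zero pre-treatment
  granules are excluded and logged, ratios above 1 are kept but
  flagged.
* `granule_size_stats()`: per-condition median equivalent diameter and
  per-cell count quartiles.

## The FRAP track

Traces are normalized full-scale:
\(F_{\text{norm}}(t) = (F(t) - F_b)/(F_{\text{pre}} - F_b)\), with
\(F_{\text{pre}}\) the pre-bleach mean and \(F_b\) the intensity at the
single first post-bleach frame (not a minimum over frames, which would
be biased by noise). The pre-bleach level maps to 1 and the bleach
frame to 0; normalization is idempotent and invariant to affine
rescaling of the raw trace. An optional reference-region division
corrects acquisition bleaching; whether the study applied it is
unstated, so both behaviours exist and the choice is logged.

`mobile_fraction()` reports 100 x the normalized intensity at the frame
nearest the evaluation time (default 60 s — percent recovery at 1 min),
ties resolved to the earlier frame; interpolation is available behind a
flag. Population summaries use the median and range, because granule
populations are heterogeneous and a mean would hide that.

`fit_exponential_recovery()` fits \(M(1 - e^{-kt})\) to the post-bleach
segment by bounded least squares (\(M \in [0, 1.2]\), \(k > 0\)). One
numerical choice deserves emphasis: when \(k\) is small enough that the
plateau is not reached within the observed window, \(M\) and \(k\) are
only jointly identified through their product and noise can push the
fit along the ridge \(k \to 0,\ M \to\) cap. Rates below the
reciprocal of the observed post-bleach window are therefore not
resolvable from the data, and the fit bounds \(k \ge 1/t_{\max}\),
flagging such fits via `k_identifiable = FALSE`. With this bound the
simulation study in the test suite recovers \(M\) with |bias| < 0.02 at
both planted M = 0.1 and M = 0.4 (k = 0.05 s\(^{-1}\), 3-s frames,
noise 0.02).

## The biochemistry track

* `fraction_in_pellet()`: pellet/(pellet + supernatant) per replicate;
  the supernatant complement is returned so the two sum to 1 exactly.
  `detergent_shift()` gives the paired with/without-detergent
  difference (membrane-associated proteins shift to the supernatant
  with detergent; membraneless assemblies do not).
* `normalize_ras_gtp()` / `normalize_band_ratio()`: the
  double-normalization chain
  \(((\text{sig}/\text{load}) / (\text{sig}_c/\text{load}_c)) /
  (\text{expr}/\text{expr}_c)\), with the expression factor applied
  only when constructs differ (drug +/- comparisons within one line set
  it to 1). Controls normalize to exactly 1 by construction, and all
  ratios are invariant to rescaling every band in a blot.
* Replicate aggregation defaults to the arithmetic mean of
  per-replicate ratios (the mean ± SEM convention of the figures); a
  geometric-mean option suits the multiplicative lognormal noise of
  densitometry. Whether the study averaged ratios or log-ratios is
  unstated.

## Statistics

`t_test()` implements the classic pooled-variance Student statistic
(the study says "t test", not Welch; a Welch option is exposed) and the
paired difference test, two-sided throughout (the conservative default
when sidedness is unstated). `anova_tukey()` implements one-way ANOVA
with Tukey-Kramer HSD: \(q = |\bar y_i - \bar y_j| /
\sqrt{\mathrm{MSE}\,(1/n_i + 1/n_j)/2}\), adjusted p from the
studentized-range distribution evaluated by numerical integration
(`stats::ptukey`); the test suite cross-checks it against a
\(10^6\)-draw Monte-Carlo studentized-range null (agreement within
0.01) and verifies the familywise error rate (0.05 ± 0.01 over 10,000
null experiments) and the two-group identity \(F = t^2\). Degenerate
inputs are handled explicitly: zero pooled variance with equal means
reports t = 0, p = 1 with a flag; all-constant equal groups report
F = 0 and all adjusted p = 1.

## The synthetic world

`synth_field_image()` renders what the quantification consumes:

* non-overlapping elliptical cells (masks are *inputs* to the pipeline,
  matching manual cell delineation) on a dark background;
* granules as 2D Gaussians with \(\sigma = d/2.355\) (FWHM convention —
  a diffraction-limited-to-small-object rendering without a full PSF
  model), planted diameters uniform in a configurable range (default
  0.4–2 µm, spanning the detection gate), with centres kept inside
  their cell and spaced so spots stay resolvable;
* a channel B whose recruiting granules carry an exactly planted fold
  enrichment: per cell, the spot amplitudes solve the linear relation
  between granule-disk mean and whole-cell mean so that on the
  noiseless flat-field image the fold over the half-maximum disk equals
  the planted value (verified to better than 0.1% in the tests);
* an exponentiated order-2 polynomial illumination field (strictly
  positive, mean 1, default ±20% amplitude), additive autofluorescence,
  then Poisson noise on a photon-scaled signal followed by Gaussian
  read noise.

Chosen constants of the stated world, and why: pixel size 0.1 µm/px
(a 100x/1.40 NA oil objective with a typical sCMOS camera); 512 x 512
px fields holding five 12–16 µm cells with ~10 granules each, giving
~50 granules per field so that six fields reproduce the ~300-granule
batches typical of this analysis; channel-A amplitude 200 over baseline
50 with unit photon scale, i.e. peak SNR ≈ 10. Field and cell size
were set by feasibility before any acceptance measurement: in smaller
fields the granules occupy so much of the cell that a fold-3 enrichment
cannot exist (the granules' own tails raise the whole-cell mean beyond
what the ratio allows) and ten granules cannot be placed.

What the generator does **not** emulate — and hence what a green test
does not establish: 3D structure and defocus, realistic PSF side lobes
and aberrations, touching/overlapping granules (no declumping is
implemented), camera-specific noise (fixed-pattern, gain maps),
photobleaching during acquisition of the imaging track, cell-to-cell
expression variability beyond the per-cell baseline, and granule
motion. `synth_frap_trace()` draws from the single-exponential
two-state exchange model itself, so FRAP tests verify estimation, not
the adequacy of single-exponential recovery for real granules.
`synth_densitometry()` plants multiplicative lognormal band noise with
unit mean; band extraction from blot images is out of scope — band
intensities are numeric inputs.

One interaction between the generator and the detector is worth
restating: planted fold enrichment is *defined* on the half-maximum
disk, while segmentation returns Otsu-level pixel sets that are
systematically larger, diluting segmentation-based fold estimates by
roughly 10–15% at fold 3. The enrichment-recovery tests therefore
evaluate `fold_enrichment()` on ground-truth pixel sets
(`truth_granule_set()`), which isolates the computation under noise;
the dilution is an inherent property of threshold-based granule-pixel
identification that applies equally to the original study's
measurements. Similarly, the brightest channel-B spots segment larger
than their channel-A counterparts, so match-probability recovery is
tested in scenes planted at fold 2, where both channels' features sit
inside the size gate and the measured quantity is matching, not gate
clipping.

## Determinism and audit trail

Every generator takes a mandatory seed and reproduces its output
bit-for-bit; `run_imaging_pipeline()` derives per-field seeds from the
config seed, stamps every CSV with the config hash and seed, writes all
stage parameters and per-image thresholds to the run log, and produces
byte-identical CSVs on re-run — this is itself an acceptance criterion.
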