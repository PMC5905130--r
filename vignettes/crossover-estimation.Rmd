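---
title: "Counting fluorescent seeds and estimating crossover frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fluorescent seeds and estimating crossover frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xoseed)
```

## The segregation model and its estimator

An F1 hybrid heterozygous for a chromosome carrying two dominant,
seed-expressed fluorescence transgenes in coupling phase (GFP and RFP in
cis) produces four gamete classes.  With recombination fraction $r$ between
the insertion sites, the parental configurations `GR` and `nn` each occur
with frequency $(1-r)/2$ and the recombinants `Gn` and `nR` each with $r/2$.
Selfing pairs two independent gametes per seed, and dominance means a seed
fluoresces in a channel iff at least one gamete carries that transgene.
Writing $q = (1-r)/2$:

$$p_\mathrm{none} = q^2,\qquad
  p_\mathrm{red\,only} = p_\mathrm{green\,only} = \tfrac14 - q^2,\qquad
  p_\mathrm{both} = \tfrac12 + q^2.$$

Only single-colored seeds show crossovers directly; recombinant chromosomes
paired with a `GR` gamete are masked inside double-fluorescent seeds.  The
single-color fraction $f(r) = \tfrac12 - \tfrac{(1-r)^2}{2}$ is strictly
increasing on $[0, 0.5]$ with maximum $0.375$, so the estimator has the
closed form

$$\hat r = 1 - \sqrt{1 - 2f},\qquad
  \mathrm{SE}(\hat r) = \frac{\mathrm{SE}(f)}{\sqrt{1-2f}}$$

(delta method, binomial $\mathrm{SE}(f)$).  This inverse is the unique
closed form consistent with the dominant-marker coupling-phase F2 design;
`seed_class_probs_enum()` re-derives the forward fractions by brute-force
enumeration of all 16 ordered gamete pairs and the test suite holds the two
routes equal to $10^{-12}$.  An observed $f > 0.375$ implies $\hat r > 0.5$
and falsifies the model's assumptions (mislabeled channels, threshold
problems, contamination), so `xo_fit()` raises an error instead of clamping
— silent clamping would hide data problems.  Two deliberate limitations:
double crossovers between the marker loci are not modelled (they regenerate
parental marker configurations and are unidentifiable from two markers, so
$\hat r$ is the usual two-point underestimate of long distances), and no
correction for differential seed viability between classes is applied (the
design gives no basis for one).

Map distances are reported under three mapping functions: identity
($100r$ cM, additive only at short distances), Haldane ($-50\ln(1-2r)$, no
interference) and Kosambi ($25\ln\frac{1+2r}{1-2r}$, partial interference).
Haldane $\ge$ Kosambi $\ge$ identity everywhere, with equality only at
$r = 0$.

```{r}
fit <- xo_fit(seed_counts(736, 736, 6764, 1764))
summary(fit)
```

## The imaging pipeline

**Pixel classification.**  Seeds are recognized in the bright-field image by
a three-class random forest (Seed / SeedEdge / Background) trained on sparse
user scribbles, not dense masks.  The feature stack covers the three
families that matter for this task — intensity (Gaussian-smoothed image),
edges (gradient magnitude and Laplacian of the smoothed image) and texture
(local variance) — each at scales $\sigma \in \{1, 2, 4, 8\}$ px, 16 planes
in a fixed, versioned order; a classifier refuses to predict on a mismatched
feature version.  Boundaries are handled by reflection, so prediction is
translation-equivariant up to boundary effects.  Forest defaults are 100
trees, unlimited depth, $\sqrt{16} = 4$ features per split, training seed 0,
single-threaded for reproducibility; out-of-bag pixel accuracy is reported
on the fitted object.

**Segmentation.**  The core seed mask keeps pixels where Seed is both the
argmax class and $\ge$ `p_seed_min` (default 0.5).  Excluding
SeedEdge-dominant pixels from the core makes the classifier's edge class act
as a barrier between tangent seeds; the core is declumped by watershed on
the Euclidean distance transform (marker neighbourhood from
`min_marker_distance`, default 7 px $\approx$ the expected seed minor axis)
and the resulting labels are expanded back over the full non-background zone
by intensity-guided propagation, so measured objects include their rims.
Defaults follow the conventions of batch image-analysis pipelines:
8-connectivity, hole filling on, border-touching objects discarded.  The
area window (30–400 px²) is calibrated to the synthetic fixtures' seed-size
distribution and must be retuned for a real microscope's pixel scale.

**Fluorescence classification.**  Each object's *mean* intensity per channel
(on the bit-depth-normalized [0, 1] scale) is compared against the channel
threshold; the defaults 0.12 (red) and 0.077 (green) are the optimized
values for the reference stereomicroscope setup and are microscope-specific.
Thresholds are inclusive ($\ge$): a fixed convention is needed and boundary
cases are measure-zero in practice.  Whether the original per-object filter
used mean or integrated intensity is not documented; mean intensity is the
convention adopted here, a compatibility caveat when comparing absolute
thresholds.  No spectral unmixing is attempted.

**Quality control.**  The model expects RedOnly:GreenOnly $\approx$ 1:1, so
images where one single-color class outnumbers the other $\ge$ 4-fold are
discarded before pooling.  The inclusive rule ($\ge$, not $>$) is used, with
strictness configurable, since the two conventions appear interchangeably in
practice.  Zero-count policy: one-sided zero with the other side positive is
the extreme of the targeted skew and is discarded (skew $= \infty$); an
image with zero seeds of both single-color classes carries no recombinant
signal to bias the ratio and is kept (skew defined as 1).  A pooled sample
in which exactly one color is entirely absent while the other has $\ge$ 10
seeds is flagged `threshold_suspect` — biologically the two classes are
exchangeable, so that pattern points at a dead channel or threshold, not at
meiosis.

## Treatment statistics

Per-plant crossover frequencies from treated and control plants are
combined across batches by dividing by the control mean
(`normalize_to_control()`; the control normalizes to mean 1, and the
operation is scale-invariant so percent and fraction inputs agree).
Treatment effects are tested with Welch's unequal-variance two-sample
t-test at the conventional 0.05 threshold, two-sided; p-values are *not*
corrected for multiple comparisons across treatments, and the `compare`
output should be read accordingly.  Histogram/Q-Q diagnostics
(`plot_normality()`) are provided as a visual check, not a gate.

## What the synthetic scenes emulate — and what they do not

`generate_scene()` reproduces the features of the acquisition that the
pipeline actually exploits: dark elliptical seed bodies (semi-axes 6–9 ×
4–6 px by default; the physical pixel size of a seed depends on microscope
zoom and is a free parameter) with a 2 px darker rim on a light speckled
background (0.85 background, 0.40 body, rim 0.15 darker), sub-seed-sized
debris distractors, per-pixel Gaussian noise (sd 0.02), and fluorescence
that is a low autofluorescence baseline inside every seed (0.03, matching
reporter seeds that show little to no autofluorescence; a higher value
builds a stress fixture for threshold-tuning tests) plus a per-seed carrier
signal (0.35 ± 0.04) in the channel(s) the genotype carries.  Genotypes are
drawn from the segregation model at `r_true`, and scenes are byte-for-byte
reproducible from `rng_seed`.  Default 400 seeds per image mirrors ten
images covering 3000–5000 seeds per sample.

By construction the default fixture is *separable*: carrier signal clears
the default thresholds by several noise standard deviations
(`carrier_signal_mean − 2·carrier_signal_sd > autofluorescence_level` is
enforced), and seeds are non-overlapping (tangency allowed at
`min_gap = 0`).  Passing the end-to-end tests therefore demonstrates that
the machinery is correct — detection F1, per-seed class accuracy and
recovery of `r_true` behave as the model predicts — but not that the
defaults transfer to any particular real microscope: real images add optics
the generator deliberately omits (point-spread blur, vignetting, chromatic
shift, channel bleed-through, seed clusters, species-specific morphology).
Classifier retraining and threshold/area recalibration are expected steps on
real data.

## Numerical and design notes

* Seed placement is rejection sampling on centre distances (conservative
  criterion: centres at least the sum of the major semi-axes plus `min_gap`
  apart); an impossible packing fails after a bounded number of attempts
  with advice rather than hanging.
* The F2 simulator's default is a single multinomial draw over the four
  seed classes — statistically identical to drawing two gametes per seed —
  with the explicit per-gamete route kept behind `method = "gamete"` as an
  independent check.
* TIFFs are written 8-bit by default (16-bit optional); intensities are
  scaled by the bit-depth maximum on read, so thresholds are bit-depth
  independent.  Quantization (1/255 ≈ 0.004) is negligible against the
  smallest threshold (0.077).
* `f = 0.375` exactly (i.e. $\hat r = 0.5$) is valid input; Haldane and
  Kosambi distances are then reported as `Inf`.  A tolerance of $10^{-9}$
  absorbs floating-point noise at that boundary.
* Empty segmentations are valid results with zero objects, not errors; a
  pipeline run fails only if a sample ends with zero QC-surviving images.
* Test and validation problem sizes: unit fixtures are 324 × 243 px scenes
  with 50 seeds; the end-to-end validation uses ten 648 × 486 px triplets
  of ~400 seeds each (~4000 seeds pooled, multinomial SE of $\hat r$
  ≈ 0.007), and estimator calibration uses 500 replicates at n = 5000 and
  one pool of 200,000 simulated seeds.  These sizes make the whole suite
  run in a few minutes on a single core while keeping every statistical
  tolerance meaningful.
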