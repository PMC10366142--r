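---
title: "Methods: condensate quantification, domain cutoffs and overlap statistics"
author: "puncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condensate quantification, domain cutoffs and overlap statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puncta)
```

# Scope

`puncta` quantifies intranuclear condensates from single-plane fluorescence
micrographs and provides two companion genomics analyses: a rank–slope
cutoff for large ChIP-seq domains and randomization-based gene-set overlap
statistics. Nuclear segmentation itself is out of scope: the imaging chain
consumes an integer nucleus label map produced upstream (e.g. by a
deep-learning segmenter run on the DAPI channel), and the synthetic
generator emits ground-truth label maps in its place.

# The imaging model and its assumptions

A recorded image is modelled as

$$ I(x) = o + F(x)\,S(x) + \varepsilon(x), $$

with camera offset $o$, a smooth multiplicative illumination field
$F \in (0,1]$ (maximum 1), the fluorescence scene $S$, and additive read
noise $\varepsilon \sim N(0, \sigma^2)$ (Poisson shot noise is an optional
generator flag, off by default so signal-to-noise stays analytically
controllable). Two reference images are acquired alongside the cells: an
*empty* well (buffer only: $o + \varepsilon$) and an *empty fluorophore*
well (dilute dye: $o + F\cdot L + \varepsilon$).

**Illumination correction.** `computeIlluminationFunction` subtracts the
empty image from the fluorophore reference (negatives clipped to zero — the
quantities are physical intensities), smooths with a Gaussian of
$\sigma = 50$ px by default, and rescales by the maximum so that
$\max F = 1$. The smoothing scale is a free parameter: it must sit well
above the object scale (condensates ≤ ~25 px) and at or below the scale on
which the optics vary; 50 px suits a field that varies over hundreds of
pixels. Values below a clamp floor of $10^{-3}\times\max$ are raised to the
floor, bounding the amplification applied by the subsequent division to
$10^3$; clamped pixels are flagged in a validity mask carried in the
corrected image's metadata. Correction is pointwise:
$(I - \text{empty})^+/F$.

Two numerical caveats are tested rather than hidden. First, smoothing a
curved field with a truncated, renormalized kernel biases the estimate
within one kernel support (3σ) of the border, so the sub-1% round-trip
guarantee applies to interior pixels, outside that support. Second,
smoothing a quadratic vignette shifts it by $\sigma^2 \nabla^2 F/2$; after
max-rescaling this leaves a relative error of order
$2c\sigma^2 \cdot c r^2$ for a vignette $1 - c r^2$ — about 0.5% at
$\sigma = 25$ on the synthetic field, within the stated tolerance.

# Two-round condensate identification

All detection parameters (`detectionParams()`) default to the published
pixel-denominated values; every one is configurable.

| parameter | default | role |
|---|---|---|
| nucleus diameter gate | 80–300 px | keep plausible nuclei, drop debris/clumps |
| border rule | on | nuclei touching the image border are removed |
| speckle feature diameter | 40 px | white top-hat structuring element |
| round I diameter gate | 6–40 px | lenient pass object sizes |
| adaptive window | 50 px | Robust Background tile size |
| Robust Background | trim 5%/5%, mean + 2 SD | lenient per-tile threshold |
| round II diameter gate | 8–40 px | stringent pass object sizes |
| Otsu correction factor | 0.5 | stringent global threshold multiplier |
| large-condensate rule | ≥ 2 condensates > 1.25 µm | cell-level classifier |

**Enhancement.** `enhanceSpeckles` is a white top-hat: the image minus its
grayscale opening with a disk of the feature diameter. Features narrower
than the disk survive; the nuclear background and smooth gradients are
removed. At the image border the opening of a monotone ramp is
underestimated by construction (any window containing an edge pixel has its
minimum half a window away), so "gradients map to ~0" holds for the
interior; the tests assert exact agreement with a direct
shift-and-accumulate oracle everywhere and near-zero output on the interior.

**Round I (lenient).** The nuclear region is tiled into 50-px windows; each
tile with at least 20 nuclear pixels receives a Robust Background threshold
(sort, discard the lowest and highest 5%, mean + 2 SD of the rest); empty
tiles inherit the global nuclear threshold. Tile-center values are
bilinearly interpolated into a threshold surface, clamped to the outer tile
centers. Connected components (8-connectivity) of above-surface nuclear
pixels with equivalent diameter 6–40 px form the round-I footprint. This
pass finds all large condensates but merges close neighbours and drags in
their dim surroundings.

**Round II (stringent).** The original step is phrased as "masking" the
round-I objects before re-identification; `puncta` interprets this as
*mask-to* — restricting round II to the round-I footprint — because the
stringent round is explicitly credited with recovering large-condensate
shapes and splitting neighbours, which is impossible if round-I pixels were
removed. Within the footprint, pixels above
$0.5 \times$ the global Otsu threshold of the nuclear intensities are
relabelled; components of 8–40 px equivalent diameter are the final
objects, each assigned to the nucleus containing its centroid. Raising the
correction factor can only shrink the footprint's thresholded subset, so
for resolvable (unimodal) condensates the object count is non-increasing in
the factor — a tested property.

**Otsu details.** The threshold maximizes between-class variance over a
256-bin histogram of the min–max-scaled sample, with ties broken toward the
first maximum (the convention of the standard scikit-image implementation).
On a cleanly bimodal sample the variance is flat across the empty
inter-mode gap, so the threshold lands at the gap's lower edge rather than
mid-gap; any value in the gap separates the classes identically. Images are
processed in floating point throughout; the only quantization is Otsu's
internal binning.

**Measurement.** "Diameter" is the equivalent diameter
$d = 2\sqrt{A/\pi}\cdot p$ (area $A$ in px, pixel size $p$ in µm/px) — the
convention of the upstream tool; the original work does not define it.
Eccentricity is $\sqrt{1-\lambda_2/\lambda_1}$ of the second-central-moment
ellipse (0 = circle). A cell is *large-condensate positive* when at least 2
of its condensates exceed 1.25 µm; an optional expression gate excludes
cells whose mean nuclear intensity falls outside a configured interval
(emulating stringent expression-level cutoffs on tag fluorescence), and
gated cells leave the denominator of the positive fraction. The numeric
gate bounds are run-time configuration, not constants.

**A known measurement bias.** Reported diameters are *threshold-contour*
diameters: for a Gaussian condensate of FWHM $d$ thresholded at
$t = \alpha A$ (peak $A$), the measured diameter is
$d\sqrt{\log_2(1/\alpha)}$ — unbiased exactly at the half-maximum
($\alpha = 0.5$) and inflated below it. Conversely the 40-px top-hat clips
condensates whose low-level footprint approaches the structuring element,
deflating objects wider than ~16 px FWHM. Green detection tests therefore
establish *phenotype discrimination* at the 1.25-µm rule under these
biases, not unbiased diameter recovery.

# The synthetic world

The generator renders what the acceptance tests need and nothing more:

- **Nuclei**: non-overlapping filled ellipses (axis ratio uniform in
  [1, 1.3] — realistic eccentricity without pathological shapes), major
  diameter 100–150 px, not touching borders; placement by rejection with
  bounded retries (an error, not silent degradation, if the field cannot
  accommodate them).
- **Condensates**: isotropic 2-D Gaussians whose FWHM equals the nominal
  diameter — this makes "true diameter" well defined and matches
  diffraction-limited puncta. Centers are at least one diameter-sum apart
  (plus 4 px), keeping planted objects individually resolvable: per-object
  recall is only meaningful when the scene contains distinguishable
  objects. Counts per nucleus are fixed or Poisson.
- **Phenotypes**: with `phenotypeMix = TRUE`, each nucleus is a
  *small-punctum* cell (FWHM uniform in 0.8–0.9 µm) or a
  *large-condensate* cell (1.5–2.0 µm), mirroring cell lines that do or do
  not form large condensates; the acceptance world uses a 50/50 mix.
- **Optics**: radial vignette $F = 1 - 0.3\,(r/r_{max})^2$, camera offset
  100 AU, nuclear background 200 AU, condensate peak 200 AU above
  background, read noise σ = 20 AU (SNR 10); all configurable.
- **Pixel size**: 0.16 µm/px by default (a typical 100× EM-CCD scale); the
  original study never states it, so it is a required, surfaced parameter.
  The acceptance world uses **0.12 µm/px**, the scale at which the
  pixel-denominated detection gates and the µm-denominated classifier are
  mutually coherent: the round-II minimum (8 px ≈ 0.96 µm) stays below the
  1.25-µm rule so sub-threshold puncta are detectable without being
  auto-"large", while the largest condensates (2 µm ≈ 17 px) remain well
  inside the 40-px enhancement feature. At substantially finer sampling the
  top-hat clips the big condensates; at coarser sampling the round-II gate
  swallows the small ones.

What the generator does *not* emulate: 3-D structure (single Z-slice only),
chromatin texture inside nuclei (background is uniform), spectral
crosstalk, photobleaching, segmentation errors in the nucleus mask (truth
masks are exact). A green recovery test therefore validates the measurement
chain given a correct mask, not the robustness of upstream segmentation.

Domain-size lists come in three regimes: *linear* (sizes ∝ rank, every
normalized slope exactly 1), *piecewise* (flat body of per-rank increment
$b$, steep tail of increment $T$; the crossing index has the closed form
$m - W + \lceil W(1-t_b)/(t_t-t_b)\rceil$ for body/tail normalized slopes
$t_b, t_t$, body length $m$, window $W$), and *lognormal* (heavy-tailed, no
analytic crossing). Gene universes are synthetic identifiers with exactly
planted overlaps.

# Rank–slope domain cutoff

Sizes are sorted ascending (stable), ranks normalized as $(i-1)/(n-1)$,
sizes min–max normalized, slopes taken at adjacent points, and windows of
10 consecutive slopes averaged. The cutoff is the size at the *first data
point* of the first window whose mean reaches the threshold (default 1).
Numerical decisions:

- "Equals 1" is realized as $\ge 1 - 10^{-9}$: exact equality is
  measure-zero on real data, and the tolerance keeps the analytically exact
  linear case (all slopes 1) from being lost to floating-point rounding.
- Min–max normalization forces the mean of *all* slopes to be exactly 1,
  so with threshold 1 some window always qualifies; the `no_crossing`
  status is reachable only for thresholds above the curve's maximum window
  mean. It is reported as a distinct status, not an error.
- The window anchor (first/center/last point) is exposed as an option;
  "first" is the default reading of "the first point at which".
- The boundary is inclusive: a domain whose size equals the cutoff is
  large — the cutoff element itself sits at the crossing.
- The cutoff is scale-equivariant (multiplying sizes by $c$ multiplies the
  cutoff by $c$) and permutation-invariant; both are tested, along with
  exact agreement with an exhaustive window-scan oracle on every simulated
  instance.

The fixed 96-kb mode replicates the previously reported megadomain cutoff
for comparison across samples. How domains are built from aligned reads is
upstream and out of scope; the module consumes BED intervals (0-based,
half-open, preserved on output).

# Gene-set overlap statistics

`expectedOverlapRandom` draws both sets independently, uniformly without
replacement, and reports the mean and SD of the intersection size over
`iters` draws (default 20, the published figure-legend procedure; tests use
10⁴ to verify convergence to the hypergeometric mean $n_A n_B/N$ within 3
standard errors). The representation factor is observed/expected, with the
randomized mean as the default denominator and the analytic value reported
alongside; an expected value of zero raises a distinct error rather than
returning infinity. The enrichment p-value is the hypergeometric upper
tail $P(X \ge k)$ — chosen because overlap p-values are reported in this
field without a named test, and the hypergeometric tail is the exhaustive
limit of the randomization; it is validated against complete enumeration
for small universes.

# Pipeline and reproducibility

`runPipeline` executes simulate → correct → detect → domains → overlap in a
fixed order from a YAML/list configuration whose defaults echo every
published value, and writes a manifest with MD5 checksums of every
artifact, the resolved configuration and the seed. One global seed
deterministically derives per-stage seeds by hashing the stage name (all
below $2^{31}$), so stages are independently reproducible and identical
runs are byte-identical — a tested property. Rasters are written as
plain-text 16-bit PGM (P2): lossless for integer images, readable by
ImageJ/scikit-image, and free of binary-format dependencies; tables are
CSV/TSV with '.' decimals, intervals BED.

# Known limitations

- Pure-R image operations (separable running min/max morphology, matrix
  Gaussian convolution, igraph-backed labelling) are efficient for the
  512–1024 px fields used here but not for large tiled acquisitions.
- The adaptive threshold surface interpolates tile-center values; threshold
  ridges narrower than the 50-px window are smoothed over.
- Equivalent-diameter measurements inherit the threshold-contour bias
  described above; comparisons across conditions are valid because the
  bias is shared, but absolute sizes should not be read as FWHM.
- No watershed declumping: objects merging at the round-II threshold stay
  merged; the generator's resolvable-separation guarantee reflects this.
- The hypergeometric p-value assumes exchangeable genes within the
  universe; structured universes (e.g. expression-matched pools) must be
  supplied by the caller.
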