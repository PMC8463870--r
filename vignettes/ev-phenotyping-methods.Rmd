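---
title: "Methods: simulating and analysing single-cell EV TIRFM experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing single-cell EV TIRFM experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfev)
```

# Scope

`tirfev` analyses four-color TIRFM experiments in which extracellular
vesicles (EVs) secreted by individually cultured cells are captured on an
antibody surface, stained against four markers, imaged field by field, and
classified into the $2^4-1 = 15$ nonempty marker-combination phenotype
populations. Because raw microscopy data are rarely shippable, the package
pairs the analysis chain with a ground-truthed forward model of the imaging
experiment, so every stage can be validated against known truth.

# The forward model

## Field geometry

One field covers `field_area_um2` (default 4356 µm², i.e. a 66 µm side).
The magnification of the original instrument is not fixed by the assay, so
the pixel pitch is a free parameter; the default `pixel_size_um = 0.1` is
typical EMCCD-TIRF sampling and yields 660 × 660 px fields. The image side
must be at least 64 px, and the PSF sigma must be at least one pixel so
spots span multiple pixels.

## Vesicles, phenotypes, amplitudes

Per field, the number of true vesicles is Poisson(`ev_rate`). Positions are
uniform: the capture surface is homogeneous within a field. Each vesicle
draws a phenotype bitmask from a 15-category mixture indexed by bitmask
value; the default mixture puts the largest single weight (0.30) on the
quadruple-positive class, 0.075 on each triple, 0.04 on each double and
single, reflecting surface-captured EV preparations in which most vesicles
carry all four markers but substantial minorities lack one or more.

Spot amplitudes are log-normal per positive channel (`amplitude_sdlog`
0.35), with mean `signal_amplitude` (default 100). The peak
signal-to-noise ratio is `signal_amplitude / background_sd` = 10 at
defaults. Log-amplitudes are independent across channels by default so the
Pearson channel-correlation matrix has a clean null — exactly the
"analysis does not manufacture correlations" control — and a common
`amplitude_correlation` can be switched on as a dependence positive
control.

TIRFM's evanescent excitation (~200 nm) means only surface-bound vesicles
are visible; all simulated vesicles are therefore rendered in focus with a
single 2-D symmetric Gaussian PSF (`psf_sigma_um = 0.15`, sub-diffraction
point emitters). Axial structure, photobleaching, drift and cell-body
fluorescence are deliberately out of scope.

## Background and noise

Each channel image is `background_mean` plus the Gaussian spot sum, with
optional Poisson shot noise on the signal, plus Gaussian read noise
(`background_sd`), clamped at zero. Empty-well controls are emulated by
unspecific single-channel false spots at `background_spot_rate` per channel
per field (Poisson). The default 0.2/channel makes roughly 45 % of
empty-well fields signal-free (4 channels × 0.2 gives
$P(\text{no signal}) = e^{-0.8} \approx 0.45$), matching the qualitative
behaviour of BSA-passivated control surfaces; it is a realism default, not
a fitted value. Vesicles may overlap — no minimum separation is imposed —
as in dense capture fields.

## Reproducibility model

Every image draws its randomness from a substream seeded by a stable hash
of the global seed, the stage name and the image id
(`substream_seed()`). Consequences: identical configuration and seed give
bit-identical images and truth tables, and *extending* a design (more
images, more conditions) never perturbs existing images. The end-to-end
determinism test compares two complete pipeline runs byte for byte across
all stage outputs; the run manifest is excluded from that comparison
because it records wall-clock timestamps by design.

# Detection

The paper trail of most published spot-detection pipelines is an opaque
script; here detection is specified to be deterministic and to have a
single interpretable sensitivity knob.

1. Robust background: median and MAD × 1.4826 per channel image. These are
   insensitive to sparse spots (tested with 50 spots on a 660² field;
   bias < 2 %).
2. Laplacian-of-Gaussian response at `log_sigma_px` (default 1.5 px,
   matching the rendered PSF), replicate-padded convolution
   (via `EBImage::filter2`).
3. Candidate spots: 8-neighbourhood local maxima of the response with raw
   peak intensity above `mu + k_threshold * sigma` (default `k = 5`).
4. Maxima closer than `min_separation_px` (default 3) merge, keeping the
   brighter peak; exact ties keep the smaller (row, col) — a total order,
   so detection is reproducible to the byte.
5. Sub-pixel centroid: intensity-weighted mean over the
   background-subtracted 3 × 3 neighbourhood.
6. Border policy: centers within `3 * log_sigma_px` of the edge are
   discarded because PSF truncation biases their centroids. On a 660 px
   field this sacrifices ~3 % of the area, which is the dominant recall
   cost in the benchmarks.

Degenerate input: a constant image has `sigma = 0`; if spots are
nevertheless present the threshold falls back to an absolute
`intensity_floor` above background, with a warning.

The detection benchmark (recall and precision ≥ 0.95 at 2 px matching)
runs at a spot SNR of exactly 10, i.e. with `amplitude_sdlog = 0`: the
benchmark measures the detector at a stated SNR, not the mixture of SNRs
that brightness heterogeneity induces. With the default heterogeneity
(sdlog 0.35) about 3.5 % of spots fall below the 5-sigma threshold at mean
SNR 10 — a property of the amplitude distribution, not of the detector.

# Colocalization and phenotyping

Detections of one image are linked across channels by greedy nearest-pair
linkage: all cross-channel pairs within `radius_um` are sorted by distance
and merged in order unless the merged cluster would hold two detections of
one channel. Conflict-free connected components therefore collapse to one
EV record, and components with channel conflicts split at the conflict.
The default radius 0.2 µm is half the PSF FWHM; chromatic offsets are
assumed pre-corrected (the simulator emits aligned channels).

Properties enforced and tested: every detection belongs to exactly one
record; record bitmasks are nonzero; enlarging the radius never increases
the number of records; on 1000 random instances (≤ 8 detections,
3 channels) the greedy partition matches the exhaustive minimum —
fewest clusters, then minimal total intra-cluster distance — in ≥ 95 % of
cases and never violates the constraints. One caveat is inherited from the
linkage rule: in a conflict-free chain `a–b–c` the end members may sit
slightly farther apart than the radius, so the "pairwise member distance
≤ radius" property is approximate for chains.

Counting: any nonzero bitmask counts once; images with zero records keep
explicit all-zero rows (the zero-signal fraction of empty-well controls is
an analysis output, so silently dropping empty images would be a bug, not
an optimization). Two-cluster composition fractions give the first cluster
marker precedence (default CD63 over ANXA5), which makes the two clusters
disjoint and exhaustive over EVs positive for either marker — fractions
sum to 1 by construction. Per-population fold changes use per-image mean
counts with a Haldane–Anscombe pseudocount of 0.5 to tolerate empty
classes; note the pseudocount shrinks programmed ratios at low counts
(a programmed 3× effect with baseline mean 3 reports ≈ 2.7).

# Statistics

- **KS statistic.** $D = \sup_t |F_x(t) - F_y(t)|$ evaluated on the pooled
  support, correct under ties. Verified against exhaustive threshold
  search on 1000 random discrete sample pairs.
- **Bootstrap KS.** Count data are discrete; the classical KS p-value is
  conservative under ties. The null distribution of $D$ is drawn by
  pooled-bootstrap resampling (sizes preserved, replacement, from the
  pooled sample), 10 000 resamples by default.
- **Density-equality permutation test.** Statistic: integrated squared
  difference between Gaussian-kernel density estimates of the two samples
  with one common bandwidth (Silverman's rule on the pooled sample) on a
  common grid (256 points, range padded by 3 bandwidths). Null by label
  permutation, which is exact for exchangeable samples. A pooled sample
  with zero variance is degenerate and returns p = 1 with a warning.
- **Distance covariance.** $n V_n^2$ with
  $V_n^2 = n^{-2}\sum_{ij} A_{ij}B_{ij}$ from double-centered distance
  matrices; verified against the explicit double/triple-sum identity. The
  scaling convention matters when comparing printed values across
  implementations, so it is part of the function contract. The
  independence null resamples one margin with replacement (breaking the
  pairing, keeping the marginal); a permutation option exists as a
  sensitivity check. In the pipeline, within-well independence is tested
  by pairing consecutive images of one condition.
- **Add-one p-values.** Every resampling test reports
  $p = (1 + \#\{stat^* \ge stat\})/(n+1) \in [1/(n+1), 1]$ — never exactly
  zero; "approximately zero" is representable as the floor.
- **Chi-squared composition test.** Two-sample homogeneity on the 2 × 15
  contingency table, no continuity correction; populations with expected
  count < 5 in either row are pooled into a single rest class, and fewer
  than two remaining classes is an error (the data cannot support the
  test). This pooling rule is deliberately simple; with very small
  margins it is aggressive, which is why composition tests should compare
  conditions with at least a few dozen vesicles each.
- **Pearson channel matrix.** Computed on complete per-EV rows: channels
  with a detection contribute the detection's peak intensity, channels
  without one contribute the background-subtracted image intensity at the
  record's consensus position. Zero-variance channels yield `NA` entries,
  reported as missing. Per-population p-values are reported raw; a
  Benjamini–Hochberg adjustment is a one-liner on the output and is left
  to the analyst.

Calibration: under null simulations (equal Poisson counts for KS and the
density test; independent Gaussian pairs for distance covariance), the
empirical type-I error at $\alpha \in \{0.01, 0.05\}$ over 500 repetitions
lies within the 99 % binomial band of $\alpha$, with reduced resample
depths (500/200/300) to keep the suite fast.

# Problem sizes used by the test suite

The validation suite chooses sizes that make each check statistically
meaningful yet quick on one CPU: full-size 660² px fields for the detection
benchmarks (50 fields of 30 spots; 100 blank fields), 400 µm² (200² px)
fields elsewhere; 200-image experiments for mixture- and fold-change
recovery; 448 images per condition for the count-law and median-ratio
designs; 500 repetitions for calibration; and a 4-condition × 12-image
demo for end-to-end byte-level determinism. The same code paths scale to
full-size designs by changing the configuration only.

# Known limitations

- The simulator is a statistical stand-in, not an optical model: no
  evanescent-decay weighting, polarization, photobleaching, drift,
  chromatic offset, or cell-body autofluorescence. Passing tests show the
  analysis chain is correct and calibrated under the stated model, not
  that any particular microscope matches that model.
- Detection equivalence with any specific published pipeline is not
  claimed; the detector here is specified for determinism and
  interpretability.
- The immobilization antibody is metadata, never a phenotype bit;
  capture-bias analyses therefore compare conditions, not bits.
- EV size, cytosolic origin, and uptake/release dynamics are out of scope.
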