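# tirfev

Counting and phenotyping extracellular vesicles (EVs) secreted by single
cells, as measured by four-color total internal reflection fluorescence
microscopy (TIRFM).

## The problem

In single-cell secretion assays, EVs released by one isolated cell are
captured on an antibody-functionalized surface and immunostained against up
to four markers (e.g. CD63, HSP70, TSG101 and Annexin V against
phosphatidylserine). TIRFM excites only fluorophores within ~200 nm of the
glass, so every surface-bound vesicle appears as a diffraction-limited spot
in the channels whose marker it carries. Three analysis questions follow:

1. **Counting** — how many vesicles per imaged field, and does the
   per-field count distribution differ between well conditions (empty
   wells, 1/2/3+ cells, capture antibody, drug treatment)?
2. **Phenotyping** — which of the 2^4 − 1 = 15 nonempty marker
   combinations does each vesicle carry, and how are the 15 populations
   distributed?
3. **Inference** — are two count distributions different, are fields from
   the same well independent, are channel intensities artifactually
   correlated, did a treatment change the population composition?

`tirfev` implements the full pipeline on synthetic, ground-truthed data:

- **simulate** — a forward model of TIRFM fields: Poisson vesicle counts
  per field, phenotypes from a 15-category mixture, log-normal spot
  amplitudes, Gaussian point-spread function (PSF), camera read noise,
  optional Poisson shot noise, and unspecific single-channel background
  adsorption for empty-well controls.
- **detect** — per-channel Laplacian-of-Gaussian blob detection with a
  robust (median/MAD) background threshold `mu + k * sigma`, deterministic
  tie-breaks and sub-pixel centroids.
- **classify** — greedy nearest-pair colocalization of detections across
  channels into single-EV records (at most one detection per channel per
  record), per-image count tables over the 15 populations, two-cluster
  composition fractions and per-population fold changes.
- **test** — the statistical suite: two-sample Kolmogorov–Smirnov (KS)
  statistic `D = sup_t |F_x(t) − F_y(t)|` on the pooled support with a
  pooled-bootstrap null (counts are discrete, so the classical KS p-value
  is conservative), a permutation test of density equality (integrated
  squared difference of common-bandwidth kernel density estimates),
  a distance-covariance independence test with a bootstrap null, Pearson
  channel-correlation matrices, chi-squared homogeneity tests of
  population compositions, and median fold changes. All resampling
  p-values use the add-one estimator `p = (1 + #{stat* ≥ stat}) / (n + 1)`.

## Worked example

Simulate empty wells against single-cell wells, run detection and
colocalization, and compare the per-field count distributions:

```r
library(tirfev)

design <- list(
  list(condition = well_condition("0cell", 0, ev_rate = 0,
                                  background_spot_rate = 0.2), n_images = 60),
  list(condition = well_condition("1cell", 1, ev_rate = 3,
                                  background_spot_rate = 0.2), n_images = 60))
cfg <- imaging_config(field_area_um2 = 400)   # 200 x 200 px demo fields
ds  <- generate_experiment(design, marker_panel(), cfg, seed = 42)

det  <- detect_dataset(ds)
recs <- colocalize_dataset(det)
ct   <- count_evs(recs, ds$metadata)

x <- ct$total[ct$condition == "1cell"]
y <- ct$total[ct$condition == "0cell"]
ks_bootstrap_pvalue(x, y, n_b = 10000, seed = 1)
#> <ev_test> D_KS = 0.716667, p = 9.999e-05 (n = 60/60, 10000 resamples, seed 1)

frequency_distribution(y)$zero_fraction   # empty wells with no signal
#> [1] 0.55
sort(table(recs$bits), decreasing = TRUE)[1:3]
#> 1111 0100 0010
#>   36   33   31
```

The KS statistic 0.72 with a bootstrap p-value at the add-one floor says
the single-cell and empty-well count distributions are clearly different;
55% of empty-well fields show no signal at all (unspecific background
adsorption is sparse); and the quadruple-positive population (`1111`) is
the most frequent detected phenotype, as expected under the default
mixture in which it carries the largest weight.

`run_pipeline(validate_config("cfg.yaml"), "out/")` chains the four stages
from a YAML configuration and writes TIFF images, CSV tables, test results
and a manifest; `inst/scripts/tirfev` wraps the same calls as a shell
command with `simulate` / `detect` / `classify` / `stats` / `run-all`
verbs. Identical configuration and seed reproduce every output byte for
byte.

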