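test_that("phenotype sampling respects degenerate, empty and invalid mixtures", {
  point_mass <- c(rep(0, 14), 1)
  expect_identical(sample_phenotypes(point_mass, 10), rep(15L, 10))
  expect_identical(sample_phenotypes(default_composition(), 0), integer(0))
  expect_error(sample_phenotypes(rep(1 / 14, 14), 5), "length 15")
  expect_error(sample_phenotypes(rep(0.06, 15), 5), "sum to 1")
  expect_error(sample_phenotypes(c(-0.1, 1.1, rep(0, 13)), 5), ">= 0")
})

test_that("uniform mixture sampling passes a chi-squared goodness-of-fit", {
  draws <- withr::with_seed(101, sample_phenotypes(rep(1 / 15, 15), 15000))
  tab <- tabulate(draws, nbins = 15)
  gof <- chisq.test(tab, p = rep(1 / 15, 15))
  expect_gt(gof$p.value, 0.01)
})

test_that("rendering reproduces background, channel structure and the Gaussian integral", {
  cfg <- small_config(background_sd = 0)
  blank <- render_field(empty_truth(), cfg)
  expect_true(all(blank == cfg$background_mean))

  img <- render_field(one_ev_truth(10, 10, bitmask = 1L, amplitude = 100), cfg)
  expect_gt(max(img[, , 1]), cfg$background_mean + 50)
  for (ch in 2:4) expect_true(all(img[, , ch] == cfg$background_mean))

  # off-grid spot: integrated intensity matches A * 2 * pi * sigma_px^2
  img2 <- render_field(one_ev_truth(10.03, 9.97, bitmask = 1L, amplitude = 100), cfg)
  integral <- sum(img2[, , 1] - cfg$background_mean)
  sigma_px <- cfg$psf_sigma_um / cfg$pixel_size_um
  expect_equal(integral, 100 * 2 * pi * sigma_px^2, tolerance = 0.01)

  expect_error(render_field(one_ev_truth(1000, 10, 1L), cfg), "inside the field")
})

test_that("experiment generation follows the Poisson count law", {
  cond <- well_condition("w", 1, ev_rate = 3)
  design <- list(list(condition = cond, n_images = 448))
  ds <- generate_experiment(design, marker_panel(), small_config(),
                            seed = 5, render = FALSE)
  counts <- vapply(ds$truth, function(t) nrow(t$ev), integer(1L))
  se <- sqrt(3 / 448)
  expect_lt(abs(mean(counts) - 3), 3 * se)
  # dispersion index ~ 1 within Monte-Carlo error
  expect_lt(abs(var(counts) / mean(counts) - 1), 3 * sqrt(2 / 447))

  zero <- generate_experiment(
    list(list(condition = well_condition("z", 0, ev_rate = 0), n_images = 20)),
    marker_panel(), small_config(), seed = 5, render = FALSE)
  expect_true(all(vapply(zero$truth, function(t)
    nrow(t$ev) + nrow(t$false_spots), integer(1L)) == 0L))
})

test_that("identical seeds give bit-identical datasets and substreams are stable", {
  cond <- well_condition("w", 1, ev_rate = 4, background_spot_rate = 0.3)
  design <- function(n) list(list(condition = cond, n_images = n))
  a <- generate_experiment(design(3), marker_panel(), small_config(), seed = 9)
  b <- generate_experiment(design(3), marker_panel(), small_config(), seed = 9)
  expect_identical(a$images, b$images)
  expect_identical(a$truth, b$truth)

  # extending the design must not perturb existing images
  c5 <- generate_experiment(design(5), marker_panel(), small_config(), seed = 9)
  expect_identical(a$truth, c5$truth[names(a$truth)])
  expect_identical(a$images, c5$images[names(a$images)])
})

test_that("a channel contains a spot exactly where some EV has its bit set", {
  cfg <- small_config(background_sd = 0, signal_amplitude = 200,
                      amplitude_sdlog = 0)
  cond <- well_condition("w", 1, ev_rate = 6)
  ds <- generate_experiment(list(list(condition = cond, n_images = 4)),
                            marker_panel(), cfg, seed = 21)
  px <- cfg$pixel_size_um
  for (id in ds$metadata$image_id) {
    tr <- ds$truth[[id]]$ev
    img <- ds$images[[id]]
    for (ch in 1:4) {
      has <- which(mask_has(tr$bitmask, ch))
      for (i in seq_len(nrow(tr))) {
        r <- as.integer(round(tr$y_um[i] / px + 0.5))
        c <- as.integer(round(tr$x_um[i] / px + 0.5))
        above <- img[r, c, ch] > cfg$background_mean + 50
        expect_identical(above, i %in% has)
      }
    }
  }
})

test_that("datasets round-trip through the TIFF/CSV layout", {
  cond <- well_condition("w", 2, ev_rate = 5, background_spot_rate = 0.2)
  ds <- generate_experiment(list(list(condition = cond, n_images = 3)),
                            marker_panel(), small_config(), seed = 13)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$metadata$image_id, ds$metadata$image_id)
  expect_equal(back$config$side_px, ds$config$side_px)
  # 16-bit storage quantizes intensities to steps of 1 unit
  id <- ds$metadata$image_id[1]
  expect_lt(max(abs(back$images[[id]] - ds$images[[id]])), 1 + 1e-9)
})
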