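# Synthetic TIRFM forward model. Vesicle counts per field are Poisson,
# phenotypes come from a 15-category mixture, each positive channel gets a
# log-normal amplitude, and fields are rendered as background + Gaussian
# PSF spots + camera noise. Unspecific adsorption is modelled as
# single-channel false spots with their own Poisson rate.

#' Sample phenotypes from a 15-category mixture
#'
#' Draws `n` nonzero 4-bit phenotype bitmasks i.i.d. from a probability
#' vector indexed by bitmask value (entry 1 = mask `0001` = channel 1 only,
#' entry 15 = quadruple positive).
#'
#' @param composition Numeric vector of length 15, entries >= 0 summing to
#'   1 within 1e-9.
#' @param n Number of draws (>= 0).
#' @return Integer vector of `n` bitmasks in 1..15.
#' @examples
#' comp <- c(rep(0, 14), 1)            # point mass on quadruple positive
#' sample_phenotypes(comp, 5)
#' @export
sample_phenotypes <- function(composition, n) {
  composition <- validate_composition(composition)
  n <- check_number(n, "n", 0)
  if (n == 0) return(integer(0))
  sample.int(15L, size = n, replace = TRUE, prob = composition)
}

# Draw log-normal spot amplitudes for one vesicle across the 4 channels,
# optionally with a common pairwise correlation on the log scale.
sample_amplitudes <- function(n, config) {
  sdlog <- config$amplitude_sdlog
  rho <- config$amplitude_correlation
  z <- matrix(rnorm(n * 4L), n, 4L)
  if (rho != 0) {
    sigma <- matrix(rho, 4L, 4L); diag(sigma) <- 1
    z <- z %*% chol(sigma)
  }
  # mean of the log-normal equals signal_amplitude for every channel
  config$signal_amplitude * exp(sdlog * z - sdlog^2 / 2)
}

#' Sample the ground truth of one field
#'
#' Draws the latent content of one image under a [well_condition()]: a
#' Poisson(`ev_rate`) number of true vesicles with mixture phenotypes,
#' uniform positions and per-channel amplitudes, plus Poisson
#' (`background_spot_rate`) unspecific single-channel false spots per
#' channel. Uses the current RNG state; [generate_experiment()] wraps it in
#' per-image substreams.
#'
#' @param condition A [well_condition()].
#' @param config An [imaging_config()].
#' @return A `ground_truth` object: list with data frames `ev`
#'   (`x_um, y_um, bitmask, A1..A4`) and `false_spots`
#'   (`x_um, y_um, channel, amplitude`).
#' @examples
#' set.seed(1)
#' tr <- sample_ground_truth(well_condition("w", 1, ev_rate = 3),
#'                           imaging_config(field_area_um2 = 400))
#' nrow(tr$ev)
#' @export
sample_ground_truth <- function(condition, config) {
  stopifnot(inherits(condition, "well_condition"),
            inherits(config, "imaging_config"))
  side <- config$side_um
  n_ev <- rpois(1L, condition$ev_rate)
  if (n_ev > 0) {
    masks <- sample_phenotypes(condition$composition, n_ev)
    amps <- sample_amplitudes(n_ev, config)
    for (ch in 1:4) amps[!mask_has(masks, ch), ch] <- NA_real_
    ev <- data.frame(x_um = runif(n_ev, 0, side),
                     y_um = runif(n_ev, 0, side),
                     bitmask = masks)
    ev[paste0("A", 1:4)] <- amps
  } else {
    ev <- data.frame(x_um = numeric(0), y_um = numeric(0),
                     bitmask = integer(0))
    for (nm in paste0("A", 1:4)) ev[[nm]] <- numeric(0)
  }
  fs <- lapply(1:4, function(ch) {
    k <- rpois(1L, condition$background_spot_rate)
    if (k == 0) return(NULL)
    data.frame(x_um = runif(k, 0, side), y_um = runif(k, 0, side),
               channel = ch,
               amplitude = sample_amplitudes(k, config)[cbind(seq_len(k), ch)])
  })
  fs <- do.call(rbind, fs[!vapply(fs, is.null, logical(1L))])
  if (is.null(fs))
    fs <- data.frame(x_um = numeric(0), y_um = numeric(0),
                     channel = integer(0), amplitude = numeric(0))
  structure(list(ev = ev, false_spots = fs), class = "ground_truth")
}

# Accumulate one Gaussian PSF spot onto an image matrix (in place value
# semantics: returns the updated matrix). Pixel (r, c) center sits at
# ((c - 0.5) * px, (r - 0.5) * px).
add_spot <- function(img, x_um, y_um, amplitude, sigma_um, pixel_um) {
  side <- nrow(img)
  r_px <- ceiling(6 * sigma_um / pixel_um)        # 6 sigma window, <0.01% lost
  c0 <- x_um / pixel_um + 0.5
  r0 <- y_um / pixel_um + 0.5
  cc <- max(1L, floor(c0 - r_px)):min(side, ceiling(c0 + r_px))
  rr <- max(1L, floor(r0 - r_px)):min(side, ceiling(r0 + r_px))
  xs <- (cc - 0.5) * pixel_um
  ys <- (rr - 0.5) * pixel_um
  g <- amplitude * exp(-outer((ys - y_um)^2, (xs - x_um)^2, "+") / (2 * sigma_um^2))
  img[rr, cc] <- img[rr, cc] + g
  img
}

#' Render a four-channel field image from ground truth
#'
#' For every channel the noise-free signal is the sum of Gaussian spots
#' (standard deviation `psf_sigma_um`) at the positions of the vesicles
#' whose bitmask has that channel set, plus that channel's false spots.
#' Optional Poisson shot noise is applied to the signal, then the camera
#' background mean and Gaussian read noise are added; pixel values are
#' clamped at zero. Uses the current RNG state.
#'
#' @param truth A `ground_truth` object from [sample_ground_truth()].
#' @param config An [imaging_config()].
#' @return A `side_px` x `side_px` x 4 numeric array (intensity units).
#' @examples
#' cfg <- imaging_config(field_area_um2 = 400, background_sd = 0)
#' tr <- structure(list(ev = data.frame(x_um = 10, y_um = 10, bitmask = 1L,
#'                                      A1 = 100, A2 = NA, A3 = NA, A4 = NA),
#'                      false_spots = data.frame(x_um = numeric(0), y_um = numeric(0),
#'                                               channel = integer(0),
#'                                               amplitude = numeric(0))),
#'                 class = "ground_truth")
#' img <- render_field(tr, cfg)
#' which(img[, , 1] == max(img[, , 1]), arr.ind = TRUE)  # row 100, col 100
#' @export
render_field <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "imaging_config"))
  side <- config$side_px
  pos <- rbind(truth$ev[c("x_um", "y_um")], truth$false_spots[c("x_um", "y_um")])
  if (nrow(pos) && (any(pos < 0) || any(pos > config$side_um)))
    stop_field("truth", "emitter positions must lie inside the field")
  out <- array(0, dim = c(side, side, 4L))
  for (ch in 1:4) {
    sig <- matrix(0, side, side)
    if (nrow(truth$ev)) {
      sel <- which(mask_has(truth$ev$bitmask, ch))
      for (i in sel)
        sig <- add_spot(sig, truth$ev$x_um[i], truth$ev$y_um[i],
                        truth$ev[[paste0("A", ch)]][i],
                        config$psf_sigma_um, config$pixel_size_um)
    }
    fsel <- which(truth$false_spots$channel == ch)
    for (i in fsel)
      sig <- add_spot(sig, truth$false_spots$x_um[i], truth$false_spots$y_um[i],
                      truth$false_spots$amplitude[i],
                      config$psf_sigma_um, config$pixel_size_um)
    if (config$photon_noise)
      sig <- matrix(rpois(length(sig), sig), side, side)
    img <- sig + config$background_mean
    if (config$background_sd > 0)
      img <- img + rnorm(length(img), 0, config$background_sd)
    out[, , ch] <- pmax(img, 0)
  }
  out
}

#' Generate a full synthetic experiment
#'
#' Draws and (optionally) renders every image of a multi-condition design.
#' Each image gets its own RNG substream derived from the global seed and
#' the image id ([substream_seed()]), so the dataset is bit-reproducible and
#' adding conditions or images never perturbs existing ones.
#'
#' @param conditions List of design entries, each a list with elements
#'   `condition` (a [well_condition()]) and `n_images` (>= 1).
#' @param panel A [marker_panel()].
#' @param config An [imaging_config()].
#' @param seed Integer global seed.
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   and metadata only (fast path for count-level studies).
#' @return An `ev_dataset`: list with `images` (named list of arrays or
#'   `NULL`s), `truth` (named list of `ground_truth`), `metadata` (one row
#'   per image: `image_id, well_id, condition, n_cells, treatment,
#'   immobilization_marker`), plus `panel`, `config`, `seed`.
#' @examples
#' design <- list(list(condition = well_condition("1cell", 1, ev_rate = 3),
#'                     n_images = 4))
#' ds <- generate_experiment(design, marker_panel(),
#'                           imaging_config(field_area_um2 = 400), seed = 7)
#' ds$metadata$image_id
#' @export
generate_experiment <- function(conditions, panel, config, seed, render = TRUE) {
  stopifnot(inherits(panel, "marker_panel"), inherits(config, "imaging_config"))
  if (!length(conditions)) stop_field("conditions", "at least one condition required")
  for (i in seq_along(conditions)) {
    entry <- conditions[[i]]
    if (!inherits(entry$condition, "well_condition"))
      stop_field(sprintf("conditions[[%d]]$condition", i),
                 "must be a well_condition")
    if (is.null(entry$n_images) || entry$n_images < 1)
      stop_field(sprintf("conditions[[%d]]$n_images", i), "must be >= 1")
  }
  seed <- check_number(seed, "seed")
  images <- list(); truth <- list(); meta <- list()
  for (entry in conditions) {
    cond <- entry$condition
    for (j in seq_len(entry$n_images)) {
      image_id <- sprintf("%s_%04d", cond$name, j)
      sub <- substream_seed(seed, "simulate", image_id)
      res <- withr::with_seed(sub, {
        tr <- sample_ground_truth(cond, config)
        img <- if (render) render_field(tr, config) else NULL
        list(tr = tr, img = img)
      })
      truth[[image_id]] <- res$tr
      images[[image_id]] <- res$img
      meta[[image_id]] <- data.frame(image_id = image_id, well_id = image_id,
                                     condition = cond$name,
                                     n_cells = cond$n_cells,
                                     treatment = cond$treatment,
                                     immobilization_marker = cond$immobilization_marker,
                                     stringsAsFactors = FALSE)
    }
  }
  structure(list(images = if (render) images else NULL,
                 truth = truth,
                 metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                 panel = panel, config = config, seed = seed),
            class = "ev_dataset")
}

#' Tabulate ground-truth EV counts per image
#'
#' Builds the same per-image count table as [count_evs()], but from the
#' simulator's ground truth (true vesicles only; unspecific false spots are
#' not EVs). Useful as the reference when validating detection and
#' classification.
#'
#' @param dataset An `ev_dataset` from [generate_experiment()].
#' @return A data frame with one row per image: metadata columns, `total`,
#'   and the 15 `pop_<bits>` columns in [enumerate_populations()] order.
#' @examples
#' design <- list(list(condition = well_condition("w", 1, ev_rate = 2), n_images = 3))
#' ds <- generate_experiment(design, marker_panel(),
#'                           imaging_config(field_area_um2 = 400),
#'                           seed = 1, render = FALSE)
#' truth_count_table(ds)$total
#' @export
truth_count_table <- function(dataset) {
  stopifnot(inherits(dataset, "ev_dataset"))
  pops <- enumerate_populations(4)
  cols <- population_columns()
  rows <- lapply(dataset$metadata$image_id, function(id) {
    masks <- dataset$truth[[id]]$ev$bitmask
    counts <- vapply(pops$bitmask, function(m) sum(masks == m), integer(1L))
    out <- data.frame(total = length(masks))
    out[cols] <- as.list(counts)
    out
  })
  cbind(dataset$metadata, do.call(rbind, rows), row.names = NULL)
}

#' Write a dataset to disk
#'
#' Writes the on-disk layout consumed by the detection stage: one 16-bit
#' multi-page TIFF per image (one page per channel, panel order) under
#' `images/`, `metadata.csv`, `ground_truth.csv` (true EVs and false spots,
#' distinguished by a `kind` column) and `dataset.yaml` with the imaging
#' configuration, panel and seed. Intensities are stored as
#' `value / 65535`, clipped to `[0, 1]`.
#'
#' @param dataset An `ev_dataset` with rendered images.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ev_dataset"))
  if (is.null(dataset$images)) stop_field("dataset", "contains no rendered images")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$images)) {
    img <- dataset$images[[id]]
    pages <- lapply(1:4, function(ch) pmin(pmax(img[, , ch] / 65535, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, "images", paste0(id, ".tif")),
                    bits.per.sample = 16L)
  }
  write.csv(dataset$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  gt <- lapply(names(dataset$truth), function(id) {
    tr <- dataset$truth[[id]]
    ev <- tr$ev
    a <- if (nrow(ev))
      data.frame(image_id = id, kind = "ev", x_um = ev$x_um, y_um = ev$y_um,
                 bitmask = mask_bits(ev$bitmask),
                 A1 = ev$A1, A2 = ev$A2, A3 = ev$A3, A4 = ev$A4,
                 stringsAsFactors = FALSE)
    fs <- tr$false_spots
    b <- if (nrow(fs)) {
      amp <- matrix(NA_real_, nrow(fs), 4L)
      amp[cbind(seq_len(nrow(fs)), fs$channel)] <- fs$amplitude
      data.frame(image_id = id, kind = "false_spot", x_um = fs$x_um,
                 y_um = fs$y_um, bitmask = mask_bits(2L^(fs$channel - 1L)),
                 A1 = amp[, 1], A2 = amp[, 2], A3 = amp[, 3], A4 = amp[, 4],
                 stringsAsFactors = FALSE)
    }
    rbind(a, b)
  })
  gt <- do.call(rbind, gt)
  if (is.null(gt))
    gt <- data.frame(image_id = character(0), kind = character(0),
                     x_um = numeric(0), y_um = numeric(0), bitmask = character(0),
                     A1 = numeric(0), A2 = numeric(0), A3 = numeric(0),
                     A4 = numeric(0))
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cfg <- unclass(dataset$config)
  yaml::write_yaml(list(config = cfg[setdiff(names(cfg), c("side_px", "side_um"))],
                        panel = unclass(dataset$panel),
                        seed = dataset$seed),
                   file.path(dir, "dataset.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `images/`, `metadata.csv` and
#'   `dataset.yaml` (and optionally `ground_truth.csv`).
#' @return An `ev_dataset` (truth omitted when no ground-truth file exists,
#'   as for real microscopy data laid out in the same format).
#' @export
read_dataset <- function(dir) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  y <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  config <- do.call(imaging_config, y$config)
  panel <- marker_panel(stain_markers = y$panel$stain_markers,
                        immobilization_marker = y$panel$immobilization_marker)
  images <- lapply(meta$image_id, function(id) {
    pages <- tiff::readTIFF(file.path(dir, "images", paste0(id, ".tif")), all = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (ch in seq_along(pages)) arr[, , ch] <- pages[[ch]] * 65535
    arr
  })
  names(images) <- meta$image_id
  structure(list(images = images, truth = NULL, metadata = meta,
                 panel = panel, config = config, seed = y$seed),
            class = "ev_dataset")
}
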