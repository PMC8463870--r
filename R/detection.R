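# Per-channel spot detection: Laplacian-of-Gaussian blob filtering with a
# robust background-referenced intensity threshold. Deterministic by
# construction (no RNG); candidate ordering and tie-breaks define a total
# order so identical inputs give identical outputs.

#' Robust background estimate of one channel image
#'
#' Median and scaled median absolute deviation (MAD, consistency constant
#' 1.4826), which are insensitive to the sparse bright spots sitting on the
#' background.
#'
#' @param channel_image Numeric matrix.
#' @return List with `mu_bg`, `sigma_bg` and `constant` (`TRUE` when the
#'   image has zero robust spread, e.g. a constant image).
#' @examples
#' estimate_background(matrix(100, 64, 64))
#' @export
estimate_background <- function(channel_image) {
  if (!is.matrix(channel_image) || !length(channel_image))
    stop_field("channel_image", "must be a nonempty numeric matrix")
  mu <- median(channel_image)
  sigma <- mad(channel_image, center = mu)
  list(mu_bg = mu, sigma_bg = sigma, constant = sigma == 0)
}

# Zero-mean scale-normalized LoG kernel, sign-flipped so bright blobs give
# positive responses.
log_kernel <- function(sigma_px) {
  r <- ceiling(4 * sigma_px)
  d2 <- outer((-r:r)^2, (-r:r)^2, "+")
  k <- (1 - d2 / (2 * sigma_px^2)) * exp(-d2 / (2 * sigma_px^2))
  k - mean(k)
}

#' Detect diffraction-limited spots in one channel image
#'
#' Computes the Laplacian-of-Gaussian response at scale `log_sigma_px`
#' (replicate-padded convolution), takes local maxima of the response whose
#' raw pixel intensity exceeds `mu_bg + k_threshold * sigma_bg` (robust
#' background statistics from [estimate_background()]), merges maxima closer
#' than `min_separation_px` keeping the brighter one (ties: smaller row,
#' then column), refines each surviving peak to a sub-pixel centroid by
#' intensity-weighted averaging over its background-subtracted 3x3
#' neighbourhood, and discards centers within `3 * log_sigma_px` of the
#' image border (PSF truncation makes those centroids unreliable).
#'
#' If the robust background SD is zero while spots are present, the
#' threshold falls back to `mu_bg + intensity_floor` with a warning.
#'
#' @param channel_image Numeric matrix in intensity units.
#' @param params A [detection_params()].
#' @param pixel_size_um Pixel pitch used to report micrometer coordinates.
#' @param image_id,channel Identifiers copied into the output rows.
#' @return A data frame of detections ordered by decreasing peak intensity
#'   (ties row-major): `image_id, channel, x_um, y_um, peak_intensity,
#'   background_local`.
#' @examples
#' cfg <- imaging_config(field_area_um2 = 400, background_sd = 5)
#' set.seed(2)
#' tr <- sample_ground_truth(well_condition("w", 1, ev_rate = 5), cfg)
#' img <- render_field(tr, cfg)
#' nrow(detect_spots(img[, , 4], detection_params(), cfg$pixel_size_um))
#' @export
detect_spots <- function(channel_image, params = detection_params(),
                         pixel_size_um = 0.1, image_id = "", channel = NA_integer_) {
  stopifnot(inherits(params, "detection_params"))
  bg <- estimate_background(channel_image)
  if (bg$constant) {
    threshold <- bg$mu_bg + params$intensity_floor
    if (any(channel_image > threshold))
      warning("zero robust background SD with spots present; ",
              "falling back to the absolute intensity floor")
  } else {
    threshold <- bg$mu_bg + params$k_threshold * bg$sigma_bg
  }
  side_r <- nrow(channel_image); side_c <- ncol(channel_image)
  resp <- EBImage::filter2(channel_image, log_kernel(params$log_sigma_px),
                           boundary = "replicate")
  # local maxima of the response on the 8-neighbourhood (plateaus yield
  # multiple candidates; the min-separation merge collapses them)
  is_max <- matrix(FALSE, side_r, side_c)
  inner_r <- 2:(side_r - 1L); inner_c <- 2:(side_c - 1L)
  m <- resp[inner_r, inner_c]
  is_max[inner_r, inner_c] <-
    m >= resp[inner_r - 1L, inner_c - 1L] & m >= resp[inner_r - 1L, inner_c] &
    m >= resp[inner_r - 1L, inner_c + 1L] & m >= resp[inner_r, inner_c - 1L] &
    m >= resp[inner_r, inner_c + 1L] & m >= resp[inner_r + 1L, inner_c - 1L] &
    m >= resp[inner_r + 1L, inner_c] & m >= resp[inner_r + 1L, inner_c + 1L] &
    m > 0
  cand <- which(is_max & channel_image > threshold, arr.ind = TRUE)
  border <- ceiling(3 * params$log_sigma_px)
  if (nrow(cand)) {
    keep_b <- cand[, 1] > border & cand[, 1] <= side_r - border &
      cand[, 2] > border & cand[, 2] <= side_c - border
    cand <- cand[keep_b, , drop = FALSE]
  }
  empty <- data.frame(image_id = character(0), channel = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      peak_intensity = numeric(0), background_local = numeric(0))
  if (!nrow(cand)) return(empty)

  peaks <- channel_image[cand]
  ord <- order(-peaks, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; peaks <- peaks[ord]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(kept)) { kept[i] <- TRUE; next }
    d2 <- (cand[kept, 1] - cand[i, 1])^2 + (cand[kept, 2] - cand[i, 2])^2
    if (min(d2) >= params$min_separation_px^2) kept[i] <- TRUE
  }
  cand <- cand[kept, , drop = FALSE]; peaks <- peaks[kept]

  n <- nrow(cand)
  x_um <- numeric(n); y_um <- numeric(n); bg_local <- numeric(n)
  for (i in seq_len(n)) {
    r <- cand[i, 1]; c <- cand[i, 2]
    win <- pmax(channel_image[(r - 1):(r + 1), (c - 1):(c + 1)] - bg$mu_bg, 0)
    w <- sum(win)
    dr <- if (w > 0) sum(win * (-1:1)) / w else 0      # row offset
    dc <- if (w > 0) sum(t(win) * (-1:1)) / w else 0   # col offset
    x_um[i] <- (c - 0.5 + dc) * pixel_size_um
    y_um[i] <- (r - 0.5 + dr) * pixel_size_um
    # local background: median over the ring of a (2h+1)-pixel window
    h <- border + 2L
    rr <- max(1L, r - h):min(side_r, r + h)
    cc <- max(1L, c - h):min(side_c, c + h)
    ring <- channel_image[rr, cc]
    inner <- outer(abs(rr - r) <= 1L, abs(cc - c) <= 1L, "&")
    bg_local[i] <- median(ring[!inner])
  }
  data.frame(image_id = image_id, channel = as.integer(channel),
             x_um = x_um, y_um = y_um,
             peak_intensity = peaks, background_local = bg_local,
             stringsAsFactors = FALSE)
}

#' Detect spots in every channel of every image of a dataset
#'
#' @param dataset An `ev_dataset` with rendered images (or one read back by
#'   [read_dataset()]).
#' @param params A [detection_params()].
#' @return A data frame of detections across all images and channels.
#' @examples
#' design <- list(list(condition = well_condition("w", 1, ev_rate = 3), n_images = 2))
#' ds <- generate_experiment(design, marker_panel(),
#'                           imaging_config(field_area_um2 = 400), seed = 3)
#' head(detect_dataset(ds))
#' @export
detect_dataset <- function(dataset, params = detection_params()) {
  stopifnot(inherits(dataset, "ev_dataset"))
  if (is.null(dataset$images)) stop_field("dataset", "contains no rendered images")
  px <- dataset$config$pixel_size_um
  out <- lapply(dataset$metadata$image_id, function(id) {
    img <- dataset$images[[id]]
    do.call(rbind, lapply(1:4, function(ch)
      detect_spots(img[, , ch], params, px, image_id = id, channel = ch)))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
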