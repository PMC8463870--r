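#' Imaging configuration for synthetic TIRFM fields
#'
#' Describes the optical and camera model used by [render_field()] and
#' assumed by [detect_spots()]. All simulated vesicles are surface-bound
#' within the evanescent excitation layer and hence rendered in focus;
#' `evanescent_depth_nm` is retained as documentation of that assumption.
#'
#' @param field_area_um2 Area of one imaged region in square micrometers.
#'   The default 4356 corresponds to a 66 um x 66 um field.
#' @param pixel_size_um Physical pixel pitch in micrometers (default 0.1,
#'   typical EMCCD-TIRF sampling; the side length in pixels is
#'   `round(sqrt(field_area_um2) / pixel_size_um)` and must be >= 64).
#' @param psf_sigma_um Standard deviation of the 2-D Gaussian point spread
#'   function, micrometers. Sub-diffraction vesicles are point emitters, so
#'   one sigma for all channels. Must be >= `pixel_size_um` so that spots
#'   span more than one pixel.
#' @param background_mean,background_sd Camera background level and Gaussian
#'   read-noise standard deviation, intensity units.
#' @param photon_noise If `TRUE`, Poisson shot noise is applied to the
#'   signal component before read noise is added.
#' @param signal_amplitude Mean spot amplitude (peak height) in intensity
#'   units. The default 100 with `background_sd = 10` gives a peak
#'   signal-to-noise ratio of 10.
#' @param amplitude_sdlog Log-scale standard deviation of the per-channel
#'   log-normal amplitude distribution (brightness heterogeneity).
#' @param amplitude_correlation Common pairwise correlation of log
#'   amplitudes across channels of one vesicle. 0 (default) keeps channels
#'   independent so that the Pearson correlation matrix has a clean null;
#'   positive values provide a dependence positive control.
#' @param evanescent_depth_nm Evanescent field depth, nanometers
#'   (documentation only; default 200).
#' @param channel_names Ordered channel labels (length 4 by default).
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `imaging_config` (a validated list, with
#'   derived elements `side_px` and `side_um`).
#' @examples
#' cfg <- imaging_config(field_area_um2 = 400, pixel_size_um = 0.1)
#' cfg$side_px
#' @export
imaging_config <- function(field_area_um2 = 4356,
                           pixel_size_um = 0.1,
                           psf_sigma_um = 0.15,
                           background_mean = 100,
                           background_sd = 10,
                           photon_noise = FALSE,
                           signal_amplitude = 100,
                           amplitude_sdlog = 0.35,
                           amplitude_correlation = 0,
                           evanescent_depth_nm = 200,
                           channel_names = c("ch405", "ch488", "ch561", "ch640"),
                           seed = NULL) {
  check_number(field_area_um2, "field_area_um2", 0, strict = TRUE)
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  check_number(psf_sigma_um, "psf_sigma_um", 0, strict = TRUE)
  if (psf_sigma_um < pixel_size_um)
    stop_field("psf_sigma_um",
               "must be >= pixel_size_um so spots span more than one pixel")
  check_number(background_mean, "background_mean", 0)
  check_number(background_sd, "background_sd", 0)
  check_flag(photon_noise, "photon_noise")
  check_number(signal_amplitude, "signal_amplitude", 0, strict = TRUE)
  check_number(amplitude_sdlog, "amplitude_sdlog", 0)
  check_number(amplitude_correlation, "amplitude_correlation", -1)
  if (amplitude_correlation > 1)
    stop_field("amplitude_correlation", "must lie in [-1, 1]")
  check_number(evanescent_depth_nm, "evanescent_depth_nm", 0, strict = TRUE)
  side_px <- as.integer(round(sqrt(field_area_um2) / pixel_size_um))
  if (side_px < 64L)
    stop_field("field_area_um2/pixel_size_um",
               sprintf("image side length %d px is below the minimum of 64",
                       side_px))
  cfg <- list(field_area_um2 = field_area_um2,
              pixel_size_um = pixel_size_um,
              psf_sigma_um = psf_sigma_um,
              background_mean = background_mean,
              background_sd = background_sd,
              photon_noise = photon_noise,
              signal_amplitude = signal_amplitude,
              amplitude_sdlog = amplitude_sdlog,
              amplitude_correlation = amplitude_correlation,
              evanescent_depth_nm = evanescent_depth_nm,
              channel_names = as.character(channel_names),
              seed = seed,
              side_px = side_px,
              side_um = side_px * pixel_size_um)
  class(cfg) <- "imaging_config"
  cfg
}

#' Marker panel: immobilization antibody plus four stain channels
#'
#' A panel couples the surface-capture (immobilization) antibody with the
#' ordered four-marker stain set that defines the phenotype bit order.
#' Bit \eqn{i} of a phenotype bitmask refers to `stain_markers[i]`. The
#' immobilization marker may also appear among the stains (capturing with
#' anti-CD63 while staining CD63 is a legitimate design).
#'
#' @param stain_markers Character vector of exactly 4 unique marker names,
#'   in channel order (e.g. 405, 488, 561, 640 nm excitation).
#' @param immobilization_marker Name of the capture antibody target.
#' @return An object of class `marker_panel`.
#' @examples
#' marker_panel()                      # CD81 capture, CD63/HSP70/TSG101/ANXA5 stains
#' gw4869_panel()                      # CD63 capture, CD81/STAM1/TSG101/ANXA5 stains
#' @export
marker_panel <- function(stain_markers = c("CD63", "HSP70", "TSG101", "ANXA5"),
                         immobilization_marker = "CD81") {
  stain_markers <- as.character(stain_markers)
  if (length(stain_markers) != 4L)
    stop_field("stain_markers", sprintf("exactly 4 stain markers required (got %d)",
                                        length(stain_markers)))
  if (anyDuplicated(stain_markers))
    stop_field("stain_markers", "marker names must be unique")
  if (!is.character(immobilization_marker) || length(immobilization_marker) != 1L ||
      !nzchar(immobilization_marker))
    stop_field("immobilization_marker", "must be a single non-empty string")
  structure(list(stain_markers = stain_markers,
                 immobilization_marker = immobilization_marker),
            class = "marker_panel")
}

#' @rdname marker_panel
#' @export
gw4869_panel <- function() {
  marker_panel(stain_markers = c("CD81", "STAM1", "TSG101", "ANXA5"),
               immobilization_marker = "CD63")
}

#' Default phenotype composition
#'
#' A 15-probability vector indexed by bitmask value 1..15 (bit 1 = first
#' stain marker). The quadruple-positive class carries the largest weight,
#' followed by triple-, double- and single-positive classes, reflecting the
#' heterogeneous but all-marker-dominated mixtures seen in surface-captured
#' EV preparations.
#'
#' @return Numeric vector of length 15 summing to 1, named by bit pattern.
#' @examples
#' default_composition()[15]  # quadruple-positive weight
#' @export
default_composition <- function() {
  pc <- mask_popcount(1:15)
  w <- c(`1` = 0.04, `2` = 0.04, `3` = 0.075, `4` = 0.30)[as.character(pc)]
  w <- unname(w)
  stopifnot(abs(sum(w) - 1) < 1e-12)
  names(w) <- mask_bits(1:15)
  w
}

#' Experimental condition of one well class
#'
#' Bundles the design parameters of one class of wells: cell occupancy,
#' treatment, capture antibody, the expected number of genuinely secreted
#' vesicles per imaged field, the per-channel rate of unspecific background
#' spots (empty-well adsorption), and the 15-category phenotype mixture.
#'
#' @param name Condition label used in metadata and comparisons.
#' @param n_cells Integer cell-occupancy class: 0, 1, 2, or 3 (meaning
#'   "3 or more").
#' @param ev_rate Expected number of true EVs per image (Poisson mean).
#' @param background_spot_rate Expected unspecific single-channel false
#'   spots per image per channel (Poisson mean).
#' @param composition Probability vector of length 15 over the nonzero
#'   phenotype bitmasks (index = bitmask value); must sum to 1 within 1e-9.
#' @param treatment `"none"` or `"GW4869"`.
#' @param immobilization_marker Capture antibody name.
#' @return An object of class `well_condition`.
#' @examples
#' well_condition("1cell", n_cells = 1, ev_rate = 3)
#' @export
well_condition <- function(name,
                           n_cells,
                           ev_rate,
                           background_spot_rate = 0,
                           composition = default_composition(),
                           treatment = c("none", "GW4869"),
                           immobilization_marker = "CD81") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_field("name", "must be a single non-empty string")
  if (!n_cells %in% 0:3)
    stop_field("n_cells", "must be 0, 1, 2 or 3 (3 meaning '3 or more')")
  check_number(ev_rate, "ev_rate", 0)
  check_number(background_spot_rate, "background_spot_rate", 0)
  treatment <- match.arg(treatment)
  composition <- validate_composition(composition)
  structure(list(name = name,
                 n_cells = as.integer(n_cells),
                 treatment = treatment,
                 immobilization_marker = immobilization_marker,
                 ev_rate = ev_rate,
                 background_spot_rate = background_spot_rate,
                 composition = composition),
            class = "well_condition")
}

validate_composition <- function(composition, field = "composition") {
  if (!is.numeric(composition) || length(composition) != 15L)
    stop_field(field, sprintf("must be a numeric vector of length 15 (got length %d)",
                              length(composition)))
  if (any(!is.finite(composition)) || any(composition < 0))
    stop_field(field, "entries must be finite and >= 0")
  s <- sum(composition)
  if (abs(s - 1) > 1e-9)
    stop_field(field, sprintf("must sum to 1 within 1e-9 (sum = %.10g)", s))
  composition <- as.numeric(composition)
  names(composition) <- mask_bits(1:15)
  composition
}

#' Spot detection parameters
#'
#' @param log_sigma_px Scale of the Laplacian-of-Gaussian blob filter in
#'   pixels; match it to the rendered PSF sigma (default 1.5 px = 0.15 um at
#'   0.1 um pixels).
#' @param k_threshold Detection threshold in units of robust background
#'   standard deviations above the robust background mean (default 5).
#' @param min_separation_px Minimum distance between accepted maxima;
#'   closer maxima are merged keeping the brighter one.
#' @param intensity_floor Absolute threshold above background used only
#'   when the robust background SD collapses to zero (constant image with
#'   isolated spots).
#' @return An object of class `detection_params`.
#' @examples
#' detection_params(k_threshold = 4)
#' @export
detection_params <- function(log_sigma_px = 1.5,
                             k_threshold = 5,
                             min_separation_px = 3,
                             intensity_floor = 10) {
  check_number(log_sigma_px, "log_sigma_px", 0, strict = TRUE)
  check_number(k_threshold, "k_threshold", 0, strict = TRUE)
  check_number(min_separation_px, "min_separation_px", 1)
  check_number(intensity_floor, "intensity_floor", 0, strict = TRUE)
  structure(list(log_sigma_px = log_sigma_px,
                 k_threshold = k_threshold,
                 min_separation_px = min_separation_px,
                 intensity_floor = intensity_floor),
            class = "detection_params")
}

#' @export
print.imaging_config <- function(x, ...) {
  cat(sprintf("<imaging_config> %d x %d px (%.0f um^2), pixel %.3g um, PSF sigma %.3g um\n",
              x$side_px, x$side_px, x$field_area_um2, x$pixel_size_um, x$psf_sigma_um))
  cat(sprintf("  background %.4g +/- %.4g, amplitude %.4g (sdlog %.3g), photon noise %s\n",
              x$background_mean, x$background_sd, x$signal_amplitude,
              x$amplitude_sdlog, x$photon_noise))
  invisible(x)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> capture %s; stains %s\n",
              x$immobilization_marker, paste(x$stain_markers, collapse = ", ")))
  invisible(x)
}

#' @export
print.well_condition <- function(x, ...) {
  cat(sprintf("<well_condition> %s: %d cell(s), %s, capture %s, ev_rate %.3g, bg spot rate %.3g\n",
              x$name, x$n_cells, x$treatment, x$immobilization_marker,
              x$ev_rate, x$background_spot_rate))
  invisible(x)
}
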