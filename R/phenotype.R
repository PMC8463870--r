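# Phenotype bitmask utilities. A phenotype is an integer bitmask over the
# stain channels: bit i (value 2^(i-1)) set means the EV tested positive in
# channel i of the panel. Mask 0 is "no marker" and is never a counted EV.

#' Bitmask helpers
#'
#' `mask_popcount()` counts set bits; `mask_bits()` renders a mask as a bit
#' string with channel 1 first (mask 1 -> `"1000"`); `bits_to_mask()`
#' inverts that; `mask_has()` tests a single channel bit.
#'
#' @param mask Integer vector of bitmasks (0..2^n_channels - 1).
#' @param bits Character vector of bit strings such as `"1010"`.
#' @param channel Channel index (1-based).
#' @param n_channels Number of stain channels (default 4).
#' @return Integer, character or logical vector matching the input length.
#' @examples
#' mask_popcount(0:15)
#' mask_bits(c(1, 6, 15))
#' bits_to_mask("1010")
#' @export
mask_popcount <- function(mask, n_channels = 4L) {
  vapply(as.integer(mask),
         function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n_channels - 1L))) > 0L),
         integer(1L))
}

#' @rdname mask_popcount
#' @export
mask_bits <- function(mask, n_channels = 4L) {
  vapply(as.integer(mask), function(m) {
    paste(ifelse(bitwAnd(m, bitwShiftL(1L, 0:(n_channels - 1L))) > 0L, "1", "0"),
          collapse = "")
  }, character(1L))
}

#' @rdname mask_popcount
#' @export
bits_to_mask <- function(bits) {
  vapply(as.character(bits), function(b) {
    v <- as.integer(strsplit(b, "")[[1]])
    as.integer(sum(v * 2L^(seq_along(v) - 1L)))
  }, integer(1L), USE.NAMES = FALSE)
}

#' @rdname mask_popcount
#' @export
mask_has <- function(mask, channel) {
  bitwAnd(as.integer(mask), bitwShiftL(1L, as.integer(channel) - 1L)) > 0L
}

#' Canonical phenotype label
#'
#' Builds labels such as `"CD63+HSP70+TSG101+ANXA5+"` from a bitmask: the
#' positive markers in panel (channel) order, each suffixed with `"+"`.
#'
#' @param mask Integer vector of nonzero bitmasks.
#' @param panel A [marker_panel()].
#' @return Character vector of labels.
#' @examples
#' mask_label(15, marker_panel())
#' mask_label(bits_to_mask("1001"), marker_panel())
#' @export
mask_label <- function(mask, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  vapply(as.integer(mask), function(m) {
    set <- bitwAnd(m, bitwShiftL(1L, 0:3)) > 0L
    paste0(paste0(panel$stain_markers[set], "+"), collapse = "")
  }, character(1L))
}

#' Enumerate the phenotype populations of a panel
#'
#' All nonzero bitmasks over the stain channels, ordered by the number of
#' positive markers (descending) and then by bitmask value (descending), so
#' the quadruple-positive class comes first. A 4-marker panel yields
#' \eqn{2^4 - 1 = 15} populations; the routine generalizes to any number of
#' markers for hypothetical panels.
#'
#' @param panel A [marker_panel()], or an integer number of markers.
#' @return A data frame with columns `bitmask`, `bits`, `n_markers` and
#'   (when a panel is given) `label`.
#' @examples
#' nrow(enumerate_populations(marker_panel()))  # 15
#' enumerate_populations(2)                     # 3 populations
#' @export
enumerate_populations <- function(panel = marker_panel()) {
  if (is.numeric(panel)) {
    k <- as.integer(panel)
    if (k < 1L) stop_field("panel", "number of markers must be >= 1")
    pan <- NULL
  } else {
    stopifnot(inherits(panel, "marker_panel"))
    k <- length(panel$stain_markers)
    pan <- panel
  }
  masks <- seq_len(2L^k - 1L)
  pc <- mask_popcount(masks, n_channels = k)
  ord <- order(-pc, -masks)
  out <- data.frame(bitmask = masks[ord],
                    bits = mask_bits(masks[ord], n_channels = k),
                    n_markers = pc[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(pan)) out$label <- mask_label(out$bitmask, pan)
  out
}

# Column names used for per-population counts in count tables,
# in enumerate_populations() order.
population_columns <- function() {
  paste0("pop_", enumerate_populations(4)$bits)
}
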