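# Cross-channel colocalization of detections into single-EV records and
# per-image tabulation of the 15 phenotype populations.

#' Colocalize per-channel detections into single-EV records
#'
#' Links detections of one image across channels: every cross-channel pair
#' of detections within `radius_um` is a candidate link; pairs are visited
#' in order of increasing distance and their clusters merged whenever the
#' union still holds at most one detection per channel (greedy nearest-pair
#' linkage). Conflict-free connected components therefore collapse into a
#' single record, while components carrying two detections of one channel
#' are split at the channel conflict. Every detection ends up in exactly
#' one record.
#'
#' @param detections Data frame of detections of a single image
#'   (columns `channel, x_um, y_um, peak_intensity`, as from
#'   [detect_spots()]).
#' @param radius_um Colocalization radius in micrometers (> 0). Default
#'   0.2 um = half the PSF full width at half maximum at the default
#'   imaging configuration.
#' @return A data frame of EV records (`image_id, x_um, y_um, bitmask,
#'   bits, n_markers, I1..I4` with `NA` for channels without a detection;
#'   positions are intensity-weighted means of the members), with attribute
#'   `"assignment"`: the record index of every input detection.
#' @examples
#' det <- data.frame(image_id = "a", channel = c(1L, 2L),
#'                   x_um = c(1, 1.05), y_um = c(1, 1),
#'                   peak_intensity = c(100, 90))
#' colocalize(det, radius_um = 0.2)$bits
#' @export
colocalize <- function(detections, radius_um = 0.2) {
  if (!is.numeric(radius_um) || length(radius_um) != 1L || radius_um <= 0)
    stop_field("radius_um", "must be a single positive number")
  n <- nrow(detections)
  empty <- data.frame(image_id = character(0), x_um = numeric(0),
                      y_um = numeric(0), bitmask = integer(0),
                      bits = character(0), n_markers = integer(0),
                      I1 = numeric(0), I2 = numeric(0), I3 = numeric(0),
                      I4 = numeric(0))
  if (!n) { attr(empty, "assignment") <- integer(0); return(empty) }
  if (length(unique(detections$image_id)) > 1L)
    stop_field("detections", "must come from a single image")

  ch <- as.integer(detections$channel)
  x <- detections$x_um; y <- detections$y_um
  # candidate links: cross-channel pairs within the radius, nearest first
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (nrow(pr)) {
    d <- sqrt((x[pr[, 1]] - x[pr[, 2]])^2 + (y[pr[, 1]] - y[pr[, 2]])^2)
    ok <- d <= radius_um & ch[pr[, 1]] != ch[pr[, 2]]
    pr <- pr[ok, , drop = FALSE]; d <- d[ok]
    ord <- order(d, pr[, 1], pr[, 2])
    pr <- pr[ord, , drop = FALSE]
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_mask <- as.integer(2L^(ch - 1L))  # channel bitmask per root
  for (k in seq_len(nrow(pr))) {
    a <- find(pr[k, 1]); b <- find(pr[k, 2])
    if (a == b) next
    if (bitwAnd(cluster_mask[a], cluster_mask[b]) == 0L) {
      parent[b] <- a
      cluster_mask[a] <- bitwOr(cluster_mask[a], cluster_mask[b])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  ids <- sort(unique(roots))
  assignment <- match(roots, ids)
  recs <- lapply(seq_along(ids), function(r) {
    mem <- which(assignment == r)
    w <- detections$peak_intensity[mem]
    I <- rep(NA_real_, 4L)
    I[ch[mem]] <- detections$peak_intensity[mem]
    mask <- as.integer(sum(2L^(unique(ch[mem]) - 1L)))
    data.frame(image_id = detections$image_id[mem[1]],
               x_um = sum(w * x[mem]) / sum(w),
               y_um = sum(w * y[mem]) / sum(w),
               bitmask = mask, bits = mask_bits(mask),
               n_markers = length(mem),
               I1 = I[1], I2 = I[2], I3 = I[3], I4 = I[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  attr(out, "assignment") <- assignment
  out
}

#' Colocalize every image of a detection table
#'
#' @param detections Detection data frame covering one or more images.
#' @param radius_um Colocalization radius, micrometers.
#' @return EV records across all images (no assignment attribute).
#' @export
colocalize_dataset <- function(detections, radius_um = 0.2) {
  parts <- split(detections, detections$image_id)
  out <- do.call(rbind, c(lapply(parts, colocalize, radius_um = radius_um),
                          list(make.row.names = FALSE)))
  if (is.null(out)) out <- colocalize(detections[0, ], radius_um)
  attr(out, "assignment") <- NULL
  rownames(out) <- NULL
  out
}

#' Count EVs per image and phenotype population
#'
#' Tabulates, per image, the total number of EV records (any nonzero
#' bitmask counts once) and the count of each of the 15 populations.
#' Images present in the metadata but without records get all-zero rows —
#' essential for zero-signal frequency statistics on empty-well controls.
#'
#' @param records EV record data frame from [colocalize()] /
#'   [colocalize_dataset()].
#' @param metadata Data frame with one row per image (`image_id` plus
#'   condition columns), as in `ev_dataset$metadata`.
#' @return A data frame: metadata columns, `total`, and 15 `pop_<bits>`
#'   columns ([enumerate_populations()] order). `total` always equals the
#'   sum of the population columns.
#' @examples
#' meta <- data.frame(image_id = c("a", "b"), condition = "w")
#' recs <- data.frame(image_id = "a", bitmask = c(1L, 1L, 6L))
#' count_evs(recs, meta)[, c("image_id", "total")]
#' @export
count_evs <- function(records, metadata) {
  if (!"image_id" %in% names(metadata))
    stop_field("metadata", "must contain an image_id column")
  unknown <- setdiff(unique(records$image_id), metadata$image_id)
  if (length(unknown))
    stop_field("records", paste("image_id(s) not present in metadata:",
                                paste(unknown, collapse = ", ")))
  pops <- enumerate_populations(4)
  cols <- population_columns()
  rows <- lapply(metadata$image_id, function(id) {
    masks <- records$bitmask[records$image_id == id]
    counts <- vapply(pops$bitmask, function(m) sum(masks == m), integer(1L))
    out <- data.frame(total = sum(counts))
    out[cols] <- as.list(counts)
    out
  })
  cbind(metadata, do.call(rbind, rows), row.names = NULL)
}

#' Two-cluster composition fractions (e.g. CD63+ vs ANXA5+)
#'
#' Assigns every counted EV to the first cluster if the bit of
#' `cluster_markers[1]` is set, otherwise to the second cluster if the bit
#' of `cluster_markers[2]` is set, otherwise excludes it. The precedence
#' makes the two clusters disjoint and exhaustive over EVs positive for
#' either marker, so the fractions sum to 1.
#'
#' @param count_table A count table from [count_evs()] or
#'   [truth_count_table()].
#' @param panel The [marker_panel()] defining the bit order.
#' @param cluster_markers Length-2 character vector of stain markers, in
#'   precedence order (default `c("CD63", "ANXA5")`).
#' @return List with `fractions` (named length-2, summing to 1), `counts`,
#'   `n_excluded` and `degenerate` (`TRUE`, with a warning, when no EV
#'   carries either marker; fractions are then `NA`).
#' @examples
#' meta <- data.frame(image_id = "a")
#' recs <- data.frame(image_id = "a", bitmask = c(1L, 8L, 9L))
#' composition_fractions(count_evs(recs, meta), marker_panel())$fractions
#' @export
composition_fractions <- function(count_table, panel,
                                  cluster_markers = c("CD63", "ANXA5")) {
  stopifnot(inherits(panel, "marker_panel"))
  idx <- match(cluster_markers, panel$stain_markers)
  if (anyNA(idx))
    stop_field("cluster_markers",
               paste("not in panel:", paste(cluster_markers[is.na(idx)], collapse = ", ")))
  pops <- enumerate_populations(4)
  totals <- vapply(paste0("pop_", pops$bits),
                   function(cl) sum(count_table[[cl]]), numeric(1L))
  in_first <- mask_has(pops$bitmask, idx[1])
  in_second <- !in_first & mask_has(pops$bitmask, idx[2])
  counts <- c(sum(totals[in_first]), sum(totals[in_second]))
  names(counts) <- paste0(cluster_markers, "+")
  n_excluded <- sum(totals) - sum(counts)
  if (sum(counts) == 0) {
    warning("no EV carries either cluster marker; fractions undefined")
    return(list(fractions = setNames(c(NA_real_, NA_real_), names(counts)),
                counts = counts, n_excluded = n_excluded, degenerate = TRUE))
  }
  list(fractions = counts / sum(counts), counts = counts,
       n_excluded = n_excluded, degenerate = FALSE)
}

#' Per-population fold change between two conditions
#'
#' For every phenotype population, the ratio of mean per-image counts in
#' `counts_a` over `counts_b`, stabilized with a Haldane–Anscombe style
#' pseudocount: `(mean_a + pseudocount) / (mean_b + pseudocount)`.
#'
#' @param counts_a,counts_b Count tables sharing the 15-population schema
#'   (from [count_evs()] / [truth_count_table()]).
#' @param pseudocount Nonnegative ratio stabilizer (default 0.5).
#' @return Data frame with `bits`, `label`-free population id, raw means
#'   `mean_a`, `mean_b`, and `fold`.
#' @examples
#' meta <- data.frame(image_id = c("a", "b"))
#' recs <- data.frame(image_id = "a", bitmask = rep(15L, 4))
#' ct <- count_evs(recs, meta)
#' fold_change(ct, ct)$fold  # all 1
#' @export
fold_change <- function(counts_a, counts_b, pseudocount = 0.5) {
  check_number(pseudocount, "pseudocount", 0)
  cols <- population_columns()
  if (!all(cols %in% names(counts_a)) || !all(cols %in% names(counts_b)))
    stop_field("counts_a/counts_b", "must share the 15-population count schema")
  ma <- vapply(cols, function(cl) mean(counts_a[[cl]]), numeric(1L))
  mb <- vapply(cols, function(cl) mean(counts_b[[cl]]), numeric(1L))
  data.frame(bits = sub("^pop_", "", cols),
             mean_a = unname(ma), mean_b = unname(mb),
             fold = unname((ma + pseudocount) / (mb + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Complete per-EV channel intensity table
#'
#' For the Pearson channel-correlation analysis every EV needs a paired
#' intensity in all four channels. Channels with a detection contribute the
#' detection's peak intensity; channels without one contribute the
#' background-subtracted image intensity at the EV's consensus position
#' (nearest pixel), so the matrix is computed on complete rows.
#'
#' @param records EV records of one dataset ([colocalize_dataset()]).
#' @param dataset The `ev_dataset` whose images the records came from.
#' @return Numeric matrix with one row per EV and one column per channel.
#' @export
ev_intensity_table <- function(records, dataset) {
  stopifnot(inherits(dataset, "ev_dataset"))
  if (is.null(dataset$images)) stop_field("dataset", "contains no rendered images")
  px <- dataset$config$pixel_size_um
  out <- matrix(NA_real_, nrow(records), 4L,
                dimnames = list(NULL, dataset$config$channel_names))
  bg <- lapply(dataset$metadata$image_id, function(id)
    vapply(1:4, function(ch) estimate_background(dataset$images[[id]][, , ch])$mu_bg,
           numeric(1L)))
  names(bg) <- dataset$metadata$image_id
  for (i in seq_len(nrow(records))) {
    id <- records$image_id[i]
    img <- dataset$images[[id]]
    r <- min(max(1L, as.integer(round(records$y_um[i] / px + 0.5))), dim(img)[1])
    c <- min(max(1L, as.integer(round(records$x_um[i] / px + 0.5))), dim(img)[2])
    for (ch in 1:4) {
      v <- records[[paste0("I", ch)]][i]
      out[i, ch] <- if (!is.na(v)) v - bg[[id]][ch] else img[r, c, ch] - bg[[id]][ch]
    }
  }
  out
}
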