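# Independent oracles and fixture builders shared across test files.

# Small imaging configuration (400 um^2 -> 200 x 200 px) for fast tests.
small_config <- function(...) {
  imaging_config(field_area_um2 = 400, ...)
}

one_ev_truth <- function(x_um, y_um, bitmask, amplitude = 100) {
  amps <- rep(NA_real_, 4)
  amps[which(mask_has(bitmask, 1:4))] <- amplitude
  structure(list(
    ev = data.frame(x_um = x_um, y_um = y_um, bitmask = as.integer(bitmask),
                    A1 = amps[1], A2 = amps[2], A3 = amps[3], A4 = amps[4]),
    false_spots = data.frame(x_um = numeric(0), y_um = numeric(0),
                             channel = integer(0), amplitude = numeric(0))),
    class = "ground_truth")
}

empty_truth <- function() {
  structure(list(
    ev = {
      ev <- data.frame(x_um = numeric(0), y_um = numeric(0), bitmask = integer(0))
      for (nm in paste0("A", 1:4)) ev[[nm]] <- numeric(0)
      ev
    },
    false_spots = data.frame(x_um = numeric(0), y_um = numeric(0),
                             channel = integer(0), amplitude = numeric(0))),
    class = "ground_truth")
}

# Greedy-to-truth matching of detections at a pixel tolerance.
match_metrics <- function(det, truth, tol_px = 2, px = 0.1) {
  if (!nrow(truth)) return(c(tp = 0, fn = 0, fp = nrow(det)))
  used <- rep(FALSE, nrow(det)); tp <- 0
  for (i in seq_len(nrow(truth))) {
    if (!nrow(det)) break
    d2 <- (det$x_um - truth$x_um[i])^2 + (det$y_um - truth$y_um[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= (tol_px * px)^2) { used[j] <- TRUE; tp <- tp + 1 }
  }
  c(tp = tp, fn = nrow(truth) - tp, fp = sum(!used))
}

# Exhaustive KS oracle: scan every integer threshold in the pooled range.
ks_oracle <- function(x, y) {
  ts <- seq(min(c(x, y)), max(c(x, y)))
  max(vapply(ts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Distance covariance by the explicit double/triple-sum identity
# S1 + S2 - 2 S3, independent of the double-centering implementation.
dcov_oracle <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-")); b <- abs(outer(y, y, "-"))
  s1 <- s3 <- 0
  for (i in 1:n) for (j in 1:n) {
    s1 <- s1 + a[i, j] * b[i, j]
    for (k in 1:n) s3 <- s3 + a[i, j] * b[i, k]
  }
  s1 <- s1 / n^2
  s2 <- (sum(a) / n^2) * (sum(b) / n^2)
  s3 <- s3 / n^3
  n * max(s1 + s2 - 2 * s3, 0)
}

# Exhaustive colocalization oracle: best partition into channel-conflict-free
# clusters connected in the cross-channel within-radius graph, minimizing
# (number of clusters, total intra-cluster pairwise distance) lexicographically.
best_partition <- function(x, y, ch, radius) {
  n <- length(x)
  dmat <- as.matrix(dist(cbind(x, y)))
  edge <- dmat <= radius & outer(ch, ch, "!=")
  best <- NULL; best_key <- c(Inf, Inf)
  assign_rec <- function(i, clusters) {
    if (i > n) {
      for (cl in clusters) {
        if (length(cl) > 1) {
          seen <- cl[1]; frontier <- cl[1]
          while (length(frontier)) {
            nb <- setdiff(cl[colSums(edge[frontier, cl, drop = FALSE]) > 0], seen)
            seen <- c(seen, nb); frontier <- nb
          }
          if (length(seen) < length(cl)) return(invisible())
        }
      }
      cost <- sum(vapply(clusters, function(cl)
        if (length(cl) > 1) sum(dmat[cl, cl][upper.tri(dmat[cl, cl])])
        else 0, numeric(1)))
      key <- c(length(clusters), cost)
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2] - 1e-12)) {
        best_key <<- key; best <<- clusters
      }
      return(invisible())
    }
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      if (!any(ch[cl] == ch[i])) assign_rec(i + 1, `[[<-`(clusters, k, c(cl, i)))
    }
    assign_rec(i + 1, c(clusters, list(i)))
  }
  assign_rec(2L, list(1L))
  best
}

canonical_partition <- function(clusters) {
  s <- unname(lapply(clusters, function(cl) as.integer(sort(cl))))
  s[order(vapply(s, `[`, integer(1), 1))]
}
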