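test_that("colocalization handles singletons and clean quadruples", {
  one <- data.frame(image_id = "a", channel = 2L, x_um = 5, y_um = 5,
                    peak_intensity = 80)
  rec <- colocalize(one, radius_um = 0.2)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$bits, "0100")

  quad <- data.frame(image_id = "a", channel = 1:4,
                     x_um = c(5, 5.05, 5.02, 4.98),
                     y_um = c(5, 4.97, 5.04, 5.01),
                     peak_intensity = c(100, 90, 80, 70))
  rec <- colocalize(quad, radius_um = 0.2)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$bits, "1111")
  expect_identical(rec$bitmask, 15L)
  expect_error(colocalize(quad, radius_um = -1), "positive")
})

test_that("greedy linkage matches the exhaustive minimal-distance partition", {
  n_agree <- 0; n_cases <- 1000
  withr::with_seed(421, {
    for (case in seq_len(n_cases)) {
      n <- sample(3:8, 1)
      x <- runif(n); y <- runif(n)
      ch <- sample(1:3, n, replace = TRUE)
      det <- data.frame(image_id = "a", channel = ch, x_um = x, y_um = y,
                        peak_intensity = runif(n, 50, 150))
      recs <- colocalize(det, radius_um = 0.25)
      assignment <- attr(recs, "assignment")
      clusters <- split(seq_len(n), assignment)
      # hard constraints must always hold
      expect_true(all(vapply(clusters, function(cl)
        anyDuplicated(ch[cl]) == 0L, logical(1L))))
      expect_identical(sort(unlist(clusters, use.names = FALSE)), seq_len(n))
      greedy <- canonical_partition(clusters)
      optimal <- canonical_partition(best_partition(x, y, ch, 0.25))
      if (identical(greedy, optimal)) n_agree <- n_agree + 1
    }
  })
  expect_gte(n_agree / n_cases, 0.95)
})

test_that("every detection belongs to exactly one EV record", {
  withr::with_seed(55, {
    for (case in 1:25) {
      n <- sample(1:20, 1)
      det <- data.frame(image_id = "a",
                        channel = sample(1:4, n, replace = TRUE),
                        x_um = runif(n, 0, 3), y_um = runif(n, 0, 3),
                        peak_intensity = runif(n, 50, 150))
      recs <- colocalize(det, radius_um = 0.3)
      assignment <- attr(recs, "assignment")
      expect_identical(length(assignment), n)
      expect_identical(sort(unique(assignment)), seq_len(nrow(recs)))
      # channel multiplicity equals the popcount of each record's bitmask
      expect_identical(sum(mask_popcount(recs$bitmask)), n)
    }
  })
})

test_that("enlarging the radius never increases the number of records", {
  withr::with_seed(56, {
    for (case in 1:50) {
      n <- sample(2:12, 1)
      det <- data.frame(image_id = "a",
                        channel = sample(1:4, n, replace = TRUE),
                        x_um = runif(n), y_um = runif(n),
                        peak_intensity = runif(n, 50, 150))
      counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(r)
        nrow(colocalize(det, r)), integer(1L))
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("population enumeration covers all nonzero marker combinations", {
  pops <- enumerate_populations(marker_panel())
  expect_identical(nrow(pops), 15L)
  expect_identical(sum(pops$n_markers == 4), 1L)
  expect_identical(sum(pops$n_markers == 3), 4L)
  expect_identical(sum(pops$n_markers == 2), 6L)
  expect_identical(sum(pops$n_markers == 1), 4L)
  expect_identical(pops$bitmask[1], 15L)
  expect_identical(pops$label[1], "CD63+HSP70+TSG101+ANXA5+")
  expect_identical(anyDuplicated(pops$bitmask), 0L)
  # generalized panel sizes
  expect_identical(nrow(enumerate_populations(2)), 3L)
  expect_identical(nrow(enumerate_populations(3)), 7L)
})

test_that("count tables conserve totals and keep zero-record images", {
  meta <- data.frame(image_id = sprintf("img%02d", 1:10), condition = "w")
  none <- data.frame(image_id = character(0), bitmask = integer(0))
  ct <- count_evs(none, meta)
  expect_identical(nrow(ct), 10L)
  expect_true(all(ct$total == 0))

  recs <- data.frame(image_id = "img01", bitmask = c(1L, 1L, 6L))
  ct <- count_evs(recs, meta)
  expect_identical(ct$total[1], 3L)
  expect_identical(ct$pop_1000[1], 2L)
  expect_identical(ct$pop_0110[1], 1L)
  pop_cols <- grep("^pop_", names(ct), value = TRUE)
  expect_identical(length(pop_cols), 15L)
  expect_true(all(ct$total == rowSums(ct[pop_cols])))
  expect_error(count_evs(data.frame(image_id = "ghost", bitmask = 1L), meta),
               "not present in metadata")
})

test_that("two-cluster composition fractions follow marker precedence", {
  meta <- data.frame(image_id = "a")
  panel <- marker_panel()  # CD63 = bit 1, ANXA5 = bit 4
  anxa_only <- count_evs(data.frame(image_id = "a", bitmask = rep(8L, 5)), meta)
  fr <- composition_fractions(anxa_only, panel)
  expect_equal(unname(fr$fractions), c(0, 1))

  even <- count_evs(data.frame(image_id = "a", bitmask = c(1L, 1L, 8L, 8L)), meta)
  fr <- composition_fractions(even, panel)
  expect_equal(unname(fr$fractions), c(0.5, 0.5))

  # hand tally: masks with CD63 bit -> cluster 1 regardless of ANXA5
  masks <- c(15L, 9L, 1L, 8L, 8L, 14L, 6L, 2L, 8L, 9L)
  mixed <- count_evs(data.frame(image_id = "a", bitmask = masks), meta)
  fr <- composition_fractions(mixed, panel)
  # CD63+: 15, 9, 1, 9 (4); ANXA5+ without CD63: 8, 8, 14, 8 (4); excluded: 6, 2
  expect_equal(unname(fr$counts), c(4, 4))
  expect_identical(unname(fr$n_excluded), 2)
  expect_equal(unname(fr$fractions), c(0.5, 0.5))

  no_marker <- count_evs(data.frame(image_id = "a", bitmask = c(2L, 6L)), meta)
  expect_warning(fr <- composition_fractions(no_marker, panel), "undefined")
  expect_true(fr$degenerate)
})

test_that("fold changes are exact on constructed tables", {
  meta <- data.frame(image_id = c("a", "b"))
  base <- count_evs(data.frame(image_id = rep(c("a", "b"), each = 2),
                               bitmask = rep(c(15L, 1L), 2)), meta)
  fc <- fold_change(base, base)
  expect_true(all(fc$fold == 1))

  doubled <- count_evs(data.frame(image_id = rep(c("a", "b"), each = 4),
                                  bitmask = rep(c(15L, 15L, 1L, 1L), 2)), meta)
  fc <- fold_change(doubled, base, pseudocount = 0)
  expect_equal(fc$fold[fc$bits == "1111"], 2)
  expect_equal(fc$fold[fc$bits == "1000"], 2)
})

test_that("intensity tables are complete for correlation analysis", {
  cfg <- small_config(signal_amplitude = 200)
  cond <- well_condition("w", 1, ev_rate = 6)
  ds <- generate_experiment(list(list(condition = cond, n_images = 3)),
                            marker_panel(), cfg, seed = 71)
  recs <- colocalize_dataset(detect_dataset(ds))
  tab <- ev_intensity_table(recs, ds)
  expect_identical(nrow(tab), nrow(recs))
  expect_identical(ncol(tab), 4L)
  expect_false(anyNA(tab))
  # channels with a detection keep background-subtracted peak intensities
  i <- which(recs$bitmask == 15L)[1]
  if (!is.na(i)) expect_true(all(tab[i, ] > 50))
})
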