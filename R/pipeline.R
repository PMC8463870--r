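# End-to-end orchestration: validate a run configuration, then
# simulate -> detect -> classify -> test, writing CSV/TIFF outputs and a
# run manifest. Every stage draws its randomness from substreams of the
# single global seed, so a config fully determines every output value.

#' Validate a run configuration
#'
#' Accepts a YAML file path, a YAML string, or a nested list, checks every
#' invariant of the nested types (imaging configuration, marker panel,
#' detection parameters, well conditions, comparisons), injects documented
#' defaults for missing fields, and returns a normalized `run_config`.
#' Error messages name the offending field path.
#'
#' @param x YAML file path, YAML text, or list.
#' @return An object of class `run_config`.
#' @examples
#' cfg <- validate_config(list(
#'   seed = 1,
#'   imaging = list(field_area_um2 = 400),
#'   conditions = list(list(name = "1cell", n_cells = 1, ev_rate = 3,
#'                          n_images = 4))))
#' cfg$colocalization_radius_um
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    raw <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  } else if (is.list(x)) {
    raw <- x
  } else {
    stop_field("config", "must be a YAML file path, YAML text, or a list")
  }
  if (is.null(raw$seed))
    stop_field("seed", "must be set explicitly (no wall-clock seeding)")
  seed <- as.integer(check_number(raw$seed, "seed"))

  imaging <- do.call(imaging_config, as.list(raw$imaging))
  panel <- if (is.null(raw$panel)) marker_panel() else
    marker_panel(stain_markers = raw$panel$stain_markers,
                 immobilization_marker = raw$panel$immobilization_marker)
  detection <- do.call(detection_params, as.list(raw$detection))
  radius <- if (is.null(raw$colocalization_radius_um)) 0.2 else raw$colocalization_radius_um
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop_field("colocalization_radius_um", "must be a single positive number")

  if (!length(raw$conditions))
    stop_field("conditions", "at least one condition with n_images >= 1 required")
  conditions <- lapply(seq_along(raw$conditions), function(i) {
    cc <- raw$conditions[[i]]
    path <- sprintf("conditions[[%d]]", i)
    if (is.null(cc$name)) stop_field(paste0(path, "$name"), "is required")
    if (is.null(cc$n_images) || !is.numeric(cc$n_images) || cc$n_images < 1)
      stop_field(paste0(path, "$n_images"), "must be >= 1")
    cond <- tryCatch(
      well_condition(name = cc$name,
                     n_cells = if (is.null(cc$n_cells)) 1L else cc$n_cells,
                     ev_rate = if (is.null(cc$ev_rate)) 0 else cc$ev_rate,
                     background_spot_rate =
                       if (is.null(cc$background_spot_rate)) 0 else cc$background_spot_rate,
                     composition = if (is.null(cc$composition)) default_composition()
                                   else unlist(cc$composition),
                     treatment = if (is.null(cc$treatment)) "none" else cc$treatment,
                     immobilization_marker =
                       if (is.null(cc$immobilization_marker))
                         panel$immobilization_marker else cc$immobilization_marker),
      error = function(e) stop_field(path, conditionMessage(e)))
    list(condition = cond, n_images = as.integer(cc$n_images))
  })
  cond_names <- vapply(conditions, function(e) e$condition$name, character(1L))
  if (anyDuplicated(cond_names))
    stop_field("conditions", "condition names must be unique")

  comparisons <- lapply(seq_along(raw$comparisons), function(i) {
    cp <- raw$comparisons[[i]]
    path <- sprintf("comparisons[[%d]]", i)
    test <- match.arg(cp$test, c("ks", "density", "median_fold", "chisq", "dcov"))
    for (grp in c("a", if (test != "dcov") "b")) {
      if (is.null(cp[[grp]]) || !cp[[grp]] %in% cond_names)
        stop_field(paste0(path, "$", grp),
                   sprintf("must reference a defined condition (have: %s)",
                           paste(cond_names, collapse = ", ")))
    }
    list(name = if (is.null(cp$name)) sprintf("%s_%s_vs_%s", test, cp$a,
                                              if (is.null(cp$b)) "self" else cp$b)
                else cp$name,
         test = test, a = cp$a, b = cp$b,
         n_resamples = if (is.null(cp$n_resamples)) 10000L
                       else as.integer(cp$n_resamples))
  })

  structure(list(seed = seed, imaging = imaging, panel = panel,
                 detection = detection, colocalization_radius_um = radius,
                 conditions = conditions, comparisons = comparisons),
            class = "run_config")
}

#' Demo run configuration
#'
#' A compact four-condition design (empty wells plus 1, 2 and 3+ cell
#' wells sharing the default phenotype mixture) with the comparison plan
#' used throughout the documentation. Image count, field size and resample
#' depth are parameters so the same design scales from smoke test to
#' full-size run.
#'
#' @param n_images Images per condition.
#' @param field_area_um2 Field area in square micrometers.
#' @param n_resamples Resamples per resampling test.
#' @param seed Global seed.
#' @return A validated `run_config`.
#' @export
demo_run_config <- function(n_images = 50, field_area_um2 = 4356,
                            n_resamples = 2000, seed = 1) {
  validate_config(list(
    seed = seed,
    imaging = list(field_area_um2 = field_area_um2),
    conditions = list(
      list(name = "0cell", n_cells = 0, ev_rate = 0,
           background_spot_rate = 0.2, n_images = n_images),
      list(name = "1cell", n_cells = 1, ev_rate = 3,
           background_spot_rate = 0.2, n_images = n_images),
      list(name = "2cell", n_cells = 2, ev_rate = 6,
           background_spot_rate = 0.2, n_images = n_images),
      list(name = "3cell", n_cells = 3, ev_rate = 12,
           background_spot_rate = 0.2, n_images = n_images)),
    comparisons = list(
      list(name = "ks_1_vs_0", test = "ks", a = "1cell", b = "0cell",
           n_resamples = n_resamples),
      list(name = "ks_1_vs_2", test = "ks", a = "1cell", b = "2cell",
           n_resamples = n_resamples),
      list(name = "ks_1_vs_3", test = "ks", a = "1cell", b = "3cell",
           n_resamples = n_resamples),
      list(name = "density_1_vs_0", test = "density", a = "1cell", b = "0cell",
           n_resamples = n_resamples),
      list(name = "median_1_vs_0", test = "median_fold", a = "1cell", b = "0cell"),
      list(name = "chisq_1_vs_3", test = "chisq", a = "1cell", b = "3cell"),
      list(name = "dcov_1cell", test = "dcov", a = "1cell",
           n_resamples = n_resamples))))
}

run_comparison <- function(cp, count_table, seed) {
  totals <- function(cond) count_table$total[count_table$condition == cond]
  sub <- substream_seed(seed, "stats", cp$name)
  if (cp$test == "ks") {
    res <- ks_bootstrap_pvalue(totals(cp$a), totals(cp$b), cp$n_resamples, sub)
  } else if (cp$test == "density") {
    res <- permutation_density_test(totals(cp$a), totals(cp$b), cp$n_resamples, sub)
  } else if (cp$test == "median_fold") {
    mf <- median_fold(totals(cp$a), totals(cp$b))
    return(data.frame(comparison = cp$name, test = cp$test,
                      group_a = cp$a, group_b = cp$b,
                      statistic_name = "median_ratio", statistic = mf$ratio,
                      p_value = NA_real_, n_resamples = NA_integer_,
                      seed = NA_integer_, n_a = length(totals(cp$a)),
                      n_b = length(totals(cp$b)), stringsAsFactors = FALSE))
  } else if (cp$test == "chisq") {
    cols <- population_columns()
    ca <- colSums(count_table[count_table$condition == cp$a, cols])
    cb <- colSums(count_table[count_table$condition == cp$b, cols])
    res <- chisq_population_test(ca, cb)
  } else { # dcov: independence of consecutive images within one condition
    v <- totals(cp$a)
    k <- floor(length(v) / 2)
    if (k < 4) stop_field(cp$name, "dcov comparison needs >= 8 images")
    res <- dcov_bootstrap_test(v[2 * seq_len(k) - 1], v[2 * seq_len(k)],
                               cp$n_resamples, sub)
  }
  data.frame(comparison = cp$name, test = cp$test, group_a = cp$a,
             group_b = if (is.null(cp$b)) cp$a else cp$b,
             statistic_name = res$statistic_name, statistic = res$statistic,
             p_value = res$p_value,
             n_resamples = if (is.na(res$n_resamples)) NA_integer_ else res$n_resamples,
             seed = res$seed, n_a = res$sample_sizes[1], n_b = res$sample_sizes[2],
             stringsAsFactors = FALSE)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Run the full pipeline
#'
#' Executes simulate, detect, classify and test in order, writing every
#' stage output under `output_dir`: the simulated dataset
#' ([write_dataset()] layout), `detections.csv`, `ev_records.csv`,
#' `count_table.csv`, `stats_results.csv`, and `manifest.json` with the
#' configuration hash, package version, per-stage row counts, seeds and
#' timestamps. Re-running with the same configuration and seed reproduces
#' every stage output byte for byte (the manifest differs only in its
#' timestamps). If a stage fails, already-written outputs are retained and
#' the manifest records the failing stage.
#'
#' @param config A `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @param output_dir Writable output directory.
#' @return The manifest, invisibly.
#' @examples
#' \donttest{
#' cfg <- demo_run_config(n_images = 4, field_area_um2 = 400, n_resamples = 99)
#' out <- tempfile()
#' manifest <- run_pipeline(cfg, out)
#' manifest$stages$classify
#' }
#' @export
run_pipeline <- function(config, output_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(packageVersion("tirfev")),
                   seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), status = "running")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed:", name)
      manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  dataset <- stage("simulate", {
    ds <- generate_experiment(config$conditions, config$panel, config$imaging,
                              config$seed)
    write_dataset(ds, output_dir)
    ds
  })
  manifest$stages$simulate <- list(n_images = nrow(dataset$metadata),
                                   n_true_evs = sum(vapply(dataset$truth,
                                     function(t) nrow(t$ev), integer(1L))))

  detections <- stage("detect", {
    d <- detect_dataset(dataset, config$detection)
    write.csv(d, file.path(output_dir, "detections.csv"), row.names = FALSE)
    d
  })
  manifest$stages$detect <- list(n_detections = nrow(detections))

  counts <- stage("classify", {
    records <- colocalize_dataset(detections, config$colocalization_radius_um)
    write.csv(records, file.path(output_dir, "ev_records.csv"), row.names = FALSE)
    ct <- count_evs(records, dataset$metadata)
    write.csv(ct, file.path(output_dir, "count_table.csv"), row.names = FALSE)
    list(records = records, table = ct)
  })
  manifest$stages$classify <- list(n_ev_records = nrow(counts$records),
                                   n_rows = nrow(counts$table))

  results <- stage("stats", {
    res <- do.call(rbind, lapply(config$comparisons, run_comparison,
                                 count_table = counts$table, seed = config$seed))
    if (is.null(res))
      res <- data.frame(comparison = character(0), test = character(0),
                        group_a = character(0), group_b = character(0),
                        statistic_name = character(0), statistic = numeric(0),
                        p_value = numeric(0), n_resamples = integer(0),
                        seed = integer(0), n_a = integer(0), n_b = integer(0))
    write.csv(res, file.path(output_dir, "stats_results.csv"), row.names = FALSE)
    res
  })
  manifest$stages$stats <- list(n_tests = nrow(results))

  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
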