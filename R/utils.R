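# Internal helpers: argument checking and reproducible substream seeding.

stop_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  ok <- if (strict) x > min else x >= min
  if (!ok)
    stop_field(field, sprintf("must be %s %g (got %g)",
                              if (strict) ">" else ">=", min, x))
  as.numeric(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be TRUE or FALSE")
  x
}

#' Derive a reproducible substream seed
#'
#' Maps a global seed plus an arbitrary set of string/numeric labels (stage
#' name, image id, ...) to a 32-bit seed by Horner hashing modulo
#' \eqn{2^{31} - 1}. Adding images or stages to a run never perturbs the
#' substream of an existing (stage, id) pair, so datasets are extensible
#' without breaking reproducibility.
#'
#' @param seed Integer global seed.
#' @param ... Labels identifying the substream (coerced to character and
#'   joined with `"|"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "simulate", "cond1_007")
#' @export
substream_seed <- function(seed, ...) {
  m <- 2147483647
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1L)), collapse = "|")
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 2) + 1)
}
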