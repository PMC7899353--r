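#' Scoring configuration
#'
#' Every lookup and score table that the CAPL-2 protocol defers to its
#' administration manual lives in a human-readable JSON config file, never in
#' code: the 15m-to-20m PACER lap conversion chart, the PACER/plank score
#' rules, CAMSA time-score bins, step-score bins, step validity bounds,
#' minimum pedometer wear hours, the self-report mapping, CSAPPA item point
#' map and orientations, BREQ point rule, knowledge-item answer keys, the
#' fill-in-the-blanks answer key, and the per-protocol interpretation inputs.
#' The packaged defaults are provisional: monotone and range-correct, but
#' synthetic stand-ins for manual content. Users holding the manual can copy
#' the packaged file, correct the tables, and pass their own path.
#'
#' @param path Path to a JSON config file. `NULL` (default) loads the
#'   packaged configuration.
#'
#' @return A validated list of class `"capl_config"`.
#'
#' @examples
#' cfg <- capl_config()
#' cfg$pacer$laps_per_point
#'
#' @export
capl_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scoring-config.json", package = "capl2score")
  }
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_capl_config(cfg)
}

#' Write a scoring configuration to file
#'
#' The file representation round-trips: reading a written config yields an
#' object identical to the one written.
#'
#' @param config A `capl_config` list.
#' @param path Output file path (JSON).
#'
#' @return `path`, invisibly.
#' @export
write_capl_config <- function(config, path) {
  config <- validate_capl_config(config)
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       always_decimal = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate a scoring configuration
#'
#' Checks that every score table is total over its declared input range and
#' monotone where the protocol is monotone: more laps, steps, or
#' seconds-held never earn a lower score, and slower CAMSA times never earn
#' a higher one.
#'
#' @param config A list with the structure of [capl_config()].
#'
#' @return The config, classed `"capl_config"`, invisibly usable.
#' @export
validate_capl_config <- function(config) {
  need <- c("pacer", "plank", "camsa", "steps", "self_report", "csappa",
            "breq", "answer_keys", "fill_in_the_blanks",
            "interpretation_inputs")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("config is missing entries: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  conv <- config$pacer$conversion_15m
  if (is.unsorted(conv$laps_15m, strictly = TRUE) ||
      is.unsorted(conv$laps_20m) ||
      length(conv$laps_15m) != length(conv$laps_20m)) {
    stop("pacer 15m->20m conversion table must be monotone non-decreasing",
         call. = FALSE)
  }
  if (config$pacer$laps_per_point <= 0 || config$plank$seconds_per_point <= 0) {
    stop("pacer/plank rules must award points for positive effort",
         call. = FALSE)
  }
  bins <- config$camsa$time_bins
  if (is.unsorted(bins$upper_seconds, strictly = TRUE) ||
      is.unsorted(rev(bins$points), strictly = TRUE) ||
      length(bins$upper_seconds) != length(bins$points) ||
      bins$slower_points >= min(bins$points)) {
    stop("camsa time bins must be increasing in time, decreasing in points",
         call. = FALSE)
  }
  if (is.unsorted(config$steps$bins_lower, strictly = TRUE)) {
    stop("step bins must be strictly increasing", call. = FALSE)
  }
  if (config$steps$min_daily_steps >= config$steps$max_daily_steps) {
    stop("step validity bounds are inverted", call. = FALSE)
  }
  if (length(config$self_report$map) != 8 ||
      is.unsorted(config$self_report$map)) {
    stop("self-report map must give a non-decreasing score for days 0..7",
         call. = FALSE)
  }
  if (length(config$csappa$points) != 4 ||
      is.unsorted(config$csappa$points, strictly = TRUE)) {
    stop("csappa point map must be 4 strictly increasing values",
         call. = FALSE)
  }
  keys <- c("pa_guideline", "crf_means", "ms_means", "sports_skill")
  if (!all(keys %in% names(config$answer_keys))) {
    stop("answer keys must cover the four knowledge items", call. = FALSE)
  }
  blanks <- c("pa_is", "pa_is_also", "improve", "increase",
              "when_cooling_down", "heart_rate")
  if (!all(blanks %in% names(config$fill_in_the_blanks))) {
    stop("fill-in-the-blanks key must cover the six blanks", call. = FALSE)
  }
  structure(config, class = "capl_config")
}

#' @export
print.capl_config <- function(x, ...) {
  cat("CAPL-2 scoring configuration\n")
  cat("  pacer: ", x$pacer$laps_per_point, " laps/point, valid 20m laps [",
      x$pacer$valid_lap_range[1], ", ", x$pacer$valid_lap_range[2], "]\n",
      sep = "")
  cat("  plank: ", x$plank$seconds_per_point, " s/point (max ",
      x$plank$max_score, ")\n", sep = "")
  cat("  camsa: ", length(x$camsa$time_bins$points),
      " time bins, divisor ", x$camsa$divisor, "\n", sep = "")
  cat("  steps: valid ", x$steps$min_daily_steps, "-",
      x$steps$max_daily_steps, " steps/day, >= ", x$steps$min_wear_hours,
      " wear hours\n", sep = "")
  invisible(x)
}
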