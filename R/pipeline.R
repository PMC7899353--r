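#' The 60 required raw variables
#'
#' Scoring a table requires exactly these column names. Columns absent from
#' an input table are scaffolded in as all-`NA` by
#' [scaffold_capl_variables()] so scoring can always proceed.
#'
#' @format A character vector of length 60.
#' @export
capl_variables <- c(
  "age", "gender", "pacer_lap_distance", "pacer_laps", "plank_time",
  "camsa_skill_score1", "camsa_time1", "camsa_skill_score2", "camsa_time2",
  as.vector(vapply(1:7, function(day) {
    paste0(c("steps", "time_on", "time_off", "non_wear_time"), day)
  }, character(4))),
  "self_report_pa",
  paste0("csappa", 1:6),
  paste0("why_active", 1:3),
  paste0("feelings_about_pa", 1:3),
  "pa_guideline", "crf_means", "ms_means", "sports_skill",
  "pa_is", "pa_is_also", "improve", "increase", "when_cooling_down",
  "heart_rate"
)

#' The 40 derived variables, in computation order
#'
#' Columns added to a scored table by [score_capl_data()] under
#' `sort = "asis"`.
#'
#' @format A character vector of length 40.
#' @export
capl_derived_variables <- c(
  "pacer_laps_20m", "pacer_score", "pacer_interpretation",
  "plank_score", "plank_interpretation",
  "camsa_time_score1", "camsa_time_score2",
  "camsa_skill_time_score1", "camsa_skill_time_score2",
  "camsa_score", "camsa_interpretation",
  "pc_score", "pc_interpretation", "pc_status",
  "step_average", "valid_days", "step_score", "step_interpretation",
  "self_report_pa_score", "db_score", "db_interpretation", "db_status",
  "predilection_score", "adequacy_score", "intrinsic_motivation_score",
  "pa_competence_score", "mc_score", "mc_interpretation", "mc_status",
  "pa_guideline_score", "crf_means_score", "ms_means_score",
  "sports_skill_score", "fill_in_the_blanks_score",
  "ku_score", "ku_interpretation", "ku_status",
  "capl_score", "capl_interpretation", "capl_status"
)

#' Add any missing required variables to a table
#'
#' Ensures every one of the 60 required raw variables ([capl_variables]) is
#' present, filling added columns with `NA`. Existing columns are never
#' touched, so the operation is idempotent.
#'
#' @param data Any data frame (possibly zero columns or zero rows).
#'
#' @return `data` with all 60 required columns present.
#' @export
scaffold_capl_variables <- function(data) {
  data <- as.data.frame(data)
  for (v in setdiff(capl_variables, names(data))) {
    data[[v]] <- rep(NA, nrow(data))
  }
  data
}

#' Rename columns of a data frame
#'
#' Renames columns positionally: the i-th name in `search` becomes the i-th
#' name in `replace`. Unlike the quiet validators this raises on a length
#' mismatch or an unknown column, because a bad rename is a programming
#' error, not messy data.
#'
#' @param x A data frame.
#' @param search Existing column names.
#' @param replace New names, same length as `search`.
#'
#' @return `x` with columns renamed.
#'
#' @examples
#' rename_variables(data.frame(Age = 1), search = "Age", replace = "age")
#'
#' @export
rename_variables <- function(x, search, replace) {
  if (length(search) != length(replace)) {
    stop("`search` and `replace` must have the same length", call. = FALSE)
  }
  unknown <- setdiff(search, names(x))
  if (length(unknown)) {
    stop("column(s) not found: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  names(x)[match(search, names(x))] <- replace
  x
}

#' Score a full table of raw CAPL-2 data
#'
#' The one-call batch scorer: scaffolds any missing raw variables, then adds
#' the 40 derived variables ([capl_derived_variables]) — protocol scores,
#' four domain scores, the overall physical literacy score, age- and
#' gender-specific interpretations, and domain completeness statuses — in
#' dependency order. Raw columns are never mutated; content problems never
#' raise (they surface as `NA` per the quiet-validation philosophy).
#'
#' @param data A data frame of raw data (any subset of [capl_variables]).
#' @param sort `"asis"` appends derived columns after the raw columns in
#'   computation order; `"abc"` sorts all columns alphabetically; `"zyx"`
#'   reverse-alphabetically.
#' @param seed Integer seed for the step-imputation draws (see
#'   [step_average()]).
#' @param config A [capl_config()] list.
#' @param norms A [capl_norms()] table.
#' @param quiet Set `FALSE` to log per-domain missingness counts.
#'
#' @return A data frame with the original columns plus the 40 derived ones.
#'
#' @examples
#' scored <- score_capl_data(capl_demo_data(25, seed = 1))
#' dim(scored)
#'
#' @export
score_capl_data <- function(data, sort = c("asis", "abc", "zyx"), seed = 1,
                            config = capl_config(), norms = capl_norms(),
                            quiet = TRUE) {
  sort <- match.arg(sort)
  raw <- scaffold_capl_variables(data)
  d <- raw

  interp <- function(score, protocol) {
    capl_interpretation(d$age, d$gender, score, protocol, norms)
  }

  # physical competence
  d$pacer_laps_20m <- pacer_laps_20m(d$pacer_lap_distance, d$pacer_laps,
                                     config)
  d$pacer_score <- pacer_score(d$pacer_laps_20m, config)
  d$pacer_interpretation <- interp(
    d[[config$interpretation_inputs$pacer]], "pacer")
  d$plank_score <- plank_score(d$plank_time, config)
  d$plank_interpretation <- interp(
    d[[config$interpretation_inputs$plank]], "plank")
  d$camsa_time_score1 <- camsa_time_score(d$camsa_time1, config)
  d$camsa_time_score2 <- camsa_time_score(d$camsa_time2, config)
  d$camsa_skill_time_score1 <- camsa_skill_time_score(
    d$camsa_skill_score1, d$camsa_time1, config)
  d$camsa_skill_time_score2 <- camsa_skill_time_score(
    d$camsa_skill_score2, d$camsa_time2, config)
  d$camsa_score <- camsa_score(d$camsa_skill_time_score1,
                               d$camsa_skill_time_score2, config)
  d$camsa_interpretation <- interp(
    d[[config$interpretation_inputs$camsa]], "camsa")
  d$pc_score <- pc_score(d$pacer_score, d$plank_score, d$camsa_score)
  d$pc_interpretation <- interp(d[[config$interpretation_inputs$pc]], "pc")
  d$pc_status <- capl_domain_status(d, "pc")

  # daily behaviour
  steps <- step_average(raw, config, seed)
  d$step_average <- steps$step_average
  d$valid_days <- steps$valid_days
  d$step_score <- step_score(d$step_average, config)
  d$step_interpretation <- interp(
    d[[config$interpretation_inputs$steps]], "steps")
  d$self_report_pa_score <- self_report_pa_score(d$self_report_pa, config)
  d$db_score <- db_score(d$step_score, d$self_report_pa_score)
  d$db_interpretation <- interp(d[[config$interpretation_inputs$db]], "db")
  d$db_status <- capl_domain_status(d, "db")

  # motivation and confidence
  d$predilection_score <- csappa_subscale_score(
    d$csappa1, d$csappa3, d$csappa5, "predilection", config)
  d$adequacy_score <- csappa_subscale_score(
    d$csappa2, d$csappa4, d$csappa6, "adequacy", config)
  d$intrinsic_motivation_score <- breq_subscale_score(
    d$why_active1, d$why_active2, d$why_active3, config)
  d$pa_competence_score <- breq_subscale_score(
    d$feelings_about_pa1, d$feelings_about_pa2, d$feelings_about_pa3, config)
  d$mc_score <- mc_score(d$predilection_score, d$adequacy_score,
                         d$intrinsic_motivation_score, d$pa_competence_score)
  d$mc_interpretation <- interp(d[[config$interpretation_inputs$mc]], "mc")
  d$mc_status <- capl_domain_status(d, "mc")

  # knowledge and understanding
  d$pa_guideline_score <- binary_score(d$pa_guideline, item = "pa_guideline",
                                       config = config)
  d$crf_means_score <- binary_score(d$crf_means, item = "crf_means",
                                    config = config)
  d$ms_means_score <- binary_score(d$ms_means, item = "ms_means",
                                   config = config)
  d$sports_skill_score <- binary_score(d$sports_skill, item = "sports_skill",
                                       config = config)
  d$fill_in_the_blanks_score <- fill_in_the_blanks_score(
    d$pa_is, d$pa_is_also, d$improve, d$increase, d$when_cooling_down,
    d$heart_rate, config)
  d$ku_score <- ku_score(d$pa_guideline_score, d$crf_means_score,
                         d$ms_means_score, d$sports_skill_score,
                         d$fill_in_the_blanks_score)
  d$ku_interpretation <- interp(d[[config$interpretation_inputs$ku]], "ku")
  d$ku_status <- capl_domain_status(d, "ku")

  # overall
  d$capl_score <- capl_score(d$pc_score, d$db_score, d$mc_score, d$ku_score)
  d$capl_interpretation <- interp(
    d[[config$interpretation_inputs$capl]], "capl")
  d$capl_status <- capl_domain_status(d, "capl")

  if (!quiet) {
    for (domain in c("pc", "db", "mc", "ku", "capl")) {
      n_missing <- sum(is.na(d[[paste0(domain, "_score")]]))
      message(sprintf("%s: %d/%d rows missing a domain score", domain,
                      n_missing, nrow(d)))
    }
  }

  out <- d[, c(names(raw), capl_derived_variables), drop = FALSE]
  if (sort == "abc") out <- out[, order(names(out)), drop = FALSE]
  if (sort == "zyx") out <- out[, order(names(out), decreasing = TRUE),
                                drop = FALSE]
  out
}
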