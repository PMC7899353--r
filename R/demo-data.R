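#' Generate demo (fake) raw data
#'
#' Simulates the kind of table field teams actually submit: 8-12-year-olds
#' with deliberately messy gender encodings (`"f"`, `"Boy"`, `"g"`,
#' `"Female"`, `0`, `1`...), PACER laps on both 15 m and 20 m courses,
#' pedometer step counts spanning implausible lows through plausible highs,
#' clock-time strings in both 12- and 24-hour dialects, Likert responses,
#' knowledge items answered sometimes by code and sometimes verbatim, and
#' sporadic missing values in every field. Useful for exploring the scoring
#' pipeline and as a fuzzing source in tests.
#'
#' @param n Number of rows; must be a whole number `>= 1`.
#' @param seed Optional integer seed; same `n` and `seed` reproduce the
#'   table exactly. The caller's RNG state is left untouched.
#' @param p_missing Probability that any given cell is missing
#'   (default 0.05).
#' @param config A [capl_config()] list (supplies the answer keys that some
#'   simulated children get right).
#'
#' @return An `n` x 60 data frame with the columns in [capl_variables].
#'
#' @examples
#' head(capl_demo_data(10, seed = 1))
#'
#' @export
capl_demo_data <- function(n = 500, seed = NULL, p_missing = 0.05,
                           config = capl_config()) {
  if (length(n) != 1 || is.na(n) || !is.numeric(n) || n != floor(n) || n < 1) {
    stop("`n` must be an integer greater than zero", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) {
    stats::runif(1) # ensure .Random.seed exists before snapshotting
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }

  miss <- function(x) {
    x[stats::runif(length(x)) < p_missing] <- NA
    x
  }
  clock <- function(hours_min, hours_max) {
    h <- sample(hours_min:hours_max, n, replace = TRUE)
    m <- sample(0:59, n, replace = TRUE)
    twelve <- stats::runif(n) < 0.5
    h12 <- ifelse(h %% 12 == 0, 12, h %% 12)
    ifelse(twelve,
           sprintf("%d:%02d %s", h12, m, ifelse(h < 12, "am", "pm")),
           sprintf("%02d:%02d", h, m))
  }
  likert <- function(k) miss(sample(1:k, n, replace = TRUE))
  knowledge_item <- function(item, n_codes = 4) {
    key <- config$answer_keys[[item]]
    correct_string <- key[suppressWarnings(is.na(as.numeric(key)))][1]
    resp <- as.character(sample(1:n_codes, n, replace = TRUE))
    verbatim <- stats::runif(n) < 0.15
    resp[verbatim] <- correct_string
    miss(resp)
  }
  blank_item <- function(blank) {
    words <- c(config$fill_in_the_blanks[[blank]],
               "exercise", "healthy", "energy", "sweat", "muscles", "rest")
    miss(sample(words, n, replace = TRUE))
  }

  out <- data.frame(
    age = miss(sample(8:12, n, replace = TRUE)),
    gender = miss(sample(
      c("girl", "Girl", "g", "f", "F", "Female", "female",
        "boy", "Boy", "b", "m", "M", "Male", "male", "0", "1"),
      n, replace = TRUE)),
    pacer_lap_distance = miss(sample(c(15, 20), n, replace = TRUE)),
    pacer_laps = miss(sample(1:220, n, replace = TRUE)),
    plank_time = miss(sample(0:300, n, replace = TRUE)),
    camsa_skill_score1 = likert(14),
    camsa_time1 = miss(sample(10:40, n, replace = TRUE)),
    camsa_skill_score2 = likert(14),
    camsa_time2 = miss(sample(10:40, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  for (day in 1:7) {
    out[[paste0("steps", day)]] <- miss(sample(500:30000, n, replace = TRUE))
    out[[paste0("time_on", day)]] <- miss(clock(5, 9))
    out[[paste0("time_off", day)]] <- miss(clock(17, 23))
    out[[paste0("non_wear_time", day)]] <- miss(sample(0:120, n,
                                                       replace = TRUE))
  }
  out$self_report_pa <- miss(sample(0:7, n, replace = TRUE))
  for (i in 1:6) out[[paste0("csappa", i)]] <- likert(4)
  for (i in 1:3) out[[paste0("why_active", i)]] <- likert(5)
  for (i in 1:3) out[[paste0("feelings_about_pa", i)]] <- likert(5)
  out$pa_guideline <- knowledge_item("pa_guideline")
  out$crf_means <- knowledge_item("crf_means")
  out$ms_means <- knowledge_item("ms_means")
  out$sports_skill <- knowledge_item("sports_skill")
  for (blank in names(config$fill_in_the_blanks)) {
    out[[blank]] <- blank_item(blank)
  }
  out[, capl_variables]
}
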