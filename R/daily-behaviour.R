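#' Pedometer wear time for one day
#'
#' Wear time in decimal hours is the time the pedometer came off minus the
#' time it went on, minus any logged non-wear minutes. A missing non-wear
#' entry counts as zero (an empty log line means "worn all day"), but a
#' missing or inverted on/off pair, or a negative result, is `NA`.
#'
#' @param time_on,time_off Clock times in decimal hours (see
#'   [parse_clock_time()]), or clock strings.
#' @param non_wear_minutes Minutes the device was logged as not worn.
#'
#' @return A numeric vector of wear hours.
#'
#' @examples
#' pedometer_wear_time("7:00 am", "9:30 pm", 90)   # 13
#'
#' @export
pedometer_wear_time <- function(time_on, time_off, non_wear_minutes = 0) {
  on <- parse_clock_time(time_on)
  off <- parse_clock_time(time_off)
  nw <- coerce_number(non_wear_minutes)
  nw[is.na(nw)] <- 0
  nw[nw < 0] <- NA
  n <- max(length(on), length(off), length(nw))
  on <- rep_len(on, n)
  off <- rep_len(off, n)
  nw <- rep_len(nw, n)
  hours <- off - on - nw / 60
  hours[is.na(on) | is.na(off) | off <= on] <- NA
  hours[hours < 0] <- NA
  hours
}

#' Validate a day of pedometer steps
#'
#' A day's step count is valid only when it is a whole number inside the
#' plausibility bounds (default 1,000-30,000 steps) *and* the device was
#' worn long enough (default at least 10.0 hours). Invalid days are `NA` and
#' do not count toward the step average.
#'
#' @param steps Daily step counts.
#' @param wear_hours Daily wear time in decimal hours, from
#'   [pedometer_wear_time()].
#' @param config A [capl_config()] list.
#'
#' @return An integer vector: the step count where valid, else `NA`.
#' @export
validate_steps <- function(steps, wear_hours, config = capl_config()) {
  s <- coerce_number(steps)
  w <- coerce_number(wear_hours)
  n <- max(length(s), length(w))
  s <- rep_len(s, n)
  w <- rep_len(w, n)
  ok <- !is.na(s) & s == floor(s) &
    s >= config$steps$min_daily_steps & s <= config$steps$max_daily_steps &
    !is.na(w) & w >= config$steps$min_wear_hours
  as.integer(ifelse(ok, s, NA_real_))
}

#' Weekly step average with fourth-day imputation
#'
#' Validates each of the seven pedometer days (step bounds and wear time),
#' counts valid days, and averages. At least four valid days are required:
#' with four or more the mean of the valid days is reported unrounded; with
#' exactly three, one of the three valid values is sampled uniformly
#' (seeded) as a stand-in fourth day before averaging; with two or fewer the
#' average is `NA`. Records are processed in row order so the imputation
#' stream is reproducible for a given seed.
#'
#' @param data A data frame holding `steps1`-`steps7`, `time_on1`-`time_on7`,
#'   `time_off1`-`time_off7`, and `non_wear_time1`-`non_wear_time7`.
#' @param config A [capl_config()] list.
#' @param seed Integer seed for the imputation draws.
#'
#' @return A data frame with nine columns: the validated `steps1`-`steps7`,
#'   `valid_days` (0-7), and `step_average`.
#' @export
step_average <- function(data, config = capl_config(), seed = 1) {
  data <- scaffold_capl_variables(data)
  n <- nrow(data)
  valid <- matrix(NA_integer_, nrow = n, ncol = 7)
  for (d in 1:7) {
    wt <- pedometer_wear_time(
      data[[paste0("time_on", d)]],
      data[[paste0("time_off", d)]],
      data[[paste0("non_wear_time", d)]]
    )
    valid[, d] <- validate_steps(data[[paste0("steps", d)]], wt, config)
  }
  valid_days <- rowSums(!is.na(valid))
  avg <- rep(NA_real_, n)
  ge4 <- valid_days >= 4
  avg[ge4] <- rowMeans(valid, na.rm = TRUE)[ge4]

  three <- which(valid_days == 3)
  if (length(three)) {
    stats::runif(1) # force RNG initialisation before snapshotting
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    for (i in three) {
      vals <- valid[i, !is.na(valid[i, ])]
      imputed <- vals[sample.int(3, 1)]
      avg[i] <- mean(c(vals, imputed))
    }
  }

  out <- as.data.frame(valid)
  names(out) <- paste0("steps", 1:7)
  out$valid_days <- as.integer(valid_days)
  out$step_average <- avg
  out
}

#' Step score
#'
#' Bins the average daily step count into a 0-25 score through the config
#' step-score table (monotone: more steps never earn a lower score).
#'
#' @param step_average Average daily steps, from [step_average()].
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of scores in 0-25.
#' @export
step_score <- function(step_average, config = capl_config()) {
  s <- coerce_number(step_average)
  s[s < 0] <- NA
  findInterval(s, config$steps$bins_lower)
}

#' Self-reported physical activity score
#'
#' Maps the number of self-reported active days in the past week (0-7) to a
#' 0-5 score via the config mapping (default: capped at 5).
#'
#' @param days Self-reported days physically active, 0-7.
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of scores in 0-5.
#' @export
self_report_pa_score <- function(days, config = capl_config()) {
  d <- validate_scale(days, 0, 7)
  as.numeric(config$self_report$map[d + 1L])
}

#' Daily behaviour domain score
#'
#' The step score (out of 25) plus the self-report score (out of 5), giving
#' a domain score out of 30. Unlike the other domains there is no
#' missing-component reweighting: either part missing makes the domain `NA`.
#'
#' @param step_score Step score in 0-25.
#' @param self_report_pa_score Self-report score in 0-5.
#'
#' @return A numeric vector of domain scores in 0-30.
#' @export
db_score <- function(step_score, self_report_pa_score) {
  st <- coerce_number(step_score)
  se <- coerce_number(self_report_pa_score)
  st[st < 0 | st > 25] <- NA
  se[se < 0 | se > 5] <- NA
  st + se
}
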