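#' Convert PACER laps to their 20-metre equivalent
#'
#' The PACER shuttle run may be administered on a 15 m or 20 m course. Laps
#' run at 20 m are returned unchanged when they are whole numbers inside the
#' valid range (1-229); laps run at 15 m are first converted to their 20 m
#' equivalent through the config conversion table (the protocol's stage
#' structure makes this a chart lookup, not a ratio), then range-checked.
#' Any other course length, out-of-range count, or unparseable value is `NA`.
#'
#' @param lap_distance Course length in metres (15 or 20), vectorized.
#' @param laps_run Lap count, vectorized.
#' @param config A [capl_config()] list.
#'
#' @return An integer vector of 20 m lap counts.
#' @export
pacer_laps_20m <- function(lap_distance, laps_run, config = capl_config()) {
  d <- coerce_number(lap_distance)
  l <- coerce_number(laps_run)
  n <- max(length(d), length(l))
  d <- rep_len(d, n)
  l <- rep_len(l, n)
  out <- rep(NA_real_, n)

  whole <- !is.na(l) & l == floor(l)
  out[!is.na(d) & d == 20 & whole] <- l[!is.na(d) & d == 20 & whole]

  conv <- config$pacer$conversion_15m
  i15 <- which(!is.na(d) & d == 15 & whole)
  if (length(i15)) {
    idx <- match(l[i15], conv$laps_15m)
    out[i15] <- conv$laps_20m[idx]
  }

  rng <- config$pacer$valid_lap_range
  out[!is.na(out) & (out < rng[1] | out > rng[2])] <- NA_real_
  as.integer(out)
}

#' Score the PACER shuttle run
#'
#' Awards one point per `laps_per_point` completed 20 m laps (default 5),
#' capped at the maximum score (default 10): `min(floor(laps / 5), 10)`.
#'
#' @param laps_20m 20 m lap counts, e.g. from [pacer_laps_20m()].
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of scores in 0-10, `NA` where laps are missing.
#' @export
pacer_score <- function(laps_20m, config = capl_config()) {
  l <- coerce_number(laps_20m)
  l[l < 0] <- NA
  pmin(floor(l / config$pacer$laps_per_point), config$pacer$max_score)
}

#' Score the isometric plank hold
#'
#' Awards one point per `seconds_per_point` seconds held (default 12),
#' capped at the maximum score (default 10). Negative, non-numeric, or
#' missing durations are `NA`.
#'
#' @param seconds Plank hold duration in seconds.
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of scores in 0-10.
#' @export
plank_score <- function(seconds, config = capl_config()) {
  s <- coerce_number(seconds)
  s[s < 0] <- NA
  pmin(floor(s / config$plank$seconds_per_point), config$plank$max_score)
}

#' Score a CAMSA trial completion time
#'
#' Bins the obstacle-course completion time into a 1-14 point time score:
#' faster times earn more points, times slower than the last bin edge earn
#' the floor score of 1, and implausibly small or missing times are `NA`.
#'
#' @param seconds Trial completion time in seconds.
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of time scores in 1-14.
#' @export
camsa_time_score <- function(seconds, config = capl_config()) {
  s <- coerce_number(seconds)
  bins <- config$camsa$time_bins
  s[s < config$camsa$min_seconds] <- NA
  # index of first bin whose upper edge is >= time (right-closed bins)
  idx <- length(bins$upper_seconds) -
    findInterval(-s, rev(-bins$upper_seconds)) + 1
  pts <- c(bins$points, bins$slower_points)[idx]
  ifelse(is.na(s), NA_real_, pts)
}

#' Combine a CAMSA trial's skill and time into a skill+time score
#'
#' The skill checklist score (whole number, 0-14) plus the 1-14 time score
#' gives a 1-28 skill+time score per trial. An invalid skill score or an
#' unscorable time makes the whole trial `NA`.
#'
#' @param skill Skill checklist score, 0-14.
#' @param seconds Trial completion time in seconds.
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of skill+time scores in 1-28.
#' @export
camsa_skill_time_score <- function(skill, seconds, config = capl_config()) {
  sk <- as.numeric(validate_scale(skill, 0, 14))
  sk + camsa_time_score(seconds, config)
}

#' Score the CAMSA from two trials
#'
#' Takes the better (maximum) of the two skill+time scores and divides by
#' 2.8 so the result is out of 10. Both trials must be present: the protocol
#' is defined over two trials, so a missing trial makes the score `NA`.
#'
#' @param skill_time1,skill_time2 Skill+time scores (1-28) for trials 1 and 2.
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of CAMSA scores in (0, 10].
#' @export
camsa_score <- function(skill_time1, skill_time2, config = capl_config()) {
  s1 <- coerce_number(skill_time1)
  s2 <- coerce_number(skill_time2)
  s1[s1 < 1 | s1 > 28] <- NA
  s2[s2 < 1 | s2 > 28] <- NA
  pmax(s1, s2) / config$camsa$divisor
}

# Shared reweighting rule for domain scores: sum the components when all are
# present; when exactly one is missing, scale the available sum up to the
# domain total; with two or more missing the domain cannot be scored.
weighted_domain_score <- function(components, maxima) {
  components <- lapply(components, coerce_number)
  n <- max(vapply(components, length, 1L))
  mat <- vapply(components, rep_len, numeric(n), length.out = n)
  if (n == 1) mat <- matrix(mat, nrow = 1)
  for (j in seq_along(maxima)) {
    bad <- !is.na(mat[, j]) & (mat[, j] < 0 | mat[, j] > maxima[j])
    mat[bad, j] <- NA
  }
  total <- sum(maxima)
  n_miss <- rowSums(is.na(mat))
  avail <- rowSums(mat, na.rm = TRUE)
  miss_max <- apply(mat, 1, function(r) sum(maxima[is.na(r)]))
  out <- rep(NA_real_, n)
  out[n_miss == 0] <- avail[n_miss == 0]
  one <- n_miss == 1
  out[one] <- avail[one] * total / (total - miss_max[one])
  out
}

#' Physical competence domain score
#'
#' Sums the PACER, plank, and CAMSA scores (each out of 10) into a domain
#' score out of 30. If exactly one protocol score is missing or invalid, a
#' weighted score is computed from the other two: `(available sum) / 20 * 30`.
#' With two or more missing, the domain is `NA`.
#'
#' @param pacer_score,plank_score,camsa_score Protocol scores, each in 0-10.
#'
#' @return A numeric vector of domain scores in 0-30.
#'
#' @examples
#' pc_score(7, 10, 5)      # 22
#' pc_score(10, 10, NA)    # 30: (20/20) * 30
#'
#' @export
pc_score <- function(pacer_score, plank_score, camsa_score) {
  weighted_domain_score(list(pacer_score, plank_score, camsa_score),
                        maxima = c(10, 10, 10))
}
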