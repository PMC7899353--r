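# Shared helpers: fixture loading, brute-force oracles, toy inputs.
#
# The reference-*.csv fixtures are frozen outputs of a published reference
# run of this scoring system on its demo dataset, transcribed once and kept
# as plain text; tests check that the documented rules reproduce them.

read_fixture <- function(name) {
  utils::read.csv(test_path("fixtures", name), stringsAsFactors = FALSE)
}

# Independent reweighting oracle: literal transcription of the rule, scalar,
# structured differently from the vectorized implementation.
oracle_domain_score <- function(values, maxima) {
  missing <- is.na(values)
  if (sum(missing) == 0) {
    sum(values)
  } else if (sum(missing) == 1) {
    sum(values[!missing]) * sum(maxima) / sum(maxima[!missing])
  } else {
    NA_real_
  }
}

# A small norms table with easily hand-checkable cut points for one
# protocol: quarters of [0, max] for every girl/boy x age 8-12 cell.
toy_norms <- function(protocol = "pc", max_score = 30) {
  cells <- expand.grid(gender = c("girl", "boy"), age = 8:12,
                       stringsAsFactors = FALSE)
  edges <- max_score * c(0, 0.25, 0.5, 0.75, 1)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(protocol = protocol, gender = cells$gender[i],
               age = cells$age[i], category = capl_categories,
               lower = edges[1:4], upper = edges[2:5])
  }))
  validate_capl_norms(rows)
}

# A one-row week of pedometer inputs: every day has 14 h of wear by
# default, so validity is controlled through the step counts.
make_week <- function(steps, time_on = "7:00 am", time_off = "9:00 pm",
                      non_wear = 0) {
  stopifnot(length(steps) == 7)
  week <- data.frame(row.names = 1)
  for (d in 1:7) {
    week[[paste0("steps", d)]] <- steps[d]
    week[[paste0("time_on", d)]] <- time_on
    week[[paste0("time_off", d)]] <- time_off
    week[[paste0("non_wear_time", d)]] <- non_wear
  }
  week
}
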