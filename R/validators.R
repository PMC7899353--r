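#' Quiet validators
#'
#' The scoring engine follows a "quiet" validation philosophy: raw field data
#' are messy, so every validator is total — any scalar (or vector of scalars)
#' is accepted, and values that cannot be validated come back as `NA` instead
#' of raising an error. Scoring functions then propagate `NA` so that a whole
#' table can be scored in one pass without try/catch scaffolding.
#'
#' @name quiet-validation
NULL

# Coerce anything to numeric without warnings; non-coercible -> NA.
coerce_number <- function(x) {
  suppressWarnings(as.numeric(as.character(x)))
}

#' Validate a child's age
#'
#' CAPL-2 scores and interpretations are normed for children aged 8 to 12
#' years. Numeric values (or numeric strings) between 8 and 12 are floored to
#' an integer age, because all age-specific lookups are keyed on integer age;
#' everything else becomes `NA`.
#'
#' @param x A vector of raw ages (numeric, character, or mixed).
#'
#' @return An integer vector the same length as `x`: the floored age for
#'   valid entries, `NA` otherwise.
#'
#' @examples
#' validate_age(c(7, 8, 9, 10, 11, 12, 13, "", NA, "12", 8.5))
#'
#' @export
validate_age <- function(x) {
  v <- coerce_number(x)
  out <- ifelse(!is.na(v) & v >= 8 & v <= 12, floor(v), NA_real_)
  as.integer(out)
}

.girl_tokens <- c("girl", "g", "female", "f", "1")
.boy_tokens <- c("boy", "b", "male", "m", "0")

#' Validate a gender label
#'
#' Field data arrive with many encodings of the same two labels. Membership
#' is case-insensitive with surrounding whitespace ignored: `"Girl"`, `"g"`,
#' `"female"`, `"F"` and `1` all standardize to `"girl"`; `"Boy"`, `"b"`,
#' `"male"`, `"M"` and `0` standardize to `"boy"`. Anything else is `NA`.
#'
#' @param x A vector of raw gender labels (character or numeric).
#'
#' @return A character vector of `"girl"`, `"boy"`, or `NA`.
#'
#' @examples
#' validate_gender(c("Girl", "GIRL", "g", "G", "Female", "f", "F", "", NA, 1))
#'
#' @export
validate_gender <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(v))
  out[!is.na(v) & v %in% .girl_tokens] <- "girl"
  out[!is.na(v) & v %in% .boy_tokens] <- "boy"
  out
}

#' Validate a questionnaire scale response
#'
#' Returns responses that are whole numbers within `[lowest, highest]`;
#' numeric strings are coerced first (spreadsheet imports routinely stringify
#' numbers). Fractional, out-of-range, non-numeric, or missing responses
#' become `NA`.
#'
#' @param x A vector of raw responses.
#' @param lowest,highest Integer bounds of the allowed response range
#'   (`lowest <= highest`).
#'
#' @return An integer vector the same length as `x`.
#'
#' @examples
#' validate_scale(c(3, 5, "2", 2.5, NA), lowest = 1, highest = 4)
#'
#' @export
validate_scale <- function(x, lowest, highest) {
  stopifnot(length(lowest) == 1, length(highest) == 1, lowest <= highest)
  v <- coerce_number(x)
  ok <- !is.na(v) & v == floor(v) & v >= lowest & v <= highest
  as.integer(ifelse(ok, v, NA_real_))
}

#' Parse a clock time to decimal hours
#'
#' Accepts the two dialects seen on CAPL-2 pedometer log sheets: 12-hour
#' times with an am/pm marker (`"7:30 pm"`, case-insensitive, optional
#' space) and 24-hour times (`"19:30"` or `"19:30:15"`). `"12:00 am"` is
#' midnight (0.0) and `"12:30 pm"` is 12.5. Values that are already numeric
#' decimal hours in `[0, 24)` pass through. Anything else is `NA`.
#'
#' @param x A vector of clock-time strings (or decimal hours).
#'
#' @return A numeric vector of decimal hours since midnight in `[0, 24)`.
#'
#' @examples
#' parse_clock_time(c("7:30 pm", "12:00 am", "07:05", "19:30:30", "garbage"))
#'
#' @export
parse_clock_time <- function(x) {
  if (is.numeric(x)) {
    return(ifelse(!is.na(x) & x >= 0 & x < 24, as.numeric(x), NA_real_))
  }
  s <- trimws(as.character(x))
  out <- rep(NA_real_, length(s))

  # numeric strings: decimal hours pass-through
  num <- suppressWarnings(as.numeric(s))
  pass <- !is.na(num) & num >= 0 & num < 24
  out[pass] <- num[pass]

  m <- regmatches(s, regexec(
    "^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?[ ]?([AaPp][Mm])?$", s,
    perl = TRUE
  ))
  for (i in seq_along(s)) {
    if (!is.na(out[i]) || is.na(s[i]) || length(m[[i]]) == 0) next
    h <- as.numeric(m[[i]][2])
    mi <- as.numeric(m[[i]][3])
    se <- if (nzchar(m[[i]][4])) as.numeric(m[[i]][4]) else 0
    ampm <- tolower(m[[i]][5])
    if (mi > 59 || se > 59) next
    if (nzchar(ampm)) {
      if (h < 1 || h > 12) next
      if (h == 12) h <- 0
      if (ampm == "pm") h <- h + 12
    } else {
      if (h > 23) next
    }
    out[i] <- h + mi / 60 + se / 3600
  }
  out
}

#' Ordered interpretive categories
#'
#' The four interpretive categories assigned to CAPL-2 scores, in increasing
#' order of attainment.
#'
#' @format A character vector of length 4.
#' @export
capl_categories <- c("beginning", "progressing", "achieving", "excelling")

#' Domain completeness statuses
#'
#' The four completeness labels a domain can receive, in decreasing order of
#' precedence (first match wins when classifying).
#'
#' @format A character vector of length 4.
#' @export
capl_statuses <- c("incomplete", "missing interpretation", "missing protocol",
                   "complete")
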