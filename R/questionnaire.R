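#' CSAPPA subscale scores (predilection and adequacy)
#'
#' Each CSAPPA item is answered on a 4-level structured-alternative format
#' and mapped to points from the 4-level map `{0.6, 1.2, 1.8, 2.5}`;
#' reverse-worded items (config `csappa$reversed_items`) earn the mirrored
#' points. A subscale is the sum over its three items — predilection uses
#' items 1, 3, 5 and adequacy items 2, 4, 6 — so it ranges from 1.8 to 7.5.
#' Any invalid or missing item makes the subscale `NA`.
#'
#' @param item_a,item_b,item_c Responses (1-4) to the subscale's three items,
#'   in item order (1/3/5 for predilection, 2/4/6 for adequacy).
#' @param subscale `"predilection"` or `"adequacy"`.
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of subscale scores in 1.8-7.5.
#'
#' @examples
#' csappa_subscale_score(4, 4, 4, "predilection")  # 7.5 with default config
#'
#' @export
csappa_subscale_score <- function(item_a, item_b, item_c,
                                  subscale = c("predilection", "adequacy"),
                                  config = capl_config()) {
  subscale <- match.arg(subscale)
  items <- config$csappa$subscales[[subscale]]
  pts <- config$csappa$points
  responses <- list(item_a, item_b, item_c)
  point_sets <- lapply(seq_along(items), function(i) {
    r <- validate_scale(responses[[i]], 1, 4)
    if (items[i] %in% config$csappa$reversed_items) r <- 5L - r
    pts[r]
  })
  point_sets[[1]] + point_sets[[2]] + point_sets[[3]]
}

#' BREQ subscale scores (intrinsic motivation and PA competence)
#'
#' Each BREQ item is answered on a 1-5 agreement scale and earns half its
#' response value, so a three-item subscale ranges from 1.5 to 7.5. The
#' intrinsic-motivation subscale uses the three "why active" items; the
#' physical-activity-competence subscale uses the three "feelings about
#' physical activity" items. Any invalid or missing item makes the subscale
#' `NA`.
#'
#' @param item1,item2,item3 Responses (1-5) to the subscale's three items.
#' @param config A [capl_config()] list.
#'
#' @return A numeric vector of subscale scores in 1.5-7.5.
#'
#' @examples
#' breq_subscale_score(3, 4, 5)  # 6
#'
#' @export
breq_subscale_score <- function(item1, item2, item3, config = capl_config()) {
  d <- config$breq$divisor
  validate_scale(item1, 1, 5) / d +
    validate_scale(item2, 1, 5) / d +
    validate_scale(item3, 1, 5) / d
}

#' Motivation and confidence domain score
#'
#' Sums the predilection, adequacy, intrinsic-motivation, and
#' physical-activity-competence subscales (each out of 7.5) into a domain
#' score out of 30. If exactly one subscale is missing or invalid, the
#' remaining three are reweighted: `(available sum) * 30 / 22.5`. With two
#' or more missing, the domain is `NA`.
#'
#' @param predilection_score,adequacy_score Subscale scores in 0-7.5.
#' @param intrinsic_motivation_score,pa_competence_score Subscale scores in
#'   0-7.5.
#'
#' @return A numeric vector of domain scores in 0-30.
#' @export
mc_score <- function(predilection_score, adequacy_score,
                     intrinsic_motivation_score, pa_competence_score) {
  weighted_domain_score(
    list(predilection_score, adequacy_score, intrinsic_motivation_score,
         pa_competence_score),
    maxima = c(7.5, 7.5, 7.5, 7.5)
  )
}

#' Score a multiple-choice knowledge item
#'
#' A response is correct (1) when it matches one of the accepted answers for
#' the item — either the integer response code or the verbatim answer string
#' (exact match after trimming outer whitespace; set
#' `case_insensitive_matching` in the config to fold case). Any other
#' non-empty response is incorrect (0); an empty or missing response is `NA`.
#'
#' @param response Raw responses: integer codes and/or answer strings.
#' @param answers Accepted values for the item. Defaults to the config
#'   answer key for `item`.
#' @param item One of `"pa_guideline"`, `"crf_means"`, `"ms_means"`,
#'   `"sports_skill"` (used only when `answers` is `NULL`).
#' @param config A [capl_config()] list.
#'
#' @return An integer vector of 0/1 scores.
#'
#' @examples
#' binary_score(c(3, 2, NA), answers = c(3, "60 minutes or 1 hour"))
#'
#' @export
binary_score <- function(response, answers = NULL, item = NULL,
                         config = capl_config()) {
  if (is.null(answers)) {
    if (is.null(item)) stop("supply either `answers` or `item`", call. = FALSE)
    answers <- config$answer_keys[[item]]
    if (is.null(answers)) stop("unknown knowledge item: ", item, call. = FALSE)
  }
  r <- trimws(as.character(response))
  a <- trimws(as.character(answers))
  if (isTRUE(config$case_insensitive_matching)) {
    r <- tolower(r)
    a <- tolower(a)
  }
  out <- as.integer(r %in% a)
  out[is.na(r) | r == ""] <- NA_integer_
  out
}

#' Fill-in-the-blanks score
#'
#' Scores the six blanks of the story-completion question (the story about
#' Sally), one point per blank matching an accepted word in the config key.
#' A blank left empty simply scores zero, so the result is always a count in
#' 0-6, never `NA`.
#'
#' @param pa_is,pa_is_also,improve,increase,when_cooling_down,heart_rate
#'   Responses to the six blanks.
#' @param config A [capl_config()] list.
#'
#' @return An integer vector of scores in 0-6.
#' @export
fill_in_the_blanks_score <- function(pa_is, pa_is_also, improve, increase,
                                     when_cooling_down, heart_rate,
                                     config = capl_config()) {
  blanks <- list(pa_is = pa_is, pa_is_also = pa_is_also, improve = improve,
                 increase = increase, when_cooling_down = when_cooling_down,
                 heart_rate = heart_rate)
  n <- max(vapply(blanks, length, 1L))
  total <- rep(0L, n)
  for (nm in names(blanks)) {
    correct <- binary_score(rep_len(blanks[[nm]], n),
                            answers = config$fill_in_the_blanks[[nm]],
                            config = config)
    correct[is.na(correct)] <- 0L
    total <- total + correct
  }
  total
}

#' Knowledge and understanding domain score
#'
#' Sums the four 1-point knowledge items and the 6-point fill-in-the-blanks
#' score into a domain score out of 10. If exactly one component is missing
#' or invalid, the rest are reweighted by the missing component's maximum:
#' `(available sum) * 10 / (10 - max_missing)`. With two or more missing,
#' the domain is `NA`.
#'
#' @param pa_guideline_score,crf_means_score,ms_means_score,sports_skill_score
#'   Binary item scores (0/1).
#' @param fill_in_the_blanks_score Fill-in-the-blanks score (0-6).
#'
#' @return A numeric vector of domain scores in 0-10.
#' @export
ku_score <- function(pa_guideline_score, crf_means_score, ms_means_score,
                     sports_skill_score, fill_in_the_blanks_score) {
  weighted_domain_score(
    list(pa_guideline_score, crf_means_score, ms_means_score,
         sports_skill_score, fill_in_the_blanks_score),
    maxima = c(1, 1, 1, 1, 6)
  )
}
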