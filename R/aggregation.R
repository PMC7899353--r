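#' Overall physical literacy score
#'
#' Sums the four domain scores — physical competence (/30), daily behaviour
#' (/30), motivation and confidence (/30), knowledge and understanding (/10)
#' — into an overall score out of 100. If exactly one domain is missing or
#' invalid, the rest are reweighted:
#' `(available sum) * 100 / (100 - max_missing)`. With two or more missing,
#' the overall score is `NA`.
#'
#' @param pc_score,db_score,mc_score Domain scores in 0-30.
#' @param ku_score Domain score in 0-10.
#'
#' @return A numeric vector of overall scores in 0-100.
#'
#' @examples
#' capl_score(30, 30, 30, 10)   # 100
#' capl_score(20, NA, 20, 5)    # 45 * 100/70
#'
#' @export
capl_score <- function(pc_score, db_score, mc_score, ku_score) {
  weighted_domain_score(list(pc_score, db_score, mc_score, ku_score),
                        maxima = c(30, 30, 30, 10))
}

#' Load a normative interpretation table
#'
#' Interpretive categories are assigned from normative thresholds by
#' protocol, gender, and integer age. The table is a CSV with columns
#' `protocol`, `gender`, `age`, `category`, `lower`, `upper`; for each
#' (protocol, gender, age) the four category intervals `[lower, upper)`
#' partition the protocol's score range with no gaps or overlaps, with the
#' top category closed at the maximum. The packaged default
#' (`norms-synthetic.csv`) is a synthetic provisional stand-in for the
#' protocol manual's normative tables and is clearly labelled as such; users
#' holding the manual should supply their own file.
#'
#' @param path Path to a norms CSV. `NULL` (default) loads the packaged
#'   synthetic table.
#'
#' @return A validated data frame of class `"capl_norms"`.
#' @export
capl_norms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "norms-synthetic.csv",
                        package = "capl2score")
  }
  if (!file.exists(path)) stop("norms file not found: ", path, call. = FALSE)
  norms <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_capl_norms(norms)
}

#' Write a normative table to CSV
#'
#' @param norms A `capl_norms` data frame.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_capl_norms <- function(norms, path) {
  norms <- validate_capl_norms(norms)
  utils::write.csv(norms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a normative table
#'
#' Rejects tables whose category intervals have gaps or overlaps within any
#' (protocol, gender, age) cell, or whose categories fall outside the
#' controlled vocabulary.
#'
#' @param norms A data frame with columns `protocol`, `gender`, `age`,
#'   `category`, `lower`, `upper`.
#'
#' @return The table, classed `"capl_norms"`.
#' @export
validate_capl_norms <- function(norms) {
  need <- c("protocol", "gender", "age", "category", "lower", "upper")
  miss <- setdiff(need, names(norms))
  if (length(miss)) {
    stop("norms table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(norms$category %in% capl_categories)) {
    stop("norms categories must be one of: ",
         paste(capl_categories, collapse = ", "), call. = FALSE)
  }
  if (!all(norms$gender %in% c("girl", "boy"))) {
    stop("norms gender must be 'girl' or 'boy'", call. = FALSE)
  }
  key <- interaction(norms$protocol, norms$gender, norms$age, drop = TRUE)
  for (cell in split(norms, key)) {
    cell <- cell[order(cell$lower), ]
    if (any(cell$upper <= cell$lower)) {
      stop("norms intervals must have upper > lower (",
           cell$protocol[1], ", ", cell$gender[1], ", age ", cell$age[1], ")",
           call. = FALSE)
    }
    if (nrow(cell) > 1 &&
        any(abs(cell$upper[-nrow(cell)] - cell$lower[-1]) > 1e-9)) {
      stop("norms intervals have a gap or overlap for (",
           cell$protocol[1], ", ", cell$gender[1], ", age ", cell$age[1], ")",
           call. = FALSE)
    }
  }
  class(norms) <- c("capl_norms", "data.frame")
  norms
}

#' Age- and gender-specific interpretation of a score
#'
#' Assigns the interpretive category (`beginning`, `progressing`,
#' `achieving`, `excelling`) whose normative interval contains the score for
#' the child's validated integer age and gender. Age and gender are passed
#' through the quiet validators first, so any invalid age, gender, or score
#' yields `NA`. Intervals are `[lower, upper)` with the top category closed
#' at its upper bound. An unknown protocol name is a programming error and
#' raises.
#'
#' @param age Raw ages (validated via [validate_age()]).
#' @param gender Raw gender labels (validated via [validate_gender()]).
#' @param score The score (or, for protocols normed on a raw measure such as
#'   the plank hold time, that measure) to interpret.
#' @param protocol Protocol or domain name present in the norms table, e.g.
#'   `"pacer"`, `"plank"`, `"camsa"`, `"steps"`, `"pc"`, `"db"`, `"mc"`,
#'   `"ku"`, `"capl"`.
#' @param norms A [capl_norms()] table.
#'
#' @return A character vector of categories, `NA` where undeterminable.
#' @export
capl_interpretation <- function(age, gender, score, protocol,
                                norms = capl_norms()) {
  stopifnot(length(protocol) == 1)
  sub <- norms[norms$protocol == protocol, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("unknown protocol in norms table: ", protocol, call. = FALSE)
  }
  a <- validate_age(age)
  g <- validate_gender(gender)
  s <- coerce_number(score)
  n <- max(length(a), length(g), length(s))
  a <- rep_len(a, n)
  g <- rep_len(g, n)
  s <- rep_len(s, n)
  out <- rep(NA_character_, n)
  for (gg in unique(sub$gender)) {
    for (aa in unique(sub$age)) {
      cell <- sub[sub$gender == gg & sub$age == aa, , drop = FALSE]
      if (nrow(cell) == 0) next
      cell <- cell[order(cell$lower), ]
      rows <- which(!is.na(g) & !is.na(a) & !is.na(s) & g == gg & a == aa)
      if (!length(rows)) next
      # edges [lower_1, ..., lower_k, top_upper]; top interval right-closed
      edges <- c(cell$lower, cell$upper[nrow(cell)])
      idx <- findInterval(s[rows], edges, rightmost.closed = TRUE)
      idx[idx < 1 | idx > nrow(cell)] <- NA
      out[rows] <- cell$category[idx]
    }
  }
  out
}

# component columns per domain, used by capl_domain_status()
.domain_components <- list(
  pc = c("pacer_score", "plank_score", "camsa_score"),
  db = c("step_score", "self_report_pa_score"),
  mc = c("predilection_score", "adequacy_score", "intrinsic_motivation_score",
         "pa_competence_score"),
  ku = c("pa_guideline_score", "crf_means_score", "ms_means_score",
         "sports_skill_score", "fill_in_the_blanks_score"),
  capl = c("pc_score", "db_score", "mc_score", "ku_score")
)

#' Domain completeness status
#'
#' Classifies each row's domain by precedence: a missing domain score is
#' `"incomplete"`; otherwise a missing interpretation is
#' `"missing interpretation"`; otherwise any missing component score is
#' `"missing protocol"`; otherwise `"complete"`. (A reweighted domain score
#' can coexist with a missing component, which is how score and
#' interpretation can be present while a protocol is missing.)
#'
#' @param data A data frame holding the domain's score, interpretation, and
#'   component columns (as produced by [score_capl_data()]).
#' @param domain One of `"pc"`, `"db"`, `"mc"`, `"ku"`, `"capl"`.
#'
#' @return A character vector of statuses (see [capl_statuses]).
#' @export
capl_domain_status <- function(data, domain = c("pc", "db", "mc", "ku",
                                                "capl")) {
  domain <- match.arg(domain)
  comp_cols <- .domain_components[[domain]]
  score_col <- paste0(domain, "_score")
  interp_col <- paste0(domain, "_interpretation")
  for (col in c(comp_cols, score_col, interp_col)) {
    if (is.null(data[[col]])) data[[col]] <- NA
  }
  comp_missing <- Reduce(`|`, lapply(comp_cols, function(cl) is.na(data[[cl]])))
  out <- rep("complete", nrow(data))
  out[comp_missing] <- "missing protocol"
  out[is.na(data[[interp_col]])] <- "missing interpretation"
  out[is.na(data[[score_col]])] <- "incomplete"
  out
}
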