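cfg <- capl_config()

csappa_triples <- expand.grid(a = 1:4, b = 1:4, c = 1:4)

test_that("CSAPPA subscales span 1.8-7.5 and reject invalid items", {
  for (sub in c("predilection", "adequacy")) {
    scores <- csappa_subscale_score(csappa_triples$a, csappa_triples$b,
                                    csappa_triples$c, sub, cfg)
    expect_equal(min(scores), 1.8)
    expect_equal(max(scores), 7.5)
    expect_false(anyNA(scores))
  }
  expect_equal(csappa_subscale_score(1, 5, 1, "predilection", cfg), NA_real_)
  expect_equal(csappa_subscale_score(1, NA, 1, "adequacy", cfg), NA_real_)
})

test_that("reference subscale vectors decompose over the 4-point map", {
  pts <- cfg$csappa$points # 0.6, 1.2, 1.8, 2.5
  sums <- round(c(outer(c(outer(pts, pts, "+")), pts, "+")), 1)
  ref <- read_fixture("reference-subscales.csv")
  for (col in c("predilection_score", "adequacy_score")) {
    vals <- round(ref[[col]][!is.na(ref[[col]])], 1)
    expect_true(all(vals %in% sums), label = col)
  }
})

test_that("BREQ subscales are half the response sum", {
  expect_equal(breq_subscale_score(1, 1, 1, cfg), 1.5)
  expect_equal(breq_subscale_score(5, 5, 5, cfg), 7.5)
  expect_equal(breq_subscale_score(3, 4, 5, cfg), 6)
  expect_equal(breq_subscale_score(0, 3, 3, cfg), NA_real_)
  # reference vectors: multiples of 0.5 within [1.5, 7.5]
  ref <- read_fixture("reference-subscales.csv")
  for (col in c("intrinsic_motivation_score", "pa_competence_score")) {
    vals <- ref[[col]][!is.na(ref[[col]])]
    expect_true(all(vals >= 1.5 & vals <= 7.5), label = col)
    expect_true(all(abs(vals * 2 - round(vals * 2)) < 1e-9), label = col)
  }
})

test_that("mc_score matches the brute-force reweighting oracle", {
  vals <- c(1.8, 4.3, 7.5, NA)
  grid <- expand.grid(p = vals, a = vals, i = vals, c = vals)
  got <- mc_score(grid$p, grid$a, grid$i, grid$c)
  want <- vapply(seq_len(nrow(grid)), function(r) {
    oracle_domain_score(unlist(grid[r, ]), rep(7.5, 4))
  }, numeric(1))
  expect_equal(got, want)
  expect_equal(mc_score(7.5, 7.5, 7.5, 7.5), 30)
  expect_equal(mc_score(6, 6, 6, NA), 24)
  expect_equal(mc_score(6, NA, NA, 6), NA_real_)
})

test_that("binary_score accepts the code or the verbatim answer", {
  expect_identical(binary_score(3, item = "pa_guideline", config = cfg), 1L)
  expect_identical(binary_score(2, item = "pa_guideline", config = cfg), 0L)
  expect_identical(binary_score("3", item = "pa_guideline", config = cfg), 1L)
  expect_identical(
    binary_score("60 minutes or 1 hour", item = "pa_guideline", config = cfg),
    1L)
  expect_identical(
    binary_score("How well the muscles can push, pull or stretch",
                 item = "ms_means", config = cfg), 1L)
  expect_identical(
    binary_score("  60 minutes or 1 hour  ", item = "pa_guideline",
                 config = cfg), 1L) # outer whitespace trimmed
  # matching is case-sensitive unless the config flag is set
  expect_identical(
    binary_score("60 MINUTES OR 1 HOUR", item = "pa_guideline",
                 config = cfg), 0L)
  cfg_ci <- cfg
  cfg_ci$case_insensitive_matching <- TRUE
  expect_identical(
    binary_score("60 MINUTES OR 1 HOUR", item = "pa_guideline",
                 config = cfg_ci), 1L)
  expect_identical(binary_score(c("", NA), item = "crf_means", config = cfg),
                   c(NA_integer_, NA_integer_))
  expect_error(binary_score(1, item = "nope", config = cfg), "unknown")
  expect_error(binary_score(1, config = cfg), "supply")
})

test_that("fill_in_the_blanks_score counts correct blanks, never NA", {
  key <- cfg$fill_in_the_blanks
  right <- vapply(key, `[`, character(1), 1)
  expect_identical(
    fill_in_the_blanks_score(right[["pa_is"]], right[["pa_is_also"]],
                             right[["improve"]], right[["increase"]],
                             right[["when_cooling_down"]],
                             right[["heart_rate"]], cfg), 6L)
  expect_identical(
    fill_in_the_blanks_score("w", "r", "o", "n", "g", "!", cfg), 0L)
  expect_identical(
    fill_in_the_blanks_score(right[["pa_is"]], right[["pa_is_also"]],
                             right[["improve"]], NA, NA, NA, cfg), 3L)
  expect_identical(fill_in_the_blanks_score(NA, NA, NA, NA, NA, NA, cfg), 0L)
})

test_that("ku_score reproduces the 80 reference rows and the oracle", {
  ref <- read_fixture("reference-ku.csv")
  got <- ku_score(ref$pa_guideline_score, ref$crf_means_score,
                  ref$ms_means_score, ref$sports_skill_score,
                  ref$fill_in_the_blanks_score)
  expect_equal(got, ref$ku_score)

  vals <- list(q = c(0, 1, NA), fill = c(0, 3, 6, NA))
  grid <- expand.grid(q1 = vals$q, q2 = vals$q, q3 = vals$q, q4 = vals$q,
                      f = vals$fill)
  got <- ku_score(grid$q1, grid$q2, grid$q3, grid$q4, grid$f)
  want <- vapply(seq_len(nrow(grid)), function(r) {
    oracle_domain_score(unlist(grid[r, ]), c(1, 1, 1, 1, 6))
  }, numeric(1))
  expect_equal(got, want)
  expect_equal(ku_score(1, 0, 0, 1, 5), 7)
  expect_equal(ku_score(1, 1, 1, 1, NA), 10)
  expect_equal(ku_score(NA, NA, 1, 1, 6), NA_real_)
})
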