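test_that("capl_score matches the brute-force reweighting oracle", {
  vals30 <- c(0, 12, 30, NA)
  vals10 <- c(0, 5, 10, NA)
  grid <- expand.grid(pc = vals30, db = vals30, mc = vals30, ku = vals10)
  got <- capl_score(grid$pc, grid$db, grid$mc, grid$ku)
  want <- vapply(seq_len(nrow(grid)), function(r) {
    oracle_domain_score(unlist(grid[r, ]), c(30, 30, 30, 10))
  }, numeric(1))
  expect_equal(got, want)
  expect_equal(capl_score(30, 30, 30, 10), 100)
  expect_equal(capl_score(20, NA, 20, 5), 45 * 100 / 70)
  expect_equal(capl_score(20, NA, NA, 5), NA_real_)
})

test_that("interpretation looks the score up in the right norm cell", {
  norms <- toy_norms("pc", 30) # quarters of [0, 30] for every cell
  # linear-scan containment oracle over injected toy norms
  oracle <- function(age, gender, score) {
    cell <- norms[norms$gender == gender & norms$age == age, ]
    hit <- which(score >= cell$lower &
                   (score < cell$upper | cell$upper == 30 & score == 30))
    if (length(hit)) cell$category[hit[1]] else NA_character_
  }
  set.seed(9)
  ages <- sample(8:12, 50, replace = TRUE)
  genders <- sample(c("girl", "boy"), 50, replace = TRUE)
  scores <- round(runif(50, 0, 30), 2)
  expect_equal(
    capl_interpretation(ages, genders, scores, "pc", norms),
    mapply(oracle, ages, genders, scores, USE.NAMES = FALSE)
  )
  # interval convention: [lower, upper) with the top closed at the maximum
  expect_equal(capl_interpretation(10, "girl", 7.5, "pc", norms),
               "progressing")
  expect_equal(capl_interpretation(10, "girl", 30, "pc", norms), "excelling")
  expect_equal(capl_interpretation(10, "girl", 0, "pc", norms), "beginning")
  expect_equal(capl_interpretation(10, "girl", 31, "pc", norms),
               NA_character_)
})

test_that("interpretation validates age and gender quietly", {
  norms <- toy_norms("pacer", 10)
  expect_equal(capl_interpretation(7, "girl", 8, "pacer", norms),
               NA_character_)
  expect_equal(capl_interpretation(10, "", 8, "pacer", norms), NA_character_)
  expect_equal(capl_interpretation(10, "girl", NA, "pacer", norms),
               NA_character_)
  # gender synonyms are interchangeable
  for (g in c("F", "female", "Girl", 1)) {
    expect_equal(capl_interpretation(9, g, 8, "pacer", norms),
                 capl_interpretation(9, "girl", 8, "pacer", norms))
  }
  # an unknown protocol is a programming error, not messy data
  expect_error(capl_interpretation(10, "girl", 8, "bogus", norms), "unknown")
})

test_that("norms validation rejects gaps, overlaps, and bad labels", {
  norms <- toy_norms("pc", 30)
  expect_s3_class(validate_capl_norms(norms), "capl_norms")
  gap <- norms
  gap$lower[gap$category == "achieving"] <-
    gap$lower[gap$category == "achieving"] + 1
  expect_error(validate_capl_norms(gap), "gap or overlap")
  bad <- norms
  bad$category[1] <- "superb"
  expect_error(validate_capl_norms(bad), "categories")
  inverted <- norms
  inverted$upper[1] <- inverted$lower[1]
  expect_error(validate_capl_norms(inverted), "upper > lower")
  # the packaged synthetic table passes its own validation
  expect_s3_class(capl_norms(), "capl_norms")
})

test_that("norms round-trip through CSV bit-exactly", {
  norms <- capl_norms()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_capl_norms(norms, tmp)
  again <- capl_norms(tmp)
  expect_identical(as.data.frame(again), as.data.frame(norms))
})

test_that("domain status precedence reproduces the 30 reference rows", {
  ref <- read_fixture("reference-pc-status.csv")
  d <- data.frame(
    pacer_score = ref$pacer_score, plank_score = ref$plank_score,
    camsa_score = ref$camsa_score, pc_score = ref$pc_score,
    pc_interpretation = ref$pc_interpretation
  )
  expect_identical(capl_domain_status(d, "pc"), ref$pc_status)
})

test_that("domain status follows its precedence order", {
  d <- data.frame(
    pacer_score = c(10, 10, 10, NA, NA),
    plank_score = c(10, 10, 10, 10, NA),
    camsa_score = c(5, 5, NA, 10, 8),
    pc_score = c(25, 25, 30, 30, NA),
    pc_interpretation = c("achieving", NA, "excelling", NA, NA)
  )
  expect_identical(
    capl_domain_status(d, "pc"),
    c("complete", "missing interpretation", "missing protocol",
      "missing interpretation", "incomplete")
  )
  # absent columns are treated as all-missing, not an error
  expect_identical(capl_domain_status(data.frame(x = 1), "db"), "incomplete")
})
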