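test_that("respondent fractions are exact", {
  sv <- survey_with_fractions(c(0, 32, 8), n_videos = 32)
  f <- respondent_fraction_seen(sv, survey_video_ids(sv))
  expect_equal(f, c(0, 1, 0.25))
  expect_error(respondent_fraction_seen(sv, "nope"), "nope")
})

test_that("weighted mean proportion matches hand computation", {
  # weights 1,2,1 with fractions 0.5, 0.25, 1.0 -> (0.5 + 0.5 + 1.0)/4 = 0.5
  sv <- survey_with_fractions(c(2, 1, 4), n_videos = 4, weight = c(1, 2, 1))
  est <- mean_proportion_viewed(sv, survey_video_ids(sv))
  expect_equal(est$p_bar, 0.5)
})

test_that("degenerate variance gives a point interval", {
  sv <- survey_with_fractions(rep(3, 5), n_videos = 4, weight = c(1, 5, 2, 1, 3))
  est <- mean_proportion_viewed(sv, survey_video_ids(sv))
  expect_equal(est$p_bar, 0.75)
  expect_equal(est$se, 0)
  expect_equal(est$ci_low, 0.75)
  expect_equal(est$ci_high, 0.75)
})

test_that("equal weights reproduce the unweighted brute-force estimate", {
  set.seed(21)
  n <- 200
  k <- sample(0:8, n, replace = TRUE)
  sv <- survey_with_fractions(k, n_videos = 8, weight = rep(2.5, n))
  est <- mean_proportion_viewed(sv, survey_video_ids(sv))

  f <- k / 8
  expect_equal(est$p_bar, mean(f))
  expect_equal(est$se, sqrt(var(f) / n))
  expect_equal(est$n_effective, n)
  # and the explicit unweighted method agrees even when weights vary
  sv2 <- survey_with_fractions(k, n_videos = 8, weight = runif(n, 0.5, 2))
  est2 <- mean_proportion_viewed(sv2, survey_video_ids(sv2), method = "unweighted")
  expect_equal(est2$p_bar, mean(f))
  expect_equal(est2$se, sqrt(var(f) / n))
})

test_that("Kish effective sample size never exceeds n when weights vary", {
  set.seed(31)
  sv <- survey_with_fractions(sample(0:4, 50, TRUE), n_videos = 4,
                              weight = rlnorm(50, 0, 0.5))
  est <- mean_proportion_viewed(sv, survey_video_ids(sv))
  expect_lt(est$n_effective, est$n_respondents)
  expect_true(est$ci_low <= est$p_bar && est$p_bar <= est$ci_high)
})

test_that("per-video proportion matches hand computation and the Fubini identity holds", {
  # weights 1,1,2 with indicators 1,0,0 -> 0.25
  seen <- cbind(v01 = c(1L, 0L, 0L), v02 = c(1L, 1L, 0L))
  sv <- make_survey(age = c(20, 30, 40), gender = c("female", "male", "female"),
                    weight = c(1, 1, 2), seen = seen)
  est <- per_video_proportion(sv, "v01")
  expect_equal(est$p_bar, 0.25)

  # mean over videos of per-video weighted proportions = weighted mean of fractions
  set.seed(41)
  n <- 80
  seen2 <- matrix(rbinom(n * 6, 1, 0.3), n, dimnames = list(NULL, sprintf("v%02d", 1:6)))
  sv2 <- make_survey(age = sample(11:70, n, TRUE),
                     gender = sample(c("female", "male"), n, TRUE),
                     weight = rlnorm(n, 0, 0.4), seen = seen2)
  ids <- survey_video_ids(sv2)
  per_video <- vapply(ids, function(v) per_video_proportion(sv2, v)$p_bar, numeric(1))
  expect_equal(mean(per_video), mean_proportion_viewed(sv2, ids)$p_bar)
})

test_that("merging two disjoint strata yields a reach between the two", {
  set.seed(51)
  n <- 120
  seen <- matrix(rbinom(n * 4, 1, rep(c(0.4, 0.1), each = n / 2)), n,
                 dimnames = list(NULL, sprintf("v%02d", 1:4)))
  sv <- make_survey(age = rep(c(15L, 40L), each = n / 2),
                    gender = sample(c("female", "male"), n, TRUE),
                    weight = rlnorm(n, 0, 0.3), seen = seen)
  ids <- survey_video_ids(sv)
  young <- mean_proportion_viewed(sv, ids, stratum(11, 19))$p_bar
  old <- mean_proportion_viewed(sv, ids, stratum(19, Inf))$p_bar
  all <- mean_proportion_viewed(sv, ids, stratum(11, Inf))$p_bar
  expect_gte(all, min(young, old))
  expect_lte(all, max(young, old))
})

test_that("CI width shrinks roughly as 1/sqrt(n)", {
  width <- function(n, seed) {
    set.seed(seed)
    sv <- survey_with_fractions(rbinom(n, 8, 0.2), n_videos = 8,
                                weight = rlnorm(n, 0, 0.3))
    est <- mean_proportion_viewed(sv, survey_video_ids(sv))
    est$ci_high - est$ci_low
  }
  ratios <- vapply(1:10, function(s) width(400, s) / width(1600, 100 + s), numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})

test_that("empty and singleton strata are explicit errors", {
  sv <- survey_with_fractions(c(1, 2, 3), n_videos = 4, age = c(20, 21, 15))
  ids <- survey_video_ids(sv)
  expect_error(mean_proportion_viewed(sv, ids, stratum(70, 80)), "no respondents")
  expect_error(mean_proportion_viewed(sv, ids, stratum(11, 19)), "one respondent")
})

test_that("survey reading validates and round-trips", {
  sv <- survey_with_fractions(c(0, 1, 2, 3, 4), n_videos = 4,
                              age = c(12, 25, 33, 47, 61),
                              weight = c(0.8, 1.1, 1.0, 1.3, 0.9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(sv, path)
  back <- read_survey(path, video_ids = survey_video_ids(sv))
  expect_equal(nrow(back), 5L)
  expect_equal(as.data.frame(back[survey_video_ids(sv)]),
               as.data.frame(sv[survey_video_ids(sv)]))

  bad <- sv; bad$respondent_id[2] <- bad$respondent_id[1]
  readr::write_csv(bad, path)
  expect_error(read_survey(path), "duplicate respondent_id")

  bad <- sv; bad$weight[3] <- -1
  readr::write_csv(bad, path)
  expect_error(read_survey(path), "weight in row 3")

  bad <- sv; bad$age[1] <- 7L
  readr::write_csv(bad, path)
  expect_error(read_survey(path), "invalid age")
})

test_that("missing ever-seen answers are recoded or dropped as configured", {
  sv <- survey_with_fractions(c(4, 0, 2), n_videos = 4)
  sv$v01[2] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sv, path)
  as_unseen <- read_survey(path, video_ids = sprintf("v%02d", 1:4))
  expect_equal(nrow(as_unseen), 3L)
  expect_identical(as_unseen$v01[2], 0L)
  dropped <- read_survey(path, video_ids = sprintf("v%02d", 1:4), missing_seen = "drop")
  expect_equal(nrow(dropped), 2L)
})
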