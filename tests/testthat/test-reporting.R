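# survey in which every respondent saw exactly half the videos, so reach is
# exactly 0.5 in every stratum
half_seen_survey <- function(n_videos = 8, per_band = 4) {
  scheme <- default_strata()
  bands <- scheme[scheme$role == "band", ]
  age <- integer(0)
  for (i in seq_len(nrow(bands))) {
    top <- if (is.infinite(bands$age_high[i])) bands$age_low[i] + 5 else bands$age_high[i] - 1
    age <- c(age, rep(c(bands$age_low[i], top), length.out = per_band))
  }
  n <- length(age)
  seen <- t(vapply(seq_len(n), function(i) {
    as.integer(seq_len(n_videos) <= n_videos / 2)
  }, integer(n_videos)))
  colnames(seen) <- sprintf("v%02d", seq_len(n_videos))
  make_survey(age = age, gender = rep(c("female", "male"), length.out = n),
              weight = runif(n, 0.5, 2), seen = seen)
}

fixed_videos <- function(n_videos = 8, alcohol_every = 2, tobacco_every = 4) {
  vids <- lapply(seq_len(n_videos), function(i) {
    n <- 20L
    flags <- tibble::tibble(
      interval_index = seq_len(n) - 1L,
      alcohol.actual_use.visual = as.integer(seq_len(n) %% alcohol_every == 0),
      tobacco.brand.visual = as.integer(seq_len(n) %% tobacco_every == 0)
    )
    coded_video(sprintf("v%02d", i), 200, flags)
  })
  names(vids) <- sprintf("v%02d", seq_len(n_videos))
  vids
}

test_that("a forced 50% reach scenario gives every cell 0.5 x N x I by hand", {
  set.seed(81)
  videos <- fixed_videos()
  sv <- half_seen_survey()
  et <- build_exposure_table(videos, sv, uk_population())
  I <- et$interval_counts
  expect_identical(unname(I), c(80L, 40L)) # 8 videos x 20 intervals, every 2nd / 4th
  res <- et$results
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_bar[i], 0.5)
    expect_equal(res$gross[i],
                 0.5 * res$population_millions[i] * I[[res$class[i]]])
  }
})

test_that("a zero-content scenario zeroes impressions but not proportions", {
  sc <- generate_scenario(generator_config(seed = 31, n_videos = 6, total_intervals = 150,
                                           n_adolescents = 200, n_adults = 200,
                                           content_rates = c(alcohol = 0, tobacco = 0,
                                                             electronic_cigarette = 0)))
  et <- build_exposure_table(sc$videos, sc$survey, sc$population)
  expect_true(all(et$results$gross == 0))
  expect_true(all(et$results$per_capita == 0))
  expect_true(any(et$results$p_bar > 0))
})

test_that("the substance-ratio identity holds in every stratum of any scenario", {
  sc <- generate_scenario(generator_config(seed = 13, n_videos = 10, total_intervals = 260,
                                           n_adolescents = 250, n_adults = 250))
  et <- build_exposure_table(sc$videos, sc$survey, sc$population)
  I <- et$interval_counts
  res <- et$results
  alc <- res[res$class == "alcohol", ]
  tob <- res[res$class == "tobacco", ]
  tob <- tob[match(alc$stratum, tob$stratum), ]
  nz <- alc$gross > 0
  expect_equal(tob$gross[nz] / alc$gross[nz],
               rep(I[["tobacco"]] / I[["alcohol"]], sum(nz)))
})

test_that("the Total row equals the aggregate of its band rows", {
  sc <- generate_scenario(generator_config(seed = 14, n_videos = 8, total_intervals = 200,
                                           n_adolescents = 300, n_adults = 400))
  et <- build_exposure_table(sc$videos, sc$survey, sc$population)
  res <- et$results
  for (cl in c("alcohol", "tobacco")) {
    bands <- res[res$class == cl & res$role == "band", ]
    tot <- res[res$class == cl & res$role == "total", ]
    expect_equal(tot$gross, sum(bands$gross))
    expect_equal(tot$gross_ci_low, sum(bands$gross_ci_low))
    expect_equal(tot$per_capita, sum(bands$gross) / sum(bands$population_millions))
  }
})

test_that("chart data projects table cells exactly, with the expected record count", {
  sc <- generate_scenario(generator_config(seed = 15, n_videos = 8, total_intervals = 200,
                                           n_adolescents = 600, n_adults = 800))
  et <- build_exposure_table(sc$videos, sc$survey,
                             split_population_by_gender(sc$population),
                             scheme = gender_band_strata(), total_label = NULL)
  chart <- build_percapita_chart_data(et)
  expect_identical(nrow(chart), 8L * 2L * 2L) # bands x genders x classes
  for (i in seq_len(nrow(chart))) {
    src <- et$results[et$results$stratum == paste(chart$age_band[i], chart$gender[i]) &
                        et$results$class == chart$class[i], ]
    expect_equal(chart$per_capita[i], src$per_capita)
  }
  # the generator's positive female effect shows up in every band
  wide <- tidyr::pivot_wider(chart[, c("age_band", "gender", "class", "per_capita")],
                             names_from = "gender", values_from = "per_capita")
  expect_true(all(wide$female > wide$male))
})

test_that("chart data requires gender-split bands", {
  set.seed(82)
  et <- build_exposure_table(fixed_videos(), half_seen_survey(), uk_population())
  expect_error(build_percapita_chart_data(et), "gender-split")
})

test_that("rendering is pure and writing produces a complete audit trail", {
  sc <- generate_scenario(generator_config(seed = 16, n_videos = 6, total_intervals = 150,
                                           n_adolescents = 200, n_adults = 200))
  et <- build_exposure_table(sc$videos, sc$survey, sc$population)
  r1 <- render_exposure_table(et)
  r2 <- render_exposure_table(et)
  expect_identical(r1, r2)

  dir <- withr::local_tempdir()
  paths <- write_exposure_table(et, dir)
  expect_true(all(file.exists(paths[c("table", "json", "audit")])))
  audit <- jsonlite::read_json(paths[["audit"]], simplifyVector = TRUE)
  cells <- audit$cells
  # every written cell reproduces from its audited (p_bar, N, I) triple
  expect_equal(cells$gross, cells$p_bar * cells$population_millions * cells$intervals,
               tolerance = 1e-12)
  back <- readr::read_csv(paths[["table"]], show_col_types = FALSE)
  expect_identical(nrow(back), length(unique(et$results$stratum)))
})

test_that("rendered cells use half-up rounding at published precision", {
  r <- tibble::tibble(stratum = "Adults", age_low = 19, age_high = Inf, gender = "all",
                      p_bar = 0.1, se = 0, ci_low = 0.1, ci_high = 0.1,
                      n_respondents = 10L, n_effective = 10)
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(-2.345, 2), -2.35)
  expect_equal(round_half_up(2.344999, 2), 2.34)
  expect_equal(round_half_up(per_capita(695.09, 49.20), 2), 14.13)
})

test_that("per-video tables rank videos by delivered impressions", {
  sc <- generate_scenario(generator_config(seed = 17, n_videos = 6, total_intervals = 150,
                                           n_adolescents = 250, n_adults = 250))
  vt <- video_exposure_table(sc$videos, sc$survey, sc$population)
  expect_identical(nrow(vt), 6L * 2L * 2L) # videos x strata x classes
  # per-video gross uses the video's own interval count and reach
  i <- which(vt$class == "alcohol" & vt$stratum == "Adults")[1]
  v <- sc$videos[[vt$video_id[i]]]
  expect_equal(vt$intervals[i], count_content_intervals(v, "alcohol"))
  expect_equal(vt$gross[i], vt$p_bar[i] * vt$population_millions[i] * vt$intervals[i])
  # summing per-video adolescent+adult gross equals per-video whole-population gross
  ado <- vt[vt$stratum == "Adolescents" & vt$class == "alcohol", ]
  adu <- vt[vt$stratum == "Adults" & vt$class == "alcohol", ]
  expect_identical(ado$video_id %in% adu$video_id, rep(TRUE, nrow(ado)))
})
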