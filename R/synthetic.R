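#' Configuration for the synthetic-data generator
#'
#' The generator emulates the structure of the UK music-video exposure
#' study: 32 coded videos totalling about 821 ten-second intervals with
#' roughly 233 alcohol, 47 tobacco and 6 e-cigarette content intervals;
#' ~2068 adolescent (11-18) and ~2232 adult (19+) survey respondents with
#' calibrated-looking weights; ever-seen probability declining with age on
#' the log-odds scale and higher for females, yielding group reach near
#' 0.22 for adolescents and 0.06 for adults; and the published mid-year
#' population margins.
#'
#' A single root `seed` is split into independent substreams (interval
#' counts, content flags, video popularity effects, ages, genders/regions,
#' weights, ever-seen draws), so changing how many draws one component
#' consumes does not perturb the others.
#'
#' @param seed integer root seed; fixed seed gives byte-identical output.
#' @param n_videos number of coded videos.
#' @param total_intervals target total interval count across videos;
#'   per-video counts are uniform integers on `interval_range`, then
#'   nudged so the realised total equals the target exactly.
#' @param interval_range length-2 integer range for per-video interval
#'   counts.
#' @param content_rates named per-interval Bernoulli probabilities for
#'   `alcohol`, `tobacco`, `electronic_cigarette`; defaults are the study
#'   margins divided by the total interval count (233/821, 47/821, 6/821).
#' @param overlap_rate probability that a tobacco interval also carries
#'   alcohol. `NULL` (default) means independence, i.e. the alcohol rate;
#'   any value keeps the alcohol margin by compensating the rate in
#'   non-tobacco intervals.
#' @param n_adolescents,n_adults respondents per survey.
#' @param viewing_model list with `intercept` (log-odds of ever-seen at
#'   `reference_age` for males), `age_slope` (per year), `female_effect`
#'   (log-odds), `video_sd` (SD of the per-video popularity random
#'   effect), `reference_age`.
#' @param weight_dispersion log-scale SD of the lognormal survey weights
#'   (mean 1); 0 gives exactly equal weights.
#' @param max_age oldest simulated age (open-ended census bands are
#'   truncated here).
#' @param population a [population_table()] providing both the simulated
#'   age distribution (persons per single year of age within each band)
#'   and the N margins of the scenario.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_videos = 32L,
                             total_intervals = 821L,
                             interval_range = c(20L, 32L),
                             content_rates = c(alcohol = 233 / 821,
                                               tobacco = 47 / 821,
                                               electronic_cigarette = 6 / 821),
                             overlap_rate = NULL,
                             n_adolescents = 2068L,
                             n_adults = 2232L,
                             viewing_model = list(intercept = -1.783, age_slope = -0.06,
                                                  female_effect = 0.5, video_sd = 0.8,
                                                  reference_age = 16),
                             weight_dispersion = 0.3,
                             max_age = 80L,
                             population = uk_population()) {
  if (length(seed) != 1 || !is.finite(seed)) stop_input("seed must be a single integer")
  if (n_videos < 1) stop_input("n_videos must be at least 1")
  if (any(content_rates < 0 | content_rates > 1))
    stop_input("content_rates must lie in [0, 1]")
  unknown <- setdiff(names(content_rates), substances())
  if (length(unknown) > 0)
    stop_input("unknown substance(s) in content_rates: %s", paste(unknown, collapse = ", "))
  if (!is.null(overlap_rate) && (overlap_rate < 0 || overlap_rate > 1))
    stop_input("overlap_rate must lie in [0, 1]")
  if (weight_dispersion < 0) stop_input("weight_dispersion must be non-negative")
  needed <- c("intercept", "age_slope", "female_effect", "video_sd", "reference_age")
  if (!all(needed %in% names(viewing_model)))
    stop_input("viewing_model must supply: %s", paste(needed, collapse = ", "))
  structure(list(
    seed = as.integer(seed), n_videos = as.integer(n_videos),
    total_intervals = as.integer(total_intervals),
    interval_range = as.integer(interval_range),
    content_rates = content_rates, overlap_rate = overlap_rate,
    n_adolescents = as.integer(n_adolescents), n_adults = as.integer(n_adults),
    viewing_model = viewing_model, weight_dispersion = weight_dispersion,
    max_age = as.integer(max_age), population = population
  ), class = "generator_config")
}

# substream seeds derived once from the root seed; components re-seed from
# these so their draw counts stay independent of each other
substream_seeds <- function(config) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  names(seeds) <- c("interval_counts", "flags", "video_effects", "ages",
                    "gender_region", "weights", "seen", "spare")
  seeds
}

#' Generate synthetic coded videos
#'
#' Per-video interval counts are uniform on `interval_range` and adjusted
#' to hit `total_intervals` exactly; durations are the implied seconds
#' minus a random 0-9 s partial-interval remainder. Tobacco presence is
#' Bernoulli at its rate; alcohol is drawn conditionally on tobacco so the
#' configured tobacco-alcohol overlap holds while the alcohol margin is
#' preserved; e-cigarette flags are independent. A content-bearing interval
#' gets one (category, channel) flag uniformly at random plus sparse extra
#' flags.
#'
#' @param config a [generator_config()].
#' @return named list of [coded_video()] objects.
#' @export
generate_videos <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ss <- substream_seeds(config)
  set.seed(ss[["interval_counts"]])
  lo <- config$interval_range[1]; hi <- config$interval_range[2]
  counts <- sample(lo:hi, config$n_videos, replace = TRUE)
  counts <- nudge_to_total(counts, config$total_intervals, lower = 10L, upper = hi + 10L)
  remainders <- sample(0:9, config$n_videos, replace = TRUE)
  durations <- counts * 10 - remainders

  rate <- function(s) unname(config$content_rates[s] %||% 0)
  p_alc <- rate("alcohol"); p_tob <- rate("tobacco"); p_ecig <- rate("electronic_cigarette")
  ov <- config$overlap_rate %||% p_alc
  # alcohol rate in non-tobacco intervals that preserves the alcohol margin
  p_alc_given_not <- if (p_tob < 1) (p_alc - p_tob * ov) / (1 - p_tob) else p_alc
  if (p_alc_given_not < 0 || p_alc_given_not > 1)
    stop_input("overlap_rate %.3f is incompatible with the configured margins", ov)

  set.seed(ss[["flags"]])
  videos <- lapply(seq_len(config$n_videos), function(i) {
    n <- counts[i]
    tob <- rbinom(n, 1, p_tob)
    alc <- ifelse(tob == 1, rbinom(n, 1, ov), rbinom(n, 1, p_alc_given_not))
    ecig <- rbinom(n, 1, p_ecig)
    intervals <- tibble::tibble(interval_index = seq_len(n) - 1L)
    for (s in substances()) {
      present <- switch(s, tobacco = tob, alcohol = alc, electronic_cigarette = ecig)
      cols <- flag_columns(s)
      mat <- matrix(0L, n, length(cols), dimnames = list(NULL, cols))
      hit <- which(present == 1)
      if (length(hit) > 0) {
        primary <- sample.int(length(cols), length(hit), replace = TRUE)
        mat[cbind(hit, primary)] <- 1L
        extra <- matrix(rbinom(length(hit) * length(cols), 1, 0.15),
                        length(hit), length(cols))
        mat[hit, ] <- pmax(mat[hit, , drop = FALSE], extra)
      }
      intervals <- dplyr::bind_cols(intervals, tibble::as_tibble(mat))
    }
    coded_video(
      video_id = sprintf("v%02d", i), duration_s = durations[i], intervals = intervals,
      title = sprintf("Synthetic Video %02d", i), artist = sprintf("Artist %02d", i),
      genre = sample(c("pop", "hip hop", "dance", "r&b"), 1),
      release_date = as.Date("2013-10-01") + sample(0:90, 1)
    )
  })
  names(videos) <- vapply(videos, function(v) v$video_id, character(1))
  videos
}

nudge_to_total <- function(counts, target, lower, upper) {
  diff <- target - sum(counts)
  while (diff != 0) {
    step <- sign(diff)
    room <- which(if (step > 0) counts < upper else counts > lower)
    if (length(room) == 0) stop_input("cannot adjust interval counts to the target total")
    i <- room[sample.int(length(room), 1)]
    counts[i] <- counts[i] + step
    diff <- diff - step
  }
  counts
}

# persons (millions) per single year of age implied by a population table,
# used as the sampling distribution of simulated ages
age_weights <- function(population, ages, max_age) {
  bands <- population[population$gender == "all", , drop = FALSE]
  w <- vapply(ages, function(a) {
    row <- bands[bands$age_low <= a & a < bands$age_high, , drop = FALSE]
    if (nrow(row) == 0) return(0)
    hi <- min(row$age_high[1], max_age + 1)
    row$persons_millions[1] / (hi - row$age_low[1])
  }, numeric(1))
  if (all(w == 0)) stop_input("population table covers none of ages %d-%d", min(ages), max(ages))
  w / sum(w)
}

#' Generate a synthetic ever-seen survey
#'
#' Ages are drawn per single year with probability proportional to the
#' population table's band counts (adolescents 11-18, adults 19 to
#' `max_age`); genders are balanced; weights are lognormal with mean 1 and
#' the configured dispersion. Ever-seen indicators follow the logistic
#' viewing model: per-respondent log-odds linear in age and gender, plus a
#' per-video popularity random effect (drawn once per video and attached
#' to the result as attribute `video_effects`).
#'
#' @param config a [generator_config()].
#' @param videos coded videos from [generate_videos()] (non-empty).
#' @return validated survey tibble with attributes `video_ids` and
#'   `video_effects`.
#' @export
generate_survey <- function(config, videos) {
  stopifnot(inherits(config, "generator_config"))
  if (length(videos) == 0) stop_input("videos must be non-empty")
  ss <- substream_seeds(config)
  vm <- config$viewing_model
  ids <- vapply(videos, function(v) v$video_id, character(1))

  set.seed(ss[["video_effects"]])
  u <- rnorm(length(ids), 0, vm$video_sd)
  names(u) <- ids

  set.seed(ss[["ages"]])
  ado_ages <- 11:18
  adult_ages <- 19:config$max_age
  age <- c(
    sample(ado_ages, config$n_adolescents, replace = TRUE,
           prob = age_weights(config$population, ado_ages, config$max_age)),
    sample(adult_ages, config$n_adults, replace = TRUE,
           prob = age_weights(config$population, adult_ages, config$max_age))
  )
  n <- length(age)

  set.seed(ss[["gender_region"]])
  gender <- sample(c("female", "male"), n, replace = TRUE)
  region <- sample(c("London", "South East", "Midlands", "North", "Scotland", "Wales"),
                   n, replace = TRUE)

  set.seed(ss[["weights"]])
  d <- config$weight_dispersion
  weight <- if (d == 0) rep(1, n) else rlnorm(n, meanlog = -d^2 / 2, sdlog = d)

  set.seed(ss[["seen"]])
  eta_r <- vm$intercept + vm$age_slope * (age - vm$reference_age) +
    vm$female_effect * (gender == "female")
  prob <- plogis(outer(eta_r, u, `+`))
  seen <- matrix(rbinom(length(prob), 1, prob), nrow = n,
                 dimnames = list(NULL, ids))

  survey <- dplyr::bind_cols(
    tibble::tibble(
      respondent_id = sprintf("r%05d", seq_len(n)),
      age = as.integer(age), gender = gender, region = region,
      weight = weight, survey_date = "2014-07-15"
    ),
    tibble::as_tibble(seen)
  )
  survey <- validate_survey(survey, video_ids = ids, source = "generated survey")
  attr(survey, "video_effects") <- u
  survey
}

#' Model-implied ever-seen reach for a stratum
#'
#' The exact expectation of the weighted reach estimator under the
#' generating model, conditional on the realised per-video popularity
#' effects: the population-age-weighted, gender-balanced mean over
#' respondents and videos of the logistic viewing probability. Used as the
#' ground truth in parameter-recovery and CI-coverage studies.
#'
#' @param config a [generator_config()].
#' @param video_effects named numeric vector of per-video log-odds effects
#'   (attribute `video_effects` of a generated survey).
#' @param x a [stratum()].
#' @return expected reach in `[0, 1]`.
#' @export
model_implied_reach <- function(config, video_effects, x) {
  stopifnot(inherits(config, "generator_config"))
  x <- as_stratum(x)
  vm <- config$viewing_model
  ages <- max(11, x$age_low):min(config$max_age, x$age_high - 1)
  w <- age_weights(config$population, ages, config$max_age)
  genders <- switch(x$gender, all = c(female = 0.5, male = 0.5),
                    female = c(female = 1), male = c(male = 1))
  total <- 0
  for (g in names(genders)) {
    eta <- vm$intercept + vm$age_slope * (ages - vm$reference_age) +
      vm$female_effect * (g == "female")
    # mean over ages (population-weighted) and videos of plogis(eta + u)
    p_age <- rowMeans(plogis(outer(eta, video_effects, `+`)))
    total <- total + genders[[g]] * sum(w * p_age)
  }
  total
}

#' Generate a complete synthetic scenario
#'
#' Videos, survey, population table and a ground-truth record sufficient
#' for parameter-recovery tests: the per-video popularity effects, the
#' realised per-class interval counts, and the model-implied reach for the
#' adolescent, adult and all-ages strata.
#'
#' @param config a [generator_config()].
#' @param classes named list of content classes for the truth record.
#' @return list of class `mediareach_scenario` with elements `videos`,
#'   `survey`, `population`, `truth`, `config`.
#' @export
generate_scenario <- function(config = generator_config(),
                              classes = list(alcohol = "alcohol", tobacco = "tobacco")) {
  videos <- generate_videos(config)
  survey <- generate_survey(config, videos)
  u <- attr(survey, "video_effects")
  intervals <- vapply(classes, function(cl) total_content_intervals(videos, cl), integer(1))
  truth_strata <- list(adolescents = stratum(11, 19, label = "Adolescents"),
                       adults = stratum(19, Inf, label = "Adults"),
                       all = stratum(11, Inf, label = "Total"))
  reach_true <- vapply(truth_strata, function(s) model_implied_reach(config, u, s), numeric(1))
  structure(list(
    videos = videos, survey = survey, population = config$population,
    truth = list(video_effects = u, interval_counts = intervals,
                 reach = reach_true, viewing_model = config$viewing_model),
    config = config
  ), class = "mediareach_scenario")
}

#' @export
print.mediareach_scenario <- function(x, ...) {
  cat(sprintf("<mediareach_scenario> %d videos (%d intervals), %d respondents\n",
              length(x$videos), sum(vapply(x$videos, n_intervals, integer(1))),
              nrow(x$survey)))
  cat("  content intervals:",
      paste(sprintf("%s=%d", names(x$truth$interval_counts), x$truth$interval_counts),
            collapse = " "), "\n")
  cat(sprintf("  model-implied reach: adolescents %.3f, adults %.3f\n",
              x$truth$reach[["adolescents"]], x$truth$reach[["adults"]]))
  invisible(x)
}

#' Write a scenario's inputs to disk
#'
#' Writes the coding-sheet CSV, video metadata CSV, survey CSV, population
#' CSV and a truth JSON into a directory, the on-disk form consumed by
#' [read_coding_sheet()], [read_survey()] and [read_population()].
#'
#' @param scenario a [generate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "mediareach_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_coding_sheet(scenario$videos, file.path(dir, "coding_sheet.csv"),
                     metadata_path = file.path(dir, "video_metadata.csv"))
  write_survey(scenario$survey, file.path(dir, "survey.csv"))
  pop <- scenario$population
  pop$age_high <- ifelse(is.infinite(pop$age_high), "Inf", as.character(pop$age_high))
  readr::write_csv(pop, file.path(dir, "population.csv"), progress = FALSE)
  jsonlite::write_json(
    list(video_effects = as.list(scenario$truth$video_effects),
         interval_counts = as.list(scenario$truth$interval_counts),
         reach = as.list(scenario$truth$reach)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
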