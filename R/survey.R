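#' Read survey microdata
#'
#' One row per respondent: `respondent_id`, `age` (integer years, >= 11),
#' `gender` (`"female"`/`"male"`), optional `region` and `survey_date`, a
#' positive calibration `weight`, then one 0/1 ever-seen column per video,
#' named by the coding-sheet `video_id`. Weights are taken as supplied
#' (already calibrated to population margins); the package never re-rakes.
#'
#' Missing ever-seen answers ("don't know") are treated as not-seen by
#' default — conservative for exposure estimation — or the respondent can
#' be dropped entirely with `missing_seen = "drop"`.
#'
#' @param path survey CSV path.
#' @param video_ids optional character vector; when given, these columns
#'   must all be present and only they are treated as ever-seen columns.
#'   Otherwise every column outside the demographic set is taken as a
#'   video column.
#' @param missing_seen `"unseen"` (default) recodes NA indicators to 0;
#'   `"drop"` removes respondents with any NA indicator.
#' @return a tibble of validated respondents with attribute `video_ids`.
#' @export
read_survey <- function(path, video_ids = NULL, missing_seen = c("unseen", "drop")) {
  missing_seen <- match.arg(missing_seen)
  if (!file.exists(path)) stop_input("survey file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_survey(raw, video_ids = video_ids, missing_seen = missing_seen, source = path)
}

validate_survey <- function(raw, video_ids = NULL, missing_seen = "unseen", source = "survey") {
  raw <- tibble::as_tibble(raw)
  demo <- c("respondent_id", "age", "gender", "region", "weight", "survey_date")
  required <- c("respondent_id", "age", "gender", "weight")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop_input("%s lacks column(s): %s", source, paste(missing, collapse = ", "))
  if (is.null(video_ids)) {
    video_ids <- setdiff(names(raw), demo)
  } else {
    absent <- setdiff(video_ids, names(raw))
    if (length(absent) > 0)
      stop_input("%s lacks ever-seen column(s): %s", source, paste(absent, collapse = ", "))
  }
  if (length(video_ids) == 0) stop_input("%s has no ever-seen video columns", source)
  if (anyDuplicated(raw$respondent_id)) {
    dup <- raw$respondent_id[duplicated(raw$respondent_id)][1]
    stop_input("duplicate respondent_id in %s: %s", source, dup)
  }
  bad_age <- which(!is.finite(raw$age) | raw$age < 11 | raw$age != floor(raw$age))
  if (length(bad_age) > 0)
    stop_input("invalid age '%s' in row %d of %s (integer >= 11 required)",
               as.character(raw$age[bad_age[1]]), bad_age[1], source)
  bad_w <- which(!is.finite(raw$weight) | raw$weight <= 0)
  if (length(bad_w) > 0)
    stop_input("nonpositive weight in row %d of %s (respondent %s)",
               bad_w[1], source, raw$respondent_id[bad_w[1]])
  if (!all(raw$gender %in% c("female", "male")))
    stop_input("%s: gender must be 'female' or 'male'", source)
  for (v in video_ids) {
    if (!all(raw[[v]] %in% c(0, 1, NA)))
      stop_input("%s: non-boolean ever-seen value in column '%s'", source, v)
  }
  seen <- raw[video_ids]
  if (missing_seen == "drop") {
    keep <- !apply(is.na(as.matrix(seen)), 1, any)
    raw <- raw[keep, , drop = FALSE]
  } else {
    for (v in video_ids) raw[[v]][is.na(raw[[v]])] <- 0
  }
  for (v in video_ids) raw[[v]] <- as.integer(raw[[v]])
  raw$age <- as.integer(raw$age)
  attr(raw, "video_ids") <- video_ids
  raw
}

#' @rdname read_survey
#' @param survey a validated survey tibble.
#' @export
survey_video_ids <- function(survey) {
  ids <- attr(survey, "video_ids")
  if (is.null(ids)) stop_input("not a validated survey (no video_ids attribute); use read_survey() or validate_survey()")
  ids
}

#' @rdname read_survey
#' @export
write_survey <- function(survey, path) {
  readr::write_csv(survey, path, progress = FALSE)
  invisible(path)
}

#' Fraction of listed videos a respondent has ever seen
#'
#' The per-respondent building block of reach estimation: the number of
#' listed videos with a positive ever-seen indicator, divided by the number
#' listed.
#'
#' @param survey validated survey tibble (any number of rows).
#' @param video_ids character vector of video ids; each must be a survey
#'   column.
#' @return numeric vector in `[0, 1]`, one value per survey row.
#' @export
respondent_fraction_seen <- function(survey, video_ids) {
  absent <- setdiff(video_ids, names(survey))
  if (length(absent) > 0)
    stop_input("survey lacks ever-seen column(s): %s", paste(absent, collapse = ", "))
  if (length(video_ids) == 0) stop_input("video_ids must be non-empty")
  rowMeans(as.matrix(survey[video_ids]))
}

#' Survey-weighted mean proportion of videos viewed, with CI
#'
#' Estimates, for one demographic stratum, the weighted mean over
#' respondents of the fraction of videos ever seen:
#' \deqn{\bar p = \sum_r w_r f_r / \sum_r w_r.}
#' The default standard error uses the weighted variance of the
#' per-respondent fractions divided by the Kish effective sample size
#' \eqn{n_{eff} = (\sum w)^2 / \sum w^2}, and the CI is the normal
#' approximation \eqn{\bar p \pm z \cdot se}, clipped to `[0, 1]`. With
#' equal weights this reduces exactly to the unweighted mean and its
#' textbook standard error.
#'
#' @param survey validated survey tibble.
#' @param video_ids videos defining the reach measure.
#' @param stratum a [stratum()]; `NULL` uses all respondents.
#' @param conf_level confidence level (default 0.95).
#' @param method `"kish"` (weighted, design-effect CI; default),
#'   `"unweighted"` (ignores weights), or `"bootstrap"` (percentile CI over
#'   respondent resampling; the point estimate stays the weighted mean).
#' @param n_boot bootstrap replicates when `method = "bootstrap"`.
#' @return one-row tibble: `stratum`, `age_low`, `age_high`, `gender`,
#'   `p_bar`, `se`, `ci_low`, `ci_high`, `n_respondents`, `n_effective`.
#' @export
mean_proportion_viewed <- function(survey, video_ids, stratum = NULL,
                                   conf_level = 0.95,
                                   method = c("kish", "unweighted", "bootstrap"),
                                   n_boot = 1000) {
  method <- match.arg(method)
  f <- respondent_fraction_seen(survey, video_ids)
  weighted_reach(f, survey, stratum, conf_level, method, n_boot)
}

#' Weighted ever-seen proportion for a single video
#'
#' As [mean_proportion_viewed()] with the per-respondent fraction replaced
#' by the single video's 0/1 indicator. Averaging the point estimates over
#' all videos (equal video weighting) recovers the
#' [mean_proportion_viewed()] point estimate exactly.
#'
#' @inheritParams mean_proportion_viewed
#' @param video_id one video id (a survey column).
#' @return one-row tibble as in [mean_proportion_viewed()].
#' @export
per_video_proportion <- function(survey, video_id, stratum = NULL,
                                 conf_level = 0.95,
                                 method = c("kish", "unweighted", "bootstrap"),
                                 n_boot = 1000) {
  method <- match.arg(method)
  if (length(video_id) != 1) stop_input("per_video_proportion() takes a single video id")
  f <- respondent_fraction_seen(survey, video_id)
  weighted_reach(f, survey, stratum, conf_level, method, n_boot)
}

#' Reach estimates for every stratum of a scheme
#'
#' @inheritParams mean_proportion_viewed
#' @param scheme a scheme tibble as from [default_strata()].
#' @return tibble with one [mean_proportion_viewed()] row per scheme row,
#'   plus the scheme's `role` column.
#' @export
reach_by_stratum <- function(survey, video_ids, scheme = default_strata(),
                             conf_level = 0.95,
                             method = c("kish", "unweighted", "bootstrap"),
                             n_boot = 1000) {
  method <- match.arg(method)
  rows <- lapply(scheme_strata(scheme), function(s) {
    mean_proportion_viewed(survey, video_ids, s, conf_level, method, n_boot)
  })
  out <- dplyr::bind_rows(rows)
  out$role <- scheme$role %||% "band"
  out
}

weighted_reach <- function(f, survey, stratum, conf_level, method, n_boot) {
  if (!is.null(stratum)) {
    stratum <- as_stratum(stratum)
    keep <- in_stratum(survey$age, survey$gender, stratum)
    f <- f[keep]
    w <- survey$weight[keep]
  } else {
    stratum <- structure(list(age_low = min(survey$age), age_high = Inf,
                              gender = "all", label = "all respondents"),
                         class = "stratum")
    w <- survey$weight
  }
  n <- length(f)
  if (n == 0) stop_input("no respondents in stratum '%s'", stratum$label)
  if (n == 1) stop_input("only one respondent in stratum '%s'; variance is undefined", stratum$label)
  if (any(!is.finite(w) | w <= 0)) stop_input("weights must be positive and finite")
  if (method == "unweighted") w <- rep(1, n)

  p_bar <- sum(w * f) / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  # weighted variance of f with an effective-sample-size small-sample correction
  v_w <- sum(w * (f - p_bar)^2) / sum(w)
  if (n_eff > 1) v_w <- v_w * n_eff / (n_eff - 1)
  se <- sqrt(v_w / n_eff)
  z <- qnorm(1 - (1 - conf_level) / 2)

  if (method == "bootstrap" && se > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sum(w[idx] * f[idx]) / sum(w[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)))
  } else {
    ci <- c(p_bar - z * se, p_bar + z * se)
  }

  st <- stratum
  tibble::tibble(
    stratum = st$label, age_low = st$age_low, age_high = st$age_high,
    gender = st$gender, p_bar = p_bar, se = se,
    ci_low = max(0, ci[1]), ci_high = min(1, ci[2]),
    n_respondents = n, n_effective = n_eff
  )
}
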