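#' Gross and per-capita impressions for one stratum and content class
#'
#' The core estimator. A "gross impression" is one person seeing one
#' 10-second interval containing content at least once, so for a stratum
#' with weighted reach \eqn{\bar p}, population \eqn{N} (millions) and
#' class interval count \eqn{I}:
#' \deqn{G = \bar p \times N \times I \quad \text{(millions)}, \qquad
#'       PC = G / N = \bar p \times I \ \text{(per person)}.}
#' N and I are deterministic multipliers, so the reach CI endpoints scale
#' linearly through both. Each person contributes at most one viewing per
#' video; repeat views can be injected with `view_multiplier`.
#'
#' @param reach one-row reach tibble from [mean_proportion_viewed()] or
#'   [per_video_proportion()].
#' @param population_millions stratum population N in millions (> 0).
#' @param intervals content interval count I for the class (>= 0; an
#'   all-zero result for I = 0 is valid, not an error).
#' @param class_label label recorded in the result (e.g. `"alcohol"`).
#' @param view_multiplier optional average viewings per ever-seen person
#'   (default 1, the at-least-once convention).
#' @return one-row tibble: stratum fields, `class`, `p_bar`/`ci` inputs,
#'   `population_millions`, `intervals`, `gross`, `gross_ci_low`,
#'   `gross_ci_high` (millions), `per_capita`, `pc_ci_low`, `pc_ci_high`.
#' @examples
#' r <- tibble::tibble(stratum = "Adults", age_low = 19, age_high = Inf,
#'                     gender = "all", p_bar = 0.06, se = 0.01,
#'                     ci_low = 0.04, ci_high = 0.08,
#'                     n_respondents = 2232, n_effective = 2000)
#' gross_impressions(r, population_millions = 49.20, intervals = 233,
#'                   class_label = "alcohol")
#' @export
gross_impressions <- function(reach, population_millions, intervals,
                              class_label = NA_character_, view_multiplier = 1) {
  check_reach_row(reach)
  if (!is.numeric(population_millions) || length(population_millions) != 1 ||
      !is.finite(population_millions) || population_millions <= 0)
    stop_input("population_millions must be a single positive number")
  if (!is.numeric(intervals) || length(intervals) != 1 || !is.finite(intervals) ||
      intervals < 0)
    stop_input("intervals must be a single non-negative count")
  if (view_multiplier <= 0) stop_input("view_multiplier must be positive")

  mult <- intervals * view_multiplier
  tibble::tibble(
    stratum = reach$stratum, age_low = reach$age_low, age_high = reach$age_high,
    gender = reach$gender, class = class_label,
    p_bar = reach$p_bar, p_ci_low = reach$ci_low, p_ci_high = reach$ci_high,
    population_millions = population_millions, intervals = intervals,
    gross = reach$p_bar * population_millions * mult,
    gross_ci_low = reach$ci_low * population_millions * mult,
    gross_ci_high = reach$ci_high * population_millions * mult,
    per_capita = reach$p_bar * mult,
    pc_ci_low = reach$ci_low * mult,
    pc_ci_high = reach$ci_high * mult
  )
}

#' @rdname gross_impressions
#' @details `video_level_impressions()` is [gross_impressions()] applied to
#'   a single video: a per-video reach estimate (from
#'   [per_video_proportion()]) and that video's own class interval count.
#' @export
video_level_impressions <- function(reach, population_millions, intervals,
                                    class_label = NA_character_, view_multiplier = 1) {
  gross_impressions(reach, population_millions, intervals, class_label, view_multiplier)
}

#' Per-capita impressions from gross impressions
#'
#' Divides gross impressions (millions) by the stratum population
#' (millions), giving impressions per person. Applied elementwise, so CI
#' endpoints can be passed directly.
#'
#' @param gross gross impressions in millions (vectorised).
#' @param population_millions population N in millions (> 0).
#' @return impressions per person.
#' @examples
#' per_capita(695.09, 49.20) # 14.13 to 2 dp
#' @export
per_capita <- function(gross, population_millions) {
  if (any(!is.finite(population_millions) | population_millions <= 0))
    stop_input("population_millions must be positive")
  if (any(gross < 0)) stop_input("gross impressions cannot be negative")
  gross / population_millions
}

#' Aggregate impressions across disjoint strata
#'
#' Gross impressions and populations add; aggregate per-capita is the
#' population-weighted combination `sum(gross) / sum(N)`. For the CI, the
#' default sums the stratum CI endpoints (`"endpoint_sum"`), the arithmetic
#' used in published stratified exposure tables. With strata estimated from
#' independent samples this is conservative; `"rss"` (root-sum-square of
#' half-widths) gives the narrower independence-based interval.
#'
#' @param results tibble of [gross_impressions()] rows with a single
#'   content class and pairwise-disjoint strata.
#' @param label label of the aggregate stratum (default `"Total"`).
#' @param ci_method `"endpoint_sum"` (default) or `"rss"`.
#' @return one-row tibble in the [gross_impressions()] layout; the reported
#'   `p_bar` is the population-weighted mean reach and `intervals` the
#'   common class interval count (NA if the rows disagree, as at video
#'   level).
#' @export
aggregate_impressions <- function(results, label = "Total",
                                  ci_method = c("endpoint_sum", "rss")) {
  ci_method <- match.arg(ci_method)
  if (nrow(results) == 0) stop_input("nothing to aggregate")
  if (length(unique(results$class)) != 1)
    stop_input("cannot aggregate across content classes: %s",
               paste(unique(results$class), collapse = ", "))
  strata <- lapply(seq_len(nrow(results)), function(i) {
    stratum(results$age_low[i], results$age_high[i], results$gender[i], results$stratum[i])
  })
  if (nrow(results) > 1) {
    for (i in seq_len(nrow(results) - 1)) {
      for (j in seq(i + 1, nrow(results))) {
        if (!strata_disjoint(strata[[i]], strata[[j]]))
          stop_input("strata '%s' and '%s' overlap; aggregation requires disjoint strata",
                     results$stratum[i], results$stratum[j])
      }
    }
  }
  N <- sum(results$population_millions)
  gross <- sum(results$gross)
  if (ci_method == "endpoint_sum") {
    lo <- sum(results$gross_ci_low)
    hi <- sum(results$gross_ci_high)
  } else {
    half_lo <- sqrt(sum((results$gross - results$gross_ci_low)^2))
    half_hi <- sqrt(sum((results$gross_ci_high - results$gross)^2))
    lo <- gross - half_lo
    hi <- gross + half_hi
  }
  I <- unique(results$intervals)
  I <- if (length(I) == 1) I else NA_real_
  gmin <- min(results$age_low)
  gmax <- max(results$age_high)
  genders <- unique(results$gender)
  tibble::tibble(
    stratum = label, age_low = gmin, age_high = gmax,
    gender = if (length(genders) == 1) genders else "all",
    class = results$class[1],
    p_bar = sum(results$p_bar * results$population_millions) / N,
    p_ci_low = sum(results$p_ci_low * results$population_millions) / N,
    p_ci_high = sum(results$p_ci_high * results$population_millions) / N,
    population_millions = N, intervals = I,
    gross = gross, gross_ci_low = lo, gross_ci_high = hi,
    per_capita = gross / N, pc_ci_low = lo / N, pc_ci_high = hi / N
  )
}

check_reach_row <- function(reach) {
  needed <- c("stratum", "age_low", "age_high", "gender", "p_bar", "ci_low", "ci_high")
  if (!is.data.frame(reach) || nrow(reach) != 1 || !all(needed %in% names(reach)))
    stop_input("reach must be a one-row tibble from mean_proportion_viewed() or per_video_proportion()")
  invisible(TRUE)
}
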