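#' Demographic strata
#'
#' A stratum is a half-open age band `[age_low, age_high)` crossed with a
#' gender (`"female"`, `"male"`, or `"all"`). `age_high = Inf` denotes an
#' open-ended band ("55+").
#'
#' @param age_low inclusive lower age bound (integer years).
#' @param age_high exclusive upper age bound; `Inf` for open-ended.
#' @param gender one of `"female"`, `"male"`, `"all"`.
#' @param label optional display label; a default is derived from the bounds.
#' @return an object of class `stratum`.
#' @examples
#' stratum(11, 19, "all", "Adolescents")
#' stratum(55, Inf)  # "55+"
#' @export
stratum <- function(age_low, age_high = Inf, gender = "all", label = NULL) {
  if (!is.numeric(age_low) || !is.numeric(age_high) || age_low < 0 || age_high <= age_low)
    stop_input("invalid age band [%s, %s)", age_low, age_high)
  gender <- match.arg(gender, c("all", "female", "male"))
  if (is.null(label)) {
    band <- if (is.infinite(age_high)) sprintf("%d+", age_low) else
      sprintf("%d-%d", age_low, age_high - 1)
    label <- if (gender == "all") band else paste(band, gender)
  }
  structure(list(age_low = age_low, age_high = age_high, gender = gender, label = label),
            class = "stratum")
}

#' @export
print.stratum <- function(x, ...) {
  cat(sprintf("<stratum> %s: ages [%s, %s), gender %s\n",
              x$label, x$age_low, x$age_high, x$gender))
  invisible(x)
}

as_stratum <- function(x) {
  if (inherits(x, "stratum")) return(x)
  if (is.data.frame(x) && nrow(x) == 1) {
    return(stratum(x$age_low, x$age_high, x$gender, x$label %||% NULL))
  }
  stop_input("cannot interpret object of class '%s' as a stratum", class(x)[1])
}

#' @rdname stratum
#' @param age,gender_values vectors of respondent ages and genders.
#' @param x a `stratum`.
#' @return `in_stratum()`: logical vector, TRUE where the person belongs.
#' @export
in_stratum <- function(age, gender_values, x) {
  x <- as_stratum(x)
  ok <- age >= x$age_low & age < x$age_high
  if (x$gender != "all") ok <- ok & gender_values == x$gender
  ok
}

strata_disjoint <- function(a, b) {
  gender_disjoint <- (a$gender != b$gender) && a$gender != "all" && b$gender != "all"
  age_disjoint <- a$age_high <= b$age_low || b$age_high <= a$age_low
  gender_disjoint || age_disjoint
}

#' Stratification schemes
#'
#' A scheme is a tibble of strata with columns `label`, `age_low`,
#' `age_high`, `gender` and `role`. Rows with `role = "band"` form a
#' disjoint partition used to build the Total row of an exposure table;
#' `role = "summary"` rows (e.g. Adolescents, Adults, their gender splits)
#' are reported but not re-counted in the Total.
#'
#' `default_strata()` is the scheme used in the UK music-video exposure
#' analysis: age bands 11-12, 13-15, 16-18, 19-24, 25-34, 35-44, 45-54,
#' 55+, with adolescent (11-18) and adult (19+) summaries split by gender.
#' `gender_band_strata()` crosses the same age bands with gender, the
#' layout behind per-capita-by-age-and-gender charts.
#'
#' @return a tibble (scheme) as described above.
#' @export
default_strata <- function() {
  bands <- age_bands()
  dplyr::bind_rows(
    tibble::tibble(label = c("Adolescents", "Adolescents female", "Adolescents male"),
                   age_low = 11, age_high = 19,
                   gender = c("all", "female", "male"), role = "summary"),
    tibble::tibble(label = c("Adults", "Adults female", "Adults male"),
                   age_low = 19, age_high = Inf,
                   gender = c("all", "female", "male"), role = "summary"),
    tibble::tibble(label = bands$label, age_low = bands$age_low, age_high = bands$age_high,
                   gender = "all", role = "band")
  )
}

#' @rdname default_strata
#' @export
gender_band_strata <- function() {
  bands <- age_bands()
  out <- tidyr::expand_grid(bands, gender = c("female", "male"))
  tibble::tibble(label = paste(out$label, out$gender),
                 age_low = out$age_low, age_high = out$age_high,
                 gender = out$gender, role = "band")
}

age_bands <- function() {
  tibble::tibble(
    label = c("11-12", "13-15", "16-18", "19-24", "25-34", "35-44", "45-54", "55+"),
    age_low = c(11, 13, 16, 19, 25, 35, 45, 55),
    age_high = c(13, 16, 19, 25, 35, 45, 55, Inf)
  )
}

scheme_strata <- function(scheme) {
  lapply(seq_len(nrow(scheme)), function(i) {
    stratum(scheme$age_low[i], scheme$age_high[i], scheme$gender[i], scheme$label[i])
  })
}
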