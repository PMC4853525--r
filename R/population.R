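#' Census population tables
#'
#' A population table maps strata (age band x gender) to persons in
#' millions — the N of every extrapolation. Units are millions throughout
#' the public interface to avoid silent factor-of-10^6 errors.
#'
#' @param entries data frame with columns `age_low`, `age_high` (`Inf` for
#'   open-ended), `gender` (`"female"`, `"male"`, `"all"`) and
#'   `persons_millions` (> 0).
#' @param reference_period free-text label, e.g. `"mid-2012/13"`.
#' @return a `population_table` (a tibble with a `reference_period`
#'   attribute).
#' @export
population_table <- function(entries, reference_period = NA_character_) {
  entries <- tibble::as_tibble(entries)
  required <- c("age_low", "age_high", "gender", "persons_millions")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0)
    stop_input("population table lacks column(s): %s", paste(missing, collapse = ", "))
  if (!all(entries$gender %in% c("female", "male", "all")))
    stop_input("population gender must be female, male or all")
  if (any(!is.finite(entries$persons_millions) | entries$persons_millions <= 0))
    stop_input("all population counts must be positive")
  if (any(entries$age_high <= entries$age_low))
    stop_input("population age bands must satisfy age_low < age_high")
  key <- paste(entries$age_low, entries$age_high, entries$gender)
  if (anyDuplicated(key))
    stop_input("duplicate population entry: %s", key[duplicated(key)][1])
  structure(entries[required], reference_period = reference_period,
            class = c("population_table", class(entries)))
}

#' Read a population CSV
#'
#' Columns: `age_low`, `age_high` (a number, or `"plus"`/`"Inf"` for an
#' open-ended band), `gender`, `persons_millions`.
#'
#' @param path CSV path.
#' @param reference_period label passed to [population_table()].
#' @return a [population_table()].
#' @export
read_population <- function(path, reference_period = NA_character_) {
  if (!file.exists(path)) stop_input("population file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(age_high = readr::col_character()))
  high <- ifelse(tolower(raw$age_high) %in% c("plus", "inf"), Inf,
                 suppressWarnings(as.numeric(raw$age_high)))
  if (any(is.na(high))) stop_input("unparseable age_high value in %s", path)
  raw$age_high <- high
  population_table(raw, reference_period)
}

#' UK mid-year population margins used in the exposure analysis
#'
#' Official UK mid-year person counts (2012-2013), in millions, at the
#' granularity published alongside the exposure estimates: the eight age
#' bands for both genders combined, plus the adolescent (11-18) and adult
#' (19+) totals split by gender.
#'
#' @return a [population_table()].
#' @export
uk_population <- function() {
  read_population(system.file("extdata", "uk_population_mid2012.csv",
                              package = "mediareach", mustWork = TRUE),
                  reference_period = "mid-2012/13")
}

#' Look up (or aggregate) the population of a stratum
#'
#' Resolution order: (1) an entry matching the stratum exactly; (2) a
#' greedy left-to-right tiling of same-gender entries covering
#' `[age_low, age_high)` without gaps or overlap, preferring the widest
#' entry at each step; (3) for `gender = "all"`, the sum of the female and
#' male resolutions. Aggregation is an exact sum, so querying the same
#' union twice is deterministic.
#'
#' @param table a [population_table()].
#' @param x a [stratum()] (or one-row scheme slice).
#' @return persons in millions.
#' @examples
#' population_for(uk_population(), stratum(11, 19, label = "Adolescents")) # 5.91
#' @export
population_for <- function(table, x) {
  stopifnot(inherits(table, "population_table"))
  x <- as_stratum(x)
  val <- resolve_population(table, x$age_low, x$age_high, x$gender)
  if (is.na(val)) {
    avail <- sprintf("[%s,%s) %s", table$age_low, table$age_high, table$gender)
    stop_input("cannot resolve stratum '%s' ([%s, %s) %s) from population entries: %s",
               x$label, x$age_low, x$age_high, x$gender, paste(avail, collapse = "; "))
  }
  val
}

resolve_population <- function(table, lo, hi, gender) {
  exact <- table$age_low == lo & table$age_high == hi & table$gender == gender
  if (any(exact)) return(table$persons_millions[which(exact)[1]])
  tiled <- tile_population(table[table$gender == gender, , drop = FALSE], lo, hi)
  if (!is.na(tiled)) return(tiled)
  if (gender == "all") {
    f <- resolve_population(table, lo, hi, "female")
    m <- resolve_population(table, lo, hi, "male")
    if (!is.na(f) && !is.na(m)) return(f + m)
  }
  NA_real_
}

# greedy tiling: at each cursor position take the entry starting there with
# the largest admissible age_high
tile_population <- function(entries, lo, hi) {
  total <- 0
  cur <- lo
  while (cur < hi) {
    cand <- entries$age_low == cur & entries$age_high <= hi
    if (!any(cand)) return(NA_real_)
    pick <- which(cand)[which.max(entries$age_high[cand])]
    total <- total + entries$persons_millions[pick]
    cur <- entries$age_high[pick]
  }
  total
}

#' Split combined-gender population entries by a fixed female share
#'
#' Census tables are sometimes published with gender detail only at coarse
#' strata (as the shipped [uk_population()] is: gender splits for
#' adolescents and adults, combined-gender age bands). Gender-split band
#' schemes such as [gender_band_strata()] then need band x gender counts;
#' this helper imputes them by applying a female share to every
#' combined-gender entry that lacks gender detail. The default share is
#' each band's enclosing gender split where resolvable, else 0.5.
#'
#' @param table a [population_table()].
#' @param female_share single number in (0, 1), or `NULL` to infer the
#'   share from enclosing gender-split entries.
#' @return a [population_table()] with female/male entries added for every
#'   combined-gender band.
#' @export
split_population_by_gender <- function(table, female_share = NULL) {
  stopifnot(inherits(table, "population_table"))
  if (!is.null(female_share) && (female_share <= 0 || female_share >= 1))
    stop_input("female_share must lie strictly between 0 and 1")
  out <- table
  alls <- which(table$gender == "all")
  for (i in alls) {
    lo <- table$age_low[i]; hi <- table$age_high[i]
    have_f <- any(table$age_low == lo & table$age_high == hi & table$gender == "female")
    if (have_f) next
    share <- female_share
    if (is.null(share)) {
      share <- 0.5
      # use the tightest enclosing stratum with a published gender split
      enclosing <- which(table$gender == "female" & table$age_low <= lo & table$age_high >= hi)
      if (length(enclosing) > 0) {
        j <- enclosing[which.min(table$age_high[enclosing] - table$age_low[enclosing])]
        tot <- resolve_population(table, table$age_low[j], table$age_high[j], "all")
        if (!is.na(tot)) share <- table$persons_millions[j] / tot
      }
    }
    extra <- tibble::tibble(
      age_low = lo, age_high = hi, gender = c("female", "male"),
      persons_millions = table$persons_millions[i] * c(share, 1 - share)
    )
    out <- dplyr::bind_rows(out, extra)
  }
  population_table(out, attr(table, "reference_period"))
}

#' Check internal consistency of a population table
#'
#' Verifies that every coarse entry agrees with the sum of finer entries
#' tiling the same stratum, within a rounding tolerance (published tables
#' carry 2-decimal rounding, so exact agreement is not expected).
#'
#' @param table a [population_table()].
#' @param tol absolute tolerance in millions (default 0.02).
#' @return invisibly TRUE; a condition is signalled on inconsistency.
#' @export
check_population_consistency <- function(table, tol = 0.02) {
  stopifnot(inherits(table, "population_table"))
  for (i in seq_len(nrow(table))) {
    finer <- table[-i, , drop = FALSE]
    class(finer) <- class(table)
    alt <- resolve_population(finer, table$age_low[i], table$age_high[i], table$gender[i])
    if (!is.na(alt) && abs(alt - table$persons_millions[i]) > tol) {
      stop_input("population entry [%s,%s) %s = %.2f disagrees with finer tiling sum %.2f",
                 table$age_low[i], table$age_high[i], table$gender[i],
                 table$persons_millions[i], alt)
    }
  }
  invisible(TRUE)
}
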