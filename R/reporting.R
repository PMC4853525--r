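#' Build a stratified exposure table
#'
#' Runs the full estimator over a stratification scheme: weighted reach
#' per stratum, population lookup, per-class gross and per-capita
#' impressions, plus a Total row aggregated (gross summed, CI endpoints
#' summed) over the scheme's `role = "band"` rows, which must form a
#' disjoint partition. Internal values are kept at full precision;
#' rounding happens only in [render_exposure_table()].
#'
#' @param videos list of [coded_video()] objects.
#' @param survey validated survey tibble; its video columns must cover the
#'   coded videos.
#' @param population a [population_table()].
#' @param classes named list of content classes (default alcohol and
#'   tobacco as separate singleton classes).
#' @param scheme scheme tibble, see [default_strata()].
#' @param conf_level,method,view_multiplier passed through to
#'   [mean_proportion_viewed()] and [gross_impressions()].
#' @param total_label label for the aggregate row; `NULL` suppresses it.
#' @return an `exposure_table`: list with `results` (long tibble, one row
#'   per stratum x class), `reach`, `interval_counts`, `population_used`,
#'   `scheme`, `metadata`.
#' @export
build_exposure_table <- function(videos, survey, population,
                                 classes = list(alcohol = "alcohol", tobacco = "tobacco"),
                                 scheme = default_strata(),
                                 conf_level = 0.95, method = "kish",
                                 view_multiplier = 1, total_label = "Total") {
  stopifnot(inherits(population, "population_table"))
  classes <- lapply(classes, as_content_class)
  video_ids <- vapply(videos, function(v) v$video_id, character(1))
  absent <- setdiff(video_ids, survey_video_ids(survey))
  if (length(absent) > 0)
    stop_input("survey lacks ever-seen column(s) for coded video(s): %s",
               paste(absent, collapse = ", "))
  intervals <- vapply(classes, function(cl) total_content_intervals(videos, cl), integer(1))

  reach <- reach_by_stratum(survey, video_ids, scheme, conf_level, method)
  pop_n <- vapply(scheme_strata(scheme), function(s) {
    tryCatch(population_for(population, s),
             mediareach_error = function(e) {
               stop_input("stratum '%s' is surveyed but unresolvable in the population table: %s",
                          s$label, conditionMessage(e))
             })
  }, numeric(1))

  rows <- list()
  for (cl in names(classes)) {
    for (i in seq_len(nrow(reach))) {
      res <- gross_impressions(reach[i, ], pop_n[i], intervals[[cl]],
                               class_label = cl, view_multiplier = view_multiplier)
      res$role <- reach$role[i]
      rows[[length(rows) + 1]] <- res
    }
    if (!is.null(total_label)) {
      bands <- dplyr::bind_rows(rows)
      bands <- bands[bands$class == cl & bands$role == "band", , drop = FALSE]
      if (nrow(bands) > 0) {
        tot <- aggregate_impressions(bands, label = total_label)
        tot$role <- "total"
        rows[[length(rows) + 1]] <- tot
      }
    }
  }
  results <- dplyr::bind_rows(rows)

  structure(list(
    results = results, reach = reach, interval_counts = intervals,
    population_used = setNames(pop_n, scheme$label), scheme = scheme,
    metadata = list(conf_level = conf_level, method = method,
                    view_multiplier = view_multiplier,
                    n_videos = length(videos),
                    n_respondents = nrow(survey),
                    created = format(Sys.time(), tz = "UTC"))
  ), class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat(sprintf("<exposure_table> %d strata x %d classes (%s reach, %.0f%% CI)\n",
              nrow(x$scheme), length(x$interval_counts),
              x$metadata$method, 100 * x$metadata$conf_level))
  print(render_exposure_table(x), n = Inf)
  invisible(x)
}

#' Render an exposure table at published precision
#'
#' Projects the full-precision results into the familiar published layout
#' — one row per stratum; population, proportion-viewed and, per class,
#' gross (millions) and per-capita columns, each as "estimate (lo to hi)"
#' — rounding half away from zero at render time only. Rendering is pure:
#' the same table always yields byte-identical output.
#'
#' @param x an `exposure_table`.
#' @param digits decimal places for impression and proportion cells.
#' @return a character tibble.
#' @export
render_exposure_table <- function(x, digits = 2) {
  stopifnot(inherits(x, "exposure_table"))
  res <- x$results
  labels <- unique(res$stratum)
  out <- tibble::tibble(stratum = labels)
  first <- res[match(labels, res$stratum), , drop = FALSE]
  out$population_millions <- fmt_fixed(first$population_millions, digits)
  out$proportion_viewed <- fmt_ci(first$p_bar, first$p_ci_low, first$p_ci_high, digits)
  for (cl in unique(res$class)) {
    sub <- res[res$class == cl, , drop = FALSE]
    sub <- sub[match(labels, sub$stratum), , drop = FALSE]
    out[[paste0("gross_", cl)]] <- fmt_ci(sub$gross, sub$gross_ci_low, sub$gross_ci_high, digits)
    out[[paste0("per_capita_", cl)]] <- fmt_ci(sub$per_capita, sub$pc_ci_low, sub$pc_ci_high, digits)
  }
  out
}

#' Long-format per-capita chart data by age band and gender
#'
#' Projects an exposure table built on a gender-split band scheme (see
#' [gender_band_strata()]) into long-format records — one per (age band,
#' gender, class) — ready for plotting per-capita exposure profiles.
#' Values equal the source cells exactly.
#'
#' @param x an `exposure_table` whose scheme contains gender-split bands.
#' @return tibble: `age_band`, `age_low`, `gender`, `class`, `per_capita`,
#'   `pc_ci_low`, `pc_ci_high`.
#' @export
build_percapita_chart_data <- function(x) {
  stopifnot(inherits(x, "exposure_table"))
  res <- x$results
  res <- res[res$role == "band" & res$gender %in% c("female", "male"), , drop = FALSE]
  if (nrow(res) == 0)
    stop_input("exposure table has no gender-split band strata; build it with gender_band_strata()")
  band <- sub("\\s+(female|male)$", "", res$stratum)
  out <- tibble::tibble(
    age_band = band, age_low = res$age_low, gender = res$gender, class = res$class,
    per_capita = res$per_capita, pc_ci_low = res$pc_ci_low, pc_ci_high = res$pc_ci_high
  )
  dplyr::arrange(out, .data$class, .data$age_low, .data$gender)
}

#' Per-video impression breakdown
#'
#' For each video, stratum and class: the video's own content interval
#' count, its per-video ever-seen proportion in the stratum, and the
#' implied gross and per-capita impressions. This is the estimator behind
#' "which video delivered the most impressions" rankings.
#'
#' @inheritParams build_exposure_table
#' @param strata list of [stratum()] objects (default adolescents, adults).
#' @return tibble of [video_level_impressions()] rows with a `video_id`
#'   column, ordered by class and descending gross.
#' @export
video_exposure_table <- function(videos, survey, population,
                                 classes = list(alcohol = "alcohol", tobacco = "tobacco"),
                                 strata = list(stratum(11, 19, label = "Adolescents"),
                                               stratum(19, Inf, label = "Adults")),
                                 conf_level = 0.95, method = "kish") {
  stopifnot(inherits(population, "population_table"))
  classes <- lapply(classes, as_content_class)
  rows <- list()
  for (v in videos) {
    for (s in strata) {
      reach <- per_video_proportion(survey, v$video_id, s, conf_level, method)
      N <- population_for(population, s)
      for (cl in names(classes)) {
        I_v <- count_content_intervals(v, classes[[cl]])
        res <- video_level_impressions(reach, N, I_v, class_label = cl)
        res <- dplyr::bind_cols(tibble::tibble(video_id = v$video_id,
                                               title = as.character(v$title)), res)
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$class, dplyr::desc(.data$gross))
}

#' Write an exposure table and its audit trail
#'
#' Writes `table1.csv` (rendered, published precision), `table1.json`
#' (full-precision long results), `figure1_data.csv` (per-capita chart
#' records, when the scheme supports them) and `audit.json` — the (reach,
#' population, interval-count) triple behind every cell plus run metadata,
#' so each printed number is reproducible from the audit inputs.
#'
#' @param x an `exposure_table`.
#' @param dir output directory (created if needed).
#' @param digits decimal places for the rendered CSV.
#' @return invisibly, the paths written.
#' @export
write_exposure_table <- function(x, dir, digits = 2) {
  stopifnot(inherits(x, "exposure_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(table = file.path(dir, "table1.csv"),
             json = file.path(dir, "table1.json"),
             audit = file.path(dir, "audit.json"))
  readr::write_csv(render_exposure_table(x, digits), paths[["table"]], progress = FALSE)
  jsonlite::write_json(x$results, paths[["json"]], auto_unbox = TRUE, digits = NA)
  chart <- tryCatch(build_percapita_chart_data(x), mediareach_error = function(e) NULL)
  if (!is.null(chart)) {
    paths[["chart"]] <- file.path(dir, "figure1_data.csv")
    readr::write_csv(chart, paths[["chart"]], progress = FALSE)
  }
  audit <- list(
    metadata = x$metadata,
    interval_counts = as.list(x$interval_counts),
    cells = lapply(seq_len(nrow(x$results)), function(i) {
      r <- x$results[i, ]
      list(stratum = r$stratum, class = r$class, p_bar = r$p_bar,
           population_millions = r$population_millions, intervals = r$intervals,
           gross = r$gross, per_capita = r$per_capita)
    })
  )
  jsonlite::write_json(audit, paths[["audit"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Published UK exposure estimates
#'
#' Reference values from the published UK study of alcohol and tobacco
#' content in the 32 most-viewed music videos: per-stratum population,
#' proportion viewed, and gross and per-capita impressions with 95% CIs
#' (`published_estimates()`), and the headline individual-video figures
#' (`published_video_estimates()`). These ship with the package so the
#' arithmetic identities linking the published cells (per-capita = gross /
#' population; tobacco/alcohol gross ratio = 47/233) can be re-derived
#' through the pipeline's own operations without the unpublished survey
#' microdata.
#'
#' @return a tibble of published values.
#' @export
published_estimates <- function() {
  readr::read_csv(system.file("extdata", "published_exposure_estimates.csv",
                              package = "mediareach", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_estimates
#' @export
published_video_estimates <- function() {
  readr::read_csv(system.file("extdata", "published_video_estimates.csv",
                              package = "mediareach", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}
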