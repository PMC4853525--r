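#' Substance, category and channel vocabularies for interval coding
#'
#' Each 10-second interval of a video is scored present/absent for every
#' (substance, category, channel) triple. `flag_columns()` enumerates the
#' corresponding column names of a coding sheet, formed as
#' `substance.category.channel` (e.g. `"alcohol.brand.visual"`).
#'
#' @return character vectors of the recognised levels / flag column names.
#' @export
substances <- function() c("tobacco", "alcohol", "electronic_cigarette")

#' @rdname substances
#' @export
coding_categories <- function() c("actual_use", "implied_use", "paraphernalia", "brand")

#' @rdname substances
#' @export
coding_channels <- function() c("visual", "lyric")

#' @rdname substances
#' @export
flag_columns <- function(substance = substances()) {
  grid <- expand.grid(channel = coding_channels(),
                      category = coding_categories(),
                      substance = substance,
                      stringsAsFactors = FALSE)
  paste(grid$substance, grid$category, grid$channel, sep = ".")
}

#' Define a content class
#'
#' A content class is a non-empty set of substances whose category/channel
#' flags are unioned into a single per-interval presence measure. The
#' default analysis uses the singleton classes `{alcohol}` and `{tobacco}`;
#' electronic cigarettes are kept as a separate substance and may be folded
#' into a combined class (e.g. `content_class(c("tobacco",
#' "electronic_cigarette"))`) by the user.
#'
#' @param substance_set character vector of substances, a subset of
#'   [substances()].
#' @return an object of class `content_class`.
#' @examples
#' content_class("alcohol")
#' content_class(c("tobacco", "electronic_cigarette"))
#' @export
content_class <- function(substance_set) {
  substance_set <- unique(as.character(substance_set))
  if (length(substance_set) == 0) stop_input("content class must contain at least one substance")
  unknown <- setdiff(substance_set, substances())
  if (length(unknown) > 0) {
    stop_input("unknown substance(s) in content class: %s (known: %s)",
               paste(unknown, collapse = ", "), paste(substances(), collapse = ", "))
  }
  structure(list(substance_set = sort(substance_set)), class = "content_class")
}

as_content_class <- function(x) {
  if (inherits(x, "content_class")) x else content_class(x)
}

#' @export
print.content_class <- function(x, ...) {
  cat("<content_class> {", paste(x$substance_set, collapse = ", "), "}\n")
  invisible(x)
}

#' Construct a coded video
#'
#' A `coded_video` holds a video's metadata and its ordered 10-second
#' interval records. A video of `duration_s` seconds has
#' `ceiling(duration_s / 10)` intervals: the trailing short interval, if
#' any, is a full coding unit, so no coded content is ever truncated away.
#' Interval `k` (0-based) covers seconds `[10k, 10(k+1))`.
#'
#' @param video_id opaque identifier, unique within a collection.
#' @param duration_s video duration in seconds (> 0).
#' @param intervals optional data frame with column `interval_index`
#'   (0-based, consecutive) and any subset of [flag_columns()] as 0/1
#'   columns; omitted flags default to absent. `NULL` means no content.
#' @param title,artist,artist_nationality,genre optional metadata strings.
#' @param release_date optional release date (`Date` or parseable string).
#' @return an object of class `coded_video`.
#' @examples
#' v <- coded_video("v01", duration_s = 195)
#' n_intervals(v) # 20
#' @export
coded_video <- function(video_id, duration_s, intervals = NULL, title = NA_character_,
                        artist = NA_character_, artist_nationality = NA_character_,
                        genre = NA_character_, release_date = NA) {
  if (!is.character(video_id) || length(video_id) != 1 || is.na(video_id) || !nzchar(video_id))
    stop_input("video_id must be a non-empty string")
  if (!is.numeric(duration_s) || length(duration_s) != 1 || is.na(duration_s) || duration_s <= 0)
    stop_input("duration_s must be a single positive number (video '%s')", video_id)
  n <- as.integer(ceiling(duration_s / 10))

  full <- tibble::tibble(interval_index = seq_len(n) - 1L)
  for (col in flag_columns()) full[[col]] <- 0L
  if (!is.null(intervals)) {
    intervals <- tibble::as_tibble(intervals)
    if (!"interval_index" %in% names(intervals))
      stop_input("intervals must have an interval_index column (video '%s')", video_id)
    extra <- setdiff(names(intervals), c("interval_index", flag_columns()))
    if (length(extra) > 0)
      stop_input("unknown flag column(s) for video '%s': %s", video_id,
                 paste(extra, collapse = ", "))
    idx <- intervals$interval_index
    if (anyDuplicated(idx))
      stop_input("duplicate interval_index in video '%s'", video_id)
    if (any(idx < 0 | idx >= n))
      stop_input("interval_index out of range 0..%d in video '%s'", n - 1L, video_id)
    for (col in setdiff(names(intervals), "interval_index")) {
      vals <- intervals[[col]]
      if (is.logical(vals)) vals <- as.integer(vals)
      if (!all(vals %in% c(0L, 1L)))
        stop_input("non-boolean flag value in column '%s' of video '%s'", col, video_id)
      full[[col]][match(idx, full$interval_index)] <- as.integer(vals)
    }
  }
  structure(list(
    video_id = video_id, title = title, artist = artist,
    artist_nationality = artist_nationality, genre = genre,
    release_date = release_date, duration_s = as.numeric(duration_s),
    intervals = full
  ), class = "coded_video")
}

#' @rdname coded_video
#' @param video a `coded_video`.
#' @export
n_intervals <- function(video) {
  stopifnot(inherits(video, "coded_video"))
  nrow(video$intervals)
}

#' @export
print.coded_video <- function(x, ...) {
  counts <- vapply(substances(), function(s) count_content_intervals(x, s), integer(1))
  cat(sprintf("<coded_video> %s (%.0f s, %d intervals) content intervals: %s\n",
              x$video_id, x$duration_s, n_intervals(x),
              paste(sprintf("%s=%d", names(counts), counts), collapse = " ")))
  invisible(x)
}

#' Count content-bearing intervals in a video
#'
#' An interval carries content for a class if ANY flag — any category, any
#' channel — of ANY substance in the class is present. Multiple flags in
#' the same interval count once (union, not sum): the coding is
#' semiquantitative, measuring in how many 10-second windows content
#' appears, not how many appearances there are.
#'
#' @param video a [coded_video()].
#' @param class a [content_class()] or character vector of substances.
#' @return non-negative integer count of intervals with class content.
#' @examples
#' v <- coded_video("v01", 30, tibble::tibble(
#'   interval_index = 0L, alcohol.brand.visual = 1L, alcohol.actual_use.lyric = 1L))
#' count_content_intervals(v, "alcohol") # 1: union within the interval
#' @export
count_content_intervals <- function(video, class) {
  stopifnot(inherits(video, "coded_video"))
  class <- as_content_class(class)
  cols <- flag_columns(class$substance_set)
  flags <- as.matrix(video$intervals[cols])
  sum(rowSums(flags) > 0L)
}

#' Total content-bearing intervals across a collection of videos
#'
#' @param videos list of [coded_video()] objects.
#' @param class a [content_class()] or character vector of substances.
#' @return sum of [count_content_intervals()] over the collection. An empty
#'   collection returns 0 with a warning.
#' @export
total_content_intervals <- function(videos, class) {
  if (length(videos) == 0) {
    warn("total_content_intervals() called on an empty video collection; returning 0")
    return(0L)
  }
  class <- as_content_class(class)
  sum(vapply(videos, count_content_intervals, integer(1), class = class))
}

#' Per-video content interval counts for one or more classes
#'
#' @param videos list of [coded_video()] objects.
#' @param classes named list of content classes (or character vectors).
#' @return tibble with one row per video: `video_id`, `n_intervals`, one
#'   count column per class.
#' @export
content_interval_summary <- function(videos,
                                     classes = list(alcohol = "alcohol", tobacco = "tobacco",
                                                    electronic_cigarette = "electronic_cigarette")) {
  classes <- lapply(classes, as_content_class)
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop_input("classes must be a named list")
  out <- tibble::tibble(
    video_id = vapply(videos, function(v) v$video_id, character(1)),
    n_intervals = vapply(videos, n_intervals, integer(1))
  )
  for (nm in names(classes)) {
    out[[nm]] <- vapply(videos, count_content_intervals, integer(1), class = classes[[nm]])
  }
  out
}

#' Convert between coded videos and the long coding-sheet layout
#'
#' The coding sheet is long format: one row per (video, interval), one 0/1
#' column per `substance.category.channel` flag. `coding_sheet()` flattens a
#' collection; [read_coding_sheet()]/[write_coding_sheet()] do file I/O.
#'
#' @param videos list of [coded_video()] objects.
#' @return tibble with columns `video_id`, `interval_index`, and the 24
#'   flag columns.
#' @export
coding_sheet <- function(videos) {
  rows <- lapply(videos, function(v) {
    dplyr::bind_cols(tibble::tibble(video_id = v$video_id), v$intervals)
  })
  dplyr::bind_rows(rows)
}

video_metadata <- function(videos) {
  tibble::tibble(
    video_id = vapply(videos, function(v) v$video_id, character(1)),
    title = vapply(videos, function(v) as.character(v$title), character(1)),
    artist = vapply(videos, function(v) as.character(v$artist), character(1)),
    artist_nationality = vapply(videos, function(v) as.character(v$artist_nationality), character(1)),
    genre = vapply(videos, function(v) as.character(v$genre), character(1)),
    release_date = vapply(videos, function(v) as.character(v$release_date), character(1)),
    duration_s = vapply(videos, function(v) v$duration_s, numeric(1))
  )
}

#' Read a coding sheet from CSV
#'
#' Expects the long layout written by [write_coding_sheet()]: columns
#' `video_id`, `interval_index` and any subset of [flag_columns()], flag
#' values strictly 0/1. Validation failures (non-boolean flags, duplicate
#' intervals, interval counts inconsistent with stated durations) raise an
#' error naming the offending video/row.
#'
#' @param path path to the coding-sheet CSV.
#' @param metadata optional video metadata: a CSV path or data frame with
#'   columns `video_id` and `duration_s` (plus optional `title`, `artist`,
#'   `genre`, `release_date`). If omitted, each video's duration is taken
#'   as 10 x its interval count.
#' @return list of validated [coded_video()] objects, named by `video_id`.
#' @export
read_coding_sheet <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop_input("coding sheet not found: %s", path)
  sheet <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("video_id", "interval_index")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0)
    stop_input("coding sheet %s lacks column(s): %s", path, paste(missing, collapse = ", "))
  flag_cols <- intersect(names(sheet), flag_columns())
  unknown <- setdiff(names(sheet), c(required, flag_columns()))
  if (length(unknown) > 0)
    stop_input("coding sheet %s has unrecognised column(s): %s", path,
               paste(unknown, collapse = ", "))
  for (col in flag_cols) {
    bad <- which(!(sheet[[col]] %in% c(0, 1)))
    if (length(bad) > 0)
      stop_input("non-boolean flag value '%s' in column '%s', row %d of %s",
                 as.character(sheet[[col]][bad[1]]), col, bad[1], path)
  }
  key <- paste(sheet$video_id, sheet$interval_index)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_input("duplicate (video_id, interval_index) pair in %s: %s", path, dup)
  }

  meta <- NULL
  if (!is.null(metadata)) {
    meta <- if (is.character(metadata)) {
      readr::read_csv(metadata, show_col_types = FALSE, progress = FALSE)
    } else tibble::as_tibble(metadata)
    if (!all(c("video_id", "duration_s") %in% names(meta)))
      stop_input("metadata must have video_id and duration_s columns")
  }

  ids <- unique(sheet$video_id)
  videos <- lapply(ids, function(id) {
    block <- sheet[sheet$video_id == id, c("interval_index", flag_cols)]
    n <- nrow(block)
    if (!setequal(block$interval_index, seq_len(n) - 1L))
      stop_input("video '%s': interval_index values are not consecutive 0..%d", id, n - 1L)
    args <- list(video_id = id, duration_s = n * 10, intervals = block)
    if (!is.null(meta)) {
      row <- meta[meta$video_id == id, , drop = FALSE]
      if (nrow(row) == 0) stop_input("video '%s' present in coding sheet but not in metadata", id)
      dur <- row$duration_s[1]
      if (ceiling(dur / 10) != n)
        stop_input("video '%s': %d intervals inconsistent with duration %.0f s (expected %d)",
                   id, n, dur, ceiling(dur / 10))
      args$duration_s <- dur
      for (f in intersect(c("title", "artist", "artist_nationality", "genre", "release_date"),
                          names(row))) {
        args[[f]] <- row[[f]][1]
      }
    }
    do.call(coded_video, args)
  })
  names(videos) <- ids
  videos
}

#' @rdname read_coding_sheet
#' @param videos list of [coded_video()] objects.
#' @param metadata_path optional path to also write the video metadata CSV.
#' @export
write_coding_sheet <- function(videos, path, metadata_path = NULL) {
  readr::write_csv(coding_sheet(videos), path, progress = FALSE)
  if (!is.null(metadata_path)) {
    readr::write_csv(video_metadata(videos), metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Read and write coded videos as nested JSON
#'
#' The JSON layout is one object per video holding its metadata and an
#' `intervals` array with only the present flags listed, which round-trips
#' losslessly with the CSV coding sheet.
#'
#' @param videos list of [coded_video()] objects.
#' @param path file path.
#' @return `read_coding_json()` returns a named list of [coded_video()].
#' @export
write_coding_json <- function(videos, path) {
  payload <- lapply(videos, function(v) {
    flags <- as.matrix(v$intervals[flag_columns()])
    present <- which(flags == 1L, arr.ind = TRUE)
    list(
      video_id = v$video_id, title = v$title, artist = v$artist,
      artist_nationality = v$artist_nationality, genre = v$genre,
      release_date = as.character(v$release_date), duration_s = v$duration_s,
      flags = if (nrow(present) > 0) {
        data.frame(interval_index = v$intervals$interval_index[present[, 1]],
                   flag = colnames(flags)[present[, 2]])
      } else data.frame(interval_index = integer(0), flag = character(0))
    )
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coding_json
#' @export
read_coding_json <- function(path) {
  if (!file.exists(path)) stop_input("coding JSON not found: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  videos <- lapply(seq_len(nrow(payload)), function(i) {
    rec <- payload[i, ]
    flags <- rec$flags[[1]]
    intervals <- NULL
    if (!is.null(flags) && nrow(flags) > 0) {
      wide <- tibble::tibble(interval_index = sort(unique(as.integer(flags$interval_index))))
      for (f in unique(flags$flag)) {
        hit <- as.integer(flags$interval_index[flags$flag == f])
        wide[[f]] <- as.integer(wide$interval_index %in% hit)
      }
      intervals <- wide
    }
    coded_video(
      video_id = rec$video_id, duration_s = rec$duration_s, intervals = intervals,
      title = rec$title %||% NA_character_, artist = rec$artist %||% NA_character_,
      artist_nationality = rec$artist_nationality %||% NA_character_,
      genre = rec$genre %||% NA_character_, release_date = rec$release_date %||% NA
    )
  })
  names(videos) <- vapply(videos, function(v) v$video_id, character(1))
  videos
}
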