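# shared fixture builders; all randomness is locally seeded so tests are
# order-independent

# a video with a random 0/1 flag matrix over n intervals
random_video <- function(id = "v01", n = 30, density = 0.2) {
  flags <- tibble::tibble(interval_index = seq_len(n) - 1L)
  for (col in flag_columns()) {
    flags[[col]] <- rbinom(n, 1, density)
  }
  coded_video(id, duration_s = n * 10, intervals = flags)
}

# brute-force oracle: loop over intervals, OR of all class flags
brute_force_count <- function(video, substance_set) {
  cols <- flag_columns(substance_set)
  hits <- 0L
  for (i in seq_len(nrow(video$intervals))) {
    any_flag <- FALSE
    for (col in cols) {
      if (video$intervals[[col]][i] == 1L) any_flag <- TRUE
    }
    if (any_flag) hits <- hits + 1L
  }
  hits
}

# a minimal validated survey from explicit vectors; seen is a matrix with
# one column per video id
make_survey <- function(age, gender, weight, seen, ids = colnames(seen)) {
  df <- tibble::tibble(
    respondent_id = sprintf("r%03d", seq_along(age)),
    age = as.integer(age), gender = gender, weight = weight
  )
  for (j in seq_along(ids)) df[[ids[j]]] <- seen[, j]
  mediareach:::validate_survey(df, video_ids = ids)
}

# survey in which respondent i saw exactly the first k_i of the videos
survey_with_fractions <- function(k, n_videos = 4, age = NULL, gender = NULL, weight = NULL) {
  n <- length(k)
  seen <- t(vapply(k, function(ki) as.integer(seq_len(n_videos) <= ki), integer(n_videos)))
  colnames(seen) <- sprintf("v%02d", seq_len(n_videos))
  if (is.null(age)) age <- rep(20L, n)
  if (is.null(gender)) gender <- rep(c("female", "male"), length.out = n)
  if (is.null(weight)) weight <- rep(1, n)
  make_survey(age = age, gender = gender, weight = weight, seen = seen)
}
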