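#' Path to the packaged stimulus table
#'
#' The package ships a 117-song music database as a plain CSV
#' (columns `id,artist,title,label,year,tempo_bpm`). All songs were selected
#' for a clear, stable beat with tempi nominally in the 130--200 BPM range
#' used for cadence-matched playback.
#'
#' @return Path to the CSV file.
#' @export
#' @examples
#' stimulus_table_path()
stimulus_table_path <- function() {
  system.file("extdata", "table1_stimuli.csv", package = "runsync",
              mustWork = TRUE)
}

#' Read a stimulus library
#'
#' Loads a song table into a stimulus library tibble, validating the schema
#' and flagging songs whose tempo falls outside the nominal BPM range.
#' Out-of-range songs are retained (flagged with `in_range = FALSE`) rather
#' than dropped, so the packaged table keeps all 117 rows.
#'
#' @param path CSV file with columns `id,artist,title,label,year,tempo_bpm`.
#'   Defaults to the packaged stimulus table.
#' @param nominal_range Length-2 numeric, the nominal BPM range
#'   (default `c(130, 200)`).
#'
#' @return A tibble of class `stimulus_library` with one row per song, in
#'   file order, and a logical `in_range` column.
#' @export
#' @examples
#' lib <- read_stimulus_library()
#' nrow(lib)                     # 117
#' dplyr::filter(lib, !in_range) # the one out-of-range song (210 BPM)
read_stimulus_library <- function(path = stimulus_table_path(),
                                  nominal_range = c(130, 200)) {
  required <- c("id", "artist", "title", "label", "year", "tempo_bpm")
  songs <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(required, names(songs))
  if (length(missing_cols) > 0) {
    abort(paste0("stimulus table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "runsync_format_error")
  }
  if (nrow(songs) == 0) {
    abort("stimulus table has no rows", class = "runsync_format_error")
  }
  tempo <- suppressWarnings(as.numeric(songs$tempo_bpm))
  bad <- which(is.na(tempo) | tempo <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-numeric or non-positive tempo in row(s): ",
                 paste(bad, collapse = ", ")),
          class = "runsync_parse_error")
  }
  id <- suppressWarnings(as.integer(songs$id))
  if (anyNA(id) || any(id <= 0)) {
    abort("song ids must be positive integers", class = "runsync_parse_error")
  }
  if (anyDuplicated(id)) {
    abort("song ids must be unique", class = "runsync_validation_error")
  }
  lib <- tibble(
    id = id,
    artist = songs$artist,
    title = songs$title,
    label = songs$label,
    year = suppressWarnings(as.integer(songs$year)),
    tempo_bpm = tempo,
    in_range = tempo >= nominal_range[1] & tempo <= nominal_range[2]
  )
  attr(lib, "nominal_range") <- nominal_range
  class(lib) <- c("stimulus_library", class(lib))
  lib
}

#' Write a stimulus library back to CSV
#'
#' Inverse of [read_stimulus_library()]; the `in_range` flag is derived, not
#' stored, so a read/write/read cycle round-trips all fields.
#'
#' @param library A `stimulus_library` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stimulus_library <- function(library, path) {
  out <- library[, c("id", "artist", "title", "label", "year", "tempo_bpm")]
  readr::write_csv(out, path)
  invisible(path)
}

#' Score a BMRI-2 rating
#'
#' The Brunel Music Rating Inventory 2 asks six questions about the
#' motivational qualities of a song, each answered on a 7-point Likert scale
#' (1 = strongly disagree, 7 = strongly agree). The song's score is the sum
#' of the six item responses, so scores range from 6 to 42.
#'
#' @param items Integer vector of exactly six responses, each in 1..7.
#' @return The integer sum of the six items.
#' @export
#' @examples
#' bmri2_score(c(4, 5, 6, 3, 7, 2)) # 27
bmri2_score <- function(items) {
  if (length(items) != 6) {
    abort("a BMRI-2 rating has exactly 6 items",
          class = "runsync_validation_error")
  }
  items <- as.numeric(items)
  if (anyNA(items) || any(items != round(items)) ||
      any(items < 1) || any(items > 7)) {
    abort("BMRI-2 items must be integers in 1..7",
          class = "runsync_validation_error")
  }
  as.integer(sum(items))
}

#' Select a personal playlist by BMRI-2 score
#'
#' Scores every rated song with [bmri2_score()] and returns the `n`
#' highest-scoring songs, ordered by descending score. Ties are broken by
#' lower song id, which keeps the selection deterministic.
#'
#' @param library A `stimulus_library` tibble.
#' @param ratings A data frame with columns `song_id,i1,i2,i3,i4,i5,i6`
#'   (one BMRI-2 rating per library song rated).
#' @param n Number of songs to keep (default 20, the per-runner playlist
#'   size used during cadence-matched playback).
#'
#' @return A tibble of `n` songs with an added `bmri2` score column, sorted
#'   by descending score (ties: ascending id).
#' @export
select_playlist <- function(library, ratings, n = 20) {
  item_cols <- paste0("i", 1:6)
  if (!all(c("song_id", item_cols) %in% names(ratings))) {
    abort("ratings need columns song_id,i1..i6",
          class = "runsync_validation_error")
  }
  unknown <- setdiff(ratings$song_id, library$id)
  if (length(unknown) > 0) {
    abort(paste0("ratings reference unknown song id(s): ",
                 paste(unknown, collapse = ", ")),
          class = "runsync_validation_error")
  }
  if (n < 1 || n > nrow(ratings)) {
    abort("n must be between 1 and the number of rated songs",
          class = "runsync_validation_error")
  }
  scores <- vapply(
    seq_len(nrow(ratings)),
    function(i) bmri2_score(unlist(ratings[i, item_cols], use.names = FALSE)),
    integer(1)
  )
  scored <- tibble(id = ratings$song_id, bmri2 = scores) |>
    left_join(library, by = "id") |>
    arrange(dplyr::desc(.data$bmri2), .data$id)
  head(scored, n)
}

#' Pick the playback song for a measured cadence
#'
#' Walks the score-ordered playlist and returns the first (highest-scoring)
#' song whose tempo lies within 5 % of the runner's cadence, i.e.
#' `|tempo - cadence| / cadence <= 0.05` (boundary inclusive). The selected
#' song is subsequently time-stretched to match the cadence exactly, so the
#' window only bounds how much stretching is needed.
#'
#' @param playlist A score-ordered song tibble (from [select_playlist()]).
#' @param cadence Measured running cadence in steps per minute (> 0).
#' @param max_rel_diff Maximum relative tempo difference (default 0.05).
#'
#' @return One song row (tibble). If no song is eligible, an error of class
#'   `runsync_eligibility_error` is thrown whose `fallback` field carries the
#'   nearest-tempo song as a suggestion.
#' @export
pick_song <- function(playlist, cadence, max_rel_diff = 0.05) {
  if (nrow(playlist) == 0) {
    abort("playlist is empty", class = "runsync_validation_error")
  }
  if (!is.numeric(cadence) || cadence <= 0) {
    abort("cadence must be positive", class = "runsync_validation_error")
  }
  rel <- abs(playlist$tempo_bpm - cadence) / cadence
  ok <- which(rel <= max_rel_diff)
  if (length(ok) == 0) {
    nearest <- playlist[which.min(rel), ]
    abort(
      sprintf("no playlist song within %.0f %% of %.1f SPM", 100 * max_rel_diff, cadence),
      class = "runsync_eligibility_error",
      fallback = nearest
    )
  }
  playlist[ok[1], ]
}
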