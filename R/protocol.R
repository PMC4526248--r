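#' The tempo-shift condition set
#'
#' Eleven signed percent shifts applied to the tempo-matched music during
#' the final two laps of a sequence. Shifts stay within +/-3 % because an
#' average listener only notices tempo changes of about 4 %; the protocol
#' probes *spontaneous* (unnoticed, uninstructed) entrainment.
#'
#' @return Numeric vector of the 11 shifts, in percent.
#' @export
#' @examples
#' tempo_shifts()
tempo_shifts <- function() {
  c(-3.00, -2.50, -2.00, -1.50, -1.00, 0.00,
    +1.00, +1.50, +2.00, +2.50, +3.00)
}

#' Build per-participant session schedules
#'
#' Each participant runs 12 four-lap sequences: one practice sequence with
#' no music, then the 11 shift conditions in a randomized order. Orders are
#' drawn as seeded random permutations with rejection until all participants'
#' orders are pairwise distinct.
#'
#' @param participant_ids Character or integer vector of unique ids.
#' @param seed Integer seed; the same ids + seed always give the same
#'   schedules.
#' @param shifts Condition set (default [tempo_shifts()]; a subset can be
#'   supplied for reduced runs).
#'
#' @return A tibble with columns `participant_id`, `sequence` (1..12),
#'   `practice` (TRUE for sequence 1) and `shift_pct` (NA for practice).
#' @export
#' @examples
#' sch <- make_cohort_schedules(paste0("R", 1:4), seed = 1)
#' dplyr::count(sch, participant_id)
make_cohort_schedules <- function(participant_ids, seed,
                                  shifts = tempo_shifts()) {
  if (anyDuplicated(participant_ids)) {
    abort("participant ids must be unique", class = "runsync_validation_error")
  }
  n <- length(participant_ids)
  if (n > factorial(length(shifts))) {
    abort("more participants than distinct condition orders",
          class = "runsync_validation_error")
  }
  orders <- list()
  seen <- character(0)
  set.seed(as.integer(seed))
  while (length(orders) < n) {
    perm <- sample(shifts)
    key <- paste(perm, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      orders[[length(orders) + 1]] <- perm
    }
  }
  k <- length(shifts)
  purrr::map2_dfr(participant_ids, orders, function(pid, ord) {
    tibble(
      participant_id = pid,
      sequence = seq_len(k + 1),
      practice = c(TRUE, rep(FALSE, k)),
      shift_pct = c(NA_real_, ord)
    )
  })
}

#' Export schedules as JSON
#'
#' One object per participant: `{"participant_id": ..., "order": [shifts]}`.
#'
#' @param schedules Tibble from [make_cohort_schedules()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedules_json <- function(schedules, path) {
  by_pid <- split(schedules, factor(schedules$participant_id,
                                    levels = unique(schedules$participant_id)))
  objs <- purrr::map(by_pid, function(df) {
    df <- df[order(df$sequence), ]
    list(participant_id = df$participant_id[1],
         order = df$shift_pct[!df$practice])
  })
  jsonlite::write_json(unname(objs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a four-lap tempo timeline
#'
#' A sequence has four laps: lap 1 is silent; lap 2 plays music whose tempo
#' equals the reference cadence measured at the end of lap 1; during laps 3
#' and 4 the tempo ramps linearly (over `ramp_s` seconds from lap-3 onset)
#' to `reference_bpm * (1 + shift_pct/100)` and stays there.
#'
#' @param shift_pct Signed percent shift, normally one of [tempo_shifts()].
#' @param reference_bpm Reference tempo in BPM (> 0), the measured cadence.
#' @param lap_durations Numeric length 4, lap durations in seconds.
#' @param ramp_s Ramp duration in seconds (default 5; the first 5 s of the
#'   shifted laps are discarded from analysis, so the ramp fits inside the
#'   discarded head).
#'
#' @return An object of class `tempo_timeline`.
#' @export
#' @examples
#' tl <- tempo_timeline(+2, reference_bpm = 160, lap_durations = rep(72, 4))
#' bpm_at(tl, c(30, 100, 250))  # NA (silent), 160, 163.2
tempo_timeline <- function(shift_pct, reference_bpm, lap_durations,
                           ramp_s = 5) {
  if (!is.numeric(reference_bpm) || reference_bpm <= 0) {
    abort("reference_bpm must be positive", class = "runsync_validation_error")
  }
  if (length(lap_durations) != 4 || any(lap_durations <= 0)) {
    abort("lap_durations must be 4 positive values",
          class = "runsync_validation_error")
  }
  bounds <- cumsum(c(0, lap_durations))
  structure(
    list(
      shift_pct = shift_pct,
      reference_bpm = reference_bpm,
      shifted_bpm = reference_bpm * (1 + shift_pct / 100),
      lap_bounds = bounds,      # t = 0 at sequence start; 5 boundaries
      music_start = bounds[2],  # lap 2 onset
      shift_start = bounds[3],  # lap 3 onset (ramp start)
      ramp_s = ramp_s,
      end = bounds[5]
    ),
    class = "tempo_timeline"
  )
}

#' @export
print.tempo_timeline <- function(x, ...) {
  cat(sprintf(
    "<tempo_timeline> ref %.2f BPM, shift %+.2f %% -> %.2f BPM; laps at %s s; ramp %g s\n",
    x$reference_bpm, x$shift_pct, x$shifted_bpm,
    paste(round(x$lap_bounds, 1), collapse = ", "), x$ramp_s))
  invisible(x)
}

#' Evaluate a tempo timeline
#'
#' Returns the music tempo in BPM at times `t` (seconds from sequence
#' start). `NA` during the silent first lap and outside the sequence.
#'
#' @param timeline A `tempo_timeline`.
#' @param t Numeric vector of times in seconds.
#' @return Numeric vector of BPM values (NA where no music plays).
#' @export
bpm_at <- function(timeline, t) {
  tl <- timeline
  out <- rep(NA_real_, length(t))
  music <- t >= tl$music_start & t < tl$end
  out[music & t < tl$shift_start] <- tl$reference_bpm
  ramp <- music & t >= tl$shift_start & t < tl$shift_start + tl$ramp_s
  if (any(ramp)) {
    frac <- (t[ramp] - tl$shift_start) / tl$ramp_s
    out[ramp] <- tl$reference_bpm + frac * (tl$shifted_bpm - tl$reference_bpm)
  }
  out[music & t >= tl$shift_start + tl$ramp_s] <- tl$shifted_bpm
  out
}

#' Beat times of a tempo timeline
#'
#' Integrates the instantaneous tempo from music onset to the sequence end
#' and returns the times at which whole beats fall. The piecewise-linear
#' tempo profile is integrated on a fine grid (trapezoidal rule) and beat
#' times are found by inverse interpolation of the cumulative beat count.
#'
#' @param timeline A `tempo_timeline`.
#' @param dt Integration step in seconds.
#' @return Numeric vector of beat times (seconds), first beat at music onset.
#' @export
beat_times <- function(timeline, dt = 0.005) {
  tl <- timeline
  tt <- seq(tl$music_start, tl$end, by = dt)
  bpm <- bpm_at(tl, tt)
  bpm[is.na(bpm)] <- tl$shifted_bpm   # right endpoint of the last lap
  rate <- bpm / 60
  beats_cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * diff(tt)))
  n_beats <- floor(beats_cum[length(beats_cum)])
  approx(beats_cum, tt, xout = 0:n_beats, ties = "ordered")$y
}

#' Reference cadence from the end of the silent lap
#'
#' Mean cadence over the final `window_s` seconds of the silent first lap;
#' this value becomes the tempo of the matched music in lap 2.
#'
#' @param steps A `step_series` (see [step_series()]).
#' @param lap1_end End time of lap 1 in seconds.
#' @param window_s Window length in seconds (default 20).
#' @return Mean cadence in SPM.
#' @export
reference_cadence <- function(steps, lap1_end, window_s = 20) {
  mean_cadence(steps, c(lap1_end - window_s, lap1_end))
}
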