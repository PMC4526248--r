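#' Analysis window for the tempo-changed laps
#'
#' The first 5 s of the tempo-changed laps are discarded because the music
#' tempo is still ramping there; the final 20 s are discarded because
#' runners may alter their behaviour in anticipation of the sequence end.
#'
#' @param lap3_start,lap4_end Start of lap 3 and end of lap 4, in seconds.
#' @param discard_head_s,discard_tail_s Trim lengths (defaults 5 and 20).
#' @return Numeric length 2, the half-open analysis window.
#' @export
#' @examples
#' trim_tcl_window(144, 288)  # c(149, 268)
trim_tcl_window <- function(lap3_start, lap4_end,
                            discard_head_s = 5, discard_tail_s = 20) {
  w <- c(lap3_start + discard_head_s, lap4_end - discard_tail_s)
  if (w[2] <= w[1]) {
    abort("tempo-changed laps too short for the trim rule",
          class = "runsync_insufficient_duration_error")
  }
  w
}

#' Analysis window for the tempo-matched lap
#'
#' The full tempo-matched lap minus its first 5 s, mirroring the head trim
#' of the tempo-changed laps.
#'
#' @param lap2_start,lap2_end Lap 2 boundaries in seconds.
#' @param discard_head_s Head trim (default 5).
#' @return Numeric length 2 window.
#' @export
tml_window <- function(lap2_start, lap2_end, discard_head_s = 5) {
  w <- c(lap2_start + discard_head_s, lap2_end)
  if (w[2] <= w[1]) {
    abort("tempo-matched lap too short for the trim rule",
          class = "runsync_insufficient_duration_error")
  }
  w
}

#' Cadence adaptation
#'
#' Ratio of the mean cadence during the (trimmed) tempo-changed laps to the
#' mean cadence during the tempo-matched lap:
#' `ratio = avg(SPM_TCL) / avg(SPM_TML)`. A ratio of 1.02 means the runner
#' sped up 2 % relative to the tempo-matched baseline; the percent-change
#' form `(ratio - 1) * 100` is directly comparable to the tempo shift.
#'
#' @param steps A [step_series()].
#' @param tml Window of the tempo-matched lap (from [tml_window()]).
#' @param tcl Window of the tempo-changed laps (from [trim_tcl_window()]).
#' @return A one-row tibble with `adaptation_ratio` and `adaptation_pct`.
#' @export
cadence_adaptation <- function(steps, tml, tcl) {
  spm_tml <- tryCatch(mean_cadence(steps, tml),
                      runsync_insufficient_data_error = function(e) {
                        abort(paste0("tempo-matched lap: ", conditionMessage(e)),
                              class = "runsync_insufficient_data_error")
                      })
  spm_tcl <- tryCatch(mean_cadence(steps, tcl),
                      runsync_insufficient_data_error = function(e) {
                        abort(paste0("tempo-changed laps: ", conditionMessage(e)),
                              class = "runsync_insufficient_data_error")
                      })
  ratio <- spm_tcl / spm_tml
  tibble(adaptation_ratio = ratio, adaptation_pct = (ratio - 1) * 100)
}

#' Tempo-entrainment score
#'
#' A step is *tempo-entrained* when its instantaneous cadence differs from
#' the concurrent music tempo by at most 1 % (inclusive):
#' `|SPM_i - BPM(t_i)| / BPM(t_i) <= 0.01`. The entrainment score is the
#' percentage of tempo-entrained steps among all steps with a defined
#' instantaneous cadence inside the window.
#'
#' @param steps A [step_series()].
#' @param timeline A [tempo_timeline()] giving BPM as a function of time.
#' @param window Half-open analysis window `c(start, end)` in seconds.
#' @param max_rel_diff Entrainment tolerance (default 0.01).
#' @return Score in percent (0--100).
#' @export
entrainment_score <- function(steps, timeline, window, max_rel_diff = 0.01) {
  inside <- steps$t >= window[1] & steps$t < window[2] & !is.na(steps$inst_spm)
  if (!any(inside)) {
    abort("no steps with defined cadence in window",
          class = "runsync_insufficient_data_error")
  }
  spm <- steps$inst_spm[inside]
  bpm <- bpm_at(timeline, steps$t[inside])
  # epsilon keeps the inclusive boundary robust to floating-point noise
  entrained <- !is.na(bpm) & abs(spm - bpm) / bpm <= max_rel_diff + 1e-12
  100 * mean(entrained)
}

#' Score every sequence of a simulated cohort
#'
#' Computes the two outcome measures for each non-practice sequence:
#' cadence adaptation (tempo-changed vs tempo-matched laps, with the
#' 5 s / 20 s trimming rule) and the tempo-entrainment score, plus the RPE
#' rating, in a tidy one-row-per-participant-x-condition table.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param steps_from `"true"` scores the simulator's step times directly;
#'   `"detected"` first runs [detect_steps()] on each accelerometer trace
#'   (requires `traces = TRUE` at simulation time), exercising the full
#'   signal chain.
#' @return A tibble with columns `participant_id, shift_pct,
#'   adaptation_ratio, adaptation_pct, entrainment_pct, rpe`.
#' @export
score_cohort <- function(sim, steps_from = c("true", "detected")) {
  steps_from <- match.arg(steps_from)
  if (steps_from == "detected" && !"trace" %in% names(sim$sessions)) {
    abort("cohort was simulated without traces",
          class = "runsync_validation_error")
  }
  sess <- sim$sessions |> filter(!.data$practice)
  purrr::map_dfr(seq_len(nrow(sess)), function(r) {
    row <- sess[r, ]
    steps <- if (steps_from == "true") row$steps[[1]] else
      detect_steps(row$trace[[1]])
    lb <- row$lap_bounds[[1]]
    tml <- tml_window(lb[2], lb[3])
    tcl <- trim_tcl_window(lb[3], lb[5])
    adapt <- cadence_adaptation(steps, tml, tcl)
    tibble(
      participant_id = row$participant_id,
      shift_pct = row$shift_pct,
      adaptation_ratio = adapt$adaptation_ratio,
      adaptation_pct = adapt$adaptation_pct,
      entrainment_pct = entrainment_score(steps, row$timeline[[1]], tcl),
      rpe = row$rpe
    )
  })
}

#' Estimate the entrainment-basin half-width from a score curve
#'
#' Given per-condition entrainment scores as a function of tempo shift, the
#' basin half-width is estimated by threshold-crossing: the detuning at
#' which the score curve crosses midway between its peak and its far tail,
#' found by linear interpolation on each side of the peak and averaged over
#' the two sides. Because a step already counts as entrained within
#' `tolerance_pct` of the music tempo, the score decays over a band of
#' about that width beyond the true basin edge; each crossing is therefore
#' de-biased by `tolerance_pct / 2` (half the band, the midpoint of a
#' linear decay). For the circle-map runner this recovers the model
#' half-width `K / (2*pi)` in relative detuning (x100 for percent),
#' provided the half-width exceeds the scoring tolerance.
#'
#' @param scores A data frame with columns `shift_pct` and
#'   `entrainment_pct` (one row per condition; replicate rows are averaged).
#' @param threshold Crossing level in score units; default midway between
#'   the curve's maximum and minimum.
#' @param tolerance_pct The entrainment scoring tolerance in percent
#'   (default 1, matching [entrainment_score()]).
#' @return Estimated half-width in percent detuning (NA if the curve never
#'   drops below the threshold on either side).
#' @export
estimate_basin_halfwidth <- function(scores, threshold = NULL,
                                     tolerance_pct = 1) {
  curve <- scores |>
    group_by(.data$shift_pct) |>
    summarise(score = mean(.data$entrainment_pct), .groups = "drop") |>
    arrange(.data$shift_pct)
  thr <- if (is.null(threshold)) (max(curve$score) + min(curve$score)) / 2
         else threshold
  peak_at <- curve$shift_pct[which.max(curve$score)]

  cross <- function(sh, sc) {
    # sh ordered moving away from the peak; find first drop below thr
    below <- which(sc < thr)
    if (length(below) == 0) return(NA_real_)
    j <- below[1]
    if (j == 1) return(abs(sh[1]))
    # linear interpolation between the last point above and first below
    s0 <- sc[j - 1]; s1 <- sc[j]
    x0 <- sh[j - 1]; x1 <- sh[j]
    abs(x0 + (thr - s0) * (x1 - x0) / (s1 - s0))
  }
  right <- curve |> filter(.data$shift_pct >= peak_at)
  left <- curve |> filter(.data$shift_pct <= peak_at) |>
    arrange(dplyr::desc(.data$shift_pct))
  est <- c(cross(left$shift_pct, left$score),
           cross(right$shift_pct, right$score))
  if (all(is.na(est))) return(NA_real_)
  max(0, mean(est, na.rm = TRUE) - tolerance_pct / 2)
}

#' Write the per-sequence metric table
#'
#' @param metrics Tibble from [score_cohort()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(path)
}
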