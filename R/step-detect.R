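#' Construct a step series
#'
#' A step series is a tibble of step-event times with the derived
#' instantaneous cadence: `inst_spm[i] = 60 / (t[i] - t[i-1])`, defined from
#' the second step and assigned to the later step of each interval.
#'
#' @param times Strictly increasing numeric vector of step times (seconds).
#' @return A tibble of class `step_series` with columns `t` and `inst_spm`
#'   (`NA` for the first step).
#' @export
#' @examples
#' step_series(seq(0, 3, by = 0.375))  # uniform 160 SPM
step_series <- function(times) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("step times must be strictly increasing",
          class = "runsync_validation_error")
  }
  out <- tibble(t = times,
                inst_spm = c(NA_real_, 60 / diff(times)))
  class(out) <- c("step_series", class(out))
  out
}

#' Mean cadence over a time window
#'
#' Arithmetic mean of the instantaneous cadence of all steps falling in the
#' half-open window `[t_start, t_end)`. Steps without a defined
#' instantaneous cadence (the first step of a series) are in the window but
#' contribute no value.
#'
#' @param steps A `step_series`.
#' @param window Numeric length 2: `c(t_start, t_end)` in seconds.
#' @return Mean cadence in steps per minute.
#' @export
mean_cadence <- function(steps, window) {
  stopifnot(length(window) == 2)
  inside <- steps$t >= window[1] & steps$t < window[2]
  if (sum(inside) < 2) {
    abort(sprintf("fewer than 2 steps in window [%.2f, %.2f)",
                  window[1], window[2]),
          class = "runsync_insufficient_data_error")
  }
  mean(steps$inst_spm[inside], na.rm = TRUE)
}

#' Detect steps in an accelerometer trace
#'
#' Detection pipeline: (1) acceleration magnitude minus its median (removes
#' gravity), (2) zero-phase Butterworth band-pass 1--5 Hz covering step
#' frequencies of 60--300 SPM, (3) peak picking against an adaptive
#' threshold of 0.5 x the rolling 95th percentile of the filtered signal,
#' with a refractory period of 60/220 s so no cadence above 220 SPM can be
#' reported. Peak times are refined by parabolic interpolation around each
#' sample-level maximum.
#'
#' The adaptive threshold makes detection invariant to a uniform rescaling
#' of the signal amplitude, and all timestamps are relative to the trace
#' start time, so shifting `t` shifts detections by exactly the same offset.
#'
#' @param trace An `accel_trace` tibble (`t,ax,ay,az`; see [synth_accel()]),
#'   uniformly sampled at >= 20 Hz.
#' @param threshold_frac Fraction of the rolling 95th percentile used as the
#'   peak threshold (default 0.5).
#' @param refractory_s Minimum step spacing in seconds (default 60/220).
#' @return A [step_series()] of detected step times.
#' @export
detect_steps <- function(trace, threshold_frac = 0.5,
                         refractory_s = 60 / 220) {
  t <- trace$t
  if (length(t) < 3 || (t[length(t)] - t[1]) < 2) {
    abort("trace shorter than 2 s", class = "runsync_insufficient_data_error")
  }
  fs <- 1 / median(diff(t))
  if (fs < 20) {
    abort("sample rate below 20 Hz", class = "runsync_validation_error")
  }
  mag <- sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
  mag <- mag - median(mag)
  bf <- signal::butter(2, c(1, 5) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, mag)

  thr <- threshold_frac * rolling_q95(bp, win = round(4 * fs))
  thr <- pmax(thr, 0.05 * max(bp))  # keep relative to the trace itself

  n <- length(bp)
  is_peak <- c(FALSE, bp[2:(n - 1)] > bp[1:(n - 2)] &
                      bp[2:(n - 1)] >= bp[3:n], FALSE) & bp > thr
  idx <- which(is_peak)
  if (length(idx) == 0) return(step_series(numeric(0)))

  # refractory: accept peaks in order of amplitude, reject close neighbours
  keep <- logical(length(idx))
  accepted <- numeric(0)
  for (j in order(bp[idx], decreasing = TRUE)) {
    ti <- t[idx[j]]
    if (length(accepted) == 0 || min(abs(accepted - ti)) >= refractory_s) {
      keep[j] <- TRUE
      accepted <- c(accepted, ti)
    }
  }
  idx <- sort(idx[keep])

  # parabolic sub-sample refinement
  times <- vapply(idx, function(i) {
    if (i <= 1 || i >= n) return(t[i])
    y0 <- bp[i - 1]; y1 <- bp[i]; y2 <- bp[i + 1]
    den <- y0 - 2 * y1 + y2
    delta <- if (den == 0) 0 else 0.5 * (y0 - y2) / den
    t[i] + max(-0.5, min(0.5, delta)) / fs
  }, numeric(1))
  step_series(times)
}

# rolling 95th percentile, computed on a decimated anchor grid and linearly
# interpolated back to full resolution (the threshold varies slowly)
rolling_q95 <- function(x, win, stride = NULL) {
  n <- length(x)
  win <- max(3, min(win, n))
  if (is.null(stride)) stride <- max(1, floor(win / 8))
  anchors <- unique(c(seq(1, n, by = stride), n))
  q <- vapply(anchors, function(i) {
    lo <- max(1, i - win %/% 2)
    hi <- min(n, i + win %/% 2)
    quantile(x[lo:hi], 0.95, names = FALSE)
  }, numeric(1))
  approx(anchors, q, xout = seq_len(n), rule = 2)$y
}

#' Write / read a step series as CSV
#'
#' Plain `t,inst_spm` columns; `inst_spm` is recomputed on read.
#'
#' @param steps A `step_series`.
#' @param path CSV path.
#' @return `path` invisibly, or the step series.
#' @export
write_step_series <- function(steps, path) {
  readr::write_csv(as_tibble(steps), path)
  invisible(path)
}

#' @rdname write_step_series
#' @export
read_step_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  step_series(df$t)
}
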