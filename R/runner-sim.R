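#' Cohort configuration for the runner simulator
#'
#' Bundles the synthetic-cohort parameters with validation. Defaults mirror
#' the study design: 16 recreational runners (9 female, 7 male), preferred
#' cadences in the 130--200 SPM range typical of recreational running, and
#' a stronger mean auditory-motor coupling for female runners, which
#' realizes the observed direction of the gender effect on entrainment.
#' Coupling values are free model parameters of the simulator, not
#' estimates.
#'
#' @param n_female,n_male Cohort composition (defaults 9 and 7).
#' @param coupling_mean_female,coupling_mean_male Mean circle-map coupling
#'   K by gender (dimensionless; defaults 0.16 and 0.09). The noiseless
#'   entrainment basin half-width in relative detuning is K / (2 * pi).
#' @param coupling_sd Between-runner SD of K (default 0.03; K is truncated
#'   at 0).
#' @param cadence_mean,cadence_sd Preferred cadence distribution in SPM
#'   (defaults 165 and 10, truncated to 130--200).
#' @param motor_noise_sd SD of Gaussian motor noise added to each inter-step
#'   interval, in seconds (default 0.010).
#' @param training_fraction Proportion of the cohort with musical training
#'   (default 0.625).
#' @param speed_mps Running speed in m/s used to derive self-paced lap
#'   durations (default 2.78, about 72 s per 200 m lap).
#' @param seed Master seed for the cohort.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_female = 9, n_male = 7,
                          coupling_mean_female = 0.16,
                          coupling_mean_male = 0.09,
                          coupling_sd = 0.03,
                          cadence_mean = 165, cadence_sd = 10,
                          motor_noise_sd = 0.010,
                          training_fraction = 0.625,
                          speed_mps = 2.78,
                          seed = 1L) {
  cfg <- list(n_female = n_female, n_male = n_male,
              coupling_mean_female = coupling_mean_female,
              coupling_mean_male = coupling_mean_male,
              coupling_sd = coupling_sd,
              cadence_mean = cadence_mean, cadence_sd = cadence_sd,
              motor_noise_sd = motor_noise_sd,
              training_fraction = training_fraction,
              speed_mps = speed_mps,
              seed = as.integer(seed))
  if (cfg$n_female < 0 || cfg$n_male < 0 || cfg$n_female + cfg$n_male < 1) {
    abort("cohort must contain at least one runner",
          class = "runsync_validation_error")
  }
  if (cfg$coupling_sd < 0 || cfg$cadence_sd < 0 || cfg$motor_noise_sd < 0) {
    abort("dispersion parameters must be >= 0",
          class = "runsync_validation_error")
  }
  if (cfg$training_fraction < 0 || cfg$training_fraction > 1) {
    abort("training_fraction must be in [0, 1]",
          class = "runsync_validation_error")
  }
  structure(cfg, class = "cohort_config")
}

# deterministic per-stage seed derivation from the master seed, so stages
# and participants can be re-run independently in any order
stage_seed <- function(master, stage, k = 0) {
  h <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.double(master) * 7919 + h * 104729 + as.double(k) * 15485863) %%
               2147483629)
}

#' Draw runner profiles for a cohort
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per runner: `participant_id`, `gender`,
#'   `preferred_cadence` (SPM), `coupling` (K), `motor_noise_sd` (s),
#'   `musical_training`, `speed_mps`.
#' @export
simulate_runners <- function(config = cohort_config()) {
  n <- config$n_female + config$n_male
  set.seed(stage_seed(config$seed, "profiles"))
  gender <- c(rep("female", config$n_female), rep("male", config$n_male))
  k_mean <- ifelse(gender == "female",
                   config$coupling_mean_female, config$coupling_mean_male)
  tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    gender = gender,
    preferred_cadence = pmin(200, pmax(130, rnorm(n, config$cadence_mean,
                                                  config$cadence_sd))),
    coupling = pmax(0, rnorm(n, k_mean, config$coupling_sd)),
    motor_noise_sd = config$motor_noise_sd,
    musical_training = runif(n) < config$training_fraction,
    speed_mps = config$speed_mps
  )
}

#' Simulate a step train with circle-map phase correction
#'
#' Steps are generated by a phase-error correction model of auditory-motor
#' coupling. While no music plays, inter-step intervals are
#' `60 / preferred_cadence` plus Gaussian motor noise. While music plays,
#' the asynchrony between each footfall and the nearest musical beat is
#' expressed as a relative phase `phi` in (-0.5, 0.5], and the next interval
#' is shortened or lengthened by the sinusoidal correction
#' `(K * T_b / (2*pi)) * sin(2*pi*phi)` with `T_b` the current beat period.
#' This is the classical sine circle map, which phase-locks exactly when the
#' relative detuning between preferred cadence and music tempo is smaller in
#' magnitude than `K / (2*pi)` (the entrainment-basin half-width), and
#' drifts outside that basin.
#'
#' The first step falls one preferred period after the sequence start, so a
#' noiseless simulation is fully deterministic.
#'
#' @param runner One-row runner profile (see [simulate_runners()]) or a list
#'   with `preferred_cadence`, `coupling`, `motor_noise_sd`.
#' @param timeline A [tempo_timeline()], or `NULL` for a fully silent run.
#' @param seed Integer seed for the motor noise.
#' @param duration Run duration in seconds; defaults to the timeline end
#'   (required when `timeline` is `NULL`).
#' @return A [step_series()].
#' @export
simulate_steps <- function(runner, timeline, seed, duration = NULL) {
  t_c <- 60 / runner$preferred_cadence
  k <- runner$coupling
  noise_sd <- runner$motor_noise_sd
  if (is.null(duration)) {
    if (is.null(timeline)) {
      abort("duration is required when timeline is NULL",
            class = "runsync_validation_error")
    }
    duration <- timeline$end
  }
  beats <- if (is.null(timeline)) numeric(0) else beat_times(timeline)
  nb <- length(beats)
  set.seed(as.integer(seed))

  times <- numeric(ceiling(duration / t_c * 1.5) + 8)
  t <- t_c  # first footfall after one preferred period
  i <- 0
  while (t <= duration) {
    i <- i + 1
    times[i] <- t
    bpm <- if (is.null(timeline)) NA_real_ else bpm_at(timeline, t)
    if (is.na(bpm)) {
      interval <- t_c
    } else {
      t_b <- 60 / bpm
      j <- findInterval(t, beats)
      near <- if (j < 1) beats[1]
              else if (j >= nb) beats[nb]
              else if (t - beats[j] <= beats[j + 1] - t) beats[j]
              else beats[j + 1]
      phi <- (t - near) / t_b
      phi <- phi - floor(phi + 0.5)  # wrap to (-0.5, 0.5]
      interval <- t_c - (k * t_b / (2 * pi)) * sin(2 * pi * phi)
    }
    if (noise_sd > 0) interval <- interval + rnorm(1, 0, noise_sd)
    interval <- max(interval, 0.3 * t_c)  # physical floor
    t <- t + interval
  }
  step_series(times[seq_len(i)])
}

#' Synthesize a tri-axial accelerometer trace from a step train
#'
#' Emulates an ankle-worn inertial sensor sampling at `sample_rate` Hz.
#' Each step contributes a biphasic, Gaussian-windowed impulse (width about
#' 80 ms) on the vertical axis over a 1 g (9.81 m/s^2) baseline; white
#' Gaussian noise is added on all three axes.
#'
#' @param steps A [step_series()].
#' @param sample_rate Sampling rate in Hz (default 100).
#' @param noise_sd Per-axis white noise SD in m/s^2 (default 0.5).
#' @param seed Integer seed for the sensor noise.
#' @param duration Trace duration in seconds (default: last step + 0.5 s).
#' @param impulse_amp Peak vertical impulse amplitude in m/s^2 (default 20,
#'   i.e. 40 x the default noise SD).
#' @param t0 Trace start time in seconds (default 0).
#' @return A tibble of class `accel_trace` with columns `t,ax,ay,az` and a
#'   `sample_rate` attribute.
#' @export
synth_accel <- function(steps, sample_rate = 100, noise_sd = 0.5, seed = 1,
                        duration = NULL, impulse_amp = 20, t0 = 0) {
  if (nrow(steps) == 0) {
    abort("step series is empty", class = "runsync_validation_error")
  }
  mean_rate_hz <- mean(steps$inst_spm, na.rm = TRUE) / 60
  if (is.finite(mean_rate_hz) && sample_rate <= 2 * mean_rate_hz) {
    abort("sample_rate must exceed twice the step frequency",
          class = "runsync_aliasing_error")
  }
  if (is.null(duration)) duration <- max(steps$t) - t0 + 0.5
  n <- round(duration * sample_rate)
  tt <- t0 + (seq_len(n) - 1) / sample_rate

  width <- 0.08                      # impulse width (s)
  sigma <- width / 4
  half_sup <- 0.12                   # support of the impulse (s)
  az <- rep(0, n)
  for (s in steps$t) {
    i0 <- max(1L, ceiling((s - half_sup - t0) * sample_rate) + 1L)
    i1 <- min(n, floor((s + half_sup - t0) * sample_rate) + 1L)
    if (i0 > i1) next
    tau <- tt[i0:i1] - s
    az[i0:i1] <- az[i0:i1] +
      impulse_amp * exp(-tau^2 / (2 * sigma^2)) * cos(2 * pi * tau / width)
  }
  set.seed(as.integer(seed))
  out <- tibble(
    t = tt,
    ax = rnorm(n, 0, noise_sd),
    ay = rnorm(n, 0, noise_sd),
    az = 9.81 + az + rnorm(n, 0, noise_sd)
  )
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("accel_trace", class(out))
  out
}

#' Simulate a full experimental cohort
#'
#' Runs the complete protocol for every runner: a practice sequence without
#' music, then the 11 shift conditions in the participant's scheduled order.
#' For each non-practice sequence the reference cadence is measured from the
#' final 20 s of the silent first lap, a playback song within 5 % of that
#' cadence is picked from the runner's BMRI-2 playlist (falling back to the
#' nearest-tempo song when none qualifies), the tempo timeline is built, and
#' the step train is simulated against it. RPE ratings are drawn as
#' integers on the Borg 6--20 scale, centred mid-scale and independent of
#' entrainment. Everything is deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @param schedules Optional schedule tibble (default:
#'   [make_cohort_schedules()] on a derived seed).
#' @param library Stimulus library (default: the packaged table).
#' @param traces If `TRUE` (default), also synthesize accelerometer traces
#'   (list-column `trace`).
#' @param lap_distance_m Lap length in metres (default 200).
#' @param ramp_s Tempo ramp duration in seconds (default 5).
#' @param reference_window_s Reference-cadence window in seconds (default 20).
#' @param accel_noise_sd Sensor noise SD passed to [synth_accel()].
#' @param shifts Condition set used when schedules are generated here
#'   (default [tempo_shifts()]).
#' @return A list of class `cohort_sim` with elements `profiles`,
#'   `schedules`, `sessions` (a tibble with list-columns `timeline`, `steps`
#'   and optionally `trace`) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), schedules = NULL,
                            library = read_stimulus_library(),
                            traces = TRUE, lap_distance_m = 200,
                            ramp_s = 5, reference_window_s = 20,
                            accel_noise_sd = 0.5, shifts = tempo_shifts()) {
  profiles <- simulate_runners(config)
  if (is.null(schedules)) {
    schedules <- make_cohort_schedules(profiles$participant_id,
                                       stage_seed(config$seed, "schedules"),
                                       shifts = shifts)
  }
  if (!setequal(unique(schedules$participant_id), profiles$participant_id)) {
    abort("schedules do not cover the configured participants",
          class = "runsync_validation_error")
  }

  # per-runner BMRI-2 ratings and 20-song playlist
  playlists <- purrr::map(seq_len(nrow(profiles)), function(i) {
    set.seed(stage_seed(config$seed, "bmri", i))
    ratings <- tibble(song_id = library$id)
    for (col in paste0("i", 1:6)) {
      ratings[[col]] <- sample(1:7, nrow(library), replace = TRUE)
    }
    select_playlist(library, ratings, n = 20)
  })
  names(playlists) <- profiles$participant_id

  sessions <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    runner <- profiles[i, ]
    sched <- schedules |>
      filter(.data$participant_id == runner$participant_id) |>
      arrange(.data$sequence)
    lap_dur <- rep(lap_distance_m / runner$speed_mps, 4)
    set.seed(stage_seed(config$seed, "rpe", i))
    rpe <- pmin(20L, pmax(6L, as.integer(round(rnorm(nrow(sched), 13, 2)))))

    purrr::map_dfr(seq_len(nrow(sched)), function(s) {
      seed_s <- stage_seed(config$seed, "steps", i * 1000 + s)
      if (sched$practice[s]) {
        steps <- simulate_steps(runner, NULL, seed_s,
                                duration = sum(lap_dur))
        tl <- NULL
        song_id <- NA_integer_
        fallback <- FALSE
        ref <- NA_real_
      } else {
        # pass 1: silent lap 1 only, to measure the reference cadence; the
        # same seed makes lap 1 of the full run identical
        silent <- simulate_steps(runner, NULL, seed_s, duration = lap_dur[1])
        ref <- reference_cadence(silent, lap_dur[1],
                                 window_s = reference_window_s)
        pick <- tryCatch(
          list(song = pick_song(playlists[[runner$participant_id]], ref),
               fallback = FALSE),
          runsync_eligibility_error = function(e) {
            list(song = e$fallback, fallback = TRUE)
          }
        )
        tl <- tempo_timeline(sched$shift_pct[s], reference_bpm = ref,
                             lap_durations = lap_dur, ramp_s = ramp_s)
        steps <- simulate_steps(runner, tl, seed_s)
        song_id <- pick$song$id
        fallback <- pick$fallback
      }
      row <- tibble(
        participant_id = runner$participant_id,
        sequence = sched$sequence[s],
        practice = sched$practice[s],
        shift_pct = sched$shift_pct[s],
        reference_bpm = ref,
        song_id = song_id,
        song_fallback = fallback,
        rpe = rpe[s],
        lap_bounds = list(cumsum(c(0, lap_dur))),
        timeline = list(tl),
        steps = list(steps)
      )
      if (traces) {
        row$trace <- list(synth_accel(
          steps, sample_rate = 100, noise_sd = accel_noise_sd,
          seed = stage_seed(config$seed, "accel", i * 1000 + s),
          duration = sum(lap_dur)))
      }
      row
    })
  })

  structure(list(profiles = profiles, schedules = schedules,
                 sessions = sessions, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d runners x %d sequences (seed %d)\n",
              nrow(x$profiles), max(x$sessions$sequence), x$config$seed))
  invisible(x)
}

#' Export a simulated dataset to plain files
#'
#' Writes one step-series CSV (`steps_<pid>_s<seq>.csv`) and, when traces
#' were simulated, one accelerometer CSV (`accel_<pid>_s<seq>.csv`,
#' columns `t,ax,ay,az`) per participant-sequence, plus a `manifest.json`
#' listing files, the seed and the runner profiles.
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if needed).
#' @param traces Also write accelerometer CSVs when present (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, traces = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sess <- sim$sessions
  files <- character(0)
  for (r in seq_len(nrow(sess))) {
    tag <- sprintf("%s_s%02d", sess$participant_id[r], sess$sequence[r])
    f <- sprintf("steps_%s.csv", tag)
    write_step_series(sess$steps[[r]], file.path(dir, f))
    files <- c(files, f)
    if (traces && "trace" %in% names(sess)) {
      f <- sprintf("accel_%s.csv", tag)
      readr::write_csv(as_tibble(sess$trace[[r]]), file.path(dir, f))
      files <- c(files, f)
    }
  }
  manifest <- list(seed = sim$config$seed,
                   n_participants = nrow(sim$profiles),
                   profiles = sim$profiles,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an exported accelerometer trace
#'
#' @param path CSV with columns `t,ax,ay,az`.
#' @return An `accel_trace` tibble.
#' @export
read_accel_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t", "ax", "ay", "az") %in% names(df))) {
    abort("accelerometer CSV needs columns t,ax,ay,az",
          class = "runsync_format_error")
  }
  attr(df, "sample_rate") <- 1 / median(diff(df$t))
  class(df) <- c("accel_trace", class(df))
  df
}
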