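test_that("uncoupled runners keep their preferred cadence under any shift", {
  run <- make_runner(cadence = 160, hw = 0)  # K = 0
  tl <- make_timeline(+3)
  st <- simulate_steps(run, tl, seed = 1)
  expect_equal(diff(st$t), rep(0.375, nrow(st) - 1), tolerance = 1e-12)
  tcl <- trim_tcl_window(tl$lap_bounds[3], tl$end)
  adapt <- cadence_adaptation(st, tml_window(tl$lap_bounds[2], tl$lap_bounds[3]), tcl)
  expect_equal(adapt$adaptation_pct, 0, tolerance = 1e-9)
})

test_that("step generation matches an independent circle-map iteration", {
  # constant tempo throughout music (shift 0) but detuned reference, so the
  # coupled dynamics run without a ramp; oracle iterates the map directly
  run <- make_runner(cadence = 160, hw = 0.02)
  tl <- make_timeline(0, ref = 162.4)  # 1.5 % detuning
  got <- simulate_steps(run, tl, seed = 1)

  t_c <- 60 / 160
  t_b <- 60 / 162.4
  k <- 0.02 * 2 * pi
  beats <- seq(72, tl$end, by = t_b)
  t <- t_c; oracle <- numeric(0)
  while (t <= tl$end) {
    oracle <- c(oracle, t)
    if (t >= 72 && t < tl$end) {
      phi <- (t - beats[which.min(abs(beats - t))]) / t_b
      phi <- phi - floor(phi + 0.5)
      t <- t + t_c - (k * t_b / (2 * pi)) * sin(2 * pi * phi)
    } else {
      t <- t + t_c
    }
  }
  expect_equal(nrow(got), length(oracle))
  expect_equal(got$t, oracle, tolerance = 1e-4)
})

test_that("locking inside the basin, drifting outside (worked cases)", {
  run <- make_runner(cadence = 160, hw = 0.02)
  # detuning 1 % < hw: phase-locks, all post-transient steps entrained
  expect_gt(lock_score(run, +1), 99.9)
  # at the lock point the interval equals the beat period exactly
  tl <- make_timeline(+1)
  st <- simulate_steps(run, tl, seed = 1)
  late <- diff(st$t[st$t > 250])
  expect_equal(late, rep(60 / 161.6, length(late)), tolerance = 1e-6)
  # detuning 3 % > hw + tolerance: drifts
  expect_lt(lock_score(run, +3), 20)
})

test_that("mean cadence moves with the shift direction inside the basin", {
  run <- make_runner(cadence = 165, hw = 0.0255)
  means <- vapply(c(-2, -1, 0, 1, 2), function(s) {
    tl <- make_timeline(s, ref = 165)
    st <- simulate_steps(run, tl, seed = 1)
    mean_cadence(st, trim_tcl_window(tl$lap_bounds[3], tl$end))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("accelerometer synthesis places one impulse per step", {
  st <- step_series(seq(0.4, 60, by = 0.4))  # 150 steps
  tr <- synth_accel(st, noise_sd = 0, seed = 1, duration = 61)
  az <- tr$az
  # local maxima above the half-amplitude baseline threshold
  n <- length(az)
  peaks <- which(az[2:(n - 1)] > az[1:(n - 2)] & az[2:(n - 1)] >= az[3:n] &
                   az[2:(n - 1)] > 9.81 + 10) + 1
  expect_equal(length(peaks), 150)

  # a step-free interval is pure baseline
  gap <- step_series(c(1, 1.4, 1.8, 30, 30.4))
  tr2 <- synth_accel(gap, noise_sd = 0, seed = 1, duration = 31)
  mid <- tr2$az[tr2$t > 5 & tr2$t < 25]
  expect_equal(mid, rep(9.81, length(mid)))

  expect_identical(synth_accel(st, seed = 9), synth_accel(st, seed = 9))
  expect_error(synth_accel(st, sample_rate = 5, seed = 1),
               class = "runsync_aliasing_error")
})

test_that("a default cohort reproduces the 16 x 12 study grid deterministically", {
  cfg <- cohort_config(seed = 21)
  sim <- simulate_cohort(cfg, traces = FALSE)
  expect_equal(nrow(sim$profiles), 16)
  expect_equal(sum(sim$profiles$gender == "female"), 9)
  expect_equal(sum(sim$profiles$gender == "male"), 7)
  expect_equal(nrow(sim$sessions), 16 * 12)
  expect_equal(sum(sim$sessions$practice), 16)

  # practice sequences have no music; others carry a valid timeline whose
  # reference equals the measured silent-lap cadence
  expect_true(all(vapply(sim$sessions$timeline[sim$sessions$practice],
                         is.null, logical(1))))
  live <- sim$sessions[!sim$sessions$practice, ]
  for (r in sample(seq_len(nrow(live)), 10)) {
    tl <- live$timeline[[r]]
    expect_s3_class(tl, "tempo_timeline")
    expect_equal(tl$reference_bpm, live$reference_bpm[r])
    expect_equal(tl$shifted_bpm,
                 live$reference_bpm[r] * (1 + live$shift_pct[r] / 100))
    # chosen song within 5 % of the reference unless flagged as fallback
    if (!live$song_fallback[r]) {
      tempo <- read_stimulus_library()$tempo_bpm[live$song_id[r]]
      expect_lte(abs(tempo - live$reference_bpm[r]) / live$reference_bpm[r],
                 0.05)
    }
  }
  expect_true(all(live$rpe >= 6 & live$rpe <= 20))

  sim2 <- simulate_cohort(cohort_config(seed = 21), traces = FALSE)
  expect_identical(sim$sessions$steps, sim2$sessions$steps)
  expect_identical(score_cohort(sim, "true"), score_cohort(sim2, "true"))
})

test_that("single-runner cohorts and schedule mismatches are handled", {
  cfg <- cohort_config(n_female = 0, n_male = 1, seed = 2)
  sim <- simulate_cohort(cfg, traces = FALSE)
  expect_equal(nrow(sim$profiles), 1)
  expect_equal(nrow(sim$sessions), 12)

  bad_sched <- make_cohort_schedules(c("X1", "X2"), seed = 1)
  expect_error(simulate_cohort(cfg, schedules = bad_sched, traces = FALSE),
               class = "runsync_validation_error")
})

test_that("stronger female coupling yields higher entrainment across seeds", {
  # cohort defaults encode coupling_mean_female > coupling_mean_male; the
  # per-participant mean entrainment should separate by gender in nearly
  # every simulated cohort
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_cohort(cohort_config(seed = seed), traces = FALSE)
    m <- score_cohort(sim, "true") |>
      dplyr::group_by(participant_id) |>
      dplyr::summarise(e = mean(entrainment_pct)) |>
      dplyr::left_join(sim$profiles, by = "participant_id")
    median(m$e[m$gender == "female"]) > median(m$e[m$gender == "male"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("datasets export to plain CSV files with a manifest", {
  cfg <- cohort_config(n_female = 1, n_male = 0, seed = 6)
  sch <- make_cohort_schedules("P01", seed = 1, shifts = c(0, 2))
  sim <- simulate_cohort(cfg, schedules = sch, traces = TRUE)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_participants, 1)
  expect_true(all(file.exists(file.path(dir, man$files))))
  # traces round-trip into detectable objects
  tr <- read_accel_trace(file.path(dir, grep("accel", man$files, value = TRUE)[2]))
  expect_s3_class(detect_steps(tr), "step_series")
})
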