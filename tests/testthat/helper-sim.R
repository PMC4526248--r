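# shared fixtures, all built in code

# a runner list as simulate_steps() expects; hw = K/(2*pi) in relative units
make_runner <- function(cadence = 160, hw = 0.02, noise = 0) {
  list(preferred_cadence = cadence, coupling = hw * 2 * pi,
       motor_noise_sd = noise)
}

# four equal laps of 72 s (200 m at ~2.78 m/s)
make_timeline <- function(shift_pct, ref = 160, lap_s = 72) {
  tempo_timeline(shift_pct, reference_bpm = ref,
                 lap_durations = rep(lap_s, 4))
}

# entrainment over the trimmed tempo-changed window of a 4 x 72 s sequence
lock_score <- function(runner, shift_pct, ref = runner$preferred_cadence,
                       seed = 1) {
  tl <- make_timeline(shift_pct, ref = ref)
  st <- simulate_steps(runner, tl, seed = seed)
  entrainment_score(st, tl, trim_tcl_window(tl$lap_bounds[3], tl$end))
}

# a small playlist tibble, already score-ordered
make_playlist <- function(tempos, ids = seq_along(tempos)) {
  tibble::tibble(id = ids, bmri2 = rev(seq_along(tempos)) + 20,
                 artist = paste0("a", ids), title = paste0("t", ids),
                 label = "lbl", year = 2000L, tempo_bpm = tempos,
                 in_range = TRUE)
}

# independent permutation generator (recursion differs from the package's)
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
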