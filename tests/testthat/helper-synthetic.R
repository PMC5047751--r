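# Shared synthetic fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_config <- function(...) {
  sim_config(n_cells = 60, n_laps_per_trajectory = 10, n_rotation_events = 10,
             seed = 101L, ...)
}

small_day <- function() {
  memo("small_day", {
    cfg <- small_config(cross_activation_fraction = 0.6)
    pop <- assign_cell_population(cfg)
    list(cfg = cfg, pop = pop,
         track = generate_track_session(pop, cfg),
         pre = generate_box_session(pop, cfg, "pre_box"),
         post = generate_box_session(pop, cfg, "post_box"))
  })
}

# constant-speed triangle-wave "position" on a 200 cm track
triangle_position <- function(n_laps = 5, lap_s = 5, hz = 33) {
  tt <- seq(0, n_laps * 2 * lap_s, by = 1 / hz)
  phase <- (tt %% (2 * lap_s)) / lap_s
  x <- ifelse(phase <= 1, 200 * phase, 200 * (2 - phase))
  data.frame(t_s = tt, x_cm = x, y_cm = 0, hd_deg = 0)
}

# head-direction ramp fixture: hd path given as breakpoints (t, hd)
hd_position <- function(knots_t, knots_hd, hz = 33) {
  tt <- seq(min(knots_t), max(knots_t), by = 1 / hz)
  hd <- approx(knots_t, knots_hd, xout = tt)$y
  data.frame(t_s = tt, x_cm = 12.5 + 6 * cos(hd * pi / 180),
             y_cm = 12.5 + 6 * sin(hd * pi / 180),
             hd_deg = ((hd + 180) %% 360) - 180)
}

# white-noise LFP with optional injected ripple bursts at given envelope SDs
noise_lfp <- function(dur_s = 30, fs = 2000, bursts = NULL, seed = 7) {
  set.seed(seed)
  x <- rnorm(dur_s * fs)
  env <- crossact::ripple_envelope(x, fs)
  m <- mean(env); s <- sd(env)
  tt_all <- seq_along(x) / fs
  if (!is.null(bursts)) {
    for (i in seq_len(nrow(bursts))) {
      idx <- round(bursts$at_s[i] * fs) + seq_len(round(bursts$dur_s[i] * fs))
      x[idx] <- x[idx] + crossact:::calibrate_burst(
        x, idx, tt_all, fs, target_sd = bursts$amp_sd[i],
        m_env = m, s_env = s)
    }
  }
  crossact:::new_lfp(x, fs)
}

# exhaustive permutations of a small vector
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}
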