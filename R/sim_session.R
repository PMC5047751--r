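# Synthetic session generators: track lap-running and box rotation sessions
# with inhomogeneous-Poisson spiking from the assigned tuning, plus a
# ground-truth sidecar used by the tests.

# spikes from a rate function sampled on a regular time grid (thinning-free
# discretised Poisson: counts per inter-sample bin, jittered uniformly)
poisson_spikes_from_rate <- function(t, rate_hz) {
  if (length(t) < 2) return(numeric(0))
  dt <- diff(t)
  lam <- rate_hz[-length(rate_hz)] * dt
  n <- stats::rpois(length(lam), lam)
  if (sum(n) == 0) return(numeric(0))
  idx <- rep(seq_along(n), n)
  sort(t[idx] + stats::runif(length(idx)) * dt[idx])
}

gauss_field_rate <- function(x, center, sigma, peak, baseline) {
  baseline + (peak - baseline) * exp(-(x - center)^2 / (2 * sigma^2))
}

vonmises_rate <- function(hd_deg, pref_deg, kappa, peak, baseline) {
  baseline + (peak - baseline) *
    exp(kappa * (cos((hd_deg - pref_deg) * pi / 180) - 1))
}

new_session <- function(id, condition, spikes, position, config,
                        ground_truth = list(), demo_position = NULL,
                        lfp = NULL) {
  structure(list(id = id, condition = condition, spikes = spikes,
                 position = position, demo_position = demo_position,
                 lfp = lfp,
                 geometry = list(track_length_cm = config$track_length_cm,
                                 box_size_cm = config$box_size_cm,
                                 opening_center_deg = 0),
                 ground_truth = ground_truth),
            class = "ca_session")
}

#' @export
print.ca_session <- function(x, ...) {
  cat(sprintf("Session '%s' (%s): %d spikes from %d cells, %.1f s of tracking%s\n",
              x$id, x$condition, nrow(x$spikes), length(unique(x$spikes$cell_id)),
              diff(range(x$position$t_s)),
              if (!is.null(x$lfp)) sprintf(", LFP at %g Hz", x$lfp$fs) else ""))
  invisible(x)
}

#' Generate a synthetic track (lap-running) session
#'
#' The animal runs `n_laps_per_trajectory` laps in each direction on a
#' `track_length_cm` track at roughly constant speed (per-lap duration
#' jittered +/-10%), pausing 1-3 s at the reward sites between laps. Spikes
#' are inhomogeneous Poisson from each cell's trajectory-specific Gaussian
#' field plus a uniform baseline.
#'
#' @param pop a [assign_cell_population()] result.
#' @param config the same [sim_config()] used for `pop`.
#' @return a `ca_session`; `$ground_truth$laps` holds the true lap intervals.
#' @export
generate_track_session <- function(pop, config) {
  stopifnot(inherits(pop, "cell_population"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 2L), {
    L <- config$track_length_cm
    # piecewise-linear position schedule: pause, lap, pause, lap, ...
    segs <- list(list(dur = 3, x0 = 0, x1 = 0, lap = NA))
    for (i in seq_len(2 * config$n_laps_per_trajectory)) {
      fwd <- (i %% 2) == 1
      segs[[length(segs) + 1]] <- list(
        dur = config$lap_duration_s * stats::runif(1, 0.9, 1.1),
        x0 = if (fwd) 0 else L, x1 = if (fwd) L else 0,
        lap = if (fwd) "A_to_B" else "B_to_A")
      segs[[length(segs) + 1]] <- list(dur = stats::runif(1, 1, 3),
                                       x0 = if (fwd) L else 0,
                                       x1 = if (fwd) L else 0, lap = NA)
    }
    t0 <- 0
    laps <- list()
    knots_t <- 0
    knots_x <- segs[[1]]$x0
    for (s in segs) {
      t1 <- t0 + s$dur
      knots_t <- c(knots_t, t1)
      knots_x <- c(knots_x, s$x1)
      if (!is.na(s$lap))
        laps[[length(laps) + 1]] <- data.frame(trajectory = s$lap,
                                               start_s = t0, end_s = t1)
      t0 <- t1
    }
    laps <- do.call(rbind, laps)
    tt <- seq(0, t0, by = 1 / config$position_hz)
    x <- stats::approx(knots_t, knots_x, xout = tt)$y
    position <- data.frame(t_s = tt, x_cm = x, y_cm = 0, hd_deg = 0)

    lap_of_sample <- rep(NA_character_, length(tt))
    for (i in seq_len(nrow(laps)))
      lap_of_sample[tt >= laps$start_s[i] & tt < laps$end_s[i]] <- laps$trajectory[i]

    spikes <- list()
    for (id in pop$cell_ids) {
      rate <- rep(config$baseline_rate_hz, length(tt))
      fields <- pop$track[pop$track$cell_id == id, , drop = FALSE]
      for (j in seq_len(nrow(fields))) {
        sel <- !is.na(lap_of_sample) & lap_of_sample == fields$trajectory[j]
        rate[sel] <- gauss_field_rate(x[sel], fields$center_cm[j],
                                      fields$width_cm[j], fields$peak_hz[j],
                                      config$baseline_rate_hz)
      }
      st <- poisson_spikes_from_rate(tt, rate)
      if (length(st))
        spikes[[length(spikes) + 1]] <- data.frame(cell_id = id, t_s = st)
    }
    spikes <- if (length(spikes)) do.call(rbind, spikes) else
      data.frame(cell_id = integer(0), t_s = numeric(0))
    spikes <- spikes[order(spikes$t_s), , drop = FALSE]
    rownames(spikes) <- NULL

    new_session("track", "Track", spikes, position, config,
                ground_truth = list(laps = laps))
  })
}

#' Generate a synthetic box (rotation) session
#'
#' The head-direction trace contains `n_rotation_events` full 360-degree
#' rotations (CW or CCW at random, constant angular speed with +/-20%
#' duration jitter), each starting and ending at the opening side (0 deg),
#' interleaved with irregular low-amplitude facing-opening epochs; immobility
#' epochs are placed at both ends of the session so stop detection and ripple
#' placement are exercised. Box-active cells spike as Poisson from their
#' circular tuning during rotations and at baseline otherwise.
#'
#' @inheritParams generate_track_session
#' @param session_id identifier, e.g. `"pre_box"`.
#' @param condition condition label for the session.
#' @return a `ca_session`; `$ground_truth$rotations` holds true event
#'   intervals with direction, `$ground_truth$immobility` the immobile epochs.
#' @export
generate_box_session <- function(pop, config, session_id = "pre_box",
                                 condition = "Trained-demo") {
  stopifnot(inherits(pop, "cell_population"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 3L + sum(utf8ToInt(session_id))), {
    fs <- config$position_hz
    hd <- c()
    tt <- c()
    t0 <- 0
    rotations <- list()
    immobility <- list()
    add_epoch <- function(dur, hd_fun) {
      n <- max(2L, round(dur * fs))
      te <- t0 + seq(0, dur, length.out = n + 1)[-(n + 1)]
      hd <<- c(hd, hd_fun(te - t0))
      tt <<- c(tt, te)
      t0 <<- t0 + dur
    }
    # leading immobility
    immobility[[1]] <- data.frame(start_s = 0, end_s = 25)
    add_epoch(25, function(u) rep(0, length(u)))
    for (i in seq_len(config$n_rotation_events)) {
      # irregular facing-opening epoch
      amp <- stats::runif(1, 15, 35)
      f <- stats::runif(1, 0.3, 0.5)
      ph <- stats::runif(1, 0, 2 * pi)
      add_epoch(stats::runif(1, 2.5, 6),
                function(u) amp * sin(2 * pi * f * u + ph) * sin(pi * u / max(u[length(u)], 1e-9)))
      # full rotation, CW (negative) or CCW (positive)
      dir <- sample(c(-1, 1), 1)
      dur <- config$rotation_duration_s * stats::runif(1, 0.8, 1.2)
      rs <- t0
      add_epoch(dur, function(u) dir * 360 * u / dur)
      rotations[[length(rotations) + 1]] <-
        data.frame(start_s = rs, end_s = t0,
                   direction = if (dir > 0) "CCW" else "CW")
    }
    add_epoch(3, function(u) 20 * sin(2 * pi * 0.4 * u) * sin(pi * u / max(u[length(u)], 1e-9)))
    immobility[[2]] <- data.frame(start_s = t0, end_s = t0 + 25)
    add_epoch(25, function(u) rep(0, length(u)))

    hd <- wrap_deg(hd)
    r <- config$box_size_cm * 0.24          # head moves on a circle in the box
    ctr <- config$box_size_cm / 2
    position <- data.frame(t_s = tt,
                           x_cm = ctr + r * cos(hd * pi / 180),
                           y_cm = ctr + r * sin(hd * pi / 180),
                           hd_deg = hd)
    rotations <- do.call(rbind, rotations)
    immobility <- do.call(rbind, immobility)

    in_rot <- in_intervals(tt, rotations)
    spikes <- list()
    for (id in pop$cell_ids) {
      rate <- rep(config$baseline_rate_hz, length(tt))
      bt <- pop$box[pop$box$cell_id == id, , drop = FALSE]
      if (nrow(bt) == 1)
        rate[in_rot] <- vonmises_rate(hd[in_rot], bt$pref_deg, bt$kappa,
                                      bt$peak_hz, config$baseline_rate_hz)
      st <- poisson_spikes_from_rate(tt, rate)
      if (length(st))
        spikes[[length(spikes) + 1]] <- data.frame(cell_id = id, t_s = st)
    }
    spikes <- if (length(spikes)) do.call(rbind, spikes) else
      data.frame(cell_id = integer(0), t_s = numeric(0))
    spikes <- spikes[order(spikes$t_s), , drop = FALSE]
    rownames(spikes) <- NULL

    new_session(session_id, condition, spikes, position, config,
                ground_truth = list(rotations = rotations,
                                    immobility = immobility))
  })
}
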