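# Band-limited surrogate LFP: theta during movement, ripple bursts during
# immobility. Not a biophysical model -- just enough spectral structure for
# the spectral and ripple-detection stages to be testable.

# Scale a Hann-windowed 150 Hz burst so the *realized* ripple-band envelope
# peak sits at target_sd SDs above the background mean. Phase interference
# with the band-limited background makes a closed-form amplitude unreliable
# at these signal-to-background ratios, so the amplitude is solved by a
# short secant iteration on a local window. Returns the waveform to add.
calibrate_burst <- function(x, idx, tt, fs, target_sd, m_env, s_env) {
  u <- seq(0, 1, length.out = length(idx))
  shape <- sin(2 * pi * 150 * tt[idx]) * (0.5 - 0.5 * cos(2 * pi * u))
  pad <- round(0.25 * fs)
  w0 <- max(1L, idx[1] - pad)
  w1 <- min(length(x), idx[length(idx)] + pad)
  win <- x[w0:w1]
  rel <- idx - w0 + 1
  peak_z <- function(amp) {
    wb <- win
    wb[rel] <- wb[rel] + amp * shape
    (max(ripple_envelope(wb, fs)[rel]) - m_env) / s_env
  }
  a1 <- target_sd * s_env * pi / 2
  z1 <- peak_z(a1)
  a2 <- a1 * target_sd / max(z1, 0.5)
  for (it in 1:3) {
    z2 <- peak_z(a2)
    if (abs(z2 - target_sd) < 0.05 || abs(z2 - z1) < 1e-9) break
    a3 <- a2 + (target_sd - z2) * (a2 - a1) / (z2 - z1)
    a1 <- a2; z1 <- z2
    a2 <- max(a3, 0)
  }
  a2 * shape
}

new_lfp <- function(values, fs, t0 = 0) {
  structure(list(values = values, fs = fs, t0 = t0), class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("LFP trace: %.1f s at %g Hz\n", length(x$values) / x$fs, x$fs))
  invisible(x)
}

#' Generate a surrogate LFP trace for a session
#'
#' During movement epochs (speed >= 2 cm/s) an 8 Hz theta sinusoid rides on
#' coloured background noise; during immobility (speed < 2 cm/s sustained
#' > 3 s) ripple bursts (150 Hz carrier, 80-120 ms Hann envelope, amplitude
#' `ripple_amp_sd` SDs of the session's ripple-band envelope) are inserted at
#' Poisson rate `ripple_rate_hz`.
#'
#' @param position a position series data frame (`t_s`, `x_cm`, `y_cm`,
#'   `hd_deg`).
#' @param config a [sim_config()].
#' @param seed_offset offset added to the config seed stream, so multiple
#'   traces per day stay independent.
#' @return an `lfp_trace`; `attr(, "ripple_truth")` holds the inserted burst
#'   intervals.
#' @export
generate_lfp <- function(position, config, seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 7L + seed_offset), {
    fs <- config$lfp_hz
    t_start <- min(position$t_s)
    t_end <- max(position$t_s)
    n <- ceiling((t_end - t_start) * fs)
    tt <- t_start + seq_len(n) / fs

    # coloured background: AR(1) low-frequency drift + broadband floor
    noise <- as.numeric(stats::filter(stats::rnorm(n), 0.9, method = "recursive")) * 0.3 +
      stats::rnorm(n) * 0.5

    spd <- session_speed(position)
    moving <- stats::approx(position$t_s, as.numeric(spd >= 2), xout = tt,
                            rule = 2)$y > 0.5
    x <- noise + ifelse(moving, 1.5 * sin(2 * pi * 8 * tt), 0)

    # immobility epochs for burst placement
    stops <- detect_stop_periods(position, speed_thresh_cm_s = 2, min_dur_s = 3)

    # calibrate burst amplitude against the ripple-band envelope of the
    # burst-free trace, so "k SD amplitude" matches the detector's z-scale
    env <- ripple_envelope(x, fs)
    m_env <- mean(env); s_env <- stats::sd(env)

    bursts <- list()
    if (config$ripple_rate_hz > 0 && nrow(stops) > 0) {
      for (i in seq_len(nrow(stops))) {
        dur <- stops$end_s[i] - stops$start_s[i]
        k <- stats::rpois(1, config$ripple_rate_hz * dur)
        if (k == 0) next
        starts <- sort(stats::runif(k, stops$start_s[i] + 0.2,
                                    stops$end_s[i] - 0.4))
        # enforce >= 300 ms separation
        keep <- c(TRUE, diff(starts) > 0.3)
        starts <- starts[keep]
        for (s0 in starts) {
          bdur <- stats::runif(1, 0.08, 0.12)
          idx <- which(tt >= s0 & tt < s0 + bdur)
          if (length(idx) < 10) next
          x[idx] <- x[idx] + calibrate_burst(
            x, idx, tt, fs, target_sd = config$ripple_amp_sd,
            m_env = m_env, s_env = s_env)
          bursts[[length(bursts) + 1]] <-
            data.frame(start_s = s0, end_s = s0 + bdur)
        }
      }
    }
    lfp <- new_lfp(x, fs, t0 = t_start)
    attr(lfp, "ripple_truth") <- if (length(bursts)) do.call(rbind, bursts) else
      empty_intervals()
    lfp
  })
}

#' Embed template replay into ripple bursts
#'
#' Inside `n_events` of the session's inserted ripple bursts, the template
#' cells fire one spike each in template order (forward or reversed, chosen
#' per event at random) compressed into the middle 80% of the burst.
#'
#' @param session a `ca_session` whose `$lfp` carries inserted-burst ground
#'   truth (see [generate_lfp()]).
#' @param template a `template_sequence` (see [build_template()]) or an
#'   ordered vector of cell ids (>= 5 cells).
#' @param n_events number of bursts to fill with replay.
#' @param config a [sim_config()] (seed source).
#' @return the session with replay spikes appended and
#'   `$ground_truth$replays` recording each injected event.
#' @export
embed_ripple_replay <- function(session, template, n_events, config) {
  cells <- if (inherits(template, "template_sequence")) template$cell_ids else template
  if (length(cells) < 5)
    stop("replay template must have at least 5 cells", call. = FALSE)
  if (is.null(session$lfp) || is.null(attr(session$lfp, "ripple_truth")))
    stop("session has no LFP with inserted ripple bursts", call. = FALSE)
  bursts <- attr(session$lfp, "ripple_truth")
  if (nrow(bursts) < n_events)
    stop(sprintf("only %d ripple bursts available for %d replay events",
                 nrow(bursts), n_events), call. = FALSE)
  with_seed(derive_seed(config$seed, 11L), {
    pick <- sort(sample(nrow(bursts), n_events))
    replays <- list()
    add <- list()
    for (b in pick) {
      fwd <- stats::runif(1) < 0.5
      ord <- if (fwd) cells else rev(cells)
      s0 <- bursts$start_s[b]; dur <- bursts$end_s[b] - s0
      # keep the replay inside the high-envelope core of the burst so the
      # detected event boundaries (2.5 SD crossings) contain every spike
      times <- s0 + dur * seq(0.3, 0.7, length.out = length(ord))
      add[[length(add) + 1]] <- data.frame(cell_id = ord, t_s = times)
      replays[[length(replays) + 1]] <-
        data.frame(start_s = s0, end_s = bursts$end_s[b],
                   direction = if (fwd) "forward" else "reverse")
    }
    session$spikes <- rbind(session$spikes, do.call(rbind, add))
    session$spikes <- session$spikes[order(session$spikes$t_s), , drop = FALSE]
    rownames(session$spikes) <- NULL
    session$ground_truth$replays <- do.call(rbind, replays)
    session$ground_truth$replay_order <- cells
    session
  })
}
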