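#' Simulation configuration for a synthetic recording day
#'
#' Collects every tunable of the synthetic-session generator. Defaults emulate
#' the study conditions the pipeline was designed for: a per-day census of
#' ~45 simultaneously recorded pyramidal cells of which ~15 are
#' rotation-active, ~22 running-active and ~11 common; a 2-m linear track run
#' in ~19 laps per trajectory of ~5.8 s each; and 25 x 25 cm box sessions
#' with ~19 head-rotation events of ~6.7 s each. Place fields are 1-D
#' Gaussian on the track and von-Mises-shaped over head direction in the
#' box.
#'
#' @param n_cells number of putative pyramidal cells on the day.
#' @param frac_track_active fraction of cells with a place field on the track.
#' @param frac_box_active fraction of cells tuned during box rotation events.
#' @param cross_activation_fraction fraction of track-active cells forced to be
#'   box-active with order-preserving tuning (the injected cross-activation).
#' @param peak_rate_hz in-field peak firing rate (Hz).
#' @param baseline_rate_hz out-of-field rate (Hz) for every non-silent cell.
#' @param field_width_cm Gaussian place-field sigma on the track (cm).
#' @param kappa_box von Mises concentration of box head-direction tuning.
#' @param n_laps_per_trajectory laps generated per running direction.
#' @param n_rotation_events rotation events generated per box session.
#' @param rotation_duration_s mean duration of one full rotation (s).
#' @param lap_duration_s mean duration of one lap (s).
#' @param track_length_cm track length (cm).
#' @param box_size_cm side of the square box (cm).
#' @param position_hz position/head-direction sampling rate (Hz).
#' @param lfp_hz LFP sampling rate (Hz).
#' @param ripple_rate_hz rate of ripple bursts inserted during immobility (1/s).
#' @param ripple_amp_sd ripple burst amplitude in SD of the background noise.
#' @param seed master seed; all generator streams derive from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 45,
                       frac_track_active = 0.5,
                       frac_box_active = 0.33,
                       cross_activation_fraction = 0.5,
                       peak_rate_hz = 10,
                       baseline_rate_hz = 0.2,
                       field_width_cm = 7,
                       kappa_box = 4,
                       n_laps_per_trajectory = 19,
                       n_rotation_events = 19,
                       rotation_duration_s = 6.67,
                       lap_duration_s = 5.8,
                       track_length_cm = 200,
                       box_size_cm = 25,
                       position_hz = 33,
                       lfp_hz = 2000,
                       ripple_rate_hz = 0.3,
                       ripple_amp_sd = 6,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells),
    frac_track_active = frac_track_active,
    frac_box_active = frac_box_active,
    cross_activation_fraction = cross_activation_fraction,
    peak_rate_hz = peak_rate_hz,
    baseline_rate_hz = baseline_rate_hz,
    field_width_cm = field_width_cm,
    kappa_box = kappa_box,
    n_laps_per_trajectory = as.integer(n_laps_per_trajectory),
    n_rotation_events = as.integer(n_rotation_events),
    rotation_duration_s = rotation_duration_s,
    lap_duration_s = lap_duration_s,
    track_length_cm = track_length_cm,
    box_size_cm = box_size_cm,
    position_hz = position_hz,
    lfp_hz = lfp_hz,
    ripple_rate_hz = ripple_rate_hz,
    ripple_amp_sd = ripple_amp_sd,
    seed = as.integer(seed)
  )
  for (p in c("frac_track_active", "frac_box_active", "cross_activation_fraction")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a proportion in [0, 1]", p), call. = FALSE)
  }
  if (cfg$baseline_rate_hz < 0 || cfg$peak_rate_hz <= cfg$baseline_rate_hz)
    stop("need peak_rate_hz > baseline_rate_hz >= 0", call. = FALSE)
  if (cfg$position_hz <= 0 || cfg$lfp_hz <= 0)
    stop("sampling rates must be strictly positive", call. = FALSE)
  if (cfg$n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-day configuration:\n")
  cat(sprintf("  %d cells | track-active %.0f%% | box-active %.0f%% | overlap %.0f%%\n",
              x$n_cells, 100 * x$frac_track_active, 100 * x$frac_box_active,
              100 * x$cross_activation_fraction))
  cat(sprintf("  %d laps/trajectory (%.1f s), %d rotation events (%.1f s), seed %d\n",
              x$n_laps_per_trajectory, x$lap_duration_s,
              x$n_rotation_events, x$rotation_duration_s, x$seed))
  invisible(x)
}
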