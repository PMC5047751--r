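# Shuffle-based tuning statistics: Rayleigh head-direction test,
# rotation-consistency (curve-rotation null), and demonstrator-position
# tuning (within-lap circular spike-shift null).

#' Rayleigh test of head-direction tuning
#'
#' Tests uniformity of the head directions at spike times within rotation
#' events, using the standard finite-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R` the resultant
#' length.
#'
#' @param spikes numeric spike times (s).
#' @param position position series with `hd_deg`.
#' @param events rotation events.
#' @param min_spikes minimum spike count within events required for a test.
#' @return list with `p_value`, `n`, `mean_angle_deg`, `resultant` (mean
#'   resultant length); `p_value` is `NA` when fewer than `min_spikes`.
#' @export
rayleigh_hd_test <- function(spikes, position, events, min_spikes = 10) {
  st <- restrict_times(spikes, events)
  n <- length(st)
  if (n < min_spikes)
    return(list(p_value = NA_real_, n = n, mean_angle_deg = NA_real_,
                resultant = NA_real_))
  a <- sample_at(st, position$t_s, position$hd_deg) * pi / 180
  C <- sum(cos(a)); S <- sum(sin(a))
  R <- sqrt(C^2 + S^2)
  rbar <- R / n
  zstat <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(p_value = min(1, p), n = n,
       mean_angle_deg = (atan2(S, C) * 180 / pi) %% 360, resultant = rbar)
}

# per-event circular rate curves as a bins x events matrix
event_curve_matrix <- function(spikes, position, events, bin_deg = 5,
                               sigma_bins = 2) {
  nb <- round(360 / bin_deg)
  mats <- matrix(NA_real_, nb, nrow(events))
  for (i in seq_len(nrow(events))) {
    cv <- circular_rate_curve(spikes, position, events[i, , drop = FALSE],
                              bin_deg = bin_deg, sigma_bins = sigma_bins)
    mats[, i] <- cv$rate_hz
  }
  mats
}

mean_pairwise_cor <- function(m) {
  keep <- colSums(!is.na(m)) > 0
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2) return(NA_real_)
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  vals <- cm[upper.tri(cm)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Rotation-consistency of a cell across rotation events
#'
#' The statistic is the mean correlation between the per-event circular rate
#' curves over all event pairs. The null rotates every event's curve
#' independently by a random whole-bin angle; the statistic is z-scored
#' against `n_shuffles` such randomisations, and the cell is called
#' rotation-consistent when z > 1.645 (p < 0.05, one-sided).
#'
#' @param spikes numeric spike times (s).
#' @param position position series with `hd_deg`.
#' @param events rotation events; only events in which the cell spiked enter
#'   the pairwise statistic.
#' @param n_shuffles number of curve-rotation randomisations.
#' @param seed RNG seed for the shuffles.
#' @param bin_deg,sigma_bins curve binning.
#' @return list: `statistic` (mean cross-event correlation), `shuffle_mean`,
#'   `shuffle_sd`, `z`, `significant`, `n_events_active`, and `reason` when
#'   undefined.
#' @export
rotation_consistency <- function(spikes, position, events, n_shuffles = 1000,
                                 seed = 1L, bin_deg = 5, sigma_bins = 2) {
  undef <- function(why, nact) list(statistic = NA_real_,
                                    shuffle_mean = NA_real_,
                                    shuffle_sd = NA_real_, z = NA_real_,
                                    significant = FALSE,
                                    n_events_active = nact, reason = why)
  if (is.null(events) || nrow(events) < 2)
    return(undef("fewer than 2 rotation events", 0L))
  nspk <- vapply(seq_len(nrow(events)), function(i) {
    sum(spikes >= events$start_s[i] & spikes < events$end_s[i])
  }, numeric(1))
  active <- nspk >= 1
  if (sum(active) < 2)
    return(undef("cell active in fewer than 2 events", sum(active)))
  m <- event_curve_matrix(spikes, position, events[active, , drop = FALSE],
                          bin_deg = bin_deg, sigma_bins = sigma_bins)
  actual <- mean_pairwise_cor(m)
  if (is.na(actual)) return(undef("degenerate event curves", sum(active)))
  nb <- nrow(m)
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b) {
      shifts <- sample.int(nb, ncol(m), replace = TRUE) - 1L
      ms <- m
      for (j in seq_len(ncol(m)))
        if (shifts[j] > 0)
          ms[, j] <- m[c((shifts[j] + 1):nb, 1:shifts[j]), j]
      mean_pairwise_cor(ms)
    }, numeric(1))
  })
  mu <- mean(null, na.rm = TRUE)
  sdv <- stats::sd(null, na.rm = TRUE)
  z <- if (isTRUE(sdv > 0)) (actual - mu) / sdv else NA_real_
  list(statistic = actual, shuffle_mean = mu, shuffle_sd = sdv, z = z,
       significant = isTRUE(z > 1.645), n_events_active = sum(active),
       reason = NULL)
}

#' Tuning of an observer cell to the demonstrator's track position
#'
#' Computes the observer cell's spatial information (and optionally lap
#' consistency) against the demonstrator's position over the demonstrator's
#' laps, and z-scores each statistic against a null obtained by circularly
#' shifting the cell's spike train independently within each lap,
#' `n_shuffles` times. Significance at z >= 1.645.
#'
#' @param spikes observer cell spike times (s).
#' @param demo_position demonstrator position series (`t_s`, `x_cm`).
#' @param demo_laps demonstrator lap events on one trajectory.
#' @param n_shuffles number of within-lap circular shifts.
#' @param seed RNG seed.
#' @param statistics which statistics to compute: `"si"`, `"lap"` or both.
#' @param track_length_cm,end_zone_cm,bin_cm,sigma_bins curve binning.
#' @return list with `si`, `z_si`, `lap_consistency`, `z_lap`, shuffle
#'   summaries, and `n_spikes`.
#' @export
demo_position_tuning <- function(spikes, demo_position, demo_laps,
                                 n_shuffles = 1000, seed = 1L,
                                 statistics = c("si", "lap"),
                                 track_length_cm = 200, end_zone_cm = 10,
                                 bin_cm = 2, sigma_bins = 2) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  nlap <- nrow(demo_laps)
  edges <- seq(end_zone_cm, track_length_cm - end_zone_cm, by = bin_cm)
  nb <- length(edges) - 1

  # per-lap occupancy of the demonstrator (fixed across shuffles)
  dt <- stats::median(diff(demo_position$t_s))
  occ_lap <- matrix(0, nb, nlap)
  for (i in seq_len(nlap)) {
    sel <- demo_position$t_s >= demo_laps$start_s[i] &
      demo_position$t_s < demo_laps$end_s[i] &
      demo_position$x_cm >= edges[1] & demo_position$x_cm < edges[nb + 1]
    if (any(sel))
      occ_lap[, i] <- tabulate(pmin(nb, floor((demo_position$x_cm[sel] - edges[1]) / bin_cm) + 1), nb) * dt
  }
  occ <- rowSums(occ_lap)
  occ_sm <- smooth_gaussian(occ, sigma_bins)
  occ_lap_sm <- apply(occ_lap, 2, smooth_gaussian, sigma_bins = sigma_bins)

  # assign spikes to laps
  lap_of <- rep(NA_integer_, length(spikes))
  for (i in seq_len(nlap))
    lap_of[spikes >= demo_laps$start_s[i] & spikes < demo_laps$end_s[i]] <- i
  keep <- !is.na(lap_of)
  st <- spikes[keep]; lp <- lap_of[keep]
  ns <- length(st)

  curve_stats <- function(times, laps_of_spike) {
    x <- sample_at(times, demo_position$t_s, demo_position$x_cm)
    inb <- x >= edges[1] & x < edges[nb + 1]
    bins <- pmin(nb, floor((x[inb] - edges[1]) / bin_cm) + 1)
    cnt <- tabulate(bins, nb)
    rate <- ifelse(occ_sm > 0, smooth_gaussian(cnt, sigma_bins) / occ_sm, NA)
    si <- spatial_information(rate, occ)
    lc <- NA_real_
    if ("lap" %in% statistics && nlap >= 2) {
      lap_of_binned <- laps_of_spike[inb]
      lap_curves <- lapply(seq_len(nlap), function(i) {
        ci <- tabulate(bins[lap_of_binned == i], nb)
        data.frame(rate_hz = ifelse(occ_lap_sm[, i] > 0,
                                    smooth_gaussian(ci, sigma_bins) / occ_lap_sm[, i], NA),
                   occupancy_s = occ_lap[, i])
      })
      active_laps <- vapply(seq_len(nlap), function(i) sum(laps_of_spike == i) > 0, logical(1))
      lc <- if (sum(active_laps) >= 2)
        lap_consistency(lap_curves[active_laps]) else NA_real_
    }
    c(si = si, lc = lc)
  }

  starts <- demo_laps$start_s[lp]
  durs <- (demo_laps$end_s - demo_laps$start_s)[lp]
  actual <- curve_stats(st, lp)
  null <- with_seed(derive_seed(seed, 13L), {
    sapply(seq_len(n_shuffles), function(b) {
      delta <- stats::runif(nlap, 0, demo_laps$end_s - demo_laps$start_s)
      ts <- starts + ((st - starts + delta[lp]) %% durs)
      curve_stats(ts, lp)
    })
  })
  zscore <- function(a, v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || stats::sd(v) == 0 || !is.finite(a)) return(NA_real_)
    (a - mean(v)) / stats::sd(v)
  }
  list(si = unname(actual["si"]),
       z_si = zscore(actual["si"], null["si", ]),
       lap_consistency = unname(actual["lc"]),
       z_lap = if ("lap" %in% statistics) zscore(actual["lc"], null["lc", ]) else NA_real_,
       n_spikes = ns, n_shuffles = n_shuffles)
}
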