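# Firing-rate curves and maps with the pipeline's canonical binning: 2 cm
# spatial bins (10 cm reward zones excluded), 72 x 5-degree arches, 1 x 1 cm
# box grids; all smoothed with a Gaussian kernel of sigma = 2 bins.

# nearest-sample lookup of a position column at spike times
sample_at <- function(t_query, t_grid, values) {
  idx <- findInterval(t_query, t_grid, all.inside = TRUE)
  # snap to nearer of the two bracketing samples
  idx2 <- idx + (t_query - t_grid[idx] > t_grid[pmin(idx + 1, length(t_grid))] - t_query)
  values[pmin(idx2, length(values))]
}

restrict_times <- function(t, iv) t[in_intervals(t, iv)]

#' Linear firing-rate curve on a track trajectory
#'
#' Spike counts and occupancy per 2 cm bin over the supplied laps (stop
#' periods excluded), reward end zones excluded, rate = smoothed counts /
#' smoothed occupancy with a Gaussian kernel of sigma = 2 bins.
#'
#' @param spikes numeric spike times (s) of one cell.
#' @param position position series; `x_cm` is the linearised coordinate.
#' @param laps lap events, all on one trajectory (`start_s`, `end_s`).
#' @param stops stop periods to exclude (may be `NULL`).
#' @param track_length_cm,end_zone_cm,bin_cm,sigma_bins binning geometry.
#' @return a `rate_curve` data frame: `bin_cm` (centres), `rate_hz`,
#'   `occupancy_s`, `count` (raw spike count per bin, before smoothing).
#' @export
linear_rate_curve <- function(spikes, position, laps, stops = NULL,
                              track_length_cm = 200, end_zone_cm = 10,
                              bin_cm = 2, sigma_bins = 2) {
  iv <- subtract_intervals(laps, stops)
  edges <- seq(end_zone_cm, track_length_cm - end_zone_cm, by = bin_cm)
  centers <- edges[-length(edges)] + bin_cm / 2
  nb <- length(centers)
  dt <- stats::median(diff(position$t_s))
  sel <- in_intervals(position$t_s, iv) &
    position$x_cm >= edges[1] & position$x_cm < edges[length(edges)]
  occ <- numeric(nb)
  if (any(sel)) {
    b <- pmin(nb, floor((position$x_cm[sel] - edges[1]) / bin_cm) + 1)
    occ <- tabulate(b, nb) * dt
  }
  if (sum(occ) == 0) stop("zero occupancy over all spatial bins", call. = FALSE)
  st <- restrict_times(spikes, iv)
  cnt <- numeric(nb)
  if (length(st)) {
    sx <- sample_at(st, position$t_s, position$x_cm)
    inb <- sx >= edges[1] & sx < edges[length(edges)]
    if (any(inb))
      cnt <- tabulate(pmin(nb, floor((sx[inb] - edges[1]) / bin_cm) + 1), nb)
  }
  occ_s <- smooth_gaussian(occ, sigma_bins)
  cnt_s <- smooth_gaussian(cnt, sigma_bins)
  rate <- ifelse(occ_s > 0, cnt_s / occ_s, NA_real_)
  structure(data.frame(bin_cm = centers, rate_hz = rate, occupancy_s = occ,
                       count = cnt),
            class = c("rate_curve", "data.frame"))
}

#' Circular firing-rate curve over rotation events
#'
#' 72 five-degree head-direction arches tiling [0, 360); smoothing wraps
#' circularly.
#'
#' @param spikes numeric spike times (s) of one cell.
#' @param position position series with `hd_deg`.
#' @param events rotation events (`start_s`, `end_s`).
#' @param bin_deg,sigma_bins binning.
#' @return a `circular_rate_curve` data frame: `bin_deg` (centres in
#'   [0, 360)), `rate_hz`, `occupancy_s`, `count`.
#' @export
circular_rate_curve <- function(spikes, position, events, bin_deg = 5,
                                sigma_bins = 2) {
  nb <- round(360 / bin_deg)
  centers <- (seq_len(nb) - 0.5) * bin_deg
  dt <- stats::median(diff(position$t_s))
  sel <- in_intervals(position$t_s, events) & !is.na(position$hd_deg)
  occ <- numeric(nb)
  if (any(sel)) {
    b <- floor((position$hd_deg[sel] %% 360) / bin_deg) + 1
    occ <- tabulate(pmin(b, nb), nb) * dt
  }
  st <- restrict_times(spikes, events)
  cnt <- numeric(nb)
  if (length(st)) {
    shd <- sample_at(st, position$t_s, position$hd_deg) %% 360
    cnt <- tabulate(pmin(floor(shd / bin_deg) + 1, nb), nb)
  }
  occ_s <- smooth_gaussian(occ, sigma_bins, circular = TRUE)
  cnt_s <- smooth_gaussian(cnt, sigma_bins, circular = TRUE)
  rate <- ifelse(occ_s > 0, cnt_s / occ_s, NA_real_)
  structure(data.frame(bin_deg = centers, rate_hz = rate, occupancy_s = occ,
                       count = cnt),
            class = c("circular_rate_curve", "data.frame"))
}

#' Two-dimensional firing-rate map in the box
#'
#' 1 x 1 cm grid over the box, smoothed with sigma = 2 bins; bins with less
#' than `min_occupancy_s` of (unsmoothed) occupancy are undefined (NA).
#'
#' @param spikes numeric spike times (s).
#' @param position position series (`x_cm`, `y_cm`).
#' @param events intervals to include.
#' @param box_size_cm,bin_cm,sigma_bins,min_occupancy_s geometry.
#' @return list with `rate` (matrix, x by y), `occupancy_s`, `count`,
#'   `bin_centers_cm`.
#' @export
rate_map_2d <- function(spikes, position, events, box_size_cm = 25,
                        bin_cm = 1, sigma_bins = 2, min_occupancy_s = 0.1) {
  nb <- ceiling(box_size_cm / bin_cm)
  dt <- stats::median(diff(position$t_s))
  sel <- in_intervals(position$t_s, events)
  bx <- pmin(pmax(floor(position$x_cm[sel] / bin_cm) + 1, 1), nb)
  by <- pmin(pmax(floor(position$y_cm[sel] / bin_cm) + 1, 1), nb)
  occ <- matrix(tabulate(bx + nb * (by - 1), nb * nb) * dt, nb, nb)
  st <- restrict_times(spikes, events)
  cnt <- matrix(0, nb, nb)
  if (length(st)) {
    sx <- pmin(pmax(floor(sample_at(st, position$t_s, position$x_cm) / bin_cm) + 1, 1), nb)
    sy <- pmin(pmax(floor(sample_at(st, position$t_s, position$y_cm) / bin_cm) + 1, 1), nb)
    cnt <- matrix(tabulate(sx + nb * (sy - 1), nb * nb), nb, nb)
  }
  # separable 2-D Gaussian smoothing, edge-renormalised
  sm <- function(m) t(apply(apply(m, 2, smooth_gaussian, sigma_bins = sigma_bins),
                            1, smooth_gaussian, sigma_bins = sigma_bins))
  occ_s <- sm(occ)
  cnt_s <- sm(cnt)
  rate <- ifelse(occ_s > 0 & occ >= min_occupancy_s, cnt_s / occ_s, NA_real_)
  list(rate = rate, occupancy_s = occ, count = cnt,
       bin_centers_cm = (seq_len(nb) - 0.5) * bin_cm)
}

#' Spatial information of a rate curve (bits per spike)
#'
#' Skaggs information `sum_i p_i (r_i/rbar) log2(r_i/rbar)` over occupied
#' bins, with `p_i` the occupancy fraction and `rbar` the occupancy-weighted
#' mean rate.
#'
#' @param rates rate per bin (Hz), or a `rate_curve`.
#' @param occupancy_s occupancy per bin (s); ignored when `rates` is a
#'   `rate_curve`.
#' @param min_occupancy_s bins below this occupancy are excluded.
#' @return spatial information in bits per spike (`NA` if the mean rate is 0).
#' @export
spatial_information <- function(rates, occupancy_s = NULL,
                                min_occupancy_s = 0.1) {
  if (inherits(rates, "rate_curve") || is.data.frame(rates)) {
    occupancy_s <- rates$occupancy_s
    rates <- rates$rate_hz
  }
  keep <- !is.na(rates) & occupancy_s >= min_occupancy_s
  r <- rates[keep]
  p <- occupancy_s[keep] / sum(occupancy_s[keep])
  rbar <- sum(p * r)
  if (!is.finite(rbar) || rbar <= 0) return(NA_real_)
  pos <- r > 0
  sum(p[pos] * (r[pos] / rbar) * log2(r[pos] / rbar))
}

#' Lap consistency: mean pairwise correlation of per-lap rate curves
#'
#' @param per_lap_curves list of `rate_curve`s (or numeric rate vectors on a
#'   common binning), one per lap.
#' @param min_occupancy_s bins below this occupancy in either lap are
#'   excluded from that pair's correlation.
#' @return mean Pearson correlation over all lap pairs (`NA` if no pair has
#'   enough joint variation).
#' @export
lap_consistency <- function(per_lap_curves, min_occupancy_s = 0.1) {
  get_rate <- function(cv) if (is.data.frame(cv)) cv$rate_hz else cv
  get_occ <- function(cv) if (is.data.frame(cv)) cv$occupancy_s else
    rep(Inf, length(cv))
  n <- length(per_lap_curves)
  if (n < 2) return(NA_real_)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ri <- get_rate(per_lap_curves[[i]]); rj <- get_rate(per_lap_curves[[j]])
    keep <- !is.na(ri) & !is.na(rj) &
      get_occ(per_lap_curves[[i]]) >= min_occupancy_s &
      get_occ(per_lap_curves[[j]]) >= min_occupancy_s
    if (sum(keep) >= 3 && stats::sd(ri[keep]) > 0 && stats::sd(rj[keep]) > 0)
      vals <- c(vals, stats::cor(ri[keep], rj[keep]))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
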