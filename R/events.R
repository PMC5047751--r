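# Behavioural event detection: rotation events, laps, stop periods, and a
# behaviour summary. All intervals are half-open [start_s, end_s).

#' Instantaneous speed of a position series
#'
#' Central difference of (x, y), smoothed over a 0.5 s boxcar.
#' @param position data frame with `t_s`, `x_cm`, `y_cm`.
#' @return speed in cm/s, one value per sample.
#' @export
session_speed <- function(position) {
  t <- position$t_s
  n <- length(t)
  if (n < 3) return(rep(0, n))
  vx <- c(NA, (position$x_cm[3:n] - position$x_cm[1:(n - 2)]) /
            (t[3:n] - t[1:(n - 2)]), NA)
  vy <- c(NA, (position$y_cm[3:n] - position$y_cm[1:(n - 2)]) /
            (t[3:n] - t[1:(n - 2)]), NA)
  spd <- sqrt(vx^2 + vy^2)
  spd[1] <- spd[2]; spd[n] <- spd[n - 1]
  w <- max(1L, round(0.5 / stats::median(diff(t))))
  if (w > 1) {
    k <- rep(1 / w, w)
    sm <- as.numeric(stats::filter(spd, k, sides = 2))
    na <- is.na(sm)
    sm[na] <- spd[na]          # raw central difference at the edges
    spd <- sm
  }
  spd
}

#' Detect stop (immobility) periods
#'
#' Maximal intervals with smoothed speed below `speed_thresh_cm_s` lasting
#' longer than `min_dur_s`.
#'
#' @param position position series data frame.
#' @param speed_thresh_cm_s immobility speed cutoff (cm/s).
#' @param min_dur_s minimum duration (s); intervals of exactly this length or
#'   shorter are not stops.
#' @return data frame of intervals (`start_s`, `end_s`).
#' @export
detect_stop_periods <- function(position, speed_thresh_cm_s = 2, min_dur_s = 3) {
  if (nrow(position) < 3) return(empty_intervals())
  spd <- session_speed(position)
  slow <- spd < speed_thresh_cm_s
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- data.frame(start_s = position$t_s[starts[r$values]],
                   end_s = position$t_s[pmin(ends[r$values] + 1, nrow(position))])
  iv <- iv[iv$end_s - iv$start_s > min_dur_s, , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Detect rotation events from head direction
#'
#' A rotation event starts with the head on the opening side (head direction
#' within +/-45 degrees of `opening_center_deg`), accumulates at least 180
#' degrees of net unwrapped rotation, and ends with the head back on the
#' opening side. Direction is CW/CCW by the sign of the net rotation.
#' Excursions that return to the opening side having spanned less than 180
#' degrees are not events.
#'
#' @param position position series with `hd_deg` defined for >= 95% of
#'   samples.
#' @param opening_center_deg direction of the centre of the opening side; all
#'   head directions are taken relative to it.
#' @param min_span_deg minimum net rotation span (degrees).
#' @param zone_halfwidth_deg half-width of the opening zone (degrees).
#' @param exclude intervals (data frame `start_s`, `end_s`) flagged as
#'   irregular; events overlapping them are dropped.
#' @return data frame of events: `start_s`, `end_s`, `direction`, `span_deg`.
#' @export
detect_rotation_events <- function(position, opening_center_deg = 0,
                                   min_span_deg = 180,
                                   zone_halfwidth_deg = 45,
                                   exclude = NULL) {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    direction = character(0), span_deg = numeric(0))
  hd <- position$hd_deg
  ok <- !is.na(hd)
  if (nrow(position) == 0 || mean(ok) < 0.95) {
    warning("head direction undefined or too sparse; no rotation events")
    return(out)
  }
  t <- position$t_s[ok]
  u <- unwrap_deg(wrap_deg(hd[ok] - opening_center_deg))
  inzone <- abs(wrap_deg(u)) <= zone_halfwidth_deg
  n <- length(u)
  tol <- 30                            # tolerated counter-rotation (deg)
  # anchors extend at most this far into the opening-side runs; at typical
  # rotation speeds the zone (+/-45 deg) is traversed in well under 2 s
  max_walk <- max(1L, round(2 / max(stats::median(diff(t)), 1e-6)))
  i <- 1
  prev_end <- 0
  while (i < n) {
    if (inzone[i] && !inzone[i + 1]) {
      exit <- i
      j <- i + 1
      while (j <= n && !inzone[j]) j <- j + 1
      if (j > n) break
      dir <- sign(u[i + 1] - u[i])     # rotation sense at zone exit
      if (dir == 0) dir <- sign(u[j] - u[exit])
      # start anchor: walk back through the opening-side run to the onset of
      # the final monotone (within tol) rotation leading to the exit, never
      # crossing into the previous event
      a <- exit
      best <- exit
      while (a > prev_end + 1 && inzone[a - 1] && (exit - a) < max_walk) {
        a <- a - 1
        if (dir * (u[best] - u[a]) >= 0) best <- a
        if (dir * (u[a] - u[best]) > tol) break
      }
      start_i <- best
      # end anchor: walk forward through the opening-side run to the farthest
      # point of continued rotation
      b <- j
      beste <- j
      while (b < n && inzone[b + 1] && (b - j) < max_walk) {
        b <- b + 1
        if (dir * (u[b] - u[beste]) >= 0) beste <- b
        if (dir * (u[beste] - u[b]) > tol) break
      }
      end_i <- beste
      span <- u[end_i] - u[start_i]
      if (abs(span) >= min_span_deg) {
        out <- rbind(out, data.frame(
          start_s = t[start_i], end_s = t[end_i],
          direction = if (span < 0) "CW" else "CCW",
          span_deg = abs(span)))
        prev_end <- end_i
      }
      i <- max(j, end_i)
    } else i <- i + 1
  }
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(out) > 0) {
    drop <- vapply(seq_len(nrow(out)), function(k) {
      any(out$start_s[k] < exclude$end_s & out$end_s[k] > exclude$start_s)
    }, logical(1))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Detect lap-running events on a linear track
#'
#' One lap per complete end-to-end traversal: the animal leaves one end zone
#' and reaches the opposite end zone without returning. Turn-arounds
#' mid-track yield no lap.
#'
#' @param position position series; `x_cm` is the linearised coordinate.
#' @param track_length_cm track length (cm).
#' @param end_zone_cm length of the reward end zones at both ends (cm).
#' @return data frame of laps: `trajectory` (`A_to_B` = increasing x),
#'   `start_s`, `end_s`.
#' @export
detect_lap_events <- function(position, track_length_cm = 200, end_zone_cm = 10) {
  x <- position$x_cm
  t <- position$t_s
  zone <- function(xx) ifelse(xx <= end_zone_cm, "A",
                              ifelse(xx >= track_length_cm - end_zone_cm, "B", NA))
  z <- zone(x)
  out <- data.frame(trajectory = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  last_zone <- NA
  last_zone_idx <- NA
  for (i in seq_along(x)) {
    if (!is.na(z[i])) {
      if (!is.na(last_zone) && z[i] != last_zone) {
        out <- rbind(out, data.frame(
          trajectory = if (last_zone == "A") "A_to_B" else "B_to_A",
          start_s = t[last_zone_idx], end_s = t[i]))
      }
      last_zone <- z[i]
      last_zone_idx <- i
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarise box behaviour
#'
#' @param position position series for the box session.
#' @param rotations rotation events (from [detect_rotation_events()]).
#' @param opening_center_deg direction of the opening centre.
#' @return a one-row data frame: `pct_time_facing_opening`,
#'   `n_rotation_events`, `mean_rotation_duration_s`, `mean_speed_cm_s`.
#' @export
behavior_summary <- function(position, rotations, opening_center_deg = 0) {
  facing <- abs(wrap_deg(position$hd_deg - opening_center_deg)) <= 45
  data.frame(
    pct_time_facing_opening = 100 * mean(facing, na.rm = TRUE),
    n_rotation_events = nrow(rotations),
    mean_rotation_duration_s = if (nrow(rotations)) {
      mean(rotations$end_s - rotations$start_s)
    } else NA_real_,
    mean_speed_cm_s = mean(session_speed(position)))
}
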