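# Common-cell accounting: active-cell classification (0.5-6 Hz in events),
# actual vs chance common-cell proportions, and the proportion difference
# index (PDI) per box-session x trajectory pairing.

#' Split a session spike table into per-cell spike-time vectors
#' @param spikes data frame with `cell_id`, `t_s`.
#' @param cell_ids cells to include (default: all present).
#' @return named list of numeric vectors.
#' @export
split_spikes <- function(spikes, cell_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- sort(unique(spikes$cell_id))
  out <- lapply(cell_ids, function(id) spikes$t_s[spikes$cell_id == id])
  names(out) <- as.character(cell_ids)
  out
}

#' Mean firing rate of each cell within events
#'
#' Rates are computed over the event time with stop periods excluded.
#'
#' @param spikes_by_cell named list of spike-time vectors (see
#'   [split_spikes()]).
#' @param events intervals (`start_s`, `end_s`).
#' @param stops stop periods excluded from the event time (may be `NULL`).
#' @return data frame: `cell_id`, `rate_hz`.
#' @export
event_firing_rates <- function(spikes_by_cell, events, stops = NULL) {
  iv <- subtract_intervals(events, stops)
  dur <- interval_duration(iv)
  if (dur <= 0) stop("events have zero duration after stop exclusion",
                     call. = FALSE)
  rate <- vapply(spikes_by_cell,
                 function(st) sum(in_intervals(st, iv)) / dur, numeric(1))
  data.frame(cell_id = names(spikes_by_cell), rate_hz = unname(rate))
}

#' Classify cells as active in an environment
#'
#' A putative pyramidal cell is active if its mean firing rate within the
#' supplied events (stop periods excluded) lies in `rate_range` -- the
#' 0.5-6 Hz pyramidal-cell activity band. Cells above the upper bound are in
#' the putative-interneuron regime and excluded.
#'
#' @inheritParams event_firing_rates
#' @param rate_range admissible mean-rate range (Hz).
#' @return data frame: `cell_id`, `rate_hz`, `active`.
#' @export
classify_active_cells <- function(spikes_by_cell, events, stops = NULL,
                                  rate_range = c(0.5, 6)) {
  r <- event_firing_rates(spikes_by_cell, events, stops)
  r$active <- r$rate_hz >= rate_range[1] & r$rate_hz <= rate_range[2]
  r
}

#' Day-level cell classification
#'
#' Pools rotation events across box sessions and lap events per trajectory,
#' and labels each cell `common` (active in rotations and on >= 1 running
#' trajectory), `rotation_only`, `running_only`, or `inactive`.
#'
#' @param spikes_box,spikes_track per-cell spike lists for the box and track
#'   sessions (same cell ids).
#' @param rotations pooled rotation events (Pre- and Post-box combined).
#' @param laps_by_trajectory named list of lap-event data frames, one per
#'   trajectory.
#' @param stops_box,stops_track stop periods per environment.
#' @param rate_range activity band (Hz).
#' @return data frame: `cell_id`, `box_rate_hz`, `box_active`,
#'   `track_active` (any trajectory), per-trajectory activity columns, and
#'   `label`.
#' @export
classify_day_cells <- function(spikes_box, spikes_track, rotations,
                               laps_by_trajectory, stops_box = NULL,
                               stops_track = NULL, rate_range = c(0.5, 6)) {
  box <- classify_active_cells(spikes_box, rotations, stops_box, rate_range)
  out <- data.frame(cell_id = box$cell_id, box_rate_hz = box$rate_hz,
                    box_active = box$active)
  track_any <- rep(FALSE, nrow(out))
  for (tr in names(laps_by_trajectory)) {
    cl <- classify_active_cells(spikes_track, laps_by_trajectory[[tr]],
                                stops_track, rate_range)
    out[[paste0("active_", tr)]] <- cl$active
    track_any <- track_any | cl$active
  }
  out$track_active <- track_any
  out$label <- ifelse(out$box_active & out$track_active, "common",
               ifelse(out$box_active, "rotation_only",
               ifelse(out$track_active, "running_only", "inactive")))
  out
}

#' Day- or study-level classification summary
#'
#' Collapses active-cell classification counts into the standard accounting:
#' total rotation-active and running-active cells and the percentage of each
#' that are common cells.
#'
#' @param x either the data frame returned by [classify_day_cells()], or a
#'   count of rotation-only cells (with `n_running_only` and `n_common`).
#' @param n_running_only,n_common counts when `x` is a count.
#' @return one-row data frame: `n_rotation_only`, `n_running_only`,
#'   `n_common`, `n_rotation_active`, `n_running_active`,
#'   `pct_rotation_active_common`, `pct_running_active_common`.
#' @export
classification_summary <- function(x, n_running_only = NULL, n_common = NULL) {
  if (is.data.frame(x)) {
    n_rot <- sum(x$label == "rotation_only")
    n_run <- sum(x$label == "running_only")
    n_com <- sum(x$label == "common")
  } else {
    n_rot <- x; n_run <- n_running_only; n_com <- n_common
  }
  data.frame(
    n_rotation_only = n_rot, n_running_only = n_run, n_common = n_com,
    n_rotation_active = n_rot + n_com, n_running_active = n_run + n_com,
    pct_rotation_active_common = 100 * n_com / (n_rot + n_com),
    pct_running_active_common = 100 * n_com / (n_run + n_com))
}

#' Percentage of a cell sample passing a significance criterion
#'
#' Shared bookkeeping for "x% of cells were significantly tuned" style
#' summaries: either from a vector of p-values (or logical flags) or from
#' printed counts.
#'
#' @param x p-values, logical flags, or a count of significant cells.
#' @param n_total total tested cells when `x` is a count.
#' @param alpha significance level applied when `x` holds p-values.
#' @return percentage in [0, 100].
#' @export
percent_significant <- function(x, n_total = NULL, alpha = 0.05) {
  if (is.logical(x)) return(100 * mean(x, na.rm = TRUE))
  if (!is.null(n_total)) return(100 * x / n_total)
  100 * mean(x < alpha, na.rm = TRUE)
}

#' Counts entering a common-cell pairing
#' @param N total putative pyramidal cells on the day.
#' @param n_t cells active on the track trajectory.
#' @param n_b cells active in the box session.
#' @param n_common cells active in both.
#' @return validated list of class `pairing_counts`.
#' @export
pairing_counts <- function(N, n_t, n_b, n_common) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (n_common > min(n_t, n_b) || min(n_t, n_b) < 0 || max(n_t, n_b) > N)
    stop("need 0 <= n_common <= min(n_t, n_b) <= N", call. = FALSE)
  structure(list(N = N, n_t = n_t, n_b = n_b, n_common = n_common),
            class = "pairing_counts")
}

#' Chance proportion of common cells
#'
#' Expected common-cell proportion under independent random activation:
#' `(n_t / N) * (n_b / N)`.
#' @param counts a [pairing_counts()].
#' @return proportion in [0, 1].
#' @export
chance_proportion <- function(counts) {
  (counts$n_t / counts$N) * (counts$n_b / counts$N)
}

#' Actual proportion of common cells
#'
#' Proportion of common cells among all cells active on the track
#' trajectory: `n_common / n_t`.
#' @param counts a [pairing_counts()].
#' @return proportion in [0, 1] (`NA` when `n_t` is 0).
#' @export
actual_proportion <- function(counts) {
  if (counts$n_t == 0) return(NA_real_)
  counts$n_common / counts$n_t
}

#' Proportion difference index (PDI)
#'
#' `(p_act - p_chance) / (p_act + p_chance)`, bounded in [-1, 1]; measures
#' the strength of cross-activation relative to independent remapping.
#' @param p_act actual proportion.
#' @param p_chance chance proportion.
#' @return PDI (`NA` when both proportions are 0).
#' @export
proportion_difference_index <- function(p_act, p_chance) {
  if (is.na(p_act) || is.na(p_chance) || p_act + p_chance <= 0)
    return(NA_real_)
  (p_act - p_chance) / (p_act + p_chance)
}

#' PDI table for all box-session x trajectory pairings of a day
#'
#' The actual proportion entering the PDI is the proportion of common cells
#' among all `N` cells of the day (`n_common / N`), which is the quantity
#' whose expectation under independent random activation equals the chance
#' proportion `(n_t / N) (n_b / N)`; the descriptive proportion of common
#' cells among trajectory-active cells (`n_common / n_t`,
#' [actual_proportion()]) is reported alongside as `p_act_track`.
#'
#' @param N total putative pyramidal cells on the day.
#' @param box_active named list: for each box session, the ids of cells
#'   active in that session's rotation events.
#' @param track_active named list: for each trajectory, the ids of cells
#'   active in its lap events.
#' @return data frame with one row per pairing: `session`, `trajectory`,
#'   `N`, `n_t`, `n_b`, `n_common`, `p_act`, `p_chance`, `p_act_track`,
#'   `pdi`.
#' @export
pairing_analysis <- function(N, box_active, track_active) {
  rows <- list()
  for (s in names(box_active)) for (tr in names(track_active)) {
    cnt <- pairing_counts(N, length(track_active[[tr]]),
                          length(box_active[[s]]),
                          length(intersect(box_active[[s]], track_active[[tr]])))
    pa <- cnt$n_common / cnt$N
    pc <- chance_proportion(cnt)
    rows[[length(rows) + 1]] <- data.frame(
      session = s, trajectory = tr, N = N, n_t = cnt$n_t, n_b = cnt$n_b,
      n_common = cnt$n_common, p_act = pa, p_chance = pc,
      p_act_track = actual_proportion(cnt),
      pdi = proportion_difference_index(pa, pc))
  }
  do.call(rbind, rows)
}
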