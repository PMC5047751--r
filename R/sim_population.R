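#' Assign tuned cell populations for a synthetic day
#'
#' Draws a population of `n_cells` cells and assigns track place fields
#' (1-D Gaussian per trajectory) and box head-direction tuning (von Mises
#' shaped). A fraction `cross_activation_fraction` of track-active cells is
#' forced to be box-active with preferred box angles that preserve the linear
#' order of their track field centres (the injected cross-activation); the
#' remaining box-active cells are drawn independently of track activity, so
#' at `cross_activation_fraction = 0` the two active sets are independent and
#' any overlap is chance overlap.
#'
#' @param config a [sim_config()].
#' @return an object of class `cell_population`: list with `cell_ids`,
#'   `labels` (common / track_only / box_only / silent), `track` (one row per
#'   cell x trajectory field: `cell_id`, `trajectory`, `center_cm`,
#'   `width_cm`, `peak_hz`), and `box` (`cell_id`, `pref_deg`, `kappa`,
#'   `peak_hz`, `order_preserved`).
#' @export
assign_cell_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_cells
    ids <- seq_len(n)
    n_track <- round(n * config$frac_track_active)
    n_box <- round(n * config$frac_box_active)
    n_forced <- round(n_track * config$cross_activation_fraction)
    if (n_forced > n_box)
      stop("cross_activation_fraction implies more common cells than box-active cells",
           call. = FALSE)

    track_ids <- sort(sample(ids, n_track))
    forced_ids <- sort(sample(track_ids, n_forced))
    pool <- setdiff(ids, forced_ids)
    other_box_ids <- sort(sample(pool, n_box - n_forced))
    box_ids <- sort(c(forced_ids, other_box_ids))

    # track fields: every track-active cell fields on trajectory A_to_B,
    # B_to_A, or both; forced (order-preserved) cells always field on A_to_B
    margin <- 2 * config$field_width_cm
    lo <- margin
    hi <- config$track_length_cm - margin
    track_rows <- list()
    for (id in track_ids) {
      traj <- sample(c("A_to_B", "B_to_A", "both"), 1, prob = c(0.4, 0.4, 0.2))
      if (id %in% forced_ids && traj == "B_to_A") traj <- "A_to_B"
      trajs <- if (traj == "both") c("A_to_B", "B_to_A") else traj
      ctr <- stats::runif(1, lo, hi)
      for (tr in trajs) {
        track_rows[[length(track_rows) + 1]] <- data.frame(
          cell_id = id, trajectory = tr, center_cm = ctr,
          width_cm = config$field_width_cm,
          peak_hz = config$peak_rate_hz * stats::runif(1, 0.8, 1.2))
      }
    }
    track <- if (length(track_rows)) do.call(rbind, track_rows) else
      data.frame(cell_id = integer(0), trajectory = character(0),
                 center_cm = numeric(0), width_cm = numeric(0),
                 peak_hz = numeric(0))

    # box tuning: forced cells get angles mapped from their A_to_B field
    # centres (order-preserving map cm -> deg); others draw angles uniformly
    box_rows <- list()
    for (id in box_ids) {
      forced <- id %in% forced_ids
      if (forced) {
        ctr <- track$center_cm[track$cell_id == id & track$trajectory == "A_to_B"][1]
        pref <- (ctr / config$track_length_cm) * 360
      } else {
        pref <- stats::runif(1, 0, 360)
      }
      box_rows[[length(box_rows) + 1]] <- data.frame(
        cell_id = id, pref_deg = pref %% 360, kappa = config$kappa_box,
        peak_hz = config$peak_rate_hz * stats::runif(1, 0.8, 1.2),
        order_preserved = forced)
    }
    box <- if (length(box_rows)) do.call(rbind, box_rows) else
      data.frame(cell_id = integer(0), pref_deg = numeric(0), kappa = numeric(0),
                 peak_hz = numeric(0), order_preserved = logical(0))

    labels <- rep("silent", n)
    labels[ids %in% track_ids] <- "track_only"
    labels[ids %in% box_ids] <- "box_only"
    labels[ids %in% intersect(track_ids, box_ids)] <- "common"

    structure(list(cell_ids = ids, labels = labels, track = track, box = box,
                   forced_common = forced_ids, config = config),
              class = "cell_population")
  })
}

#' @export
print.cell_population <- function(x, ...) {
  tb <- table(factor(x$labels, levels = c("common", "track_only", "box_only", "silent")))
  cat(sprintf("Cell population: %d cells (%d common, %d track-only, %d box-only, %d silent)\n",
              length(x$cell_ids), tb["common"], tb["track_only"], tb["box_only"], tb["silent"]))
  cat(sprintf("  %d common cells with order-preserved box tuning\n",
              length(x$forced_common)))
  invisible(x)
}
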