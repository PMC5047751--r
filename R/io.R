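# Session serialisation (delimited text + JSON sidecar) and the end-to-end
# day pipeline. All tables are plain TSV so fixtures stay diffable.

#' Write a session to a directory of delimited-text files
#'
#' Layout: `spikes.tsv` (cell_id, t_s), `position.tsv` (t_s, x_cm, y_cm,
#' hd_deg), optional `demo_position.tsv`, optional `lfp.tsv` (one value per
#' sample; rate and origin in the metadata), `meta.json`, and a
#' `truth.json` ground-truth sidecar when the session carries one.
#'
#' @param session a `ca_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(session$spikes, "spikes.tsv")
  tsv(session$position, "position.tsv")
  if (!is.null(session$demo_position)) tsv(session$demo_position, "demo_position.tsv")
  meta <- list(id = session$id, condition = session$condition,
               geometry = session$geometry)
  if (!is.null(session$lfp)) {
    tsv(data.frame(value = session$lfp$values), "lfp.tsv")
    meta$lfp_fs <- session$lfp$fs
    meta$lfp_t0 <- session$lfp$t0
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (length(session$ground_truth))
    jsonlite::write_json(session$ground_truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return a `ca_session`. Sessions without an `lfp.tsv` are valid; the
#'   LFP-dependent stages are simply unavailable for them.
#' @export
read_session <- function(dir) {
  need <- c("spikes.tsv", "position.tsv", "meta.json")
  for (f in need) if (!file.exists(file.path(dir, f)))
    stop(sprintf("missing session file '%s' in %s", f, dir), call. = FALSE)
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE)
  spikes <- rd("spikes.tsv")
  if (!all(c("cell_id", "t_s") %in% names(spikes)))
    stop("malformed spikes.tsv: need columns cell_id, t_s", call. = FALSE)
  position <- rd("position.tsv")
  if (!all(c("t_s", "x_cm", "y_cm", "hd_deg") %in% names(position)))
    stop("malformed position.tsv: need t_s, x_cm, y_cm, hd_deg", call. = FALSE)
  if (anyNA(position$t_s) || is.unsorted(position$t_s))
    stop(sprintf("malformed position.tsv: unsorted or missing t_s near line %d",
                 which(is.na(position$t_s) | c(FALSE, diff(position$t_s) < 0))[1] + 1),
         call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  demo <- NULL
  if (file.exists(file.path(dir, "demo_position.tsv")))
    demo <- rd("demo_position.tsv")
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.tsv")))
    lfp <- new_lfp(rd("lfp.tsv")$value, meta$lfp_fs, meta$lfp_t0)
  truth <- list()
  if (file.exists(file.path(dir, "truth.json")))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
  structure(list(id = meta$id, condition = meta$condition, spikes = spikes,
                 position = position, demo_position = demo, lfp = lfp,
                 geometry = meta$geometry, ground_truth = truth),
            class = "ca_session")
}

#' Run the cross-activation pipeline on one recording day
#'
#' Chains the stages end-to-end: event detection (laps, rotations, stops,
#' ripples), per-environment active-cell classification, common-cell pairing
#' table with PDI, track template construction, rotation-sequence matching,
#' and ripple-sequence (replay) matching where an LFP is present.
#'
#' @param track the day's Track `ca_session`.
#' @param boxes named list of box `ca_session`s (e.g. pre_box, post_box).
#' @param seed master seed for all shuffle procedures.
#' @param n_shuffles per-sequence identity shuffles.
#' @param n_template_sets randomized template sets for group significance.
#' @param N total putative pyramidal cells on the day; defaults to the
#'   number of distinct cells observed across the sessions.
#' @param verbose log stage progress and parameter echo.
#' @return list of class `day_report`: `laps`, `rotations`, `classification`,
#'   `pairings`, `templates`, `rotation_match`, `ripple_match` (NULL without
#'   LFP), `behavior`, and `params`.
#' @export
run_pipeline <- function(track, boxes, seed = 1L, n_shuffles = 1000,
                         n_template_sets = 200, N = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(inherits(track, "ca_session"))
  geom <- track$geometry
  say("detecting laps and stops on the track (track %g cm, end zones 10 cm)",
      geom$track_length_cm)
  laps <- detect_lap_events(track$position, geom$track_length_cm, 10)
  stops_track <- detect_stop_periods(track$position)
  laps_by_traj <- split(laps, laps$trajectory)

  rotations <- list(); stops_box <- list(); behavior <- list()
  for (s in names(boxes)) {
    rotations[[s]] <- detect_rotation_events(boxes[[s]]$position,
                                             boxes[[s]]$geometry$opening_center_deg)
    stops_box[[s]] <- detect_stop_periods(boxes[[s]]$position)
    behavior[[s]] <- behavior_summary(boxes[[s]]$position, rotations[[s]],
                                      boxes[[s]]$geometry$opening_center_deg)
    say("box session %s: %d rotation events", s, nrow(rotations[[s]]))
  }
  all_rot <- do.call(rbind, rotations)

  ids <- sort(unique(c(track$spikes$cell_id,
                       unlist(lapply(boxes, function(b) b$spikes$cell_id)))))
  if (is.null(N)) N <- length(ids)
  spikes_track <- split_spikes(track$spikes, ids)
  spikes_box <- lapply(boxes, function(b) split_spikes(b$spikes, ids))

  # day-level classification pools rotation events across box sessions
  pooled_box_spikes <- split_spikes(
    do.call(rbind, lapply(boxes, function(b) b$spikes)), ids)
  classification <- classify_day_cells(
    pooled_box_spikes, spikes_track, all_rot, laps_by_traj,
    stops_box = do.call(rbind, stops_box), stops_track = stops_track)

  # pairing table: per box session (own rotation events) x trajectory
  box_active <- lapply(names(boxes), function(s) {
    cl <- classify_active_cells(spikes_box[[s]], rotations[[s]], stops_box[[s]])
    cl$cell_id[cl$active]
  })
  names(box_active) <- names(boxes)
  track_active <- lapply(laps_by_traj, function(lp) {
    cl <- classify_active_cells(spikes_track, lp, stops_track)
    cl$cell_id[cl$active]
  })
  pairings <- pairing_analysis(N, box_active, track_active)

  # track templates from common cells
  common <- classification$cell_id[classification$label == "common"]
  say("%d common cells", length(common))
  curves <- lapply(laps_by_traj, function(lp) {
    cv <- lapply(common, function(id) {
      tryCatch(linear_rate_curve(spikes_track[[id]], track$position, lp,
                                 stops_track, geom$track_length_cm),
               error = function(e) NULL)
    })
    names(cv) <- common
    Filter(Negate(is.null), cv)
  })
  templates <- build_template(curves)
  say("%d templates", length(templates))

  rotation_match <- NULL
  if (length(templates)) {
    tmpl_cells <- unique(unlist(lapply(templates, `[[`, "cell_ids")))
    candidates <- list()
    for (s in names(boxes)) {
      ev <- rotations[[s]]
      for (i in seq_len(nrow(ev))) {
        cd <- extract_rotation_sequence(ev[i, , drop = FALSE], tmpl_cells,
                                        spikes_box[[s]], boxes[[s]]$position)
        if (!is.null(cd)) candidates[[length(candidates) + 1]] <- cd
      }
    }
    say("%d candidate rotation sequences", length(candidates))
    rotation_match <- count_matching_sequences(
      candidates, templates, n_shuffles = n_shuffles,
      n_template_sets = n_template_sets, seed = seed, circular = TRUE)
  }

  ripple_match <- NULL
  if (length(templates) && any(!vapply(lapply(boxes, `[[`, "lfp"), is.null, logical(1)))) {
    tmpl_cells <- unique(unlist(lapply(templates, `[[`, "cell_ids")))
    rip_cands <- list()
    for (s in names(boxes)) {
      if (is.null(boxes[[s]]$lfp)) next
      rips <- detect_ripple_events(boxes[[s]]$lfp)
      say("box session %s: %d ripple events", s, nrow(rips))
      for (i in seq_len(nrow(rips))) {
        cd <- extract_ripple_sequence(rips[i, , drop = FALSE], tmpl_cells,
                                      spikes_box[[s]])
        if (!is.null(cd)) rip_cands[[length(rip_cands) + 1]] <- cd
      }
    }
    ripple_match <- count_matching_sequences(
      rip_cands, templates, n_shuffles = n_shuffles,
      n_template_sets = n_template_sets, seed = seed, circular = FALSE)
  }

  structure(list(laps = laps, rotations = rotations,
                 classification = classification, pairings = pairings,
                 templates = templates, rotation_match = rotation_match,
                 ripple_match = ripple_match,
                 behavior = do.call(rbind, behavior),
                 params = list(seed = seed, n_shuffles = n_shuffles,
                               n_template_sets = n_template_sets, N = N)),
            class = "day_report")
}

#' @export
print.day_report <- function(x, ...) {
  tb <- table(x$classification$label)
  cat("Day report\n")
  cat(sprintf("  laps: %d | rotation events: %d | cells: %d (%d common)\n",
              nrow(x$laps), sum(vapply(x$rotations, nrow, integer(1))),
              nrow(x$classification), sum(x$classification$label == "common")))
  cat(sprintf("  mean PDI over %d pairings: %.3f\n", nrow(x$pairings),
              mean(x$pairings$pdi, na.rm = TRUE)))
  if (!is.null(x$rotation_match))
    cat(sprintf("  rotation matching: %d/%d (p %s)\n",
                x$rotation_match$n_matches, x$rotation_match$n_candidates,
                x$rotation_match$p_label))
  if (!is.null(x$ripple_match))
    cat(sprintf("  ripple replay: %d/%d (p %s)\n",
                x$ripple_match$n_matches, x$ripple_match$n_candidates,
                x$ripple_match$p_label))
  invisible(x)
}
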