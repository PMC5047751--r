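# Template construction and rank-order sequence matching. Rotation sequences
# are matched with a circular-shift max |Spearman| score; ripple sequences
# with plain |Spearman|. Per-sequence significance uses cell-identity
# shuffles; group-level significance uses 200 randomized template sets.

new_template <- function(trajectory, cell_ids, peak_cm) {
  structure(list(trajectory = trajectory, cell_ids = cell_ids,
                 peak_locations_cm = peak_cm),
            class = "template_sequence")
}

#' @export
print.template_sequence <- function(x, ...) {
  cat(sprintf("Template (%s): %d cells ordered by peak location\n",
              x$trajectory, length(x$cell_ids)))
  invisible(x)
}

#' Build track template sequences
#'
#' For each trajectory, cells whose rate curve has a prominent peak (peak
#' rate >= `peak_sd` standard deviations above the curve's mean rate) are
#' ordered by peak firing location; when a curve has several local peaks the
#' highest is used (the argmax). Templates with fewer than `min_cells`
#' qualifying cells are dropped.
#'
#' @param curves_by_trajectory named list (one entry per trajectory) of named
#'   lists of `rate_curve`s keyed by cell id -- typically common cells only.
#' @param min_cells minimum template length.
#' @param peak_sd peak prominence criterion in SDs of the cell's rate curve.
#' @return named list of `template_sequence` objects (possibly empty).
#' @export
build_template <- function(curves_by_trajectory, min_cells = 5, peak_sd = 3) {
  out <- list()
  for (tr in names(curves_by_trajectory)) {
    curves <- curves_by_trajectory[[tr]]
    ids <- c(); locs <- c()
    for (id in names(curves)) {
      r <- curves[[id]]$rate_hz
      b <- curves[[id]]$bin_cm
      ok <- is.finite(r)
      if (sum(ok) < 3) next
      if (max(r[ok]) >= mean(r[ok]) + peak_sd * stats::sd(r[ok])) {
        ids <- c(ids, id)
        locs <- c(locs, b[ok][which.max(r[ok])])
      }
    }
    if (length(ids) >= min_cells) {
      o <- order(locs, ids)
      out[[tr]] <- new_template(tr, ids[o], locs[o])
    }
  }
  out
}

new_candidate <- function(source, event, cell_ids, key) {
  structure(list(source = source, event = event, cell_ids = cell_ids,
                 order_key = key),
            class = "candidate_sequence")
}

#' Extract the firing sequence of a rotation event
#'
#' Template cells with at least one spike in the event are ordered by the
#' peak angle of their within-event circular rate curve (relative to the
#' opening at 0 degrees); ties broken by cell id.
#'
#' @param event one rotation event (single-row data frame).
#' @param template_cells cell ids eligible for the sequence.
#' @param spikes_by_cell named list of spike-time vectors.
#' @param position position series with `hd_deg`.
#' @param min_cells minimum number of active cells for a candidate.
#' @param bin_deg,sigma_bins within-event curve binning.
#' @return a `candidate_sequence`, or `NULL` if fewer than `min_cells` cells
#'   are active.
#' @export
extract_rotation_sequence <- function(event, template_cells, spikes_by_cell,
                                      position, min_cells = 5, bin_deg = 5,
                                      sigma_bins = 2) {
  active <- c(); angle <- c()
  for (id in template_cells) {
    st <- spikes_by_cell[[as.character(id)]]
    st <- st[st >= event$start_s & st < event$end_s]
    if (length(st) == 0) next
    cv <- circular_rate_curve(st, position, event, bin_deg = bin_deg,
                              sigma_bins = sigma_bins)
    r <- cv$rate_hz
    ok <- is.finite(r)
    if (!any(ok)) next
    active <- c(active, id)
    angle <- c(angle, cv$bin_deg[ok][which.max(r[ok])])
  }
  if (length(active) < min_cells) return(NULL)
  o <- order(angle, active)
  new_candidate("rotation", event, active[o], angle[o])
}

#' Peak firing times of cells within an event
#'
#' Each cell's spike train is convolved with a Gaussian kernel into an
#' instantaneous rate curve on a 1 ms grid; the peak time is the argmax.
#'
#' @param spikes_by_cell named list of spike-time vectors.
#' @param event interval (single-row data frame `start_s`, `end_s`).
#' @param cells cells to evaluate.
#' @param sigma_s kernel SD (s): 0.1 s for rotation events, 0.01 s within
#'   ripples.
#' @return named numeric vector of peak times (s), cells without spikes in
#'   the event omitted.
#' @export
peak_firing_times <- function(spikes_by_cell, event, cells, sigma_s = 0.01) {
  grid <- seq(event$start_s, event$end_s, by = 0.001)
  out <- c()
  for (id in cells) {
    st <- spikes_by_cell[[as.character(id)]]
    st <- st[st >= event$start_s & st < event$end_s]
    if (length(st) == 0) next
    dens <- rowSums(outer(grid, st, function(g, s) exp(-(g - s)^2 / (2 * sigma_s^2))))
    out[as.character(id)] <- grid[which.max(dens)]
  }
  out
}

#' Extract the firing sequence of a candidate ripple event
#'
#' Template cells with at least one spike in the ripple are ordered by peak
#' firing time within the event.
#'
#' @param ripple one ripple event (single-row data frame).
#' @param template_cells eligible cell ids.
#' @param spikes_by_cell named list of spike-time vectors.
#' @param min_cells minimum number of active cells.
#' @param sigma_s instantaneous-rate kernel SD (s).
#' @return a `candidate_sequence`, or `NULL`.
#' @export
extract_ripple_sequence <- function(ripple, template_cells, spikes_by_cell,
                                    min_cells = 5, sigma_s = 0.01) {
  pk <- peak_firing_times(spikes_by_cell, ripple, template_cells, sigma_s)
  if (length(pk) < min_cells) return(NULL)
  o <- order(pk, names(pk))
  new_candidate("ripple", ripple, names(pk)[o], unname(pk)[o])
}

# ranks of candidate cells within the template order, template restricted to
# the candidate's cells; returns list(cand = 1..k, temp = template ranks)
restrict_ranks <- function(cand_cells, template_cells) {
  shared <- cand_cells[cand_cells %in% template_cells]
  k <- length(shared)
  if (k < 2) return(NULL)
  temp_order <- template_cells[template_cells %in% shared]
  list(k = k, cand = seq_len(k), temp = match(shared, temp_order))
}

score_ranks <- function(cand_rank, temp_rank, circular = TRUE) {
  k <- length(cand_rank)
  shifts <- if (circular) 0:(k - 1) else 0L
  best <- -Inf; best_signed <- NA_real_
  for (s in shifts) {
    shifted <- ((cand_rank - 1 + s) %% k) + 1
    # rank correlations of k-permutations take few distinct values; round
    # away floating fuzz so score comparisons (the >95% rule) are exact
    rho <- round(stats::cor(shifted, temp_rank), 10)
    if (abs(rho) > best) { best <- abs(rho); best_signed <- rho }
  }
  list(score = best, signed_best = best_signed)
}

#' Circular-shift match score between a candidate sequence and a template
#'
#' The candidate's cell order is circularly shifted one cell at a time; for
#' each shift the Spearman rank-order correlation with the template order
#' (both restricted to shared cells) is computed. The score is the maximum
#' absolute correlation; `signed_best` carries its sign (negative = matched
#' in reverse order).
#'
#' @param seq a `candidate_sequence` (or ordered vector of cell ids).
#' @param template a `template_sequence` (or ordered vector of cell ids).
#' @param min_cells minimum shared cells for a defined score.
#' @return list with `score` in [0, 1], `signed_best` in [-1, 1], and
#'   `n_shared`; `NULL` if fewer than `min_cells` shared cells.
#' @export
circular_match_score <- function(seq, template, min_cells = 5) {
  cand <- if (inherits(seq, "candidate_sequence")) seq$cell_ids else seq
  temp <- if (inherits(template, "template_sequence")) template$cell_ids else template
  rk <- restrict_ranks(as.character(cand), as.character(temp))
  if (is.null(rk) || rk$k < min_cells) return(NULL)
  c(score_ranks(rk$cand, rk$temp, circular = TRUE), n_shared = rk$k)
}

#' Rank-order match score for a ripple sequence (no circular shifts)
#' @inheritParams circular_match_score
#' @return as [circular_match_score()].
#' @export
linear_match_score <- function(seq, template, min_cells = 5) {
  cand <- if (inherits(seq, "candidate_sequence")) seq$cell_ids else seq
  temp <- if (inherits(template, "template_sequence")) template$cell_ids else template
  rk <- restrict_ranks(as.character(cand), as.character(temp))
  if (is.null(rk) || rk$k < min_cells) return(NULL)
  c(score_ranks(rk$cand, rk$temp, circular = FALSE), n_shared = rk$k)
}

# Null match-score sample for a k-cell sequence: score between a uniformly
# random permutation and a fixed order. By relabeling invariance the
# distribution depends only on k (and on circular vs linear scoring), so
# samples are memoised per (k, n, circular).
.match_null_cache <- new.env(parent = emptyenv())

match_null_scores <- function(k, n_shuffles = 1000, circular = TRUE,
                              seed = 20201L) {
  key <- sprintf("k%d_n%d_%s", k, n_shuffles, if (circular) "c" else "l")
  if (!is.null(.match_null_cache[[key]])) return(.match_null_cache[[key]])
  ref <- seq_len(k)
  vals <- with_seed(derive_seed(seed, k * 1000L + n_shuffles), {
    vapply(seq_len(n_shuffles), function(b) {
      score_ranks(sample(ref), ref, circular = circular)$score
    }, numeric(1))
  })
  .match_null_cache[[key]] <- sort(vals)
  vals
}

# the ">95% of shuffled scores" rule
is_match_rule <- function(score, null_scores) {
  sum(score > null_scores) / length(null_scores) > 0.95
}

#' Per-sequence match significance via cell-identity shuffles
#'
#' The candidate's cell identities are randomly permuted `n_shuffles` times;
#' each shuffled sequence is scored against the template with the same
#' (circular or linear) procedure. The candidate is a significant match when
#' its score exceeds more than 95% of the shuffled scores.
#'
#' @param seq a `candidate_sequence`.
#' @param template a `template_sequence`.
#' @param n_shuffles number of identity shuffles.
#' @param seed RNG seed.
#' @param circular circular-shift scoring (rotation sequences) or plain
#'   rank-order (ripple sequences).
#' @param min_cells minimum shared cells.
#' @return list of class `match_result`: `score`, `signed_best`,
#'   `null_scores`, `percentile` (fraction of null below the score),
#'   `is_match`, `n_shared`; `NULL` when the score is undefined.
#' @export
sequence_match_significance <- function(seq, template, n_shuffles = 1000,
                                        seed = 1L, circular = TRUE,
                                        min_cells = 5) {
  sc <- if (circular) circular_match_score(seq, template, min_cells) else
    linear_match_score(seq, template, min_cells)
  if (is.null(sc)) return(NULL)
  k <- sc$n_shared
  null <- with_seed(derive_seed(seed, 17L), {
    ref <- seq_len(k)
    vapply(seq_len(n_shuffles), function(b) {
      score_ranks(sample(ref), ref, circular = circular)$score
    }, numeric(1))
  })
  structure(list(score = sc$score, signed_best = sc$signed_best,
                 null_scores = null,
                 percentile = sum(sc$score > null) / length(null),
                 is_match = is_match_rule(sc$score, null),
                 n_shared = k),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Match score %.3f (signed %.3f, %d shared cells): %s (beats %.1f%% of %d shuffles)\n",
              x$score, x$signed_best, x$n_shared,
              if (x$is_match) "significant match" else "not significant",
              100 * x$percentile, length(x$null_scores)))
  invisible(x)
}

#' Count matching sequences against randomized template sets
#'
#' Each candidate is a matching sequence when it significantly matches at
#' least one template (the >95%-of-shuffles rule, with the null score sample
#' memoised per shared-cell count, which is exactly equivalent to shuffling
#' cell identities per sequence). The actual match count is compared against
#' `n_template_sets` sets of identity-randomized templates processed
#' identically; p is the proportion of randomized sets yielding more matches
#' than the actual templates.
#'
#' @param candidates list of `candidate_sequence`s (pooled over a condition).
#' @param templates list of `template_sequence`s (the same-day templates).
#' @param n_shuffles per-sequence identity-shuffle count.
#' @param n_template_sets number of randomized template sets.
#' @param seed RNG seed.
#' @param circular scoring mode (TRUE for rotation sequences).
#' @param min_cells minimum shared cells.
#' @return list of class `group_match_result`: `n_candidates`, `n_matches`,
#'   `null_match_counts`, `p`, `p_label`, and `match_flags`.
#' @export
count_matching_sequences <- function(candidates, templates, n_shuffles = 1000,
                                     n_template_sets = 200, seed = 1L,
                                     circular = TRUE, min_cells = 5) {
  candidates <- Filter(Negate(is.null), candidates)
  count_matches <- function(tset) {
    flags <- vapply(candidates, function(cd) {
      for (tp in tset) {
        sc <- if (circular) circular_match_score(cd, tp, min_cells) else
          linear_match_score(cd, tp, min_cells)
        if (is.null(sc)) next
        null <- match_null_scores(sc$n_shared, n_shuffles, circular)
        if (is_match_rule(sc$score, null)) return(TRUE)
      }
      FALSE
    }, logical(1))
    flags
  }
  if (length(candidates) == 0 || length(templates) == 0) {
    warning("no candidate sequences or no templates; p reported as 1")
    return(structure(list(n_candidates = length(candidates), n_matches = 0L,
                          rate_pct = NA_real_,
                          null_match_counts = rep(0L, n_template_sets),
                          p = 1, p_label = "1", match_flags = logical(0)),
                     class = "group_match_result"))
  }
  flags <- count_matches(templates)
  actual <- sum(flags)
  null_counts <- with_seed(derive_seed(seed, 19L), {
    vapply(seq_len(n_template_sets), function(r) {
      tset <- lapply(templates, function(tp) {
        new_template(tp$trajectory, sample(tp$cell_ids), tp$peak_locations_cm)
      })
      sum(count_matches(tset))
    }, integer(1))
  })
  # strict exceedance per the matching rule; with zero actual matches the
  # one-sided exceedance probability (ties included) is 1 by construction
  p <- if (actual == 0) 1 else mean(null_counts > actual)
  structure(list(n_candidates = length(candidates), n_matches = actual,
                 rate_pct = matching_rate(actual, length(candidates)),
                 null_match_counts = null_counts, p = p,
                 p_label = if (p == 0) sprintf("<%.3f", 1 / n_template_sets)
                 else format(p), match_flags = flags),
            class = "group_match_result")
}

#' Matching-sequence rate
#'
#' Percentage of candidate sequences that are matching sequences; the
#' group-level bookkeeping behind "x% of rotation sequences were matching
#' sequences" summaries.
#' @param n_matches number of matching sequences.
#' @param n_candidates number of candidate sequences.
#' @return percentage in [0, 100] (`NA` when there are no candidates).
#' @export
matching_rate <- function(n_matches, n_candidates) {
  if (n_candidates == 0) return(NA_real_)
  100 * n_matches / n_candidates
}

#' @export
print.group_match_result <- function(x, ...) {
  cat(sprintf("%d of %d candidate sequences match (p %s vs %d randomized template sets)\n",
              x$n_matches, x$n_candidates,
              if (x$p == 0) x$p_label else sprintf("= %s", x$p_label),
              length(x$null_match_counts)))
  invisible(x)
}

#' Time-gap preservation between a matching sequence and its template
#'
#' For each pair of cells with neighbouring template peaks present in the
#' matching sequence, the track peak-location gap is converted to a time gap
#' via the trajectory's mean running speed and rescaled so the mean lap
#' length is 1; the event peak-time gap is rescaled so the event length
#' is 1. The mean absolute difference |delta_d - delta_t| over pairs is
#' z-scored against `n_shuffles` order-preserving re-timings (sorted uniform
#' peak times on the unit event).
#'
#' @param peak_times_s named vector of within-event peak firing times (s) for
#'   the sequence cells (see [peak_firing_times()]).
#' @param event the event interval (single-row data frame).
#' @param template a `template_sequence` with `peak_locations_cm`.
#' @param track_mean_speed_cm_s mean running speed on the trajectory (cm/s).
#' @param mean_lap_duration_s mean temporal length of the trajectory's laps
#'   (s); track gaps are rescaled by it.
#' @param n_shuffles order-preserving shuffles for the z-score.
#' @param seed RNG seed.
#' @return list: `mean_abs_diff`, `z`, `pairs` (per-pair `delta_d`,
#'   `delta_t`), `n_pairs`.
#' @export
time_gap_difference <- function(peak_times_s, event, template,
                                track_mean_speed_cm_s, mean_lap_duration_s,
                                n_shuffles = 200, seed = 1L) {
  cells <- names(peak_times_s)
  tcells <- as.character(template$cell_ids)
  shared <- tcells[tcells %in% cells]
  if (length(shared) < 2)
    stop("need at least one pair of cells with template peaks", call. = FALSE)
  loc <- template$peak_locations_cm[match(shared, tcells)]
  tev <- peak_times_s[shared]
  dur <- event$end_s - event$start_s
  delta_d <- abs(diff(loc)) / track_mean_speed_cm_s / mean_lap_duration_s
  delta_t <- abs(diff(tev)) / dur
  actual <- mean(abs(delta_d - delta_t))
  k <- length(shared)
  # order of the shared cells within the event (by peak time)
  ord <- rank(tev, ties.method = "first")
  null <- with_seed(derive_seed(seed, 23L), {
    vapply(seq_len(n_shuffles), function(b) {
      u <- sort(stats::runif(k))          # order-preserving re-timing
      tb <- u[ord]
      mean(abs(delta_d - abs(diff(tb))))
    }, numeric(1))
  })
  z <- (actual - mean(null)) / stats::sd(null)
  list(mean_abs_diff = actual, z = z,
       pairs = data.frame(cell_a = shared[-k], cell_b = shared[-1],
                          delta_d = delta_d, delta_t = delta_t),
       n_pairs = k - 1)
}
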