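# Template construction and rank-order sequence matching.

test_that("templates require five prominent-peaked cells ordered by location", {
  bins <- seq(11, 189, by = 2)
  peaked <- function(ctr) {
    r <- 0.2 + 9 * exp(-(bins - ctr)^2 / (2 * 6^2))
    data.frame(bin_cm = bins, rate_hz = r, occupancy_s = 1)
  }
  flat <- data.frame(bin_cm = bins, rate_hz = rep(2, length(bins)) +
                       0.05 * sin(bins), occupancy_s = 1)
  curves <- lapply(c(150, 30, 90, 60, 120), peaked)
  names(curves) <- c("c1", "c2", "c3", "c4", "c5")
  tpl <- build_template(list(A_to_B = curves))
  expect_length(tpl, 1)
  expect_equal(tpl$A_to_B$cell_ids, c("c2", "c4", "c3", "c5", "c1"))
  # a flat-rate cell fails the 3 SD peak criterion
  curves$flat <- flat
  tpl2 <- build_template(list(A_to_B = curves))
  expect_false("flat" %in% tpl2$A_to_B$cell_ids)
  # four qualifying cells -> no template
  tpl3 <- build_template(list(A_to_B = curves[1:4]))
  expect_length(tpl3, 0)
})

test_that("synthetic common cells yield templates in field-centre order", {
  d <- small_day()
  laps <- d$track$ground_truth$laps
  lapsA <- laps[laps$trajectory == "A_to_B", ]
  forced <- sort(d$pop$forced_common)
  curves <- lapply(as.character(forced), function(id)
    linear_rate_curve(d$track$spikes$t_s[d$track$spikes$cell_id == id],
                      d$track$position, lapsA))
  names(curves) <- as.character(forced)
  tpl <- build_template(list(A_to_B = curves))$A_to_B
  expect_gte(length(tpl$cell_ids), 5)
  truth_ctr <- vapply(tpl$cell_ids, function(id)
    d$pop$track$center_cm[d$pop$track$cell_id == as.integer(id) &
                            d$pop$track$trajectory == "A_to_B"][1], numeric(1))
  # template order tracks the true field-centre order; near-ties (centres
  # closer than the 2 cm bin) may swap under estimation noise
  expect_gt(cor(seq_along(truth_ctr), truth_ctr, method = "spearman"), 0.85)
  inv <- which(diff(truth_ctr) <= 0)
  if (length(inv)) expect_lt(max(abs(diff(truth_ctr)[inv])), 5)
})

test_that("rotation sequences order cells by within-event peak angle", {
  tt <- seq(0, 10, by = 1 / 33)
  hd <- 360 * tt / 10
  pos <- data.frame(t_s = tt, x_cm = 0, y_cm = 0,
                    hd_deg = ((hd + 180) %% 360) - 180)
  ev <- data.frame(start_s = 0, end_s = 10)
  # single spikes at angles 10, 50, 90, 130, 170 degrees
  angles <- c(90, 10, 170, 50, 130)
  spikes <- lapply(angles, function(a) 10 * a / 360)
  names(spikes) <- paste0("c", 1:5)
  cd <- extract_rotation_sequence(ev, names(spikes), spikes, pos)
  expect_equal(cd$cell_ids, paste0("c", c(2, 4, 1, 5, 3)))
  # only four active cells -> no candidate
  expect_null(extract_rotation_sequence(ev, names(spikes)[1:4],
                                        spikes[1:4], pos))
})

test_that("circular match scores behave like the quoted shift examples", {
  tpl <- as.character(1:5)
  expect_equal(circular_match_score(tpl, tpl)$score, 1)
  r <- circular_match_score(rev(tpl), tpl)
  expect_equal(r$score, 1)
  expect_equal(r$signed_best, -1)
  # 45123 is a circular shift of 12345
  expect_equal(circular_match_score(as.character(c(4, 5, 1, 2, 3)), tpl)$score, 1)
  # invariance under any rotation of the candidate
  set.seed(2)
  cand <- as.character(sample(1:7))
  tpl7 <- as.character(1:7)
  s0 <- circular_match_score(cand, tpl7)$score
  for (s in 1:6) {
    rot <- c(cand[-(1:s)], cand[1:s])
    expect_equal(circular_match_score(rot, tpl7)$score, s0)
  }
  # reversal flips the sign but keeps the score
  sr <- circular_match_score(rev(cand), tpl7)
  expect_equal(sr$score, s0)
})

test_that("shuffle nulls agree with exhaustive permutation for 5-7 cells", {
  for (k in 5:7) {
    exact <- vapply(all_perms(seq_len(k)), function(p)
      crossact:::score_ranks(p, seq_len(k), circular = TRUE)$score, numeric(1))
    null <- crossact:::match_null_scores(k, 1000, circular = TRUE)
    # compare P(identity beats shuffle) with the exact brute-force value
    p_exact <- mean(1 > exact)
    p_mc <- mean(1 > null)
    se <- sqrt(p_exact * (1 - p_exact) / 1000)
    expect_lt(abs(p_mc - p_exact), 3 * se + 1e-6)
    # and compare full distributions
    expect_lt(suppressWarnings(ks.test(null, exact)$statistic), 0.06)
  }
})

test_that("per-sequence significance is reproducible and rate-controlled", {
  tpl <- crossact:::new_template("A_to_B", as.character(1:10), (1:10) * 10)
  cand <- structure(list(source = "rotation", event = NULL,
                         cell_ids = as.character(1:10), order_key = 1:10),
                    class = "candidate_sequence")
  m1 <- sequence_match_significance(cand, tpl, n_shuffles = 500, seed = 8)
  m2 <- sequence_match_significance(cand, tpl, n_shuffles = 500, seed = 8)
  expect_identical(m1$is_match, m2$is_match)
  expect_true(m1$is_match)              # identity order matches
  # random candidates are flagged at roughly the discrete-null rate
  set.seed(14)
  nrep <- 300
  null10 <- crossact:::match_null_scores(10, 1000, TRUE)
  flag <- replicate(nrep, {
    cd <- as.character(sample(1:10))
    sc <- circular_match_score(cd, tpl)$score
    crossact:::is_match_rule(sc, null10)
  })
  # the expected rate is the exact probability that a random permutation
  # beats >95% of the permutation null; estimate it from the null itself
  q <- quantile(null10, 0.95, type = 1)
  p_expect <- mean(null10 > q)
  expect_lt(abs(mean(flag) - p_expect), 3 * sqrt(0.05 * 0.95 / nrep) + 0.01)
  expect_lte(mean(flag), 0.07)
})

test_that("ripple sequences use plain rank order and single-spike timing", {
  ev <- data.frame(start_s = 0, end_s = 0.2)
  spikes <- list(a = 0.02, b = 0.06, c = 0.10, d = 0.14, e = 0.18)
  cd <- extract_ripple_sequence(ev, names(spikes), spikes)
  expect_equal(cd$cell_ids, c("a", "b", "c", "d", "e"))
  expect_null(extract_ripple_sequence(ev, names(spikes)[1:4], spikes[1:4]))
  tpl <- crossact:::new_template("A_to_B", c("a", "b", "c", "d", "e"), 1:5)
  m <- sequence_match_significance(cd, tpl, n_shuffles = 400, seed = 2,
                                   circular = FALSE)
  expect_equal(m$score, 1)
  expect_true(m$is_match)
  # exhaustive oracle for the linear score at k = 5
  exact <- vapply(all_perms(1:5), function(p)
    crossact:::score_ranks(p, 1:5, circular = FALSE)$score, numeric(1))
  null <- crossact:::match_null_scores(5, 1000, circular = FALSE)
  expect_lt(abs(mean(1 > null) - mean(1 > exact)),
            3 * sqrt(mean(1 > exact) * (1 - mean(1 > exact)) / 1000) + 1e-6)
})

test_that("group-level counting flags injected structure, not noise", {
  tpl <- crossact:::new_template("A_to_B", as.character(1:12), (1:12) * 10)
  mk <- function(cells) structure(
    list(source = "rotation", event = NULL, cell_ids = cells,
         order_key = seq_along(cells)), class = "candidate_sequence")
  # candidates echoing the template order (with one swap) vs pure noise
  set.seed(6)
  echo <- lapply(1:10, function(i) {
    cells <- as.character(1:12)
    j <- sample(11, 1); cells[c(j, j + 1)] <- cells[c(j + 1, j)]
    mk(cells)
  })
  noise <- lapply(1:10, function(i) mk(as.character(sample(1:12))))
  g1 <- count_matching_sequences(echo, list(tpl), n_template_sets = 100, seed = 3)
  g0 <- count_matching_sequences(noise, list(tpl), n_template_sets = 100, seed = 3)
  expect_gte(g1$n_matches, 9)
  expect_lt(g1$p, 0.05)
  expect_lte(g0$n_matches, 2)
  expect_gt(g0$p, 0.05)
  # degenerate input: no candidates
  expect_warning(gz <- count_matching_sequences(list(), list(tpl)))
  expect_equal(gz$n_matches, 0)
  expect_equal(gz$p, 1)
})

test_that("time-gap preservation is detected and the null is centred", {
  tpl <- crossact:::new_template("A_to_B", as.character(1:6), c(10, 40, 70, 100, 130, 160))
  ev <- data.frame(start_s = 0, end_s = 6)
  speed <- 30; lapdur <- 6
  # event timing exactly proportional to track spacing -> zero gap difference
  pk <- setNames((c(10, 40, 70, 100, 130, 160) - 10) / speed, as.character(1:6))
  g <- time_gap_difference(pk, ev, tpl, speed, lapdur, n_shuffles = 200, seed = 5)
  expect_equal(g$mean_abs_diff, 0, tolerance = 1e-12)
  expect_lt(g$z, 0)
  # order-preserving but random event times -> z near 0 over replicates
  set.seed(9)
  zs <- replicate(60, {
    pk2 <- setNames(sort(runif(6, 0, 6)), as.character(1:6))
    time_gap_difference(pk2, ev, tpl, speed, lapdur, n_shuffles = 100,
                        seed = sample.int(1e6, 1))$z
  })
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)) + 0.1)
  # single pair degenerate case
  pk1 <- setNames(c(1, 3), c("1", "2"))
  g1 <- time_gap_difference(pk1, ev, tpl, speed, lapdur, n_shuffles = 50)
  expect_equal(g1$n_pairs, 1)
  expect_equal(g1$mean_abs_diff,
               abs(30 / speed / lapdur - 2 / 6), tolerance = 1e-9)
})
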