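# Behavioural and LFP event detection.

test_that("a monotone full rotation is one event with the full span", {
  pos <- hd_position(c(0, 2, 10, 12), c(0, 0, 360, 360))
  ev <- detect_rotation_events(pos)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "CCW")
  expect_equal(ev$span_deg, 360, tolerance = 0.05)
})

test_that("sub-180-degree excursions are not rotation events", {
  pos <- hd_position(c(0, 1, 4, 7, 8), c(0, 0, 120, 0, 0))
  expect_equal(nrow(detect_rotation_events(pos)), 0)
})

test_that("rotation detection is symmetric under head-direction negation", {
  pos_ccw <- hd_position(c(0, 2, 10, 12), c(0, 0, 360, 360))
  pos_cw <- pos_ccw
  pos_cw$hd_deg <- ((-pos_ccw$hd_deg + 180) %% 360) - 180
  ev <- detect_rotation_events(pos_cw)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "CW")
  expect_equal(ev$span_deg, 360, tolerance = 0.05)
})

test_that("rotation detection is invariant to a common opening shift", {
  pos <- hd_position(c(0, 2, 10, 12, 14, 16, 26, 28),
                     c(0, 0, 360, 360, 360, 360, 0, 0))
  base <- detect_rotation_events(pos, opening_center_deg = 0)
  shifted <- pos
  shifted$hd_deg <- ((pos$hd_deg + 90 + 180) %% 360) - 180
  ev <- detect_rotation_events(shifted, opening_center_deg = 90)
  expect_equal(ev$span_deg, base$span_deg, tolerance = 1e-6)
  expect_equal(ev$direction, base$direction)
})

test_that("degenerate position input yields no events with a warning", {
  expect_warning(ev <- detect_rotation_events(
    data.frame(t_s = numeric(0), x_cm = numeric(0), y_cm = numeric(0),
               hd_deg = numeric(0))))
  expect_equal(nrow(ev), 0)
})

test_that("the detector recovers the generated rotation events", {
  d <- small_day()
  for (ses in list(d$pre, d$post)) {
    ev <- detect_rotation_events(ses$position)
    truth <- ses$ground_truth$rotations
    expect_equal(nrow(ev), nrow(truth))
    expect_equal(ev$direction, truth$direction)
    # each detected event covers its generated rotation
    expect_true(all(ev$start_s <= truth$start_s + 0.5 &
                      ev$end_s >= truth$end_s - 0.5))
  }
})

test_that("triangle-wave running yields one lap per traversal", {
  pos <- triangle_position(n_laps = 5)
  laps <- detect_lap_events(pos)
  expect_equal(sum(laps$trajectory == "A_to_B"), 5)
  expect_equal(sum(laps$trajectory == "B_to_A"), 5)
  expect_true(all(laps$end_s > laps$start_s))
  # laps on the same trajectory do not overlap
  for (tr in c("A_to_B", "B_to_A")) {
    lp <- laps[laps$trajectory == tr, ]
    lp <- lp[order(lp$start_s), ]
    expect_true(all(diff(lp$start_s) >= 0) &&
                  all(lp$end_s[-nrow(lp)] <= lp$start_s[-1] + 1e-9))
  }
})

test_that("mid-track turn-arounds do not produce laps", {
  tt <- seq(0, 40, by = 1 / 33)
  # oscillates 15..195 cm: visits the B end zone but turns around before A
  pos <- data.frame(t_s = tt, x_cm = 105 + 90 * sin(2 * pi * tt / 20),
                    y_cm = 0, hd_deg = 0)
  expect_equal(nrow(detect_lap_events(pos)), 0)
})

test_that("detected lap times agree with the generator ground truth", {
  d <- small_day()
  laps <- detect_lap_events(d$track$position)
  truth <- d$track$ground_truth$laps
  expect_equal(nrow(laps), nrow(truth))
  o <- order(laps$start_s); ot <- order(truth$start_s)
  expect_equal(laps$trajectory[o], truth$trajectory[ot])
  # detected boundaries sit at the end-zone crossings, i.e. 5% and 95% of
  # the constant-speed traversal; agreement within two position samples
  dur <- truth$end_s[ot] - truth$start_s[ot]
  expect_lt(max(abs(laps$start_s[o] - (truth$start_s[ot] + 0.05 * dur))), 0.07)
  expect_lt(max(abs(laps$end_s[o] - (truth$end_s[ot] - 0.05 * dur))), 0.07)
})

test_that("stop detection honours the duration threshold", {
  hz <- 33
  still <- function(dur) data.frame(t_s = seq(0, dur, by = 1 / hz), x = 0)
  mk <- function(segs) {
    t0 <- 0; rows <- list()
    for (s in segs) {
      tt <- seq(0, s$dur, by = 1 / hz)
      rows[[length(rows) + 1]] <- data.frame(
        t_s = t0 + tt, x_cm = s$x0 + s$v * tt, y_cm = 0, hd_deg = 0)
      t0 <- t0 + s$dur + 1 / hz
    }
    do.call(rbind, rows)
  }
  # 10 s immobile -> one stop of about 10 s
  pos <- mk(list(list(dur = 10, x0 = 0, v = 0)))
  st <- detect_stop_periods(pos)
  expect_equal(nrow(st), 1)
  expect_equal(st$end_s - st$start_s, 10, tolerance = 0.5)
  # constant 20 cm/s motion -> none
  pos2 <- mk(list(list(dur = 10, x0 = 0, v = 20)))
  expect_equal(nrow(detect_stop_periods(pos2)), 0)
  # a 2.5 s pause flanked by motion is below the 3 s minimum
  pos3 <- mk(list(list(dur = 5, x0 = 0, v = 20),
                  list(dur = 2.5, x0 = 100, v = 0),
                  list(dur = 5, x0 = 100, v = 20)))
  expect_equal(nrow(detect_stop_periods(pos3)), 0)
})

test_that("white noise below threshold yields no ripple events", {
  lfp <- noise_lfp(dur_s = 10, seed = 16)
  env <- ripple_envelope(lfp$values, lfp$fs)
  z <- (env - mean(env)) / sd(env)
  expect_lt(max(z), 4)                   # fixture condition
  expect_equal(nrow(detect_ripple_events(lfp)), 0)
})

test_that("an injected 6 SD burst is detected once, a 3 SD burst not at all", {
  lfp6 <- noise_lfp(dur_s = 10, seed = 16,
                    bursts = data.frame(at_s = 5, dur_s = 0.1, amp_sd = 6))
  ev <- detect_ripple_events(lfp6)
  expect_equal(nrow(ev), 1)
  expect_true(ev$start_s < 5.05 && ev$end_s > 5.05)  # contains burst midpoint
  expect_gte(ev$peak_z, 4)
  lfp3 <- noise_lfp(dur_s = 10, seed = 16,
                    bursts = data.frame(at_s = 5, dur_s = 0.1, amp_sd = 3))
  expect_equal(nrow(detect_ripple_events(lfp3)), 0)
})

test_that("bursts 500 ms apart stay two events and counts fall with threshold", {
  lfp <- noise_lfp(dur_s = 10, seed = 16,
                   bursts = data.frame(at_s = c(5, 5.5), dur_s = 0.1,
                                       amp_sd = c(6, 6)))
  ev <- detect_ripple_events(lfp)
  expect_equal(nrow(ev), 2)
  counts <- vapply(c(3, 4, 5, 6, 8), function(th)
    nrow(detect_ripple_events(lfp, peak_thresh_sd = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the detector recovers generated ripple bursts", {
  d <- small_day()
  lfp <- generate_lfp(d$pre$position, d$cfg)
  truth <- attr(lfp, "ripple_truth")
  ev <- detect_ripple_events(lfp)
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(ev$peak_s >= truth$start_s[i] & ev$peak_s <= truth$end_s[i]),
    logical(1))
  expect_gte(mean(hit), 0.9)
  expect_true(all(ev$peak_z >= 4))
  expect_true(all(ev$start_s <= ev$peak_s & ev$peak_s <= ev$end_s))
})

test_that("spectra localise a pure tone and normalise correctly", {
  fs <- 2000
  tt <- seq(0, 10, by = 1 / fs)
  lfp <- crossact:::new_lfp(sin(2 * pi * 8 * tt) + 0.01 * rnorm(length(tt)), fs)
  sp <- lfp_spectra(lfp)
  expect_lt(abs(sp$freq_hz[which.max(sp$psd)] - 8), 0.5)
  inband <- sp$freq_hz >= 0.5 & sp$freq_hz <= 400
  expect_equal(sum(sp$psd_norm[inband]), 1, tolerance = 1e-9)
})

test_that("rotation epochs are theta-dominated, not ripple-dominated", {
  d <- small_day()
  lfp <- generate_lfp(d$pre$position, d$cfg)
  sp <- lfp_spectra(lfp, intervals = d$pre$ground_truth$rotations)
  expect_gt(band_power(sp, c(6, 10)), band_power(sp, c(100, 250)))
})

test_that("behaviour summary geometry is right", {
  pos0 <- data.frame(t_s = seq(0, 10, by = 0.03), x_cm = 0, y_cm = 0, hd_deg = 0)
  bs <- behavior_summary(pos0, empty_rot <- data.frame())
  expect_equal(bs$pct_time_facing_opening, 100)
  set.seed(2)
  posu <- data.frame(t_s = seq(0, 300, by = 0.03), x_cm = 0, y_cm = 0,
                     hd_deg = runif(10001, -180, 180))
  bsu <- behavior_summary(posu, data.frame())
  expect_equal(bsu$pct_time_facing_opening, 25, tolerance = 2)
  d <- small_day()
  rot <- detect_rotation_events(d$pre$position)
  bs2 <- behavior_summary(d$pre$position, rot)
  expect_equal(bs2$n_rotation_events, nrow(d$pre$ground_truth$rotations))
})
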