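# Rate curves, spatial information, and shuffle-based tuning statistics.

test_that("linear rate curves conserve spike counts and handle empty cells", {
  d <- small_day()
  laps <- d$track$ground_truth$laps
  lapsA <- laps[laps$trajectory == "A_to_B", ]
  pos <- d$track$position
  # empty spike train -> all-zero curve
  cv0 <- linear_rate_curve(numeric(0), pos, lapsA)
  expect_true(all(cv0$rate_hz == 0, na.rm = TRUE))
  # raw counts equal the number of in-lap spikes landing inside the bins
  spk <- d$track$spikes$t_s[d$track$spikes$cell_id == d$pop$track$cell_id[1]]
  cv <- linear_rate_curve(spk, pos, lapsA)
  st <- spk[crossact:::in_intervals(spk, lapsA)]
  x <- crossact:::sample_at(st, pos$t_s, pos$x_cm)
  expect_equal(sum(cv$count), sum(x >= 10 & x < 190))
  expect_true(all(cv$rate_hz >= 0, na.rm = TRUE))
  # all-excluded occupancy errors
  expect_error(linear_rate_curve(spk, pos, data.frame(start_s = 1e6, end_s = 1e6 + 1)),
               "occupancy")
})

test_that("circular curves peak where the spikes are and wrap equivariantly", {
  tt <- seq(0, 36, by = 1 / 33)
  hd <- (tt * 10) %% 360                     # steady 10 deg/s sweep
  pos <- data.frame(t_s = tt, x_cm = 0, y_cm = 0, hd_deg = ((hd + 180) %% 360) - 180)
  ev <- data.frame(start_s = 0, end_s = 36)
  spk <- tt[abs(hd - 90) < 2]                # all spikes near 90 degrees
  cv <- circular_rate_curve(spk, pos, ev)
  expect_equal(cv$bin_deg[which.max(cv$rate_hz)], 92.5)
  # global rotation of head direction and spikes rotates the curve
  rot <- 90
  pos2 <- pos
  pos2$hd_deg <- ((pos$hd_deg + rot + 180) %% 360) - 180
  cv2 <- circular_rate_curve(spk, pos2, ev)
  shift <- rot / 5
  nb <- length(cv$rate_hz)
  expect_equal(cv2$rate_hz, cv$rate_hz[((seq_len(nb) - 1 - shift) %% nb) + 1],
               tolerance = 1e-9)
})

test_that("2-D rate maps conserve mass and localise", {
  d <- small_day()
  ev <- d$pre$ground_truth$rotations
  pos <- d$pre$position
  id <- d$pop$box$cell_id[1]
  spk <- d$pre$spikes$t_s[d$pre$spikes$cell_id == id]
  m <- rate_map_2d(spk, pos, ev)
  expect_equal(sum(m$count), sum(crossact:::in_intervals(spk, ev)))
  expect_true(all(m$rate[!is.na(m$rate)] >= 0))
  m0 <- rate_map_2d(numeric(0), pos, ev)
  expect_true(all(m0$rate[!is.na(m0$rate)] == 0))
})

test_that("spatial information matches closed forms and brute force", {
  # uniform rate, equal occupancy -> 0 bits/spike
  expect_equal(spatial_information(rep(3, 10), rep(1, 10)), 0)
  # two equal bins, rates (2r, 0) -> 1 bit/spike
  expect_equal(spatial_information(c(4, 0), c(1, 1)), 1)
  # four equal bins, all mass in one -> 2 bits/spike
  expect_equal(spatial_information(c(8, 0, 0, 0), rep(1, 4)), 2)
  # random curves agree with a direct evaluation of the sum
  set.seed(42)
  for (i in 1:20) {
    r <- rgamma(30, 1.5); p_occ <- rgamma(30, 2)
    brute <- {
      p <- p_occ / sum(p_occ); rbar <- sum(p * r)
      sum(ifelse(r > 0, p * (r / rbar) * log2(r / rbar), 0))
    }
    expect_equal(spatial_information(r, p_occ, min_occupancy_s = 0), brute,
                 tolerance = 1e-12)
  }
  # zero mean rate is undefined
  expect_true(is.na(spatial_information(rep(0, 5), rep(1, 5))))
})

test_that("lap consistency is 1 for identical laps and near 0 for noise", {
  base <- dnorm(seq(-3, 3, length.out = 40))
  expect_equal(lap_consistency(list(base, base, base)), 1)
  # an anti-correlated pair contributes -1
  expect_equal(lap_consistency(list(base, max(base) - base)), -1)
  set.seed(1)
  vals <- replicate(200, lap_consistency(list(rpois(40, 2), rpois(40, 2))))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.02)
})

test_that("the Rayleigh test is calibrated and monotone in concentration", {
  ev <- data.frame(start_s = 0, end_s = 100)
  pos <- data.frame(t_s = seq(0, 100, by = 0.03), x_cm = 0, y_cm = 0,
                    hd_deg = 90)
  # perfectly concentrated spikes: extremely small p
  expect_lt(rayleigh_hd_test(seq(1, 99, length.out = 40), pos, ev)$p_value, 1e-6)
  # uniform head direction: p approximately Uniform(0, 1)
  set.seed(5)
  np <- 300
  ps <- replicate(np, {
    posu <- data.frame(t_s = seq(0, 100, length.out = 3000), x_cm = 0,
                       y_cm = 0, hd_deg = runif(3000, -180, 180))
    rayleigh_hd_test(sort(runif(40, 0, 100)), posu, ev)$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / np))
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
  # below the minimum spike count the test is not run
  expect_true(is.na(rayleigh_hd_test(c(1, 2, 3), pos, ev)$p_value))
})

test_that("rotation consistency flags tuned cells and stays exchangeable", {
  d <- small_day()
  rot <- d$pre$ground_truth$rotations
  sbc <- split_spikes(d$pre$spikes)
  tuned <- as.character(d$pop$box$cell_id[1:4])
  for (id in tuned) {
    rc <- rotation_consistency(sbc[[id]], d$pre$position, rot,
                               n_shuffles = 300, seed = 9)
    expect_gt(rc$z, 1.645)
    expect_true(rc$significant)
  }
  # invariance under event reordering
  id <- tuned[1]
  rc1 <- rotation_consistency(sbc[[id]], d$pre$position, rot, 200, seed = 3)
  rc2 <- rotation_consistency(sbc[[id]], d$pre$position,
                              rot[rev(seq_len(nrow(rot))), ], 200, seed = 3)
  expect_equal(rc2$statistic, rc1$statistic, tolerance = 1e-12)
  # fewer than 2 active events is undefined, reported with a reason
  rc0 <- rotation_consistency(c(rot$start_s[1] + 0.1), d$pre$position, rot, 50)
  expect_false(rc0$significant)
  expect_match(rc0$reason, "fewer than 2")
})

test_that("rotation-consistency null is calibrated near the nominal level", {
  d <- small_day()
  rot <- d$pre$ground_truth$rotations
  Tend <- max(d$pre$position$t_s)
  set.seed(31)
  n <- 100
  zs <- replicate(n, {
    spk <- sort(runif(rpois(1, 1.5 * Tend), 0, Tend))
    rotation_consistency(spk, d$pre$position, rot, n_shuffles = 200,
                         seed = sample.int(1e6, 1))$z
  })
  frac <- mean(zs > 1.645, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.01)
})

test_that("demonstrator-position tuning has power and honest nulls", {
  d <- small_day()
  laps <- d$track$ground_truth$laps
  lapsA <- laps[laps$trajectory == "A_to_B", ]
  demo <- d$track$position[, c("t_s", "x_cm")]
  # positive control: observer spikes generated from the demo position
  set.seed(12)
  lam <- function(x) 0.2 + 8 * exp(-(x - 120)^2 / (2 * 8^2))
  tt <- d$track$position$t_s
  rate <- lam(d$track$position$x_cm)
  rate[!crossact:::in_intervals(tt, lapsA)] <- 0.2
  spk <- crossact:::poisson_spikes_from_rate(tt, rate)
  r <- demo_position_tuning(spk, demo, lapsA, n_shuffles = 200, seed = 4)
  expect_gt(r$z_si, 5)
  # the null shuffle with shift ~0 reproduces the actual statistic's scale
  expect_true(is.finite(r$si) && r$si > 0)
})
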