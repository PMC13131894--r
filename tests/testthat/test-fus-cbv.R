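test_that("SVD clutter filtering removes exactly the leading subspace", {
  set.seed(31)
  d <- c(12, 10, 40)
  blk <- array(rnorm(prod(d)), d)
  # cutoff 0: identity
  expect_equal(svd_clutter_filter(blk, clutter_filter_spec(0, 40)), blk)
  # rank-1 stack of identical frames annihilated by cutoff 1
  frame <- matrix(rnorm(12 * 10), 12, 10)
  rk1 <- array(rep(frame, 40), d)
  out <- svd_clutter_filter(rk1, clutter_filter_spec(1, 40))
  expect_lt(sqrt(sum(out^2)), 1e-8 * sqrt(sum(rk1^2)))
  # energy conservation: removed and kept components are orthogonal
  for (cutoff in c(1, 5, 15)) {
    kept <- svd_clutter_filter(blk, clutter_filter_spec(cutoff, 40))
    removed <- blk - kept
    expect_equal(sum(blk^2), sum(kept^2) + sum(removed^2),
                 tolerance = 1e-6)
  }
  expect_error(svd_clutter_filter(blk, clutter_filter_spec(45, 50)),
               class = "dgfus_invalid_parameter")
})

test_that("power Doppler is the summed squared filtered signal", {
  d <- c(8, 6, 50)
  expect_true(all(power_doppler(array(0, d)) == 0))
  set.seed(32)
  blk <- array(rnorm(prod(d)), d)
  # quadratic in amplitude
  expect_equal(power_doppler(2 * blk), 4 * power_doppler(blk))
  # i.i.d. noise: per-pixel mean ~ block_len * sigma^2
  big <- array(rnorm(20 * 20 * 400, sd = 1.5), c(20, 20, 400))
  expect_equal(mean(power_doppler(big)), 400 * 1.5^2, tolerance = 0.02)
})

test_that("percent CBV change follows its defining arithmetic", {
  pd <- array(10, c(3, 3, 20))
  ser <- cbv_series(pd, 1:5)
  expect_true(all(ser$rel == 0))
  pd2 <- pd; pd2[, , 11:20] <- 13
  ser2 <- cbv_series(pd2, 1:5)
  expect_true(all(abs(ser2$rel[, , 11:20] - 30) < 1e-12))
  # zero-baseline pixels flagged as missing
  pd3 <- pd; pd3[1, 1, ] <- 0
  ser3 <- cbv_series(pd3, 1:5)
  expect_identical(ser3$n_zero_baseline, 1L)
  expect_true(all(is.na(ser3$rel[1, 1, ])))
  expect_error(cbv_series(pd, integer(0)), class = "dgfus_invalid_parameter")
})

test_that("activation maps correlate pixels against the lagged stimulus", {
  ses <- session_spec()
  stim <- synth_stimulus_vector(ses)
  v <- as.numeric(stim$values)
  pd <- array(0, c(4, 4, 270))
  pd[1, 1, ] <- 5 + 2 * v                        # proportional to stimulus
  pd[2, 2, ] <- 5 - 2 * v                        # anti-correlated
  shifted <- c(rep(0, 3), v[1:267])              # response delayed 3 s
  pd[3, 3, ] <- 5 + shifted
  pd[4, 4, ] <- 5                                # constant
  ser <- cbv_series(pd, 1:30)
  am0 <- activation_map(ser, stim, lag = 0)
  expect_equal(am0$r[1, 1], 1)
  expect_true(am0$mask[1, 1])
  expect_equal(am0$r[2, 2], -1)
  expect_false(am0$mask[2, 2])                   # one-sided threshold
  expect_equal(am0$r[4, 4], 0)                   # zero variance -> 0, unmasked
  # exhaustive lag sweep localizes the 3 s delay
  lags <- -5:8
  rs <- sapply(lags, function(l)
    activation_map(ser, stim, lag = l)$r[3, 3])
  expect_equal(lags[which.max(rs)], 3)
  expect_equal(max(rs), 1, tolerance = 1e-9)
  # truncation bookkeeping
  expect_equal(activation_map(ser, stim, lag = 4)$n_samples, 266)
  expect_error(activation_map(ser, stim, lag = 265),
               class = "dgfus_invalid_parameter")
})

test_that("activated area counts thresholded pixels per lag", {
  ses <- session_spec()
  stim <- synth_stimulus_vector(ses)
  pd <- array(0, c(5, 5, 270))
  ser <- cbv_series(pd + 1, 1:30)
  av0 <- activated_area(ser, stim, lags = -2:2)
  expect_true(all(av0$n_pixels == 0))            # constant series
  v <- as.numeric(stim$values)
  pd[2:3, 2:3, ] <- rep(5 + v, each = 4)
  ser2 <- cbv_series(pd + 1, 1:30)
  av <- activated_area(ser2, stim, lags = -2:2,
                       pixel_area_mm2 = 0.01)
  expect_equal(av$n_pixels[av$lag == 0], 4)
  expect_equal(av$area_mm2[av$lag == 0], 0.04)
  expect_equal(area_peak_lag(av), 0)
  # region restriction
  reg <- matrix(FALSE, 5, 5); reg[2, 2] <- TRUE
  avr <- activated_area(ser2, stim, lags = 0, mask_region = reg)
  expect_equal(avr$n_pixels, 1)
})

test_that("epoch averaging recovers the generator's response and latency", {
  ses <- session_spec(n_samples = 140, stim_onsets = c(30, 64, 98),
                      stim_duration = 10)
  stim <- synth_stimulus_vector(ses)
  hemo <- hemodynamics_spec(0.2)
  act <- matrix(FALSE, 16, 16); act[5:10, 6:11] <- TRUE
  fs <- synth_functional_session(16, 16, ses, hemo, active_mask = act,
                                 seed = 41)
  # cutoff matched to the generator's tissue rank so the blood modulation
  # itself is preserved; the protocol cutoff of 30 is exercised elsewhere
  ser <- cbv_series(pd_sequence(fs, clutter_filter_spec(4, 150)), 1:30)
  am <- activation_map(ser, stim, lag = 1)
  ctr <- activation_argmax(am)
  expect_true(act[ctr[1], ctr[2]])
  # amplitude is read at the region centre so the 5x5 ROI lies fully
  # inside the active region (the correlation argmax may sit at its edge)
  rr <- roi_response(ser, c(7, 8), ses)
  expect_lte(abs(rr$peak_latency - 4), 1)
  expect_equal(rr$peak, 20, tolerance = 0.2)     # percent, chi-square noise
  expect_identical(ncol(rr$epochs), 3L)
  # identical epochs average to any single epoch
  trace <- rep(0, 140); for (on in ses$stim_onsets)
    trace[(on + 1):(on + 15)] <- trace[(on + 1):(on + 15)] + seq(1, 0.3, length.out = 15)
  pdt <- array(rep(1 + trace, each = 4), c(2, 2, 140))
  sert <- cbv_series(pdt, 1:30)
  rrt <- roi_response(sert, c(1, 1), ses, window = 1)
  one <- sert$rel[1, 1, (ses$stim_onsets[1] - 5 + 1):(ses$stim_onsets[1] + 25 + 1)]
  expect_equal(rrt$epoch_mean, one)
})

test_that("contralateral responses are scaled down and delayed", {
  ses <- session_spec(n_samples = 140, stim_onsets = c(30, 64, 98),
                      stim_duration = 10)
  hemo <- hemodynamics_spec(0.3, contralateral_amplitude_ratio = 0.5,
                            contralateral_extra_lag = 1)
  ipsi <- matrix(FALSE, 16, 16); ipsi[5:10, 2:7] <- TRUE
  contra <- matrix(FALSE, 16, 16); contra[5:10, 10:15] <- TRUE
  fs <- synth_functional_session(16, 16, ses, hemo, active_mask = ipsi,
                                 contra_mask = contra, seed = 51)
  ser <- cbv_series(pd_sequence(fs, clutter_filter_spec(4, 150)), 1:30)
  rr_i <- roi_response(ser, c(7, 4), ses)
  rr_c <- roi_response(ser, c(7, 12), ses)
  expect_equal(rr_i$peak, 30, tolerance = 0.2)
  expect_equal(rr_c$peak / rr_i$peak, 0.5, tolerance = 0.25)
  expect_gte(rr_c$peak_latency, rr_i$peak_latency)
})

test_that("RF-domain pipeline localizes a modulated vessel end to end", {
  td <- transducer_spec(n_elements = 32)
  vess <- data.frame(x_min = -0.5e-3, x_max = 0.5e-3, z_min = 2.2e-3,
                     z_max = 2.8e-3, vx = 0, vz = 15e-3)
  ph <- make_phantom(500, c(-1e-3, 1e-3, 1.6e-3, 3.4e-3),
                     vessel_layout = vess, blood_density = 900, seed = 5)
  ses <- session_spec(functional_rate = 1, n_samples = 24,
                      stim_onsets = c(4, 16), stim_duration = 4)
  stim <- synth_stimulus_vector(ses)
  hemo <- hemodynamics_spec(0.6, peak_time = 2, shape = 3)
  sch <- plane_wave_scheme(3, 3)
  g <- beam_grid(td, c(1.8e-3, 3.2e-3), x_range = c(-0.7e-3, 0.7e-3))
  nfr <- 15; fr_dt <- 0.002
  pd <- array(0, c(length(g$z), length(g$x), ses$n_samples))
  for (k in seq_len(ses$n_samples)) {
    blk <- array(0, c(length(g$z), length(g$x), nfr))
    for (f in seq_len(nfr)) {
      t <- (k - 1) + (f - 1) * fr_dt
      pht <- evolve_phantom(ph, hemo = hemo, stim = stim, t = t)
      blk[, , f] <- simulate_compound_frame(pht, td, sch, g,
                                            noise_sd = 0.05,
                                            seed = k * 1000 + f)$values
    }
    pd[, , k] <- power_doppler(
      svd_clutter_filter(blk, clutter_filter_spec(4, nfr)))
  }
  ser <- cbv_series(pd, 1:4)
  am <- activation_map(ser, stim, lag = 1, threshold = 0.2)
  expect_gt(sum(am$mask), 50)
  cen <- colMeans(which(am$mask, arr.ind = TRUE))
  truth <- c(mean(which(g$z >= vess$z_min & g$z <= vess$z_max)),
             mean(which(g$x >= vess$x_min & g$x <= vess$x_max)))
  expect_lt(sqrt(sum((cen - truth)^2)), 2)
})
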