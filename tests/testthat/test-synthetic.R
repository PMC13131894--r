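test_that("phantom generation is seeded and respects its extent", {
  ext <- c(-4.5e-3, 4.5e-3, 0, 5e-3)      # 9 x 5 mm
  ph <- make_phantom(5, ext, seed = 42)
  n <- nrow(ph$scatterers)
  # Poisson(225): 225 +/- 6 sd
  expect_gt(n, 225 - 6 * 15); expect_lt(n, 225 + 6 * 15)
  expect_true(all(ph$scatterers$x >= ext[1] & ph$scatterers$x <= ext[2]))
  expect_true(all(ph$scatterers$z >= ext[3] & ph$scatterers$z <= ext[4]))
  expect_true(all(ph$scatterers$compartment == "tissue"))
  ph2 <- make_phantom(5, ext, seed = 42)
  expect_identical(ph, ph2)
  expect_error(make_phantom(5, c(0, 0, 0, 1e-3)),
               class = "dgfus_invalid_parameter")
})

test_that("blood scatterers are confined to vessel boxes", {
  vess <- data.frame(x_min = -1e-3, x_max = 1e-3, z_min = 2e-3,
                     z_max = 3e-3, vx = 0, vz = 10e-3)
  ph <- make_phantom(50, c(-2e-3, 2e-3, 1e-3, 4e-3), vessel_layout = vess,
                     seed = 1)
  b <- ph$scatterers[ph$scatterers$compartment == "blood", ]
  expect_gt(nrow(b), 0)
  expect_true(all(b$x >= vess$x_min & b$x <= vess$x_max))
  expect_true(all(b$z >= vess$z_min & b$z <= vess$z_max))
})

test_that("push displacement field evolves scatterers as prescribed", {
  push <- arf_push_spec(focus = c(0, 3e-3), lateral_sigma = 0.5e-3,
                        axial_sigma = 0.4e-3, peak_displacement = 2,
                        push_window = c(1e-3, 81e-3))
  ph <- point_phantom(x = c(0, 3e-3), z = c(3e-3, 3e-3), refl = c(1, 1))
  # before the push: unchanged
  e0 <- evolve_phantom(ph, push = push, t = 0)
  expect_identical(e0$scatterers$z, ph$scatterers$z)
  # at the focus with envelope 1: exactly peak displacement
  e1 <- evolve_phantom(ph, push = push, t = 0.05)
  expect_equal(e1$scatterers$z[1] - ph$scatterers$z[1], 2e-6)
  # >= 5 sigma off-focus: Gaussian tail bound
  shift_far <- e1$scatterers$z[2] - ph$scatterers$z[2]
  expect_lt(abs(shift_far), 1e-5 * 2e-6)
})

test_that("blood advection wraps within the vessel and modulation scales power", {
  vess <- data.frame(x_min = -1e-3, x_max = 1e-3, z_min = 2e-3,
                     z_max = 2.5e-3, vx = 0, vz = 10e-3)
  ph <- make_phantom(20, c(-2e-3, 2e-3, 1e-3, 4e-3), vessel_layout = vess,
                     blood_density = 200, seed = 2)
  ses <- session_spec(n_samples = 60, stim_onsets = c(10, 30),
                      stim_duration = 10)
  stim <- synth_stimulus_vector(ses)
  hemo <- hemodynamics_spec(0.5)
  ev <- evolve_phantom(ph, hemo = hemo, stim = stim, t = 14)
  b0 <- ph$scatterers$compartment == "blood"
  expect_true(all(ev$scatterers$z[b0] >= vess$z_min &
                  ev$scatterers$z[b0] <= vess$z_max))
  # power gain = refl variance ratio equals 1 + a * response(t)
  gain2 <- ev$scatterers$refl[b0]^2 / ph$scatterers$refl[b0]^2
  resp <- expected_response(hemo, stim)
  expect_equal(unique(round(gain2, 10)), round(1 + 0.5 * resp[15], 10))
  # tissue reflectivity untouched
  expect_identical(ev$scatterers$refl[!b0], ph$scatterers$refl[!b0])
})

test_that("simulated RF places a point echo at its analytic delay", {
  td <- transducer_spec()
  ph <- point_phantom(x = 0, z = 10e-3)
  rf <- simulate_rf(ph, td, 0)
  ce <- which.min(abs(element_positions(td)))
  tr <- rf$samples[, ce]
  i <- which.max(abs(tr))
  t_peak <- (i - 1) / td$sampling_freq
  # round trip 2 z / c plus half the 1.5-cycle pulse
  t_expect <- 2 * 0.010 / td$sound_speed + 0.75 / td$carrier_freq
  expect_lt(abs(t_peak - t_expect), 2 / td$sampling_freq)
})

test_that("RF simulation is linear in reflectivity and mirror-symmetric", {
  td <- small_transducer(16)
  a <- point_phantom(x = -0.3e-3, z = 2e-3, refl = 1.3)
  b <- point_phantom(x = 0.4e-3, z = 2.5e-3, refl = -0.7)
  ab <- a; ab$scatterers <- rbind(a$scatterers, b$scatterers)
  ns <- 500L
  rf_a <- simulate_rf(a, td, 2, n_samples = ns)
  rf_b <- simulate_rf(b, td, 2, n_samples = ns)
  rf_ab <- simulate_rf(ab, td, 2, n_samples = ns)
  expect_equal(rf_ab$samples, rf_a$samples + rf_b$samples, tolerance = 1e-12)
  # mirroring x and negating the angle mirrors the element axis
  m <- ab; m$scatterers$x <- -m$scatterers$x
  rf_m <- simulate_rf(m, td, -2, n_samples = ns)
  expect_equal(rf_m$samples, rf_ab$samples[, rev(seq_len(td$n_elements))],
               tolerance = 1e-10)
  # scatterers behind the array are excluded with a warning
  bad <- ab; bad$scatterers$z[1] <- -1e-3
  expect_warning(rf_bad <- simulate_rf(bad, td, 0, n_samples = ns),
                 "behind the array")
  expect_identical(rf_bad$n_excluded, 1L)
})

test_that("noise-only RF has the requested variance", {
  td <- small_transducer(16)
  empty <- point_phantom(x = 0, z = 1e-3, refl = 0)
  rf <- simulate_rf(empty, td, 0, noise_sd = 0.5, seed = 9,
                    n_samples = 4000L)
  expect_equal(var(as.vector(rf$samples)), 0.25, tolerance = 0.02)
})

test_that("stimulus vectors follow the half-open onset convention", {
  ses <- session_spec()
  stim <- synth_stimulus_vector(ses)
  expect_length(stim$values, 270)
  expect_identical(sum(stim$values), 70L)     # 7 x 10 s at 1 Hz
  ses0 <- session_spec(stim_onsets = numeric(0))
  expect_identical(sum(synth_stimulus_vector(ses0)$values), 0L)
  ses1 <- session_spec(n_samples = 30, stim_onsets = 0, stim_duration = 10)
  v <- synth_stimulus_vector(ses1)$values
  expect_identical(which(v == 1L), 1:10)      # indices 0..9 in time
})

test_that("synthetic EMG bursts land at the prescribed latency", {
  cm <- cmap_spec(latency = 65, amplitude = 0.5, noise_sd = 0)
  rec <- synth_emg(c(1, 2), cm, fs = 10e3, duration = 3, seed = 1)
  t_ms <- (seq_along(rec$samples) - 1) / rec$fs * 1000
  # peak of the burst itself (before the 80 ms offset artifact)
  seg1 <- abs(rec$samples[t_ms >= 1050 & t_ms < 1078])
  peak_ms <- t_ms[t_ms >= 1050 & t_ms < 1078][which.max(seg1)] - 1000
  expect_gte(peak_ms, 64); expect_lte(peak_ms, 67)
  # time invariance: pulse 2 is pulse 1 shifted by exactly 1 s
  i1 <- which(t_ms >= 1000 & t_ms < 1200)
  expect_lt(max(abs(rec$samples[i1 + 10000] - rec$samples[i1])), 1e-8)
  # amplitude 0: nothing inside the detection window
  cm0 <- cmap_spec(latency = 65, amplitude = 0, noise_sd = 0)
  rec0 <- synth_emg(1, cm0, fs = 10e3, duration = 2, seed = 1)
  t0 <- (seq_along(rec0$samples) - 1) / rec0$fs
  expect_true(all(rec0$samples[t0 > 1.050 & t0 < 1.079] == 0))
  # burst beyond the trace end is rejected
  expect_error(synth_emg(1.99, cm, fs = 10e3, duration = 2),
               class = "dgfus_invalid_parameter")
})

test_that("keypoint tracks encode their analytic peak velocity", {
  sp <- list(fps = 200, duration = 4, pulse_onsets = c(1, 2.5),
             peak_velocity = 20, excursion_duration = 0.2)
  kp <- synth_tracks("keypoints", sp, seed = 1)
  v <- paw_velocity(kp, "hindpaw_paw", pulse_onsets = sp$pulse_onsets)
  expect_equal(nrow(v$pulse_peaks), 2)
  expect_equal(v$pulse_peaks$peak_speed, c(20, 20), tolerance = 0.05)
  # static pose: zero everywhere
  kp0 <- synth_tracks("keypoints", list(fps = 100, duration = 2), seed = 1)
  v0 <- paw_velocity(kp0, "hindpaw_paw")
  expect_true(all(v0$speed == 0))
})

test_that("open-field walks stay in the arena and respond to center affinity", {
  tr <- synth_tracks("openfield", list(duration = 120, step_sd = 2), seed = 4)
  expect_true(all(tr$x_cm >= 0 & tr$x_cm <= 40))
  expect_true(all(tr$y_cm >= 0 & tr$y_cm <= 40))
  # pinned to the centre
  pin <- synth_tracks("openfield",
                      list(duration = 60, step_sd = 0, center_affinity = 1),
                      seed = 4)
  expect_true(all(abs(pin$x_cm - 20) < 1e-9))
  tz <- time_in_center(pin)
  expect_equal(tz$periphery_time, 0)
  # determinism
  tr2 <- synth_tracks("openfield", list(duration = 120, step_sd = 2), seed = 4)
  expect_identical(tr, tr2)
})
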