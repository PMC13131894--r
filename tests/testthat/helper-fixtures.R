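# Shared reduced-scale fixtures: a 64-element probe and a small dense
# speckle phantom keep the RF-domain tests fast while preserving the
# physics (developed speckle, carrier-band images).

small_transducer <- function(n_elements = 64) {
  transducer_spec(n_elements = n_elements)
}

# speckle phantom dense enough for developed speckle (~10 scatterers per
# resolution cell at 15.625 MHz)
small_phantom <- function(seed = 3, density = 1500,
                          extent = c(-1.2e-3, 1.2e-3, 1.6e-3, 3.4e-3),
                          vessel_layout = NULL, blood_density = density) {
  make_phantom(density, extent, vessel_layout = vessel_layout,
               blood_density = blood_density, seed = seed)
}

small_grid <- function(td, z_range = c(1.9e-3, 3.1e-3),
                       x_range = c(-0.9e-3, 0.9e-3)) {
  beam_grid(td, z_range, x_range = x_range)
}

# one-scatterer phantom for delay / PSF oracles
point_phantom <- function(x = 0, z = 3e-3, refl = 1) {
  structure(list(
    scatterers = data.frame(x = x, z = z, refl = refl,
                            compartment = "tissue", vessel = NA_integer_),
    vessel_layout = NULL,
    extent = c(min(x) - 1e-3, max(x) + 1e-3, 0, max(z) + 1e-3)
  ), class = "phantom")
}

# band-limited analytic test signal with an exact fractional delay:
# Gaussian-enveloped carrier at fc_frac cycles/sample, envelope centred
# mid-vector, sigma in samples
delayed_burst <- function(n, delay, fc_frac = 0.25, sigma = 12) {
  t <- seq_len(n) - n / 2
  exp(-((t - delay)^2) / (2 * sigma^2)) *
    cos(2 * pi * fc_frac * (t - delay))
}

# push recovery mini-pipeline shared by displacement tests and the
# dose-ladder acceptance run
run_displacement_mini <- function(peak_um, seed = 3, n_frames = 3,
                                  noise_sd = 0) {
  td <- small_transducer()
  ph <- small_phantom(seed = seed)
  push <- arf_push_spec(focus = c(0, 2.5e-3), lateral_sigma = 0.6e-3,
                        axial_sigma = 0.5e-3, peak_displacement = peak_um,
                        push_window = c(1.2e-3, 81.2e-3))
  sch <- plane_wave_scheme(6, 3)
  g <- small_grid(td, z_range = c(1.9e-3, 3.1e-3))
  dt <- 0.768e-3
  frames <- lapply(seq_len(n_frames), function(fi) {
    t <- (fi - 1) * dt
    simulate_compound_frame(evolve_phantom(ph, push = push, t = t),
                            td, sch, g, noise_sd = noise_sd,
                            seed = seed * 100 + fi, timestamp = t)
  })
  maps <- displacement_sequence(frames, ncc_spec(), td)
  fz <- which.min(abs(g$z - push$focus[2]))
  fx <- which.min(abs(g$x - push$focus[1]))
  roi <- roi_displacement(maps, c(fz, fx), 5)
  list(maps = maps, roi = roi, grid = g, push = push,
       focus_px = c(fz, fx), transducer = td)
}
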