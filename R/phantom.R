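#' Acoustic-radiation-force push specification
#'
#' A Gaussian focal displacement field with a first-order temporal envelope:
#' displacement rises toward `peak_displacement` with time constant `rise`
#' while the push is on (`push_window`), then decays with `decay`.
#'
#' @param focus `(x, z)` focal coordinates, m.
#' @param lateral_sigma,axial_sigma Gaussian widths of the push field, m.
#' @param peak_displacement Peak axial displacement at the focus, micrometres.
#' @param rise,decay Temporal time constants, s; `rise = 0` gives a step.
#' @param push_window `(t_on, t_off)` push interval, s.
#' @return An object of class `arf_push_spec`.
#' @export
arf_push_spec <- function(focus = c(0, 3e-3), lateral_sigma = 0.6e-3,
                          axial_sigma = 0.5e-3, peak_displacement = 2.0,
                          rise = 0, decay = Inf,
                          push_window = c(0, 80e-3)) {
  if (peak_displacement < 0) stop_invalid("peak_displacement must be >= 0")
  if (lateral_sigma <= 0 || axial_sigma <= 0)
    stop_invalid("push sigmas must be positive")
  structure(list(focus = focus, lateral_sigma = lateral_sigma,
                 axial_sigma = axial_sigma,
                 peak_displacement = peak_displacement,
                 rise = rise, decay = decay, push_window = push_window),
            class = "arf_push_spec")
}

#' Evaluate the push displacement field (micrometres)
#'
#' @param push An [arf_push_spec()].
#' @param x,z Coordinates, m (vectorized, recycled together).
#' @param t Time, s (scalar).
#' @return Axial displacement in micrometres (positive = deeper).
#' @export
push_displacement <- function(push, x, z, t) {
  g <- exp(-((x - push$focus[1])^2 / (2 * push$lateral_sigma^2) +
             (z - push$focus[2])^2 / (2 * push$axial_sigma^2)))
  push$peak_displacement * g * push_envelope(push, t)
}

push_envelope <- function(push, t) {
  t_on <- push$push_window[1]; t_off <- push$push_window[2]
  if (t < t_on) return(0)
  ramp <- function(dt) if (push$rise <= 0) 1 else 1 - exp(-dt / push$rise)
  if (t <= t_off) return(ramp(t - t_on))
  e_off <- ramp(t_off - t_on)
  if (!is.finite(push$decay)) return(e_off)
  e_off * exp(-(t - t_off) / push$decay)
}

#' Hemodynamic response specification for the generator
#'
#' The blood-signal power in the active region is modulated by
#' `1 + response_amplitude * response(t)`, where each stimulation period
#' elicits one stereotyped response: the kernel, gamma-shaped with its
#' mode at `peak_time` (4 s by default) and normalized to a peak of 1, is
#' convolved with the train of stimulation *onsets*.  An event-like
#' response that peaks a few seconds into the 10 s stimulation and then
#' relaxes reflects the adaptation seen in stimulus-locked CBV recordings;
#' the kernel is nonetheless a generator stand-in for an unknown
#' FUS-evoked hemodynamic response, not a measured quantity.
#'
#' @param response_amplitude Fractional peak change in CBV (0.2 = 20%).
#' @param kernel Discrete non-negative impulse response sampled at the
#'   functional rate; `NULL` for the default gamma kernel.  It is always
#'   rescaled to a peak of 1 so `response_amplitude` is the peak
#'   fractional change.
#' @param peak_time Mode of the default gamma kernel, s.
#' @param shape Gamma shape parameter of the default kernel; the default
#'   of 3 gives a tail that keeps the response elevated 10-20 s past the
#'   stimulation onset, matching the slow relaxation seen in
#'   stimulus-locked CBV responses.
#' @param functional_rate Sampling rate of the kernel, Hz.
#' @param contralateral_amplitude_ratio,contralateral_extra_lag Optional
#'   secondary (contralateral) response scaling and added delay, s.
#' @return An object of class `hemodynamics_spec`.
#' @export
hemodynamics_spec <- function(response_amplitude = 0.2, kernel = NULL,
                              peak_time = 4, shape = 3,
                              functional_rate = 1,
                              contralateral_amplitude_ratio = 0,
                              contralateral_extra_lag = 1) {
  if (response_amplitude < 0) stop_invalid("response_amplitude must be >= 0")
  if (is.null(kernel)) {
    rate_b <- peak_time / (shape - 1)           # gamma mode = (shape-1)*b
    t <- seq(0, peak_time + 6 * rate_b * sqrt(shape), by = 1 / functional_rate)
    kernel <- t^(shape - 1) * exp(-t / rate_b)
  }
  if (any(kernel < 0)) stop_invalid("kernel must be non-negative")
  if (max(kernel) > 0) kernel <- kernel / max(kernel)
  structure(list(response_amplitude = response_amplitude, kernel = kernel,
                 functional_rate = functional_rate,
                 contralateral_amplitude_ratio = contralateral_amplitude_ratio,
                 contralateral_extra_lag = contralateral_extra_lag),
            class = "hemodynamics_spec")
}

# full linear convolution, base R
conv_full <- function(a, b) {
  stats::convolve(a, rev(b), type = "open")
}

#' Expected fractional CBV response time course
#'
#' Convolves the hemodynamic kernel with the stimulation-onset impulse
#' train extracted from a binary stimulus vector (rising edges) and
#' truncates to the session length; this is the generator's analytic
#' ground truth for `ΔCBV/CBV / 100 / response_amplitude`.
#'
#' @param hemo A [hemodynamics_spec()].
#' @param stim A [synth_stimulus_vector()] or binary numeric vector.
#' @return Numeric vector, same length as `stim`, peaking at 1 for
#'   well-separated stimulations.
#' @export
expected_response <- function(hemo, stim) {
  v <- as.numeric(unclass_stim(stim))
  ev <- as.numeric(diff(c(0, v)) == 1)
  full <- conv_full(hemo$kernel, ev)
  # kernel is causal: sample k of the response aligns with sample k of stim
  full[seq_along(v)]
}

unclass_stim <- function(stim) {
  if (inherits(stim, "stimulus_vector")) stim$values else stim
}

#' Random scatterer phantom
#'
#' A 2D field of point scatterers with standard-normal reflectivities.
#' Tissue scatterers are uniform over the extent; each vessel box gets its
#' own population of blood scatterers carrying the box's flow velocity.
#'
#' @param density Tissue scatterer density, scatterers per mm^2.
#' @param extent `(x_min, x_max, z_min, z_max)`, m.
#' @param vessel_layout `NULL`, or a data.frame with columns
#'   `x_min, x_max, z_min, z_max, vx, vz` (m and m/s).
#' @param blood_density Blood scatterer density inside vessels, per mm^2.
#' @param seed Integer RNG seed.
#' @return An object of class `phantom`: a list with a `scatterers`
#'   data.frame (`x`, `z`, `refl`, `compartment`, `vessel`), the
#'   `vessel_layout` and the `extent`.
#' @export
make_phantom <- function(density, extent, vessel_layout = NULL,
                         blood_density = density, seed = 1L) {
  if (density <= 0) stop_invalid("density must be positive")
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop_invalid("empty phantom extent")
  set.seed(seed)
  area_mm2 <- (extent[2] - extent[1]) * (extent[4] - extent[3]) * 1e6
  n <- rpois(1, density * area_mm2)
  sc <- data.frame(
    x = runif(n, extent[1], extent[2]),
    z = runif(n, extent[3], extent[4]),
    refl = rnorm(n), compartment = rep("tissue", n),
    vessel = rep(NA_integer_, n)
  )
  if (!is.null(vessel_layout) && nrow(vessel_layout) > 0) {
    for (v in seq_len(nrow(vessel_layout))) {
      vb <- vessel_layout[v, ]
      a_mm2 <- (vb$x_max - vb$x_min) * (vb$z_max - vb$z_min) * 1e6
      nb <- rpois(1, blood_density * a_mm2)
      if (nb > 0) {
        sc <- rbind(sc, data.frame(
          x = runif(nb, vb$x_min, vb$x_max),
          z = runif(nb, vb$z_min, vb$z_max),
          refl = rnorm(nb), compartment = rep("blood", nb),
          vessel = rep(v, nb)
        ))
      }
    }
  }
  structure(list(scatterers = sc, vessel_layout = vessel_layout,
                 extent = extent), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d scatterers (%d blood) over [%.1f, %.1f] x [%.1f, %.1f] mm\n",
              nrow(x$scatterers), sum(x$scatterers$compartment == "blood"),
              x$extent[1] * 1e3, x$extent[2] * 1e3,
              x$extent[3] * 1e3, x$extent[4] * 1e3))
  invisible(x)
}

#' Phantom state at time t
#'
#' Applies (i) the push displacement field to every scatterer (axial shift,
#' micrometre scale), (ii) advection of blood scatterers along their
#' vessel's flow velocity with wrap-around inside the vessel box, and
#' (iii) blood reflectivity scaling so that blood signal *power* follows
#' `1 + response_amplitude * (kernel (*) stim)(t)` inside the active
#' region.
#'
#' @param phantom A [make_phantom()] result.
#' @param push An [arf_push_spec()] or `NULL`.
#' @param hemo A [hemodynamics_spec()] or `NULL`.
#' @param stim Stimulus vector (see [synth_stimulus_vector()]) or `NULL`.
#' @param t Time, s.
#' @param active_region `NULL` (everywhere) or a function `(x, z) -> logical`.
#' @return A `phantom` whose scatterers reflect the state at `t`.
#' @export
evolve_phantom <- function(phantom, push = NULL, hemo = NULL, stim = NULL,
                           t = 0, active_region = NULL) {
  sc <- phantom$scatterers
  if (!is.null(push)) {
    dz_um <- push_displacement(push, sc$x, sc$z, t)
    sc$z <- sc$z + dz_um * 1e-6
  }
  blood <- which(sc$compartment == "blood")
  if (length(blood) > 0 && !is.null(phantom$vessel_layout)) {
    for (v in unique(sc$vessel[blood])) {
      idx <- blood[sc$vessel[blood] == v]
      vb <- phantom$vessel_layout[v, ]
      wrap <- function(p, lo, hi) lo + (p - lo) %% (hi - lo)
      sc$x[idx] <- wrap(sc$x[idx] + vb$vx * t, vb$x_min, vb$x_max)
      sc$z[idx] <- wrap(sc$z[idx] + vb$vz * t, vb$z_min, vb$z_max)
    }
  }
  if (length(blood) > 0 && !is.null(hemo) && !is.null(stim)) {
    rate <- if (inherits(stim, "stimulus_vector")) stim$rate else
      hemo$functional_rate
    resp <- expected_response(hemo, stim)
    k <- min(length(resp), max(1L, 1L + floor(t * rate)))
    gain2 <- 1 + hemo$response_amplitude * resp[k]
    act <- if (is.null(active_region)) rep(TRUE, length(blood)) else
      active_region(sc$x[blood], sc$z[blood])
    sc$refl[blood[act]] <- sc$refl[blood[act]] * sqrt(gain2)
  }
  phantom$scatterers <- sc
  phantom
}

#' Simulate plane-wave RF channel data for one transmit
#'
#' Point-scatterer echo model: each scatterer contributes a gated sinusoid
#' (raised-cosine envelope, `tx_cycles` cycles at the carrier) delayed by
#' the plane-wave transmit time plus the element-to-scatterer return time.
#'
#' @param phantom A [make_phantom()] result (possibly evolved).
#' @param transducer A [transducer_spec()].
#' @param angle Plane-wave tilt, degrees.
#' @param noise_sd White Gaussian noise s.d. added to every sample.
#' @param seed RNG seed for the noise (`NULL` leaves the RNG state alone).
#' @param tx_cycles Cycles per transmitted pulse.
#' @param n_samples Trace length; default covers the deepest scatterer.
#' @param t0 Time of the first sample, s.
#' @return An `rf_channel_data` object: `samples` (time x element matrix),
#'   `angle` (deg), `t0`, `fs`, and `n_excluded` scatterers behind the
#'   array.
#' @export
simulate_rf <- function(phantom, transducer, angle, noise_sd = 0,
                        seed = NULL, tx_cycles = 1.5, n_samples = NULL,
                        t0 = 0) {
  if (abs(angle) >= 90) stop_invalid("plane-wave angle must satisfy |angle| < 90")
  sc <- phantom$scatterers
  behind <- sc$z < 0
  if (any(behind)) {
    warning(sprintf("%d scatterer(s) behind the array excluded", sum(behind)))
    sc <- sc[!behind, , drop = FALSE]
  }
  ex <- element_positions(transducer)
  fs <- transducer$sampling_freq
  cc <- transducer$sound_speed
  if (is.null(n_samples)) {
    zmax <- max(c(sc$z, phantom$extent[4]))
    xspan <- max(abs(c(sc$x, ex)))
    tmax <- 2 * sqrt(zmax^2 + xspan^2) / cc +
      tx_cycles / transducer$carrier_freq
    n_samples <- ceiling((tmax - t0) * fs) + 4L
  }
  samples <- rf_simulate_cpp(sc$x, sc$z, sc$refl, ex,
                             angle * pi / 180, cc, fs,
                             transducer$carrier_freq, tx_cycles,
                             as.integer(n_samples), t0)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    samples <- samples + rnorm(length(samples), sd = noise_sd)
  }
  structure(list(samples = samples, angle = angle, t0 = t0, fs = fs,
                 n_excluded = sum(behind)),
            class = "rf_channel_data")
}
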