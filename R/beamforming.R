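#' Default reconstruction pixel grid
#'
#' Lateral spacing equals the element pitch and axial spacing equals
#' `c / (2 fs)`, so one RF sample corresponds to one axial pixel and the
#' NCC sample-lag to displacement conversion stays exact.
#'
#' @param transducer A [transducer_spec()].
#' @param z_range `(z_min, z_max)` axial extent, m.
#' @param x_range Optional lateral extent, m; default spans the aperture.
#' @return A `beam_grid` object with `x` and `z` coordinate vectors (m).
#' @export
beam_grid <- function(transducer, z_range, x_range = NULL) {
  if (is.null(x_range)) {
    ex <- element_positions(transducer)
    x_range <- range(ex)
  }
  dz <- transducer$sound_speed / (2 * transducer$sampling_freq)
  structure(list(
    x = seq(x_range[1], x_range[2], by = transducer$pitch),
    z = seq(z_range[1], z_range[2], by = dz),
    dx = transducer$pitch, dz = dz
  ), class = "beam_grid")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$z, b$z))
}

#' Delay-and-sum beamforming of one plane-wave transmit
#'
#' Each pixel sums, over elements, the RF trace sampled (with linear
#' inter-sample interpolation) at the plane-wave transmit delay
#' `(z cos(theta) + x sin(theta)) / c` plus the receive delay
#' `sqrt((x - x_e)^2 + z^2) / c`.  Delays beyond the recorded trace
#' contribute zero and are counted in `n_clipped`.
#'
#' @param rf An `rf_channel_data` object from [simulate_rf()] (or a list
#'   with `samples`, `angle`, `t0`, `fs`).
#' @param transducer A [transducer_spec()].
#' @param grid A [beam_grid()].
#' @param timestamp Acquisition time attached to the frame, s.
#' @param f_number Receive f-number: only elements within the aperture
#'   `|x - x_e| <= z / (2 f_number)` contribute to a pixel.  The default
#'   of 1 keeps the receive angular spread narrow enough that the axial
#'   image spectrum stays centred near `2 fc / c`, which sub-sample NCC
#'   tracking relies on; `0` disables the gate (full aperture).
#' @return A `compound_frame`: `values` (axial x lateral matrix of real RF
#'   amplitude), `grid`, `timestamp`, `n_angles = 1`, `n_clipped`.
#' @export
das_beamform <- function(rf, transducer, grid, timestamp = 0,
                         f_number = 1) {
  ex <- element_positions(transducer)
  if (ncol(rf$samples) != length(ex))
    stop_invalid("RF element count does not match the transducer")
  res <- das_beamform_cpp(rf$samples, ex, rf$angle * pi / 180,
                          grid$x, grid$z, transducer$sound_speed,
                          rf$fs, rf$t0, f_number)
  structure(list(values = res$image, grid = grid, timestamp = timestamp,
                 n_angles = 1L, n_clipped = res$n_clipped),
            class = "compound_frame")
}

#' Coherent compounding of single-angle frames
#'
#' @param frames List of `compound_frame`s on an identical grid.
#' @return A `compound_frame` holding the arithmetic mean of the inputs;
#'   its timestamp is the mean of the input timestamps.
#' @export
compound <- function(frames) {
  if (length(frames) == 0) stop_invalid("no frames to compound")
  g <- frames[[1]]$grid
  for (f in frames[-1]) {
    if (!same_grid(f$grid, g)) stop_invalid("frames have mismatched grids")
  }
  acc <- Reduce(`+`, lapply(frames, `[[`, "values")) / length(frames)
  structure(list(values = acc, grid = g,
                 timestamp = mean(vapply(frames, `[[`, 0, "timestamp")),
                 n_angles = sum(vapply(frames, `[[`, 0L, "n_angles")),
                 n_clipped = sum(vapply(frames, `[[`, 0, "n_clipped"))),
            class = "compound_frame")
}

#' Simulate, beamform and compound one multi-angle frame
#'
#' Convenience wrapper running [simulate_rf()] and [das_beamform()] for
#' every angle of a plane-wave scheme, then [compound()].
#'
#' @param phantom A `phantom` (already evolved to the acquisition time).
#' @param transducer A [transducer_spec()].
#' @param scheme A [plane_wave_scheme()].
#' @param grid A [beam_grid()].
#' @param noise_sd Channel noise s.d. passed to [simulate_rf()].
#' @param seed Base RNG seed for the channel noise; incremented per angle.
#' @param timestamp Frame timestamp, s.
#' @param f_number Receive f-number passed to [das_beamform()].
#' @return A `compound_frame`.
#' @export
simulate_compound_frame <- function(phantom, transducer, scheme, grid,
                                    noise_sd = 0, seed = NULL,
                                    timestamp = 0, f_number = 1) {
  frames <- lapply(seq_along(scheme$angles), function(i) {
    s <- if (is.null(seed)) NULL else seed + i
    rf <- simulate_rf(phantom, transducer, scheme$angles[i],
                      noise_sd = noise_sd, seed = s,
                      tx_cycles = scheme$tx_cycles)
    das_beamform(rf, transducer, grid, timestamp = timestamp,
                 f_number = f_number)
  })
  compound(frames)
}

#' @export
print.compound_frame <- function(x, ...) {
  cat(sprintf("<compound_frame> %d x %d px (axial x lateral), %d angle(s), t = %.4g s\n",
              nrow(x$values), ncol(x$values), x$n_angles, x$timestamp))
  invisible(x)
}
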