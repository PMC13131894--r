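#' Binary stimulus vector for a functional session
#'
#' One sample per functional frame; 1 during each half-open stimulation
#' interval `[onset, onset + stim_duration)`.
#'
#' @param session A [session_spec()].
#' @return A `stimulus_vector`: `values` (0/1), `rate` (Hz), `lag` (s).
#' @export
synth_stimulus_vector <- function(session) {
  t <- (seq_len(session$n_samples) - 1) / session$functional_rate
  v <- rep(0L, session$n_samples)
  for (on in session$stim_onsets) {
    v[t >= on & t < on + session$stim_duration] <- 1L
  }
  structure(list(values = v, rate = session$functional_rate, lag = 0),
            class = "stimulus_vector")
}

#' @export
print.stimulus_vector <- function(x, ...) {
  cat(sprintf("<stimulus_vector> %d samples @ %g Hz, %d on\n",
              length(x$values), x$rate, sum(x$values)))
  invisible(x)
}

#' Compound-frame-level functional session generator
#'
#' Emulates the statistics of a beamformed functional-ultrasound session
#' without per-frame RF simulation: each 1 s power-Doppler block is a
#' stack of compound frames containing (i) a strong low-rank tissue
#' clutter component with slow temporal drift, (ii) frame-to-frame
#' independent blood speckle whose variance in the active region follows
#' `1 + amplitude * (kernel (*) stim)(t)`, and (iii) white thermal noise.
#' Blocks are generated lazily and reproducibly (block `k` reseeds at
#' `seed + k`), so full-length sessions never hold the frame data in
#' memory at once.
#'
#' @param nz,nx Grid size in pixels.
#' @param session A [session_spec()].
#' @param hemo A [hemodynamics_spec()].
#' @param active_mask Logical `nz x nx` matrix of hemodynamically active
#'   pixels.
#' @param contra_mask Optional logical matrix of contralateral pixels,
#'   modulated at `contralateral_amplitude_ratio` of the amplitude and
#'   delayed by `contralateral_extra_lag` (both from the
#'   [hemodynamics_spec()]).
#' @param n_frames Compound frames per block.
#' @param tissue_rank Number of tissue clutter spatial modes.
#' @param tissue_amp Clutter amplitude relative to unit blood speckle s.d.
#' @param blood_sd Baseline blood speckle s.d.
#' @param noise_sd Thermal noise s.d.
#' @param seed Integer base seed.
#' @return A `functional_session` object: `block(k)` returning the 3D
#'   frame array for block `k`, plus `truth` (expected response trace,
#'   `active_mask`, amplitude) and the generating parameters.
#' @export
synth_functional_session <- function(nz, nx, session = session_spec(),
                                     hemo = hemodynamics_spec(),
                                     active_mask = NULL,
                                     contra_mask = NULL,
                                     n_frames = 150L, tissue_rank = 4L,
                                     tissue_amp = 30, blood_sd = 1,
                                     noise_sd = 0.1, seed = 1L) {
  if (is.null(active_mask)) active_mask <- matrix(FALSE, nz, nx)
  stopifnot(nrow(active_mask) == nz, ncol(active_mask) == nx)
  stim <- synth_stimulus_vector(session)
  resp <- expected_response(hemo, stim)
  # contralateral response: scaled down and delayed
  lag_k <- round(hemo$contralateral_extra_lag * session$functional_rate)
  resp_c <- c(rep(0, lag_k), resp)[seq_along(resp)]
  npix <- nz * nx
  act <- as.vector(active_mask)
  con <- if (is.null(contra_mask)) rep(FALSE, npix) else as.vector(contra_mask)
  set.seed(seed)
  # smooth-ish fixed tissue spatial modes, shared by all blocks
  modes <- matrix(rnorm(npix * tissue_rank), npix, tissue_rank)
  block_fn <- function(k) {
    if (k < 1 || k > session$n_samples) stop_invalid("block index out of range")
    set.seed(seed + k)
    gain2 <- 1 + hemo$response_amplitude * resp[k]
    sd_pix <- rep(blood_sd, npix)
    sd_pix[act] <- blood_sd * sqrt(gain2)
    sd_pix[con] <- blood_sd * sqrt(1 + hemo$response_amplitude *
                                   hemo$contralateral_amplitude_ratio *
                                   resp_c[k])
    # tissue: constant + small slow drift per mode within the block
    drift <- matrix(1, tissue_rank, n_frames) +
      0.02 * t(apply(matrix(rnorm(tissue_rank * n_frames, sd = 0.05),
                            tissue_rank), 1, cumsum))
    cas <- tissue_amp * (modes %*% drift) +
      matrix(rnorm(npix * n_frames), npix) * sd_pix +
      matrix(rnorm(npix * n_frames, sd = noise_sd), npix)
    array(cas, c(nz, nx, n_frames))
  }
  structure(list(block = block_fn, nz = nz, nx = nx, session = session,
                 stim = stim,
                 truth = list(response = resp, contra_response = resp_c,
                              active_mask = active_mask,
                              contra_mask = contra_mask,
                              amplitude = hemo$response_amplitude)),
            class = "functional_session")
}

#' Run the clutter-filter / power-Doppler stage over a session
#'
#' @param fsession A [synth_functional_session()] result, or any list with
#'   a `block(k)` closure and a `session`.
#' @param spec A [clutter_filter_spec()].
#' @param n_blocks Number of blocks to process (default: the whole
#'   session).
#' @return 3D array (axial x lateral x blocks) of power-Doppler images.
#' @export
pd_sequence <- function(fsession, spec = clutter_filter_spec(),
                        n_blocks = NULL) {
  if (is.null(n_blocks)) n_blocks <- fsession$session$n_samples
  pd <- array(0, c(fsession$nz, fsession$nx, n_blocks))
  for (k in seq_len(n_blocks)) {
    blk <- fsession$block(k)
    pd[, , k] <- power_doppler(svd_clutter_filter(blk, spec))
  }
  pd
}

#' CMAP burst model parameters for the EMG generator
#'
#' @param latency Burst onset after the FUS pulse onset, ms.
#' @param amplitude Burst peak amplitude, mV.
#' @param burst_duration Burst decay scale, ms.
#' @param burst_freq Oscillation frequency of the damped sinusoid, Hz.
#' @param artifact_amplitude Biphasic stimulus-artifact spike amplitude at
#'   FUS onset and offset, mV.
#' @param noise_sd Baseline noise s.d., mV.
#' @return An object of class `cmap_spec`.
#' @export
cmap_spec <- function(latency = 65, amplitude = 0.5, burst_duration = 8,
                      burst_freq = 300, artifact_amplitude = 2,
                      noise_sd = 0.01) {
  if (latency <= 0) stop_invalid("latency must be positive")
  if (amplitude < 0 || artifact_amplitude < 0 || noise_sd < 0)
    stop_invalid("amplitudes must be non-negative")
  structure(list(latency = latency, amplitude = amplitude,
                 burst_duration = burst_duration, burst_freq = burst_freq,
                 artifact_amplitude = artifact_amplitude,
                 noise_sd = noise_sd), class = "cmap_spec")
}

# damped sinusoid starting at t = 0 (ms); peaks near the first sine crest.
# truncated at 5 decay constants so a burst has finite support (< 0.7%
# residual), as a physiological CMAP does
cmap_wave <- function(t_ms, spec) {
  out <- numeric(length(t_ms))
  tau <- spec$burst_duration / 3
  p <- t_ms >= 0 & t_ms <= 5 * tau
  out[p] <- spec$amplitude * exp(-t_ms[p] / tau) *
    sin(2 * pi * spec$burst_freq * t_ms[p] / 1000)
  out
}

# biphasic spike (one cycle, 1 ms wide) used for FUS on/off artifacts
artifact_wave <- function(t_ms, amp) {
  out <- numeric(length(t_ms))
  p <- t_ms >= 0 & t_ms < 1
  out[p] <- amp * sin(2 * pi * t_ms[p])
  out
}

#' Synthetic EMG trace with CMAP bursts and FUS artifacts
#'
#' Baseline Gaussian noise plus, for every FUS pulse, biphasic electrical
#' artifacts at the pulse onset and offset and a damped-sinusoid CMAP
#' burst starting `latency` ms after the onset.
#'
#' @param pulse_onsets FUS pulse onset times, s.
#' @param cmap A [cmap_spec()].
#' @param fs Sampling rate, Hz (>= 2 kHz; 10 kHz in the recording preset).
#' @param duration Trace duration, s.
#' @param pulse_duration FUS pulse duration (sets the offset artifact), s.
#' @param seed RNG seed for the noise.
#' @return An `emg_record`: `samples` (mV), `fs`, `pulse_onsets`, `meta`
#'   (bandpass 0.5-5 kHz, gain 2000 — descriptive of the emulated
#'   front-end), and `truth` (the CMAP spec).
#' @export
synth_emg <- function(pulse_onsets, cmap = cmap_spec(), fs = 10e3,
                      duration = NULL, pulse_duration = 80e-3, seed = 1L) {
  if (fs < 2e3) stop_invalid("fs must be at least 2 kHz")
  if (is.null(duration))
    duration <- max(pulse_onsets) + 1
  n <- round(duration * fs)
  t_s <- (seq_len(n) - 1) / fs
  if (any(pulse_onsets + cmap$latency / 1000 +
          cmap$burst_duration / 1000 > duration))
    stop_invalid("CMAP burst extends beyond the trace end")
  set.seed(seed)
  x <- rnorm(n, sd = cmap$noise_sd)
  for (on in pulse_onsets) {
    t_ms <- (t_s - on) * 1000
    x <- x + artifact_wave(t_ms, cmap$artifact_amplitude)
    x <- x + artifact_wave(t_ms - pulse_duration * 1000,
                           cmap$artifact_amplitude)
    x <- x + cmap_wave(t_ms - cmap$latency, cmap)
  }
  structure(list(samples = x, fs = fs, pulse_onsets = sort(pulse_onsets),
                 meta = list(bandpass = c(500, 5000), gain = 2000),
                 truth = cmap), class = "emg_record")
}

#' Synthetic keypoint and open-field trajectories
#'
#' `kind = "keypoints"` produces a DeepLabCut-style table: three tracked
#' points per body part (paw edge, mid, ankle) at a resting pose, with a
#' pulse-locked lateral excursion whose velocity profile is an analytic
#' half-sine of prescribed peak velocity — so the downstream
#' finite-difference velocity has a known truth.  `kind = "openfield"`
#' produces a reflecting Gaussian random walk in a square arena with a
#' tunable attraction toward the centre.
#'
#' @param kind `"keypoints"` or `"openfield"`.
#' @param spec Named list of parameters.  Keypoints: `fps` (100),
#'   `duration` (s), `pulse_onsets` (s), `peak_velocity` (px/ms, 20),
#'   `excursion_duration` (s, 0.2), `noise_px` (0), `bodypart` ("hindpaw").
#'   Openfield: `fps` (25), `duration` (s, 600), `arena` (cm, 40),
#'   `step_sd` (cm, 1), `center_affinity` (0..1 pull per frame, 0),
#'   `start` (cm pair, arena centre).
#' @param seed RNG seed.
#' @return A data.frame; keypoint tables carry attributes `fps` and
#'   `truth` (peak velocity), open-field tables carry `fps` and `arena`.
#' @export
synth_tracks <- function(kind = c("keypoints", "openfield"), spec = list(),
                         seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "keypoints") {
    p <- utils::modifyList(list(fps = 100, duration = 10,
                                pulse_onsets = numeric(0),
                                peak_velocity = 20, excursion_duration = 0.2,
                                noise_px = 0, bodypart = "hindpaw",
                                rest = c(200, 300)), spec)
    n <- round(p$duration * p$fps)
    t_s <- (seq_len(n) - 1) / p$fps
    # analytic out-and-back excursion: x(u) = A sin^2(pi u), u in [0, 1],
    # so v(t) = Vp sin(2 pi u) with |v| peaking exactly at Vp
    vp_px_s <- p$peak_velocity * 1000
    offset <- numeric(n)
    for (on in p$pulse_onsets) {
      u <- (t_s - on) / p$excursion_duration
      inb <- u >= 0 & u <= 1
      offset[inb] <- offset[inb] +
        vp_px_s * p$excursion_duration / pi * sin(pi * u[inb])^2
    }
    pts <- c("paw", "mid", "ankle"); scl <- c(1, 0.6, 0.3)
    df <- data.frame(frame = seq_len(n) - 1)
    for (i in seq_along(pts)) {
      nm <- paste0(p$bodypart, "_", pts[i])
      df[[paste0(nm, "_x")]] <- p$rest[1] + 20 * (i - 1) +
        scl[i] * offset + rnorm(n, sd = p$noise_px)
      df[[paste0(nm, "_y")]] <- p$rest[2] + 10 * (i - 1) +
        rnorm(n, sd = p$noise_px)
      df[[paste0(nm, "_likelihood")]] <- rep(0.99, n)
    }
    attr(df, "fps") <- p$fps
    attr(df, "truth") <- list(peak_velocity = p$peak_velocity,
                              pulse_onsets = p$pulse_onsets)
    return(df)
  }
  p <- utils::modifyList(list(fps = 25, duration = 600, arena = 40,
                              step_sd = 1, center_affinity = 0,
                              start = NULL), spec)
  n <- round(p$duration * p$fps)
  ctr <- p$arena / 2
  pos <- if (is.null(p$start)) c(ctr, ctr) else p$start
  xy <- matrix(0, n, 2)
  reflect <- function(v, lo, hi) {
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }
  for (i in seq_len(n)) {
    pos <- pos + rnorm(2, sd = p$step_sd) +
      p$center_affinity * (c(ctr, ctr) - pos)
    pos <- reflect(pos, 0, p$arena)
    xy[i, ] <- pos
  }
  df <- data.frame(time_s = (seq_len(n) - 1) / p$fps,
                   x_cm = xy[, 1], y_cm = xy[, 2])
  attr(df, "fps") <- p$fps
  attr(df, "arena") <- p$arena
  df
}
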