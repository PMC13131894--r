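#' Moving-RMS envelope of a rectified EMG trace
#'
#' @param rec An `emg_record` (see [synth_emg()]) or numeric vector of
#'   samples (mV).
#' @param window_ms Centred RMS window length, ms.  The default of 1 ms
#'   respects the 1 ms guard between the end of the 50-79 ms CMAP
#'   detection window and the FUS-offset artifact of an 80 ms pulse: a
#'   centred window wider than 2 ms would smear that artifact into the
#'   detection window.
#' @param fs Sampling rate, Hz; taken from the record when available.
#' @return An `emg_envelope`: `values` (mV RMS), `times` (s), `fs`,
#'   `pulse_onsets` carried over from the record.
#' @export
rms_envelope <- function(rec, window_ms = 1, fs = NULL) {
  x <- if (inherits(rec, "emg_record")) rec$samples else as.numeric(rec)
  if (is.null(fs)) fs <- if (inherits(rec, "emg_record")) rec$fs else
    stop_invalid("fs required for a bare numeric trace")
  if (window_ms <= 0) stop_invalid("window_ms must be positive")
  w <- max(1L, round(window_ms / 1000 * fs))
  if (w > length(x)) stop_invalid("RMS window longer than the trace")
  # centred moving mean of the squared rectified signal
  ms <- stats::filter(x^2, rep(1 / w, w), sides = 2)
  ms <- as.numeric(ms)
  # edges: shrink the window instead of dropping samples
  half <- (w - 1) %/% 2
  n <- length(x)
  for (i in which(is.na(ms))) {
    lo <- max(1, i - half); hi <- min(n, i + (w - 1 - half))
    ms[i] <- mean(x[lo:hi]^2)
  }
  structure(list(values = sqrt(pmax(ms, 0)), times = (seq_len(n) - 1) / fs,
                 fs = fs,
                 pulse_onsets = if (inherits(rec, "emg_record"))
                   rec$pulse_onsets else numeric(0)),
            class = "emg_envelope")
}

#' Windowed CMAP peak detection on an RMS envelope
#'
#' For every FUS pulse, searches for local maxima of the envelope inside
#' the artifact-avoiding detection window (50-79 ms post onset by
#' default) and keeps the largest; a pulse with no interior local maximum
#' yields no peak.  Local maxima found outside the window (e.g. early
#' responses) are reported separately in `diagnostics`.
#'
#' @param envelope An [rms_envelope()] result.
#' @param pulse_onsets Pulse onset times, s; defaults to the envelope's.
#' @param window `(min, max)` detection window, ms post onset.
#' @param min_amplitude Minimum peak amplitude, mV.  `NULL` (default) uses
#'   three times the median envelope — a robust noise-floor estimate, so
#'   baseline ripple alone never registers as a response.
#' @return A data.frame of class `emg_peaks` with `pulse_index`,
#'   `amplitude` (mV RMS), `latency` (ms); attribute `diagnostics` lists
#'   per-pulse envelope maxima falling outside the window.
#' @export
detect_peaks <- function(envelope, pulse_onsets = NULL,
                         window = c(50, 79), min_amplitude = NULL) {
  if (is.null(pulse_onsets)) pulse_onsets <- envelope$pulse_onsets
  if (length(pulse_onsets) == 0) stop_invalid("no pulse onsets supplied")
  v <- envelope$values
  if (is.null(min_amplitude)) min_amplitude <- 3 * median(v)
  n <- length(v)
  dur <- n / envelope$fs
  if (any(pulse_onsets < 0 | pulse_onsets > dur))
    stop_invalid("pulse onsets outside the trace")
  out <- list(); diag <- list()
  for (pi in seq_along(pulse_onsets)) {
    on <- pulse_onsets[pi]
    i0 <- max(2L, floor((on + window[1] / 1000) * envelope$fs) + 1L)
    i1 <- min(n - 1L, ceiling((on + window[2] / 1000) * envelope$fs) + 1L)
    if (i1 <= i0) next
    seg <- i0:i1
    locmax <- seg[v[seg] > v[seg - 1] & v[seg] >= v[seg + 1] &
                  v[seg] >= min_amplitude]
    if (length(locmax) > 0) {
      k <- locmax[which.max(v[locmax])]
      out[[length(out) + 1]] <- data.frame(
        pulse_index = pi, amplitude = v[k],
        latency = ((k - 1) / envelope$fs - on) * 1000)
    } else {
      # diagnostics: where the envelope actually peaks near this pulse
      near <- max(1L, floor(on * envelope$fs) + 1L):
        min(n, floor((on + 0.2) * envelope$fs) + 1L)
      km <- near[which.max(v[near])]
      diag[[length(diag) + 1]] <- data.frame(
        pulse_index = pi, amplitude = v[km],
        latency = ((km - 1) / envelope$fs - on) * 1000)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(pulse_index = integer(0), amplitude = numeric(0),
               latency = numeric(0))
  attr(res, "diagnostics") <- if (length(diag) > 0) do.call(rbind, diag) else
    data.frame(pulse_index = integer(0), amplitude = numeric(0),
               latency = numeric(0))
  class(res) <- c("emg_peaks", class(res))
  res
}

#' Dose-response normalization of EMG peak amplitudes
#'
#' Divides every peak amplitude by the mean peak amplitude of the
#' highest-pressure group.
#'
#' @param peaks data.frame with columns `amplitude` and `pressure`.
#' @return The input with an added `norm_amplitude` column.
#' @export
normalize_peaks <- function(peaks) {
  if (nrow(peaks) == 0) stop_invalid("no peaks to normalize")
  top <- peaks$pressure == max(peaks$pressure)
  if (!any(top)) stop_invalid("highest-pressure group is empty")
  denom <- mean(peaks$amplitude[top])
  if (denom == 0) stop_invalid("highest-pressure mean amplitude is zero")
  peaks$norm_amplitude <- peaks$amplitude / denom
  peaks
}

#' Paw velocity from a keypoint table
#'
#' Uses the paw-edge point's x/y trajectory.  Frames with likelihood below
#' the cutoff are linearly interpolated (and counted).  Velocity is the
#' 2D Euclidean frame-to-frame step converted to px/ms, signed by the
#' lateral (x) displacement direction so lateralized movements carry a
#' sign; the unsigned magnitude is also returned.
#'
#' @param table Keypoint data.frame (see [synth_tracks()] or
#'   [read_dlc_csv()]).
#' @param bodypart Column-name prefix of the paw-edge point, e.g.
#'   `"hindpaw_paw"`.
#' @param fps Frame rate, Hz; defaults to the table's `fps` attribute.
#' @param pulse_onsets Optional FUS pulse onsets, s, for per-pulse peaks.
#' @param likelihood_cutoff Minimum keypoint likelihood.
#' @param peak_window Post-onset span searched for the per-pulse peak, s.
#' @return List with `velocity` (signed, px/ms), `speed` (unsigned),
#'   `times` (s), `n_interpolated`, and if onsets were given `pulse_peaks`
#'   (data.frame `pulse_index`, `peak_velocity`, `peak_speed`).
#' @export
paw_velocity <- function(table, bodypart, fps = NULL, pulse_onsets = NULL,
                         likelihood_cutoff = 0.9, peak_window = 0.5) {
  if (is.null(fps)) fps <- attr(table, "fps")
  if (is.null(fps) || fps <= 0) stop_invalid("fps must be positive")
  x <- table[[paste0(bodypart, "_x")]]
  y <- table[[paste0(bodypart, "_y")]]
  lik <- table[[paste0(bodypart, "_likelihood")]]
  if (is.null(x) || is.null(y))
    stop_invalid("bodypart columns not found in the table")
  n <- length(x)
  n_interp <- 0L
  if (!is.null(lik)) {
    bad <- lik < likelihood_cutoff
    n_interp <- sum(bad)
    if (any(bad) && sum(!bad) >= 2) {
      idx <- seq_len(n)
      x[bad] <- approx(idx[!bad], x[!bad], xout = idx[bad], rule = 2)$y
      y[bad] <- approx(idx[!bad], y[!bad], xout = idx[bad], rule = 2)$y
    }
  }
  dx <- diff(x); dy <- diff(y)
  speed <- sqrt(dx^2 + dy^2) * fps / 1000        # px/ms
  velocity <- speed * ifelse(dx >= 0, 1, -1)
  times <- (seq_len(n - 1) - 0.5) / fps          # step midpoints
  res <- list(velocity = velocity, speed = speed, times = times,
              n_interpolated = n_interp)
  if (!is.null(pulse_onsets)) {
    pk <- lapply(seq_along(pulse_onsets), function(pi) {
      on <- pulse_onsets[pi]
      inw <- times >= on & times <= on + peak_window
      if (!any(inw)) return(NULL)
      k <- which(inw)[which.max(abs(velocity[inw]))]
      data.frame(pulse_index = pi, peak_velocity = velocity[k],
                 peak_speed = speed[k])
    })
    res$pulse_peaks <- do.call(rbind, pk)
  }
  res
}
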