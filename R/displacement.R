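#' NCC speckle-tracking parameters
#'
#' @param window_len Axial correlation window length, samples.  The default
#'   corresponds to two wavelengths at a 15.625 MHz carrier sampled at
#'   62.5 MHz (16 samples, ~197 um).
#' @param window_overlap Fractional overlap between successive windows.
#' @param max_lag Integer search range, samples.
#' @param subsample Sub-sample peak refinement: `"cosine"` (3-point
#'   narrowband fit, exact for a sampled cosine correlation peak — the
#'   default, since interframe displacements are a fraction of a sample) or
#'   `"parabolic"` (3-point parabola).
#' @param upsample Integer axial upsampling factor (FFT zero-padding)
#'   applied to each RF line before correlation.  Micron pushes are
#'   ~0.1-0.2 samples at the default grid and 3-point fits shrink such
#'   estimates toward zero; correlating at 4x the grid removes that bias.
#'   Set to 1 to correlate raw samples.
#' @return An object of class `ncc_spec`.
#' @export
ncc_spec <- function(window_len = 16L, window_overlap = 0.8,
                     max_lag = 8L, subsample = c("cosine", "parabolic"),
                     upsample = 4L) {
  if (window_overlap <= 0 || window_overlap >= 1)
    stop_invalid("window_overlap must be in (0, 1)")
  if (max_lag < 1) stop_invalid("max_lag must be >= 1")
  if (window_len < 4) stop_invalid("window_len must be >= 4 samples")
  if (upsample < 1) stop_invalid("upsample must be >= 1")
  structure(list(window_len = as.integer(window_len),
                 window_overlap = window_overlap,
                 max_lag = as.integer(max_lag),
                 subsample = match.arg(subsample),
                 upsample = as.integer(upsample)),
            class = "ncc_spec")
}

# band-limited (FFT zero-padding) upsampling of a real vector
fft_upsample <- function(x, U) {
  if (U == 1) return(x)
  n <- length(x)
  X <- stats::fft(x)
  nh <- floor(n / 2)
  Xp <- complex(real = rep(0, n * U))
  Xp[1:(nh + 1)] <- X[1:(nh + 1)]
  if (nh >= 2) Xp[(n * U - nh + 2):(n * U)] <- X[(n - nh + 2):n]
  if (n %% 2 == 0) {       # split the Nyquist bin
    Xp[nh + 1] <- X[nh + 1] / 2
    Xp[n * U - nh + 1] <- X[nh + 1] / 2
  }
  Re(stats::fft(Xp, inverse = TRUE)) / n
}

# 3-point sub-sample peak refinement around the integer argmax.
# y: NCC values at lags (peak-1, peak, peak+1). Returns delta in (-1, 1).
subsample_peak <- function(ym1, y0, yp1, method) {
  if (method == "cosine") {
    arg <- (yp1 + ym1) / (2 * y0)
    if (is.finite(arg) && abs(arg) < 1 && y0 != 0) {
      w <- acos(arg)
      # w is the local correlation-peak frequency (rad/sample); outside
      # this band the fit is ill-conditioned (too broad or near-Nyquist)
      # and the bounded parabolic fit is safer
      if (w > 0.35 && w < 2.8) {
        d <- atan2(yp1 - ym1, 2 * y0 * sin(w)) / w
        if (is.finite(d) && abs(d) < 1) return(d)
      }
    }
    # degenerate (broadband / flat) peak: fall through to parabola
  }
  denom <- ym1 - 2 * y0 + yp1
  if (denom >= 0) return(0)
  d <- (ym1 - yp1) / (2 * denom)
  max(-1, min(1, d))
}

#' Sub-sample delay between two 1D RF segments by normalized
#' cross-correlation
#'
#' Core estimator used by [ncc_displacement()]; exposed for calibration
#' sweeps.  Positive lag means `cur` is a delayed (deeper) copy of `ref`.
#'
#' @param ref,cur Equal-length numeric vectors.
#' @param max_lag Integer search range, samples.
#' @param subsample `"cosine"` or `"parabolic"`.
#' @return List with `lag` (samples, sub-sample resolution) and `quality`
#'   (NCC value at the integer peak).  A zero-variance window returns
#'   `lag = 0`, `quality = 0` and `flat = TRUE`.
#' @export
ncc_delay <- function(ref, cur, max_lag = 8L,
                      subsample = c("cosine", "parabolic")) {
  subsample <- match.arg(subsample)
  n <- length(ref)
  if (n <= 2 * max_lag + 4)
    stop_invalid("signal too short for the requested search range")
  lags <- -max_lag:max_lag
  # ref window fixed at the centre; cur window slides
  pad <- max_lag
  core <- (pad + 1):(n - pad)
  r <- ref[core]
  if (sd(r) == 0) return(list(lag = 0, quality = 0, flat = TRUE))
  cc <- vapply(lags, function(l) {
    cwin <- cur[core + l]
    if (sd(cwin) == 0) return(NA_real_)
    cor(r, cwin)
  }, 0)
  if (all(is.na(cc))) return(list(lag = 0, quality = 0, flat = TRUE))
  k <- which.max(cc)
  lag <- lags[k]
  d <- 0
  if (k > 1 && k < length(cc) && !is.na(cc[k - 1]) && !is.na(cc[k + 1]))
    d <- subsample_peak(cc[k - 1], cc[k], cc[k + 1], subsample)
  list(lag = lag + d, quality = cc[k], flat = FALSE)
}

#' Interframe axial displacement map by 1D normalized cross-correlation
#'
#' For every lateral line, overlapping axial windows of the reference
#' frame's RF are correlated against the current frame over integer lags
#' `+/- max_lag`; the peak lag is refined to sub-sample resolution and
#' converted to micrometres with `c / (2 fs)` per sample.  Window-centre
#' estimates are interpolated back onto the full pixel rows.
#'
#' @param ref,cur `compound_frame`s on the same grid.
#' @param spec An [ncc_spec()].
#' @param transducer The [transducer_spec()] that produced the frames
#'   (supplies `c` and `fs` for the lag-to-micron conversion).
#' @return A `displacement_map`: `values` (axial x lateral, micrometres,
#'   positive = away from the array), `quality` (NCC peak per pixel),
#'   `grid`, `frame_time`, `n_flat` zero-variance windows.
#' @export
ncc_displacement <- function(ref, cur, spec = ncc_spec(),
                             transducer = transducer_spec()) {
  if (!same_grid(ref$grid, cur$grid)) stop_invalid("frames on different grids")
  nz <- nrow(ref$values); nx <- ncol(ref$values)
  if (spec$window_len >= nz)
    stop_invalid("window_len exceeds the axial extent")
  U <- spec$upsample
  L <- spec$window_len * U
  ml <- spec$max_lag * U
  nzu <- nz * U
  hop <- max(1L, as.integer(round(spec$window_len *
                                  (1 - spec$window_overlap)))) * U
  starts <- seq(1L + ml, nzu - L - ml, by = hop)
  if (length(starts) < 1) stop_invalid("axial extent too small for NCC windows")
  centers <- (starts + (L - 1) / 2 - 1) / U + 1    # original pixel rows
  um_per_sample <- transducer$sound_speed /
    (2 * transducer$sampling_freq) * 1e6 / U
  lags <- -ml:ml
  win_idx <- outer(seq_len(L) - 1L, starts, `+`)   # L x W index matrix
  vals <- matrix(0, nz, nx); qual <- matrix(0, nz, nx)
  n_flat <- 0L
  for (j in seq_len(nx)) {
    rl <- fft_upsample(ref$values[, j], U)
    cl <- fft_upsample(cur$values[, j], U)
    # windows whose energy is at numerical noise level relative to the
    # line are flat (zero-variance), not informative
    flat_tol <- 1e-9 * sqrt(L) * max(abs(rl), 1e-300)
    R <- matrix(rl[win_idx], nrow = L)
    Rc <- sweep(R, 2, colMeans(R))
    rss <- sqrt(colSums(Rc^2))
    ncc <- matrix(NA_real_, length(lags), length(starts))
    for (li in seq_along(lags)) {
      C <- matrix(cl[win_idx + lags[li]], nrow = L)
      Cc <- sweep(C, 2, colMeans(C))
      css <- sqrt(colSums(Cc^2))
      ncc[li, ] <- colSums(Rc * Cc) / (rss * css)
    }
    disp_w <- numeric(length(starts)); qual_w <- numeric(length(starts))
    for (w in seq_along(starts)) {
      col <- ncc[, w]
      if (rss[w] <= flat_tol || all(!is.finite(col))) {
        n_flat <- n_flat + 1L
        disp_w[w] <- 0; qual_w[w] <- 0
        next
      }
      col[!is.finite(col)] <- -Inf
      k <- which.max(col)
      d <- 0
      if (k > 1 && k < length(col) && is.finite(col[k - 1]) &&
          is.finite(col[k + 1]))
        d <- subsample_peak(col[k - 1], col[k], col[k + 1], spec$subsample)
      disp_w[w] <- (lags[k] + d) * um_per_sample
      qual_w[w] <- col[k]
    }
    if (length(starts) == 1) {
      vals[, j] <- disp_w; qual[, j] <- qual_w
    } else {
      vals[, j] <- approx(centers, disp_w, xout = seq_len(nz),
                          rule = 2)$y
      qual[, j] <- approx(centers, qual_w, xout = seq_len(nz),
                          rule = 2)$y
    }
  }
  structure(list(values = vals, quality = qual, grid = ref$grid,
                 frame_time = cur$timestamp, n_flat = n_flat),
            class = "displacement_map")
}

#' Displacement map sequence against a pre-push reference
#'
#' Every frame is tracked against the first (pre-push) frame, yielding
#' cumulative displacement — the plateau metric used for peak
#' quantification; set `mode = "interframe"` to track consecutive pairs.
#'
#' @param frames Ordered list of `compound_frame`s (>= 2).
#' @param spec An [ncc_spec()].
#' @param transducer A [transducer_spec()].
#' @param mode `"cumulative"` (reference = frame 1) or `"interframe"`.
#' @return List of `displacement_map`s (length `length(frames) - 1`).
#' @export
displacement_sequence <- function(frames, spec = ncc_spec(),
                                  transducer = transducer_spec(),
                                  mode = c("cumulative", "interframe")) {
  mode <- match.arg(mode)
  if (length(frames) < 2) stop_invalid("need at least 2 frames")
  lapply(seq_along(frames)[-1], function(i) {
    ref <- if (mode == "cumulative") frames[[1]] else frames[[i - 1]]
    ncc_displacement(ref, frames[[i]], spec, transducer)
  })
}

#' -3 dB focal contour mask of a displacement map
#'
#' @param map A `displacement_map` (or any object with a `values` matrix).
#' @param level_db Contour level relative to the map maximum, dB
#'   (amplitude convention: threshold = `max * 10^(level_db / 20)`).
#' @return Logical matrix; empty (with a warning) if the map maximum is
#'   not positive.
#' @export
focal_contour <- function(map, level_db = -3) {
  v <- if (is.list(map)) map$values else map
  m <- max(v)
  if (m <= 0) {
    warning("map maximum is not positive; returning an empty mask")
    return(matrix(FALSE, nrow(v), ncol(v)))
  }
  v >= m * 10^(level_db / 20)
}

#' ROI-averaged displacement trace and its peak
#'
#' Averages each displacement map over a square window centred on
#' `center_pixel` — by contract the pixel with the highest stimulus
#' correlation from the activation map ([activation_argmax()]).
#'
#' @param maps List of `displacement_map`s.
#' @param center_pixel `(row, col)` pixel indices.
#' @param window Odd window side length in pixels.
#' @return List with `trace` (per-frame mean, um), `times` (s), `peak`
#'   (um), `peak_frame`, and `n_border_clipped` pixels lost at map borders.
#' @export
roi_displacement <- function(maps, center_pixel, window = 5) {
  v1 <- maps[[1]]$values
  if (center_pixel[1] < 1 || center_pixel[1] > nrow(v1) ||
      center_pixel[2] < 1 || center_pixel[2] > ncol(v1))
    stop_invalid("center_pixel outside the map")
  h <- (window - 1) / 2
  rows <- max(1, center_pixel[1] - h):min(nrow(v1), center_pixel[1] + h)
  cols <- max(1, center_pixel[2] - h):min(ncol(v1), center_pixel[2] + h)
  clipped <- window^2 - length(rows) * length(cols)
  trace <- vapply(maps, function(m) mean(m$values[rows, cols]), 0)
  times <- vapply(maps, `[[`, 0, "frame_time")
  k <- which.max(trace)
  list(trace = trace, times = times, peak = trace[k], peak_frame = k,
       n_border_clipped = clipped)
}

#' @export
print.displacement_map <- function(x, ...) {
  cat(sprintf("<displacement_map> %d x %d px, peak %.2f um, t = %.4g s\n",
              nrow(x$values), ncol(x$values), max(x$values), x$frame_time))
  invisible(x)
}
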