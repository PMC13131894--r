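#' SVD clutter filter parameters
#'
#' @param svd_cutoff Number of leading singular components removed
#'   (tissue clutter); 30 in the Doppler preset.
#' @param block_len Compound frames per power-Doppler block (150 at a
#'   500 Hz compound rate for a 1 Hz functional rate).
#' @return An object of class `clutter_filter_spec`.
#' @export
clutter_filter_spec <- function(svd_cutoff = 30L, block_len = 150L) {
  if (svd_cutoff < 0 || svd_cutoff >= block_len)
    stop_invalid("svd_cutoff must satisfy 0 <= cutoff < block_len")
  structure(list(svd_cutoff = as.integer(svd_cutoff),
                 block_len = as.integer(block_len)),
            class = "clutter_filter_spec")
}

as_stack <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.list(x) && inherits(x[[1]], "compound_frame")) {
    d <- dim(x[[1]]$values)
    arr <- array(0, c(d, length(x)))
    for (i in seq_along(x)) arr[, , i] <- x[[i]]$values
    return(arr)
  }
  stop_invalid("expected a 3D array or a list of compound frames")
}

#' SVD clutter filtering of a compound-frame block
#'
#' Reshapes the block into its Casorati matrix (pixels x frames), zeroes
#' the `svd_cutoff` largest singular components (stationary / slowly
#' varying tissue), and reshapes back.
#'
#' @param block 3D array (axial x lateral x frames) or list of
#'   `compound_frame`s.
#' @param spec A [clutter_filter_spec()]; the cutoff must be smaller than
#'   the number of frames supplied.
#' @return 3D array of the same shape containing the blood signal.
#' @export
svd_clutter_filter <- function(block, spec = clutter_filter_spec()) {
  arr <- as_stack(block)
  d <- dim(arr)
  nt <- d[3]
  if (spec$svd_cutoff >= nt)
    stop_invalid("svd_cutoff must be smaller than the block length")
  if (spec$svd_cutoff == 0) return(arr)
  cas <- matrix(arr, nrow = d[1] * d[2], ncol = nt)
  sv <- svd(cas, nu = spec$svd_cutoff, nv = spec$svd_cutoff)
  k <- seq_len(spec$svd_cutoff)
  clutter <- sv$u %*% (sv$d[k] * t(sv$v))
  array(cas - clutter, dim = d)
}

#' Power-Doppler image of a filtered block
#'
#' Per-pixel sum of squared clutter-filtered RF samples over the block —
#' proportional to blood volume in the pixel.
#'
#' @param block 3D array (axial x lateral x frames) or list of
#'   `compound_frame`s, normally the output of [svd_clutter_filter()].
#' @return Matrix (axial x lateral) of non-negative Doppler power.
#' @export
power_doppler <- function(block) {
  arr <- as_stack(block)
  rowSums(arr^2, dims = 2)
}

#' ΔCBV/CBV time series from a power-Doppler sequence
#'
#' @param pd 3D array (axial x lateral x time) of power-Doppler images at
#'   the functional rate.
#' @param baseline_frames Indices of pre-stimulus frames defining the
#'   baseline.
#' @param times Frame times, s; defaults to `0, 1, ...` at 1 Hz.
#' @return A `cbv_series`: `pd`, `rel` (percent change from baseline,
#'   `NA` where the baseline is zero), `times`, `baseline_frames`,
#'   `n_zero_baseline`.
#' @export
cbv_series <- function(pd, baseline_frames, times = NULL) {
  if (length(baseline_frames) == 0) stop_invalid("empty baseline")
  d <- dim(pd)
  if (is.null(times)) times <- seq_len(d[3]) - 1
  base <- rowMeans(pd[, , baseline_frames, drop = FALSE], dims = 2)
  zero <- base <= 0
  rel <- 100 * sweep(sweep(pd, c(1, 2), base, `-`), c(1, 2), base, `/`)
  if (any(zero)) rel[array(zero, d)] <- NA_real_
  structure(list(pd = pd, rel = rel, times = times,
                 baseline_frames = baseline_frames,
                 n_zero_baseline = sum(zero)),
            class = "cbv_series")
}

# Shift a binary stimulus by `lag` seconds (positive = stimulus delayed)
# and pair it with series indices, truncating the overhang on both sides.
lag_align <- function(n, stim_values, lag, rate) {
  k <- as.integer(round(lag * rate))
  if (k >= 0) {
    idx_series <- (k + 1):n
    idx_stim <- 1:(n - k)
  } else {
    idx_series <- 1:(n + k)
    idx_stim <- (1 - k):n
  }
  list(series = idx_series, stim = idx_stim)
}

#' Stimulus-correlation activation map
#'
#' Per-pixel Pearson correlation between the power-Doppler time series and
#' the binary stimulus vector shifted by `lag` (positive lag delays the
#' stimulus; overhanging samples are truncated, never wrapped).  Pixels
#' with `r` greater than the threshold (one-sided; 0.2 corresponds to
#' z > 3.3, p < 0.001 at 270 samples) are flagged as activated.
#'
#' @param series A [cbv_series()].
#' @param stim A [synth_stimulus_vector()] or binary vector at the
#'   functional rate.
#' @param lag Stimulus lag, s.
#' @param threshold Significance threshold on `r`.
#' @return An `activation_map`: `r` (matrix), `mask` (`r > threshold`),
#'   `threshold`, `n_samples` used after truncation, `lag`.
#' @export
activation_map <- function(series, stim, lag = 0, threshold = 0.2) {
  v <- as.numeric(unclass_stim(stim))
  d <- dim(series$pd)
  if (length(v) != d[3])
    stop_invalid("stimulus length does not match the series")
  rate <- if (inherits(stim, "stimulus_vector")) stim$rate else 1
  al <- lag_align(d[3], v, lag, rate)
  if (length(al$series) < 10)
    stop_invalid("fewer than 10 samples remain after lag truncation")
  x <- v[al$stim]
  if (sd(x) == 0) stop_invalid("stimulus is constant over the aligned span")
  mat <- matrix(series$pd[, , al$series], nrow = d[1] * d[2])
  xc <- x - mean(x)
  mc <- mat - rowMeans(mat)
  denom <- sqrt(rowSums(mc^2)) * sqrt(sum(xc^2))
  r <- as.vector(mc %*% xc) / denom
  r[!is.finite(r)] <- 0
  r <- matrix(r, d[1], d[2])
  structure(list(r = r, mask = r > threshold, threshold = threshold,
                 n_samples = length(al$series), lag = lag),
            class = "activation_map")
}

#' Pixel with the highest stimulus correlation
#'
#' @param amap An [activation_map()].
#' @param region Optional logical matrix restricting the search (e.g. one
#'   hemisphere).
#' @return `(row, col)` indices of the correlation argmax.
#' @export
activation_argmax <- function(amap, region = NULL) {
  r <- amap$r
  if (!is.null(region)) r[!region] <- -Inf
  k <- which.max(r)
  c(row = (k - 1) %% nrow(r) + 1, col = (k - 1) %/% nrow(r) + 1)
}

#' Activated area as a function of stimulus lag
#'
#' @param series A [cbv_series()].
#' @param stim Stimulus vector.
#' @param lags Numeric lag grid, s.
#' @param mask_region Optional logical matrix restricting the count.
#' @param threshold Significance threshold on `r`.
#' @param pixel_area_mm2 Area of one pixel for the mm^2 column.
#' @return data.frame with `lag`, `n_pixels`, `area_mm2`.
#' @export
activated_area <- function(series, stim, lags, mask_region = NULL,
                           threshold = 0.2, pixel_area_mm2 = NA_real_) {
  rows <- lapply(lags, function(l) {
    am <- activation_map(series, stim, lag = l, threshold = threshold)
    m <- am$mask
    if (!is.null(mask_region)) m <- m & mask_region
    data.frame(lag = l, n_pixels = sum(m),
               area_mm2 = sum(m) * pixel_area_mm2)
  })
  do.call(rbind, rows)
}

#' Plateau-aware peak lag of an activated-area curve
#'
#' Area-vs-lag curves saturate when every truly active pixel clears the
#' threshold over a range of lags; the bare argmax is then arbitrary
#' within the plateau.  The peak lag is therefore reported as the centroid
#' of the lags whose area reaches `frac` of the curve maximum.
#'
#' @param area_curve data.frame from [activated_area()].
#' @param frac Plateau fraction of the maximum.
#' @return Peak lag, s.
#' @export
area_peak_lag <- function(area_curve, frac = 0.95) {
  mx <- max(area_curve$n_pixels)
  if (mx <= 0) return(NA_real_)
  mean(area_curve$lag[area_curve$n_pixels >= frac * mx])
}

#' Epoch-averaged ROI response metrics
#'
#' Averages the percent-CBV trace over a square window centred on
#' `center_pixel` (by contract the activation-map argmax), aligns epochs
#' at the stimulation onsets, averages them, and reports the peak percent
#' change and its latency within `[onset, onset + peak_window]`.
#'
#' @param series A [cbv_series()].
#' @param center_pixel `(row, col)` pixel indices.
#' @param session A [session_spec()].
#' @param window Odd ROI side length, pixels.
#' @param peak_window Post-onset peak-search span, s (responses outlast
#'   the 10 s stimulus, so the default searches 20 s).
#' @param epoch_span `(pre, post)` epoch extent around each onset, s.
#' @return List with `epoch_mean`, `epoch_times` (s relative to onset),
#'   `epochs` (matrix), `peak` (percent), `peak_latency` (s),
#'   `roi_trace`, `n_epochs_dropped`.
#' @export
roi_response <- function(series, center_pixel, session, window = 5,
                         peak_window = 20, epoch_span = c(5, 25)) {
  d <- dim(series$rel)
  if (center_pixel[1] < 1 || center_pixel[1] > d[1] ||
      center_pixel[2] < 1 || center_pixel[2] > d[2])
    stop_invalid("center_pixel outside the map")
  h <- (window - 1) / 2
  rows <- max(1, center_pixel[1] - h):min(d[1], center_pixel[1] + h)
  cols <- max(1, center_pixel[2] - h):min(d[2], center_pixel[2] + h)
  trace <- apply(series$rel[rows, cols, , drop = FALSE], 3, mean,
                 na.rm = TRUE)
  rate <- session$functional_rate
  rel_idx <- seq(-round(epoch_span[1] * rate), round(epoch_span[2] * rate))
  epoch_times <- rel_idx / rate
  epochs <- list(); dropped <- 0L
  for (on in session$stim_onsets) {
    i0 <- round(on * rate) + 1          # sample at the onset
    idx <- i0 + rel_idx
    if (min(idx) < 1 || max(idx) > length(trace)) {
      dropped <- dropped + 1L
      next
    }
    epochs[[length(epochs) + 1]] <- trace[idx]
  }
  if (length(epochs) == 0) stop_invalid("no complete epochs in the session")
  em <- Reduce(`+`, epochs) / length(epochs)
  search <- which(epoch_times >= 0 & epoch_times <= peak_window)
  k <- search[which.max(em[search])]
  list(epoch_mean = em, epoch_times = epoch_times,
       epochs = do.call(cbind, epochs), peak = em[k],
       peak_latency = epoch_times[k], roi_trace = trace,
       n_epochs_dropped = dropped)
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d x %d px, lag %g s, %d px with r > %.2f (max r = %.3f)\n",
              nrow(x$r), ncol(x$r), x$lag, sum(x$mask), x$threshold,
              max(x$r)))
  invisible(x)
}

#' @export
print.cbv_series <- function(x, ...) {
  d <- dim(x$pd)
  cat(sprintf("<cbv_series> %d x %d px, %d samples, baseline %d frames\n",
              d[1], d[2], d[3], length(x$baseline_frames)))
  invisible(x)
}
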