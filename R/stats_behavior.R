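#' Fisher z statistic for a Pearson correlation
#'
#' `z = atanh(r) * sqrt(n - 3)`; at the activation threshold r = 0.2 with
#' 270 samples this gives z > 3.3 (one-sided p < 0.001), the calibration
#' behind the fixed activation threshold.
#'
#' @param r Pearson correlation, `|r| < 1`.
#' @param n Sample count, `> 3`.
#' @return List with `z` and the one-sided upper-tail `p`.
#' @examples
#' fisher_z(0.2, 270)$z   # > 3.3
#' @export
fisher_z <- function(r, n) {
  if (any(abs(r) >= 1)) stop_invalid("|r| must be < 1")
  if (any(n <= 3)) stop_invalid("n must exceed 3")
  z <- atanh(r) * sqrt(n - 3)
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Monte-Carlo false-positive rate of the activation threshold
#'
#' Correlates i.i.d. standard-normal traces with a binary stimulus vector
#' and reports the fraction exceeding `r_thr` — the empirical one-sided
#' false-positive rate of the fixed-threshold activation criterion.
#'
#' @param stim A [synth_stimulus_vector()] or binary vector; its length
#'   sets `n`.
#' @param r_thr Threshold on `r`.
#' @param reps Number of replicate traces (>= 1e5 for a stable tail
#'   estimate).
#' @param seed RNG seed.
#' @param chunk Traces per internal block (memory control).
#' @return List with `fpr`, `se` (binomial Monte-Carlo s.e.), `reps`, `n`,
#'   and `analytic` — the normal-approximation tail
#'   `P(z > atanh(r_thr) sqrt(n-3))`.
#' @export
null_threshold_fpr <- function(stim = synth_stimulus_vector(session_spec()),
                               r_thr = 0.2, reps = 2e5, seed = 1L,
                               chunk = 2e4) {
  v <- as.numeric(unclass_stim(stim))
  if (sd(v) == 0) stop_invalid("degenerate stimulus (constant)")
  n <- length(v)
  set.seed(seed)
  vc <- v - mean(v)
  vn <- vc / sqrt(sum(vc^2))
  hits <- 0
  done <- 0
  while (done < reps) {
    m <- min(chunk, reps - done)
    x <- matrix(rnorm(m * n), m, n)
    xc <- x - rowMeans(x)
    r <- as.vector(xc %*% vn) / sqrt(rowSums(xc^2))
    hits <- hits + sum(r > r_thr)
    done <- done + m
  }
  fpr <- hits / reps
  list(fpr = fpr, se = sqrt(fpr * (1 - fpr) / reps), reps = reps, n = n,
       analytic = pnorm(atanh(r_thr) * sqrt(n - 3), lower.tail = FALSE))
}

#' Two-tailed Spearman correlation
#'
#' Mid-ranks for ties; the p-value is exact (permutation distribution) for
#' `n <= 10` and t-approximated otherwise.
#'
#' @param x,y Numeric vectors, `n >= 4`.
#' @return List with `rho` and two-sided `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) < 4) stop_invalid("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) stop_invalid("zero variance input")
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = length(x) <= 10))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Ordinary least-squares regression summary
#'
#' @param x,y Numeric vectors.
#' @return List with `slope`, `intercept`, `r_squared`, and the two-sided
#'   slope `p`.
#' @export
linreg <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) stop_invalid("zero variance input")
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, p = s$coefficients[2, 4])
}

#' Displacement-activation colocalization statistics
#'
#' Pixelwise Spearman correlation between the displacement map and the
#' stimulus-correlation map inside a brain mask, plus a Welch two-sample
#' t-test of displacement between activated (`r > act_threshold`) and
#' non-activated pixels.
#'
#' @param disp_map `displacement_map` or numeric matrix (um).
#' @param corr_map `activation_map` or numeric matrix of Pearson r.
#' @param brain_mask Logical matrix of in-brain pixels.
#' @param act_threshold Activation threshold on r.
#' @return List with `spearman` (`rho`, `p`), `welch` (`t`, `p`,
#'   group means; `NULL` with a message field if a group is empty),
#'   `n_activated`, `n_nonactivated`.
#' @export
colocalization <- function(disp_map, corr_map, brain_mask,
                           act_threshold = 0.2) {
  d <- if (is.list(disp_map)) disp_map$values else disp_map
  r <- if (is.list(corr_map)) corr_map$r else corr_map
  if (!all(dim(d) == dim(r)) || !all(dim(d) == dim(brain_mask)))
    stop_invalid("maps and mask must share a grid")
  if (!any(brain_mask)) stop_invalid("empty brain mask")
  dv <- d[brain_mask]; rv <- r[brain_mask]
  sp <- spearman(dv, rv)
  act <- rv > act_threshold
  welch <- NULL
  if (any(act) && any(!act) && sum(act) >= 2 && sum(!act) >= 2) {
    tt <- t.test(dv[act], dv[!act])   # Welch by default
    welch <- list(t = unname(tt$statistic), p = tt$p.value,
                  mean_activated = mean(dv[act]),
                  mean_nonactivated = mean(dv[!act]))
  } else {
    message("one pixel group is (nearly) empty; Welch test skipped")
  }
  list(spearman = sp, welch = welch, n_activated = sum(act),
       n_nonactivated = sum(!act))
}

#' Open-field zone specification
#'
#' @param arena_side Square arena side, cm.
#' @param border_width Peripheral band width, cm.
#' @param interval_len Reporting interval, s.
#' @param test_duration Total test duration, s.
#' @return An object of class `zone_spec`.
#' @export
zone_spec <- function(arena_side = 40, border_width = 8,
                      interval_len = 300, test_duration = 600) {
  if (2 * border_width >= arena_side)
    stop_invalid("2 * border_width must be smaller than arena_side")
  structure(list(arena_side = arena_side, border_width = border_width,
                 interval_len = interval_len,
                 test_duration = test_duration), class = "zone_spec")
}

#' Open-field zone geometry
#'
#' @param spec A [zone_spec()]; the default 40 cm arena with an 8 cm
#'   border yields a 576 cm^2 centre (36% of the arena; periphery 64%).
#' @return List with `center_area` (cm^2), `center_fraction`,
#'   `periphery_fraction` (both in percent).
#' @export
openfield_zones <- function(spec = zone_spec()) {
  side <- spec$arena_side - 2 * spec$border_width
  ca <- side^2
  cf <- 100 * ca / spec$arena_side^2
  list(center_area = ca, center_fraction = cf,
       periphery_fraction = 100 - cf)
}

#' Zone dwell times and path length of an open-field track
#'
#' The centre zone is the open square strictly inside the peripheral
#' band (points exactly on the border line count as periphery).
#'
#' @param track data.frame with `time_s`, `x_cm`, `y_cm` (see
#'   [synth_tracks()]); positions outside the arena are clipped to it and
#'   counted.
#' @param spec A [zone_spec()].
#' @return List with `center_time` / `periphery_time` (s, total),
#'   `by_interval` (data.frame per `interval_len` window),
#'   `total_distance` (cm), `center_time_per_distance` (s/cm, `NA` when
#'   the distance is zero), `n_clipped`.
#' @export
time_in_center <- function(track, spec = zone_spec()) {
  if (nrow(track) == 0) stop_invalid("empty track")
  x <- track$x_cm; y <- track$y_cm
  n_clipped <- sum(x < 0 | x > spec$arena_side |
                   y < 0 | y > spec$arena_side)
  x <- pmin(pmax(x, 0), spec$arena_side)
  y <- pmin(pmax(y, 0), spec$arena_side)
  b <- spec$border_width; s <- spec$arena_side
  in_center <- x > b & x < s - b & y > b & y < s - b
  dt <- if (nrow(track) > 1) median(diff(track$time_s)) else 0
  dist <- if (nrow(track) > 1) sum(sqrt(diff(x)^2 + diff(y)^2)) else 0
  interval <- floor(track$time_s / spec$interval_len)
  by_int <- do.call(rbind, lapply(sort(unique(interval)), function(iv) {
    sel <- interval == iv
    data.frame(interval = iv + 1,
               t_start = iv * spec$interval_len,
               center_time = sum(in_center[sel]) * dt,
               periphery_time = sum(!in_center[sel]) * dt)
  }))
  ct <- sum(in_center) * dt
  list(center_time = ct, periphery_time = sum(!in_center) * dt,
       by_interval = by_int, total_distance = dist,
       center_time_per_distance = if (dist > 0) ct / dist else NA_real_,
       n_clipped = n_clipped)
}

#' Group-comparison wrappers
#'
#' Thin wrappers over the base-R tests used for cross-modal comparisons:
#' paired t, Welch two-sample t, one-way ANOVA with Tukey multiple
#' comparisons, and Welch one-way ANOVA.
#'
#' @param x,y Numeric vectors (paired or independent samples).
#' @param values Numeric response vector for the ANOVA wrappers.
#' @param groups Factor (or coercible) of group labels.
#' @return For the t wrappers, a list with `t`, `df`, `p`; for
#'   `anova_tukey`, a list with `f`, `p` and the Tukey table; for
#'   `anova_welch`, a list with `f`, `df`, `p`.
#' @name group_tests
NULL

#' @rdname group_tests
#' @export
paired_t <- function(x, y) {
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname group_tests
#' @export
welch_t <- function(x, y) {
  tt <- t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname group_tests
#' @export
anova_tukey <- function(values, groups) {
  g <- factor(groups)
  fit <- aov(values ~ g)
  s <- summary(fit)[[1]]
  list(f = s$`F value`[1], p = s$`Pr(>F)`[1],
       tukey = TukeyHSD(fit)$g)
}

#' @rdname group_tests
#' @export
anova_welch <- function(values, groups) {
  ot <- oneway.test(values ~ factor(groups))
  list(f = unname(ot$statistic), df = unname(ot$parameter),
       p = ot$p.value)
}
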