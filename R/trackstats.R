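# Track-level observables of confined Brownian motion: vibration amplitude,
# position-maps, positional autocorrelation, MSD and its power-law exponent.
# All functions take a track data frame with columns time_s, x_nm, y_nm
# (uniform frame spacing), the shared currency of simulated and experimental
# tracks.

as_track <- function(track) {
  need <- c("time_s", "x_nm", "y_nm")
  if (!is.data.frame(track) || !all(need %in% names(track))) {
    abort_format("a track needs columns time_s, x_nm, y_nm")
  }
  if (nrow(track) < 2) abort_data("a track needs at least 2 frames")
  dt <- diff(track$time_s)
  if (any(!is.finite(track$x_nm)) || any(!is.finite(track$y_nm))) {
    abort_data("track positions must be finite")
  }
  if (diff(range(dt)) > 1e-6) {
    abort_format("track frame spacing is not uniform (tolerance 1e-6 s)")
  }
  track
}

track_dt <- function(track) mean(diff(track$time_s))

sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

#' Vibration amplitude of a position track
#'
#' The vibration amplitude is the standard deviation of the particle's
#' position about its mean — the width of the position-map. For a circular
#' map the x and y widths agree; the amplitude is reported as the mean of the
#' per-axis population standard deviations. The amplitude of a co-recorded
#' fixed marker (instrument/building vibration) is subtracted linearly and the
#' result floored at zero; quadrature subtraction (appropriate when marker
#' noise is independent of particle motion) is available via `quadrature`.
#'
#' @param track Track data frame (`time_s`, `x_nm`, `y_nm`).
#' @param marker_amplitude Fixed-marker amplitude to subtract (nm).
#' @param quadrature If `TRUE` subtract in quadrature instead of linearly.
#' @return Amplitude in nm (scalar).
#' @examples
#' tr <- generate_track(model = "ou_confined", sd_nm = 50, tau_s = 0.3,
#'                      n_frames = 500, seed = 1)
#' vibration_amplitude(tr)
#' @export
vibration_amplitude <- function(track, marker_amplitude = 0,
                                quadrature = FALSE) {
  track <- as_track(track)
  amp <- mean(c(sd_pop(track$x_nm), sd_pop(track$y_nm)))
  if (quadrature) {
    sqrt(max(0, amp^2 - marker_amplitude^2))
  } else {
    max(0, amp - marker_amplitude)
  }
}

#' 2D occupancy histogram (position-map) of a track
#'
#' Counts how often each (x, y) bin was occupied, on a uniform grid centred
#' on the track mean.
#'
#' @param track Track data frame.
#' @param bin_width Bin width (nm).
#' @return A `position_map`: tibble `x_nm`, `y_nm` (bin centres), `count`,
#'   with `bin_edges_x`/`bin_edges_y` attributes. Counts sum to the frame
#'   count.
#' @export
position_map <- function(track, bin_width = 5) {
  track <- as_track(track)
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    abort_invalid("`bin_width` must be a positive number")
  }
  x <- track$x_nm - mean(track$x_nm)
  y <- track$y_nm - mean(track$y_nm)
  half_n <- function(v) max(1L, ceiling((max(abs(v)) + bin_width / 2) / bin_width))
  nx <- half_n(x); ny <- half_n(y)
  ex <- seq(-nx, nx) * bin_width
  ey <- seq(-ny, ny) * bin_width
  ix <- findInterval(x, ex, rightmost.closed = TRUE)
  iy <- findInterval(y, ey, rightmost.closed = TRUE)
  counts <- table(factor(ix, levels = seq_len(length(ex) - 1)),
                  factor(iy, levels = seq_len(length(ey) - 1)))
  grid <- tidyr::expand_grid(
    ix = seq_len(length(ex) - 1), iy = seq_len(length(ey) - 1))
  grid$x_nm <- (ex[grid$ix] + ex[grid$ix + 1]) / 2
  grid$y_nm <- (ey[grid$iy] + ey[grid$iy + 1]) / 2
  grid$count <- as.vector(counts)[(grid$iy - 1) * (length(ex) - 1) + grid$ix]
  out <- tibble(x_nm = grid$x_nm, y_nm = grid$y_nm, count = grid$count)
  structure(out, bin_edges_x = ex, bin_edges_y = ey,
            class = c("position_map", class(out)))
}

#' Positional autocorrelation of a track
#'
#' Biased autocorrelation estimator of the mean-centred position,
#' `R(h) = sum_n x(n) x(n+h) / sum_n x(n)^2`, computed on the x-coordinate
#' (the conventional reporting axis for near-circular position maps); set
#' `axis = "y"` for anisotropy checks. `R(0) = 1` and `|R(h)| <= 1` for all
#' lags by Cauchy-Schwarz.
#'
#' @param track Track data frame.
#' @param axis `"x"` (default) or `"y"`.
#' @param max_lag_s Largest lag to report (s); default the whole track.
#' @return An `autocorr_curve` tibble with columns `lag_s`, `r`.
#' @export
track_autocorrelation <- function(track, axis = c("x", "y"),
                                  max_lag_s = NULL) {
  track <- as_track(track)
  axis <- match.arg(axis)
  v <- if (axis == "x") track$x_nm else track$y_nm
  v <- v - mean(v)
  n <- length(v)
  denom <- sum(v^2)
  if (denom <= 0) abort_data("zero positional variance: autocorrelation undefined")
  dt <- track_dt(track)
  hmax <- n - 1L
  if (!is.null(max_lag_s)) hmax <- min(hmax, floor(max_lag_s / dt))
  r <- vapply(0:hmax, function(h) {
    sum(v[seq_len(n - h)] * v[seq_len(n - h) + h]) / denom
  }, numeric(1))
  out <- tibble(lag_s = (0:hmax) * dt, r = r)
  structure(out, class = c("autocorr_curve", class(out)))
}

#' Time at which 50 % of the positional autocorrelation is lost
#'
#' Smallest lag at which `R` drops to 0.5, linearly interpolated between the
#' bracketing lags; `Inf` if the curve never crosses 0.5.
#'
#' @param curve An `autocorr_curve` from [track_autocorrelation()], or any
#'   data frame with `lag_s` and `r`.
#' @return Half-time in seconds (possibly `Inf`).
#' @export
autocorrelation_half_time <- function(curve) {
  lag <- curve$lag_s; r <- curve$r
  below <- which(r <= 0.5)
  if (length(below) == 0) return(Inf)
  j <- below[1]
  if (j == 1) return(lag[1])
  # linear interpolation between (lag[j-1], r[j-1]) and (lag[j], r[j])
  lag[j - 1] + (0.5 - r[j - 1]) * (lag[j] - lag[j - 1]) / (r[j] - r[j - 1])
}

#' Mean-squared displacement of a track
#'
#' Lag-resolved 2D MSD averaged over `n_starts` starting positions spaced
#' `start_spacing` frames apart:
#' `MSD(i) = (1/M) * sum_k |r(j_k + i) - r(j_k)|^2`, `j_k = (k-1) * spacing`,
#' with r the 2D (x, y) position and lags `i = 0 .. n_lags`. Defaults follow the
#' vibration-spectroscopy convention: 1000 lags (16 s at 60 Hz) averaged over
#' 10 starting positions 100 frames apart.
#'
#' @param track Track data frame.
#' @param n_lags Number of lags N.
#' @param n_starts Number of starting positions M.
#' @param start_spacing Spacing between starting positions (frames).
#' @return An `msd_curve` tibble with `lag_s`, `msd_nm2`, and attributes
#'   `n_starts`, `n_lags`, `frame_dt`.
#' @export
track_msd <- function(track, n_lags = 1000, n_starts = 10,
                      start_spacing = 100) {
  track <- as_track(track)
  n <- nrow(track)
  need <- (n_starts - 1) * start_spacing + n_lags + 1
  if (n < need) {
    abort_data(sprintf(
      "track too short for MSD: %d frames needed (M=%d starts, N=%d lags), %d available",
      need, n_starts, n_lags, n))
  }
  x <- track$x_nm; y <- track$y_nm
  acc <- numeric(n_lags + 1)
  for (k in seq_len(n_starts)) {
    j <- (k - 1) * start_spacing + 1
    idx <- j + (0:n_lags)
    acc <- acc + (x[idx] - x[j])^2 + (y[idx] - y[j])^2
  }
  out <- tibble(lag_s = (0:n_lags) * track_dt(track),
                msd_nm2 = acc / n_starts)
  structure(out, n_starts = n_starts, n_lags = n_lags,
            frame_dt = track_dt(track),
            class = c("msd_curve", class(out)))
}

#' Ensemble-averaged MSD over several tracks
#'
#' Pointwise mean of the per-track MSD curves (all tracks must share the same
#' frame interval), the convention used when averaging MSD over individual
#' bacteria.
#'
#' @param tracks A list of track data frames, or of `msd_curve` objects.
#' @param ... Passed on to [track_msd()] when `tracks` are raw tracks.
#' @return An `msd_curve` tibble.
#' @export
msd_ensemble <- function(tracks, ...) {
  if (length(tracks) == 0) abort_invalid("`tracks` is empty")
  curves <- lapply(tracks, function(t) {
    if (inherits(t, "msd_curve")) t else track_msd(t, ...)
  })
  dts <- vapply(curves, function(c) attr(c, "frame_dt"), numeric(1))
  if (diff(range(dts)) > 1e-9) {
    abort_data("tracks have mismatched frame intervals")
  }
  nl <- vapply(curves, nrow, integer(1))
  if (length(unique(nl)) != 1) abort_data("MSD curves have different lengths")
  msd <- rowMeans(vapply(curves, function(c) c$msd_nm2,
                         numeric(nl[1])))
  out <- tibble(lag_s = curves[[1]]$lag_s, msd_nm2 = msd)
  structure(out, n_starts = attr(curves[[1]], "n_starts"),
            n_lags = attr(curves[[1]], "n_lags"),
            frame_dt = dts[1], n_tracks = length(curves),
            class = c("msd_curve", class(out)))
}

#' Power-law fit MSD(t) = A t^alpha
#'
#' Ordinary least squares on (log t, log MSD) restricted to a lag window:
#' `alpha` is the slope and `A = exp(intercept)`. Log-log OLS weighs the
#' decades of lag evenly, the standard choice in single-particle tracking.
#' `alpha = 1` indicates free diffusion, `alpha = 0` full confinement, and
#' `0 < alpha << 1` confined displacement with slow escape.
#'
#' @param curve An `msd_curve` (or data frame with `lag_s`, `msd_nm2`).
#' @param t_min,t_max Fit window (s): lags with `t_min < lag <= t_max` are
#'   used. The conventions in this package are `t_min = 1` (reported per
#'   strain) and `t_min = 5` (long-time confinement exponent).
#' @return A `power_law_fit` object (list: `A` in nm^2 s^-alpha, `alpha`,
#'   `r_squared`, `window`, `n_points`). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' msd <- tibble::tibble(lag_s = 1:100 / 10, msd_nm2 = 3 * (1:100 / 10)^0.5)
#' fit_power_law(msd, t_min = 0, t_max = 10)$alpha
#' @export
fit_power_law <- function(curve, t_min = 5, t_max = Inf) {
  sel <- curve$lag_s > t_min & curve$lag_s <= t_max
  t <- curve$lag_s[sel]; m <- curve$msd_nm2[sel]
  if (length(t) < 3) abort_data("fewer than 3 lags inside the fit window")
  if (any(m <= 0)) abort_data("non-positive MSD inside the fit window")
  fit <- lm(log(m) ~ log(t))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((log(m) - mean(log(m)))^2)
  # r^2 computed directly; a flat noiseless curve (tss = 0) is a perfect fit
  r2 <- if (tss > 0) 1 - rss / tss else as.numeric(rss < 1e-20)
  out <- list(
    A = exp(unname(coef(fit)[1])),
    alpha = unname(coef(fit)[2]),
    r_squared = r2,
    window = c(t_min = t_min, t_max = t_max),
    n_points = length(t)
  )
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("MSD(t) = A t^alpha: alpha = %.3f, A = %.3g nm^2 s^-alpha (r^2 = %.3f, %d lags in (%g, %g] s)\n",
              x$alpha, x$A, x$r_squared, x$n_points,
              x$window["t_min"], x$window["t_max"]))
  invisible(x)
}

#' Ordinary least-squares line with Pearson correlation test
#'
#' Fits `y ~ x` and reports the squared Pearson correlation together with the
#' two-tailed p-value from the t-test on r with n - 2 degrees of freedom —
#' the statistic used to relate adhesion forces to vibration amplitudes
#' across strains.
#'
#' @param data A data frame.
#' @param x,y Column names (unquoted) of predictor and response.
#' @return A `linear_fit` object (list: `slope`, `intercept`, `r_squared`,
#'   `p_two_tailed`, `n`). Supports [generics::tidy()] / [generics::glance()].
#' @examples
#' d <- tibble::tibble(force = c(1.1, 1.4, 0.8, 1.5, 1.8, 0.6, 1.1, 1.0),
#'                     amp = c(25, 17, 78, 21, 6, 95, 94, 69))
#' glance(pearson_linear_fit(d, force, amp))
#' @export
pearson_linear_fit <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) != length(yv)) abort_invalid("x and y lengths differ")
  n <- length(xv)
  if (n < 3) abort_data("need at least 3 points")
  if (sd(xv) == 0 || sd(yv) == 0) abort_data("zero variance in x or y")
  sxy <- sum((xv - mean(xv)) * (yv - mean(yv)))
  slope <- sxy / sum((xv - mean(xv))^2)
  intercept <- mean(yv) - slope * mean(xv)
  r <- sxy / (n * sd_pop(xv) * sd_pop(yv))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- list(slope = slope, intercept = intercept, r_squared = r^2,
              p_two_tailed = p, n = n)
  class(out) <- "linear_fit"
  out
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("y = %.4g + %.4g x;  r^2 = %.3f, two-tailed p = %.3g (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$p_two_tailed, x$n))
  invisible(x)
}
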