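mk_track <- function(x, y = x, dt = 1 / 60) {
  tibble::tibble(time_s = (seq_along(x) - 1) * dt, x_nm = x, y_nm = y)
}

test_that("vibration amplitude: closed forms and marker subtraction", {
  expect_equal(vibration_amplitude(mk_track(rep(3, 10))), 0)
  # alternating +-10 nm on both axes: population SD is exactly 10
  alt <- rep(c(10, -10), 50)
  expect_equal(vibration_amplitude(mk_track(alt, alt)), 10)
  # linear marker subtraction, floored at zero
  expect_equal(vibration_amplitude(mk_track(alt, alt), marker_amplitude = 4), 6)
  expect_equal(vibration_amplitude(mk_track(alt, alt), marker_amplitude = 50), 0)
  # quadrature option
  expect_equal(vibration_amplitude(mk_track(alt, alt), marker_amplitude = 6,
                                   quadrature = TRUE), 8)
  expect_error(vibration_amplitude(mk_track(1)), class = "retether_data_error")
})

test_that("vibration amplitude matches the sampling distribution of the SD", {
  # Gaussian track sigma = 50 nm, marker 5 nm, n = 2000 -> 45 +- 1.5 nm
  set.seed(101)
  amps <- replicate(20, {
    tr <- mk_track(rnorm(2000, 0, 50), rnorm(2000, 0, 50))
    vibration_amplitude(tr, marker_amplitude = 5)
  })
  expect_equal(mean(amps), 45, tolerance = 1.5 / 45)
})

test_that("position maps conserve counts and centre on the track mean", {
  tr <- mk_track(rep(2, 25))
  pm <- position_map(tr, bin_width = 5)
  expect_equal(sum(pm$count), 25)
  expect_equal(sum(pm$count > 0), 1)

  set.seed(7)
  tr2 <- mk_track(rnorm(2000, 0, 30), rnorm(2000, 0, 30))
  pm2 <- position_map(tr2, bin_width = 10)
  expect_equal(sum(pm2$count), 2000)
  # marginal SDs of an isotropic map agree within 10 %
  sx <- sqrt(sum(pm2$count * pm2$x_nm^2) / 2000)
  sy <- sqrt(sum(pm2$count * pm2$y_nm^2) / 2000)
  expect_equal(sx, sy, tolerance = 0.1)
  expect_error(position_map(tr2, bin_width = 0),
               class = "retether_invalid_argument")
})

test_that("autocorrelation: exact closed forms and estimator bound", {
  # R(0) = 1 for any track with variance
  set.seed(1)
  tr <- mk_track(rnorm(100), rnorm(100))
  ac <- track_autocorrelation(tr)
  expect_equal(ac$r[1], 1)
  # alternating series: R(1) = -(N-1)/N
  n <- 200
  alt <- rep(c(1, -1), n / 2)
  ac2 <- track_autocorrelation(mk_track(alt))
  expect_equal(ac2$r[2], -(n - 1) / n)
  # |R(h)| <= 1 for arbitrary tracks (biased estimator, Cauchy-Schwarz)
  for (s in 1:5) {
    set.seed(s)
    x <- cumsum(rnorm(300)) + rnorm(300, 0, 10)
    aci <- track_autocorrelation(mk_track(x))
    expect_true(all(abs(aci$r) <= 1 + 1e-12))
  }
  # white noise: |R(h)| < 0.07 for 1 <= h <= 100 at N = 2000
  set.seed(2)
  acw <- track_autocorrelation(mk_track(rnorm(2000)), max_lag_s = 100 / 60)
  expect_lt(max(abs(acw$r[-1])), 0.07)
  # agrees with the standard biased estimator in stats::acf
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.9), 500))
  ours <- track_autocorrelation(mk_track(x), max_lag_s = 50 / 60)
  ref <- stats::acf(x, lag.max = 50, plot = FALSE, demean = TRUE)
  expect_equal(ours$r, as.numeric(ref$acf), tolerance = 1e-12)
  expect_error(track_autocorrelation(mk_track(rep(1, 50))),
               class = "retether_data_error")
})

test_that("autocorrelation half-time: interpolation and OU relaxation", {
  lag <- seq(0, 5, by = 1 / 60)
  exp_curve <- tibble::tibble(lag_s = lag, r = exp(-lag))
  expect_equal(autocorrelation_half_time(exp_curve), log(2), tolerance = 1e-4)
  flat <- tibble::tibble(lag_s = lag, r = rep(1, length(lag)))
  expect_identical(autocorrelation_half_time(flat), Inf)
  # OU track with tau = 0.3 s: half-time = 0.3 ln 2 within 20 % (10 seeds)
  ht <- sapply(1:10, function(s) {
    tr <- generate_track("ou_confined", sd_nm = 50, tau_s = 0.3,
                         n_frames = 2000, measurement_noise_sd_nm = 0,
                         seed = s)
    autocorrelation_half_time(track_autocorrelation(tr))
  })
  expect_equal(mean(ht), 0.3 * log(2), tolerance = 0.2)
})

test_that("MSD: closed forms, start averaging, and ensemble identities", {
  # constant track
  cst <- mk_track(rep(5, 1200))
  m0 <- track_msd(cst, n_lags = 100, n_starts = 5, start_spacing = 100)
  expect_true(all(m0$msd_nm2 == 0))
  # uniform drift: MSD(i) = (v i dt)^2 exactly (x drifts, y constant)
  v <- 120; dt <- 1 / 60
  dr <- mk_track(v * (0:1199) * dt, rep(0, 1200))
  m1 <- track_msd(dr, n_lags = 100, n_starts = 5, start_spacing = 100)
  expect_equal(m1$msd_nm2, (v * m1$lag_s)^2, tolerance = 1e-12)
  expect_equal(m1$msd_nm2[1], 0)
  # free 2D diffusion: fitted MSD slope = 4D within 15 % over 10 tracks
  D <- 0.05 * 1e6  # nm^2/s
  msds <- lapply(1:10, function(s) {
    tr <- generate_track("free_diffusion", d_um2_s = 0.05, n_frames = 2000,
                         measurement_noise_sd_nm = 0, seed = 100 + s)
    track_msd(tr)
  })
  ens <- msd_ensemble(msds)
  sel <- ens$lag_s > 0
  slope <- sum(ens$msd_nm2[sel] * ens$lag_s[sel]) / sum(ens$lag_s[sel]^2)
  expect_equal(slope, 4 * D, tolerance = 0.15)
  # ensemble of identical tracks equals the individual curve
  same <- msd_ensemble(list(m1, m1))
  expect_equal(same$msd_nm2, m1$msd_nm2)
  # two-curve ensemble is the pointwise mean
  two <- msd_ensemble(list(m0, m1))
  expect_equal(two$msd_nm2, (m0$msd_nm2 + m1$msd_nm2) / 2)
  # averaging 10 OU tracks shrinks the error about the analytic OU MSD
  sd_ou <- 50; tau <- 0.3; noise <- 5
  ou_msds <- lapply(1:10, function(s) {
    track_msd(generate_track("ou_confined", sd_nm = sd_ou, tau_s = tau,
                             n_frames = 2000, measurement_noise_sd_nm = noise,
                             seed = 200 + s))
  })
  lag_idx <- c(100, 500, 900)
  ens_ou <- msd_ensemble(ou_msds)
  theory <- 4 * sd_ou^2 * (1 - exp(-ens_ou$lag_s[lag_idx] / tau)) +
    4 * noise^2
  err_ind <- rowMeans(sapply(ou_msds,
                             function(m) abs(m$msd_nm2[lag_idx] - theory)))
  err_ens <- abs(ens_ou$msd_nm2[lag_idx] - theory)
  expect_true(all(err_ens < err_ind))
  # short track errors
  expect_error(track_msd(mk_track(rnorm(100))), class = "retether_data_error")
  # mismatched frame intervals error
  tr_a <- track_msd(mk_track(rnorm(1200), dt = 1 / 60),
                    n_lags = 100, n_starts = 2, start_spacing = 100)
  tr_b <- track_msd(mk_track(rnorm(1200), dt = 1 / 50),
                    n_lags = 100, n_starts = 2, start_spacing = 100)
  expect_error(msd_ensemble(list(tr_a, tr_b)), class = "retether_data_error")
})

test_that("power-law fit recovers exponents exactly on noiseless input", {
  t <- seq(0.1, 20, by = 0.1)
  for (alpha in c(0, 0.25, 0.5, 0.77, 1)) {
    curve <- tibble::tibble(lag_s = t, msd_nm2 = 3 * t^alpha)
    fit <- fit_power_law(curve, t_min = 0, t_max = 21)
    expect_equal(fit$alpha, alpha, tolerance = 1e-10)
    expect_equal(fit$A, 3, tolerance = 1e-10)
    # r^2 of a constant response (alpha = 0) is indeterminate; skip it there
    if (alpha > 0) expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  }
  # linear MSD -> alpha 1
  lin <- tibble::tibble(lag_s = t, msd_nm2 = 4 * 5e4 * t)
  expect_equal(fit_power_law(lin, t_min = 0)$alpha, 1, tolerance = 1e-10)
  # plateaued OU MSD with window t > 5 tau -> alpha < 0.1
  tau <- 0.3
  ou <- tibble::tibble(lag_s = t, msd_nm2 = 4 * 50^2 * (1 - exp(-t / tau)))
  expect_lt(fit_power_law(ou, t_min = 5 * tau)$alpha, 0.1)
  # window restriction is honoured
  mixed <- tibble::tibble(lag_s = t, msd_nm2 = ifelse(t <= 10, t, 10 * t^0))
  fit_in <- fit_power_law(mixed, t_min = 0, t_max = 10)
  expect_equal(fit_in$alpha, 1, tolerance = 1e-10)
  expect_equal(fit_in$n_points, sum(t > 0 & t <= 10))
  # errors: too few points, non-positive MSD
  expect_error(fit_power_law(tibble::tibble(lag_s = 1:2, msd_nm2 = 1:2),
                             t_min = 0), class = "retether_data_error")
  bad <- tibble::tibble(lag_s = t, msd_nm2 = c(-1, 3 * t[-1]^0.5))
  expect_error(fit_power_law(bad, t_min = 0), class = "retether_data_error")
})

test_that("pearson linear fit matches lm/cor.test and handles degeneracies", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5.5), y = 2 * c(1, 2, 3, 4, 5.5) + 1)
  fit <- pearson_linear_fit(d, x, y)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  # independent oracle: stats::lm and stats::cor.test
  set.seed(9)
  d2 <- tibble::tibble(x = rnorm(30), y = rnorm(30) + 0.5 * rnorm(30))
  fit2 <- pearson_linear_fit(d2, x, y)
  ref_lm <- lm(y ~ x, data = d2)
  ref_ct <- cor.test(d2$x, d2$y)
  expect_equal(fit2$slope, unname(coef(ref_lm)[2]))
  expect_equal(fit2$intercept, unname(coef(ref_lm)[1]))
  expect_equal(fit2$r_squared, unname(ref_ct$estimate)^2)
  expect_equal(fit2$p_two_tailed, ref_ct$p.value)
  # tidy/glance
  expect_named(glance(fit2),
               c("r_squared", "p_two_tailed", "n", "slope", "intercept"))
  expect_equal(tidy(fit2)$estimate, c(fit2$intercept, fit2$slope))
  # degenerate inputs
  expect_error(pearson_linear_fit(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               class = "retether_data_error")
  expect_error(pearson_linear_fit(tibble::tibble(x = 1:2, y = 1:2), x, y),
               class = "retether_data_error")
})

test_that("cross-strain permutation: the printed force/amplitude pairing ranks high", {
  force <- c(1.1, 1.4, 0.8, 1.5, 1.8, 0.6, 1.1, 1.0)
  amp <- c(25, 17, 78, 21, 6, 95, 94, 69)
  r2_obs <- pearson_linear_fit(tibble::tibble(f = force, a = amp), f, a)$r_squared
  set.seed(4)
  r2_perm <- replicate(2000, {
    pearson_linear_fit(tibble::tibble(f = force, a = sample(amp)), f, a)$r_squared
  })
  expect_gt(mean(r2_obs >= r2_perm), 0.95)
})
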