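#' Generate a synthetic position track
#'
#' Emulates experimental-style centroid tracks with known statistical
#' structure, for testing the track-analysis pipeline:
#'
#' * `white_noise`: i.i.d. Gaussian positions of per-axis SD `sd_nm`.
#' * `ou_confined`: exact discrete Ornstein-Uhlenbeck update with stationary
#'   per-axis SD `sd_nm` and relaxation time `tau_s` — the canonical model of
#'   a particle confined by an elastic bond.
#' * `free_diffusion`: Gaussian increments of per-axis variance `2 D dt`.
#' * `drift`: uniform motion at `drift_nm_s` along x.
#'
#' Independent Gaussian measurement noise of SD `measurement_noise_sd_nm` is
#' added to every frame (default 5 nm, the spatial resolution of the tracking
#' experiments the generator emulates).
#'
#' @param model One of `"white_noise"`, `"ou_confined"`, `"free_diffusion"`,
#'   `"drift"`.
#' @param n_frames Number of frames.
#' @param frame_rate Frame rate (Hz).
#' @param sd_nm Stationary per-axis SD (nm), for `white_noise`/`ou_confined`.
#' @param tau_s Relaxation time (s), for `ou_confined`.
#' @param d_um2_s Diffusion coefficient (micron^2/s), for `free_diffusion`.
#' @param drift_nm_s Drift speed (nm/s) along x, for `drift`.
#' @param measurement_noise_sd_nm Measurement noise SD (nm).
#' @param seed Optional integer seed.
#' @return A track tibble (`time_s`, `x_nm`, `y_nm`).
#' @examples
#' tr <- generate_track("ou_confined", sd_nm = 50, tau_s = 0.3, seed = 7)
#' vibration_amplitude(tr)
#' @export
generate_track <- function(model = c("white_noise", "ou_confined",
                                     "free_diffusion", "drift"),
                           n_frames = 2000, frame_rate = 60,
                           sd_nm = 50, tau_s = 0.3, d_um2_s = 0.1,
                           drift_nm_s = 100,
                           measurement_noise_sd_nm = 5, seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(n_frames) || n_frames < 2) {
    abort_invalid("`n_frames` must be >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / frame_rate
  n <- as.integer(n_frames)
  one_axis <- switch(model,
    white_noise = {
      if (sd_nm <= 0) abort_invalid("`sd_nm` must be positive")
      function() rnorm(n, 0, sd_nm)
    },
    ou_confined = {
      if (sd_nm <= 0 || tau_s <= 0) {
        abort_invalid("`sd_nm` and `tau_s` must be positive")
      }
      rho <- exp(-dt / tau_s)
      function() {
        x <- numeric(n)
        x[1] <- rnorm(1, 0, sd_nm)
        innov <- rnorm(n - 1, 0, sd_nm * sqrt(1 - rho^2))
        for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
        x
      }
    },
    free_diffusion = {
      if (d_um2_s <= 0) abort_invalid("`d_um2_s` must be positive")
      step_sd <- sqrt(2 * d_um2_s * 1e6 * dt)  # nm
      function() cumsum(c(0, rnorm(n - 1, 0, step_sd)))
    },
    drift = function() drift_nm_s * (seq_len(n) - 1) * dt
  )
  x <- one_axis()
  y <- if (model == "drift") numeric(n) else one_axis()
  if (measurement_noise_sd_nm > 0) {
    x <- x + rnorm(n, 0, measurement_noise_sd_nm)
    y <- y + rnorm(n, 0, measurement_noise_sd_nm)
  }
  tibble(time_s = (seq_len(n) - 1) * dt, x_nm = x, y_nm = y)
}
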