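# Force-distance-curve metrics for bacterial-probe AFM: adhesion force,
# adhesion peaks, rupture length and adhesion energy from the retract segment,
# plus cantilever calibration and a synthetic multi-tether rupture-curve
# generator for testing.
#
# Storage convention: attractive (adhesive) forces are negative; metrics are
# reported as positive magnitudes. Curves are data frames with columns
# separation_nm, force_nN, segment ("approach"/"retract").

as_fd_curve <- function(curve) {
  need <- c("separation_nm", "force_nN", "segment")
  if (!is.data.frame(curve) || !all(need %in% names(curve))) {
    abort_format("a force-distance curve needs columns separation_nm, force_nN, segment")
  }
  if (!all(curve$segment %in% c("approach", "retract"))) {
    abort_format("segment must be 'approach' or 'retract'")
  }
  if (any(!is.finite(curve$separation_nm)) || any(!is.finite(curve$force_nN))) {
    abort_data("separations and forces must be finite")
  }
  curve
}

retract_part <- function(curve) {
  r <- curve[curve$segment == "retract", , drop = FALSE]
  if (nrow(r) == 0) abort_data("no retract segment in curve")
  r[order(r$separation_nm), , drop = FALSE]
}

#' Applied normal force from cantilever calibration
#'
#' `F_n = alpha_s * V_n * K_n`: deflection sensitivity times photodiode
#' voltage times cantilever stiffness.
#'
#' @param deflection_sensitivity alpha_s, m/V.
#' @param voltage V_n, V (photodiode output).
#' @param stiffness K_n, N/m.
#' @return Normal force in N.
#' @examples
#' normal_force(100e-9, 1, 0.046) # 4.6 nN
#' @export
normal_force <- function(deflection_sensitivity, voltage, stiffness) {
  if (!is.numeric(deflection_sensitivity) || deflection_sensitivity <= 0) {
    abort_invalid("`deflection_sensitivity` must be positive")
  }
  if (!is.numeric(stiffness) || stiffness <= 0) {
    abort_invalid("`stiffness` must be positive")
  }
  deflection_sensitivity * voltage * stiffness
}

#' Baseline and noise of a retract curve
#'
#' Robust estimate from the far-separation tail (final 10 % of retract
#' points, at least 5): baseline is the median force, noise the MAD scaled to
#' a Gaussian SD (x 1.4826).
#'
#' @param curve Force-distance curve data frame.
#' @param tail_fraction Fraction of the largest separations used.
#' @return Named list `baseline_nN`, `noise_sd_nN`, `n_tail`.
#' @export
estimate_baseline <- function(curve, tail_fraction = 0.1) {
  r <- retract_part(as_fd_curve(curve))
  n_tail <- max(5L, floor(nrow(r) * tail_fraction))
  if (nrow(r) < 5 || n_tail > nrow(r)) {
    abort_data("retract tail shorter than 5 points")
  }
  tail_f <- tail(r$force_nN, n_tail)
  list(baseline_nN = stats::median(tail_f),
       noise_sd_nN = 1.4826 * stats::mad(tail_f, constant = 1),
       n_tail = n_tail)
}

#' Adhesion force of a force-distance curve
#'
#' Magnitude of the strongest attractive force recorded during retraction:
#' the most negative baseline-subtracted retract force, reported positive.
#' Returns 0 when the retract segment never drops below baseline.
#'
#' @param curve Force-distance curve data frame.
#' @return Adhesion force, nN (>= 0).
#' @export
adhesion_force <- function(curve) {
  r <- retract_part(as_fd_curve(curve))
  bl <- estimate_baseline(curve)$baseline_nN
  max(0, -min(r$force_nN - bl))
}

# topographic prominence of peaks in g (standard definition): height above
# the higher of the two key saddles, where a key saddle is the lowest point
# between the peak and the nearest higher terrain on that side (or the lowest
# point to the edge when no higher terrain exists)
peak_prominence <- function(g, idx) {
  n <- length(g)
  vapply(idx, function(i) {
    gi <- g[i]
    higher_l <- which(g[seq_len(max(0, i - 1))] > gi)
    saddle_l <- if (length(higher_l)) min(g[max(higher_l):i]) else min(g[1:i])
    higher_r <- if (i < n) which(g[(i + 1):n] > gi) + i else integer()
    saddle_r <- if (length(higher_r)) min(g[i:min(higher_r)]) else min(g[i:n])
    gi - max(saddle_l, saddle_r)
  }, numeric(1))
}

#' Detect adhesion peaks in a retract curve
#'
#' Local minima of the baseline-subtracted retract force that lie below
#' `-min_prominence * noise_sd` and have topographic prominence of at least
#' `min_prominence * noise_sd`. Each such minimum marks the rupture of an
#' individual tether. The curve is lightly smoothed (boxcar, `smooth_window`
#' samples) before candidate detection so that single-sample noise excursions
#' — which in a curve of a thousand samples routinely exceed a 3 sigma
#' threshold somewhere — do not register as ruptures; reported separations
#' and forces refer to the smoothed curve.
#'
#' @param curve Force-distance curve data frame.
#' @param min_prominence Prominence threshold in multiples of the tail noise
#'   SD (default 3).
#' @param smooth_window Boxcar width in samples (odd; 1 disables smoothing).
#' @return Tibble `separation_nm`, `force_nN` (baseline-subtracted, negative),
#'   `prominence_nN`, ordered by separation. May be empty.
#' @export
detect_adhesion_peaks <- function(curve, min_prominence = 3,
                                  smooth_window = 5) {
  r <- retract_part(as_fd_curve(curve))
  bl <- estimate_baseline(curve)
  f <- r$force_nN - bl$baseline_nN
  thr <- min_prominence * bl$noise_sd_nN
  n <- length(f)
  if (n < 3) return(tibble(separation_nm = numeric(), force_nN = numeric(),
                           prominence_nN = numeric()))
  w <- max(1L, min(as.integer(smooth_window), n))
  if (w %% 2L == 0L) w <- w - 1L
  if (w > 1L) {
    pad <- (w - 1L) %/% 2L
    fs <- stats::filter(c(rep(f[1], pad), f, rep(f[n], pad)),
                        rep(1 / w, w), sides = 2)
    f <- as.numeric(fs[(pad + 1L):(pad + n)])
  }
  g <- -f  # adhesion wells become peaks
  cand <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n]) + 1L
  cand <- cand[g[cand] > thr]
  if (length(cand) == 0) {
    return(tibble(separation_nm = numeric(), force_nN = numeric(),
                  prominence_nN = numeric()))
  }
  prom <- peak_prominence(g, cand)
  keep <- prom >= thr
  tibble(separation_nm = r$separation_nm[cand[keep]],
         force_nN = f[cand[keep]],
         prominence_nN = prom[keep])
}

#' Rupture length of a force-distance curve
#'
#' Separation at which the entire bond has detached: the first retract sample
#' after the final adhesion peak where the baseline-subtracted force has
#' returned to within `min_prominence * noise_sd` of zero. Returns 0 (with a
#' warning) when the curve shows no adhesion peaks.
#'
#' @inheritParams detect_adhesion_peaks
#' @return Rupture length, nm.
#' @export
rupture_length <- function(curve, min_prominence = 3) {
  peaks <- detect_adhesion_peaks(curve, min_prominence)
  if (nrow(peaks) == 0) {
    warn("no adhesion peaks: rupture length undefined, returning 0")
    return(0)
  }
  r <- retract_part(as_fd_curve(curve))
  bl <- estimate_baseline(curve)
  f <- r$force_nN - bl$baseline_nN
  thr <- min_prominence * bl$noise_sd_nN
  last_peak <- max(peaks$separation_nm)
  after <- which(r$separation_nm > last_peak & f >= -thr)
  if (length(after) == 0) return(max(r$separation_nm))
  r$separation_nm[after[1]]
}

#' Adhesion energy of a force-distance curve
#'
#' Area of the adhesive well under the retract curve: trapezoidal integral of
#' the sub-baseline (attractive) force magnitude over separation, from contact
#' (minimum separation) up to the rupture length. The approach segment is
#' excluded.
#'
#' @inheritParams detect_adhesion_peaks
#' @param temperature Temperature (K) used for the kBT conversion.
#' @return Named list `energy_J`, `energy_kBT`.
#' @export
adhesion_energy <- function(curve, min_prominence = 3, temperature = 298) {
  r <- retract_part(as_fd_curve(curve))
  bl <- estimate_baseline(curve)
  f <- r$force_nN - bl$baseline_nN
  peaks <- detect_adhesion_peaks(curve, min_prominence)
  s_max <- if (nrow(peaks) == 0) max(r$separation_nm) else
    suppressWarnings(rupture_length(curve, min_prominence))
  sel <- r$separation_nm <= s_max
  s <- r$separation_nm[sel]
  w <- pmax(0, -f[sel])
  if (length(s) < 2) return(list(energy_J = 0, energy_kBT = 0))
  area_nN_nm <- sum(diff(s) * (head(w, -1) + tail(w, -1)) / 2)
  e_J <- area_nN_nm * 1e-18  # nN x nm = 1e-18 J
  list(energy_J = e_J, energy_kBT = e_J / (.kB * temperature))
}

#' Full retract-curve analysis
#'
#' One-stop summary of a force-distance curve: baseline, noise, adhesion
#' force, adhesion peaks, rupture length and adhesion energy.
#'
#' @inheritParams adhesion_energy
#' @return One-row tibble `adhesion_force_nN`, `n_peaks`, `rupture_length_nm`,
#'   `adhesion_energy_J`, `adhesion_energy_kBT`, `baseline_nN`, `noise_sd_nN`;
#'   the peak table is attached as attribute `peaks`.
#' @export
analyze_fd_curve <- function(curve, min_prominence = 3, temperature = 298) {
  curve <- as_fd_curve(curve)
  bl <- estimate_baseline(curve)
  peaks <- detect_adhesion_peaks(curve, min_prominence)
  rl <- if (nrow(peaks) > 0) rupture_length(curve, min_prominence) else 0
  en <- adhesion_energy(curve, min_prominence, temperature)
  out <- tibble(
    adhesion_force_nN = adhesion_force(curve),
    n_peaks = nrow(peaks),
    rupture_length_nm = rl,
    adhesion_energy_J = en$energy_J,
    adhesion_energy_kBT = en$energy_kBT,
    baseline_nN = bl$baseline_nN,
    noise_sd_nN = bl$noise_sd_nN
  )
  structure(out, peaks = peaks)
}

#' Synthetic multi-tether rupture curve
#'
#' Generates a retract force-distance curve as the superposition of Hookean
#' tethers: tether `j` engages once the separation passes its attachment
#' offset, loads linearly with spring constant `k`, and ruptures (force drops
#' to zero) when its elastic force exceeds its rupture force. Gaussian
#' measurement noise is added. The returned curve carries a ground-truth
#' ledger (per-tether rupture separations and forces, total stored elastic
#' energy) for round-trip testing of the retract-curve metrics.
#'
#' @param n_tethers Number of tethers.
#' @param k Spring constant, N/m (numerically equal to nN/nm). The default
#'   0.01 N/m gives nN-scale rupture forces over ~100 nm extensions, the
#'   scale seen in forced single-bacterium retract curves.
#' @param rupture_forces Per-tether rupture force, nN (length `n_tethers`).
#' @param attachment_offsets Per-tether engagement separation, nm.
#' @param noise_sd Gaussian noise SD, nN.
#' @param ds Separation sampling step, nm.
#' @param tail_nm Baseline tail length beyond the last rupture, nm.
#' @param seed Optional seed for the noise.
#' @return An `fd_curve` tibble (`separation_nm`, `force_nN`, `segment`) with
#'   attribute `ledger`: list `rupture_separations_nm`, `rupture_forces_nN`,
#'   `deepest_force_nN`, `last_rupture_nm`, `energy_J`.
#' @examples
#' fd <- synth_fd_curve(3, rupture_forces = c(0.4, 0.7, 1.1),
#'                      attachment_offsets = c(0, 40, 90), noise_sd = 0)
#' attr(fd, "ledger")$last_rupture_nm
#' @export
synth_fd_curve <- function(n_tethers, k = 0.01,
                           rupture_forces = numeric(n_tethers),
                           attachment_offsets = numeric(n_tethers),
                           noise_sd = 0.01, ds = 0.5, tail_nm = 60,
                           seed = NULL) {
  if (length(rupture_forces) != n_tethers ||
      length(attachment_offsets) != n_tethers) {
    abort_invalid("rupture_forces and attachment_offsets must have length n_tethers")
  }
  if (!is.null(seed)) set.seed(seed)
  k_nN_nm <- k  # 1 N/m = 1 nN/nm
  rupture_sep <- attachment_offsets + rupture_forces / k_nN_nm
  s_end <- if (n_tethers > 0) max(rupture_sep) + tail_nm else 100
  s <- seq(0, s_end, by = ds)
  f <- numeric(length(s))
  for (j in seq_len(n_tethers)) {
    engaged <- s >= attachment_offsets[j] & s < rupture_sep[j]
    f[engaged] <- f[engaged] - k_nN_nm * (s[engaged] - attachment_offsets[j])
  }
  noiseless_min <- if (length(f)) min(f) else 0
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  energy_J <- sum(0.5 * k_nN_nm * (rupture_forces / k_nN_nm)^2) * 1e-18
  curve <- tibble(separation_nm = s, force_nN = f, segment = "retract")
  approach <- tibble(separation_nm = s, force_nN =
                       if (noise_sd > 0) rnorm(length(s), 0, noise_sd) else 0,
                     segment = "approach")
  out <- dplyr::bind_rows(approach, curve)
  ledger <- list(
    rupture_separations_nm = rupture_sep,
    rupture_forces_nN = rupture_forces,
    deepest_force_nN = -noiseless_min,
    last_rupture_nm = if (n_tethers > 0) max(rupture_sep) else 0,
    energy_J = energy_J
  )
  structure(out, ledger = ledger, class = c("fd_curve", class(out)))
}
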