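#' Sweep the tether adhesion force over replicate seeds
#'
#' Runs [simulate_tpm()] on a grid of tether adhesion forces with replicate
#' seeds and summarises each run: vibration amplitude of the simulated track,
#' final number of bound tethers, detachment count, and residence-time
#' summaries. This reproduces the amplitude-versus-adhesion-force relation and
#' the force-dependence of tether turnover.
#'
#' @param config Base [sim_config()]; its `tether_adhesion_force` and `seed`
#'   are overridden by the grid.
#' @param forces Adhesion forces to sweep (N). Default [default_force_sweep()].
#' @param seeds Integer seeds replicated at every force.
#' @return Tibble with one row per (force, seed): `force_N`, `seed`,
#'   `amplitude_nm`, `final_bound`, `n_detach`, `n_attach`,
#'   `median_residence_s` (completed intervals only; `NA` when none).
#' @examples
#' \donttest{
#' sw <- sweep_adhesion_force(sim_config(duration = 2), seeds = 1:2,
#'                            forces = c(1e-13, 1e-12))
#' }
#' @export
sweep_adhesion_force <- function(config = sim_config(),
                                 forces = default_force_sweep(),
                                 seeds = 1:6) {
  if (length(forces) < 1) abort_invalid("`forces` must be non-empty")
  grid <- tidyr::expand_grid(force_N = forces, seed = as.integer(seeds))
  purrr::pmap_dfr(grid, function(force_N, seed) {
    cfg <- config
    cfg$tether_adhesion_force <- force_N
    cfg$seed <- seed
    traj <- simulate_tpm(validate_sim_config(cfg))
    ev <- tether_events(traj)
    res <- residence_times(traj)
    done <- res$duration_s[!res$censored]
    tibble(
      force_N = force_N, seed = seed,
      amplitude_nm = vibration_amplitude(traj),
      final_bound = utils::tail(traj$n_bound, 1),
      n_detach = sum(ev$event == "detach"),
      n_attach = sum(ev$event == "attach"),
      median_residence_s = if (length(done)) stats::median(done) else NA_real_
    )
  })
}

#' Summarise an adhesion-force sweep
#'
#' Mean and SD of the vibration amplitude per force, plus the mean final
#' bound-tether count, from a [sweep_adhesion_force()] table.
#'
#' @param sweep Output of [sweep_adhesion_force()].
#' @return Tibble `force_N`, `n_runs`, `mean_amplitude_nm`, `sd_amplitude_nm`,
#'   `mean_final_bound`.
#' @export
summarize_sweep <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(sweep, .data$force_N),
    n_runs = dplyr::n(),
    mean_amplitude_nm = mean(.data$amplitude_nm),
    sd_amplitude_nm = sd(.data$amplitude_nm),
    mean_final_bound = mean(.data$final_bound),
    .groups = "drop"
  )
}
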