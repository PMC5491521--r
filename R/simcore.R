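#' Quasi-uniform anchor directions on the unit sphere
#'
#' Places `n` tether anchor directions on the unit sphere with a Fibonacci
#' spiral lattice, the standard deterministic construction for near-equal-area
#' point sets. Anchors are fixed in the particle body frame (the particle is
#' not rotated during a simulation).
#'
#' @param n Number of anchors (>= 1).
#' @return A tibble with columns `tether`, `ux`, `uy`, `uz`; each row a unit
#'   vector.
#' @examples
#' place_anchors(4)
#' @export
place_anchors <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort_invalid("`n` must be a count >= 1")
  }
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  tibble(tether = i + 1L, ux = r * cos(phi), uy = r * sin(phi), uz = z)
}

#' Initialize particle and tether states
#'
#' The sphere is placed resting on the substratum (centre at `z = a`). The
#' `n_tethers_initial_bound` anchors whose tips are closest to the plane are
#' bound, each attached at the perpendicular projection of its anchor tip onto
#' `z = 0` (ties broken by tether index). Tethers attached this way start
#' slack: a pull-only tether exerts no force until the tip-to-attachment
#' distance exceeds the rest length.
#'
#' @param config A [sim_config()].
#' @return A list with `particle` (named list: `position` (m, length 3),
#'   `velocity`, `time`) and `tethers` (tibble: `tether`, `ux`, `uy`, `uz`,
#'   `bound`, `att_x`, `att_y`, `bind_time`).
#' @export
initialize_tethers <- function(config) {
  config <- validate_sim_config(config)
  a <- config$particle_diameter / 2
  anc <- place_anchors(config$n_tethers_total)
  tip_height <- a + a * anc$uz       # centre at z = a
  within <- tip_height <= config$tether_rest_length
  nb <- config$n_tethers_initial_bound
  if (sum(within) < nb) {
    abort_config(sprintf(
      "only %d anchors within tether rest length of the surface; %d bound tethers requested",
      sum(within), nb))
  }
  ord <- order(tip_height, anc$tether)
  bound_idx <- ord[seq_len(nb)]
  tethers <- anc
  tethers$bound <- FALSE
  tethers$att_x <- NA_real_
  tethers$att_y <- NA_real_
  tethers$bind_time <- NA_real_
  if (nb > 0) {
    tethers$bound[bound_idx] <- TRUE
    tethers$att_x[bound_idx] <- 0 + a * tethers$ux[bound_idx]
    tethers$att_y[bound_idx] <- 0 + a * tethers$uy[bound_idx]
    tethers$bind_time[bound_idx] <- 0
  }
  list(
    particle = list(position = c(0, 0, a), velocity = c(0, 0, 0), time = 0),
    tethers = tethers
  )
}

#' Elastic force of one bound tether on the particle
#'
#' Pull-only Hookean restoring force: magnitude `k * max(0, d - L0)` where `d`
#' is the distance from the anchor tip to the surface attachment point,
#' directed from the tip toward the attachment point. Slack tethers
#' (`d <= L0`) exert no force unless `allow_compression` is set in the
#' configuration, in which case the spring is two-sided.
#'
#' @param tether One row of the tether tibble (see [initialize_tethers()]).
#' @param particle Particle state list with a `position` element (m).
#' @param config A [sim_config()].
#' @return Numeric length-3 force vector (N).
#' @export
tether_force <- function(tether, particle, config) {
  if (nrow(tether) != 1) abort_invalid("`tether` must be a single row")
  if (!isTRUE(tether$bound)) {
    abort_contract("tether_force() called on an unbound tether")
  }
  a <- config$particle_diameter / 2
  tip <- particle$position + a * c(tether$ux, tether$uy, tether$uz)
  d <- c(tether$att_x, tether$att_y, 0) - tip
  dist <- sqrt(sum(d^2))
  if (dist < 1e-15) return(c(0, 0, 0))
  ext <- dist - config$tether_rest_length
  if (ext <= 0 && !config$allow_compression) return(c(0, 0, 0))
  config$tether_spring_constant * ext * d / dist
}

total_tether_force <- function(particle, tethers, config) {
  f <- c(0, 0, 0)
  for (i in which(tethers$bound)) {
    f <- f + tether_force(tethers[i, ], particle, config)
  }
  f
}

#' Advance the particle by one timestep (reference R implementation)
#'
#' Overdamped Euler-Maruyama update: displacement `F dt / gamma` plus an
#' isotropic Gaussian kick of per-axis variance `2 kB T dt / gamma`, with
#' `gamma = 6 pi eta a` the Stokes drag. The centre is reflected at
#' `z = a` (non-penetration). This R version defines the update used, step
#' for step, by the compiled loop inside [simulate_tpm()].
#'
#' @param particle Particle state list (`position`, `time`).
#' @param tethers Tether tibble.
#' @param config A [sim_config()].
#' @return Updated particle state.
#' @export
step_particle <- function(particle, tethers, config) {
  if (config$timestep <= 0) abort_invalid("timestep must be positive")
  gamma <- drag_coefficient(config)
  dt <- config$timestep
  f <- total_tether_force(particle, tethers, config)
  sig <- sqrt(2 * .kB * config$temperature * dt / gamma)
  pos <- particle$position + f / gamma * dt + rnorm(3, 0, sig)
  a <- config$particle_diameter / 2
  if (pos[3] < a) pos[3] <- 2 * a - pos[3]
  particle$position <- pos
  particle$time <- particle$time + dt
  particle
}

#' Update tether binding states (reference R implementation)
#'
#' Detachments first: every bound tether whose elastic force strictly exceeds
#' the tether adhesion force is released. Then attachments: every unbound
#' tether whose anchor tip lies within the rest length of the plane binds at
#' the perpendicular projection of its tip (subject to
#' `attachment_probability`). Both passes run in ascending tether index.
#'
#' @param particle Particle state list.
#' @param tethers Tether tibble.
#' @param config A [sim_config()].
#' @param time Current simulation time (s), stamped on logged events.
#' @return List with updated `tethers` and an `events` tibble
#'   (`time_s`, `tether`, `event` in `c("attach", "detach")`).
#' @export
update_tethers <- function(particle, tethers, config, time) {
  a <- config$particle_diameter / 2
  L0 <- config$tether_rest_length
  ev_t <- numeric(); ev_i <- integer(); ev_e <- character()
  for (i in which(tethers$bound)) {
    f <- sqrt(sum(tether_force(tethers[i, ], particle, config)^2))
    if (f > config$tether_adhesion_force) {
      tethers$bound[i] <- FALSE
      tethers$att_x[i] <- NA_real_; tethers$att_y[i] <- NA_real_
      ev_t <- c(ev_t, time); ev_i <- c(ev_i, i); ev_e <- c(ev_e, "detach")
    }
  }
  for (i in which(!tethers$bound)) {
    tip <- particle$position + a * c(tethers$ux[i], tethers$uy[i], tethers$uz[i])
    if (tip[3] <= L0 &&
        (config$attachment_probability >= 1 ||
         runif(1) < config$attachment_probability)) {
      tethers$bound[i] <- TRUE
      tethers$att_x[i] <- tip[1]; tethers$att_y[i] <- tip[2]
      tethers$bind_time[i] <- time
      ev_t <- c(ev_t, time); ev_i <- c(ev_i, i); ev_e <- c(ev_e, "attach")
    }
  }
  list(tethers = tethers,
       events = tibble(time_s = ev_t, tether = ev_i, event = ev_e))
}

#' Simulate tethered particle motion
#'
#' Runs the Brownian-dynamics loop (compiled) for `config$duration` seconds
#' and returns the track sampled at `config$frame_rate`, in nm, together with
#' the full tether attach/detach event log. Frames are recorded at the
#' integration step nearest each multiple of the frame interval; the frame
#' count is `floor(duration * frame_rate)`. Runs are bit-reproducible for a
#' fixed seed and timestep.
#'
#' @param config A [sim_config()].
#' @param init Optional initial state (as returned by [initialize_tethers()]),
#'   overriding the default placement. Used e.g. to start from pre-tensioned
#'   tethers in validation studies.
#' @return A `tpm_trajectory`: a tibble with columns `time_s`, `x_nm`, `y_nm`,
#'   `z_nm` (centre position; x/y relative to the starting position) and
#'   `n_bound`, with attributes `events` (tibble `time_s`, `tether`, `event`),
#'   `config`, and `final_state`. Access the log with [tether_events()].
#' @examples
#' traj <- simulate_tpm(sim_config(duration = 0.5, seed = 42))
#' nrow(traj)
#' @export
simulate_tpm <- function(config, init = NULL) {
  config <- validate_sim_config(config)
  if (is.null(init)) init <- initialize_tethers(config)
  a <- config$particle_diameter / 2
  dt <- config$timestep
  n_frames <- floor(config$duration * config$frame_rate)
  frame_steps <- round((seq_len(n_frames) - 1) / config$frame_rate / dt)
  n_steps <- max(frame_steps)
  te <- init$tethers
  set.seed(config$seed)
  res <- simulate_core(
    anchors = cbind(te$ux, te$uy, te$uz),
    radius = a,
    bound0 = te$bound,
    attx0 = ifelse(is.na(te$att_x), 0, te$att_x),
    atty0 = ifelse(is.na(te$att_y), 0, te$att_y),
    bindt0 = ifelse(is.na(te$bind_time), -1, te$bind_time),
    pos0 = init$particle$position,
    gamma = drag_coefficient(config),
    kBT = .kB * config$temperature,
    kspring = config$tether_spring_constant,
    L0 = config$tether_rest_length,
    f_adh = config$tether_adhesion_force,
    dt = dt,
    n_steps_d = n_steps,
    frame_steps = frame_steps,
    attach_prob = config$attachment_probability,
    allow_compression = config$allow_compression,
    inertial = identical(config$integrator, "inertial"),
    mass = config$particle_mass
  )
  fr <- res$frames
  traj <- tibble(
    time_s = (seq_len(n_frames) - 1) / config$frame_rate,
    x_nm = (fr[, 1] - init$particle$position[1]) * 1e9,
    y_nm = (fr[, 2] - init$particle$position[2]) * 1e9,
    z_nm = fr[, 3] * 1e9,
    n_bound = res$frame_bound
  )
  events <- tibble(
    time_s = res$event_time,
    tether = res$event_tether,
    event = c("attach", "detach")[res$event_type]
  )
  final <- list(
    position = res$final_position,
    tethers = tibble(
      tether = te$tether, ux = te$ux, uy = te$uy, uz = te$uz,
      bound = res$final_bound,
      att_x = ifelse(res$final_bound, res$final_attx, NA_real_),
      att_y = ifelse(res$final_bound, res$final_atty, NA_real_),
      bind_time = ifelse(res$final_bind_time < 0, NA_real_,
                         res$final_bind_time)
    )
  )
  structure(traj,
            events = events, config = config, final_state = final,
            class = c("tpm_trajectory", class(traj)))
}

#' Tether attach/detach event log of a trajectory
#' @param traj A `tpm_trajectory` from [simulate_tpm()].
#' @return Tibble `time_s`, `tether`, `event`.
#' @export
tether_events <- function(traj) {
  ev <- attr(traj, "events")
  if (is.null(ev)) abort_data("no event log attached to this track")
  ev
}

#' Tether residence times from an event log
#'
#' One duration per completed attach -> detach pair, replayed per tether in
#' time order. Tethers still bound at the end of the run contribute a
#' right-censored interval (`censored = TRUE`) lasting until `duration`.
#'
#' @param events Event tibble (`time_s`, `tether`, `event`) as returned by
#'   [tether_events()], or a `tpm_trajectory`.
#' @param duration Run length (s), used to close censored intervals. Taken
#'   from the trajectory's config when `events` is a `tpm_trajectory`.
#' @param initial_bound Optional integer vector of tether indices bound at
#'   t = 0 (their first interval starts at 0). Inferred from the trajectory
#'   when available.
#' @return Tibble `tether`, `start_s`, `end_s`, `duration_s`, `censored`.
#' @export
residence_times <- function(events, duration = NULL, initial_bound = NULL) {
  if (inherits(events, "tpm_trajectory")) {
    cfg <- attr(events, "config")
    if (is.null(duration)) duration <- cfg$duration
    init <- initialize_tethers(cfg)
    initial_bound <- init$tethers$tether[init$tethers$bound]
    events <- tether_events(events)
  }
  if (is.null(duration)) abort_invalid("`duration` is required")
  if (nrow(events) == 0 && length(initial_bound) == 0) {
    return(tibble(tether = integer(), start_s = numeric(),
                  end_s = numeric(), duration_s = numeric(),
                  censored = logical()))
  }
  out <- list()
  idx <- sort(unique(c(events$tether, initial_bound)))
  for (i in idx) {
    ev <- events[events$tether == i, , drop = FALSE]
    ev <- ev[order(ev$time_s), , drop = FALSE]
    open <- if (i %in% initial_bound) 0 else NA_real_
    expected <- if (is.na(open)) "attach" else "detach"
    for (j in seq_len(nrow(ev))) {
      if (ev$event[j] != expected) {
        abort_data(sprintf("tether %d: events do not alternate attach/detach", i))
      }
      if (ev$event[j] == "attach") {
        open <- ev$time_s[j]
        expected <- "detach"
      } else {
        out[[length(out) + 1]] <- tibble(
          tether = i, start_s = open, end_s = ev$time_s[j],
          duration_s = ev$time_s[j] - open, censored = FALSE)
        open <- NA_real_
        expected <- "attach"
      }
    }
    if (!is.na(open)) {
      out[[length(out) + 1]] <- tibble(
        tether = i, start_s = open, end_s = duration,
        duration_s = duration - open, censored = TRUE)
    }
  }
  dplyr::bind_rows(out)
}
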