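# shared fixtures, built in code

kB <- 1.380649e-23

# short run for structural tests (2 s, default physics)
short_config <- function(seed = 11, ...) {
  sim_config(duration = 2, seed = seed, ...)
}

# a pre-tensioned, 4-fold symmetric tether arrangement whose potential is
# nearly harmonic at the equilibrium (0, 0, a): anchors tilted down-outward,
# attachments displaced radially so each tether carries a 100 nm extension
pretensioned_init <- function(cfg, pre_extension = 100e-9) {
  a <- cfg$particle_diameter / 2
  L0 <- cfg$tether_rest_length
  polar <- 150 * pi / 180
  az <- c(0, 0.5, 1, 1.5) * pi
  anc <- tibble::tibble(
    tether = 1:4,
    ux = sin(polar) * cos(az),
    uy = sin(polar) * sin(az),
    uz = cos(polar)
  )
  tipz <- a + a * anc$uz
  d_target <- L0 + pre_extension
  rho <- sqrt(d_target^2 - tipz^2)  # radial offset of attachment from tip
  tipx <- a * anc$ux; tipy <- a * anc$uy
  tipr <- sqrt(tipx^2 + tipy^2)
  anc$bound <- TRUE
  anc$att_x <- tipx * (1 + rho / tipr)
  anc$att_y <- tipy * (1 + rho / tipr)
  anc$bind_time <- 0
  list(particle = list(position = c(0, 0, a), velocity = c(0, 0, 0), time = 0),
       tethers = anc)
}

# total tether potential energy at particle centre position p (pull-only)
tether_potential <- function(p, tethers, cfg) {
  a <- cfg$particle_diameter / 2
  u <- 0
  for (i in which(tethers$bound)) {
    tip <- p + a * c(tethers$ux[i], tethers$uy[i], tethers$uz[i])
    d <- sqrt(sum((c(tethers$att_x[i], tethers$att_y[i], 0) - tip)^2))
    ext <- max(0, d - cfg$tether_rest_length)
    u <- u + 0.5 * cfg$tether_spring_constant * ext^2
  }
  u
}

# lateral stiffness at the constrained equilibrium (central finite difference)
lateral_stiffness <- function(init, cfg, h = 1e-10) {
  p0 <- init$particle$position
  u <- function(dx) tether_potential(p0 + c(dx, 0, 0), init$tethers, cfg)
  (u(h) - 2 * u(0) + u(-h)) / h^2
}
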