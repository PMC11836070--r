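# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Gauss-Legendre quadrature of the defining Schulz-swimmer ISF integral
# f(q, tau) = Int P_Schulz(v) sinc(q v tau) dv, with the Schulz distribution
# parameterised as gamma(shape Z + 1, rate (Z + 1)/v_bar). Nodes are computed
# once per session.
.gl_nodes <- local({
  nodes <- NULL
  function() {
    if (is.null(nodes)) nodes <<- pracma::gaussLegendre(600, 0, 1)
    nodes
  }
})

schulz_isf_quadrature <- function(q, tau, v_bar, Z) {
  gl <- .gl_nodes()
  vmax <- qgamma(1 - 1e-14, shape = Z + 1, rate = (Z + 1) / v_bar)
  x <- gl$x * vmax
  w <- gl$w * vmax
  phase <- q * x * tau
  s <- dgamma(x, shape = Z + 1, rate = (Z + 1) / v_bar) *
    ifelse(phase < 1e-12, 1, sin(phase) / phase)
  sum(w * s)
}

# Dense linear-algebra oracle for the force/torque balance: build the raw
# (unscaled) 3x3 system in SI units and solve it via qr.solve.
swim_oracle <- function(pm, bd, motor_hz) {
  omega_m <- 2 * pi * motor_hz
  M <- matrix(c(
    pm$A + bd$A0_eff, -pm$B, 0,
    -pm$B, pm$C, -bd$C0_eff,
    0, 1, 1
  ), nrow = 3, byrow = TRUE)
  # same equilibration trick, but an independent code path and factorisation
  s <- c(1e-7, 1, 1)
  Ms <- sweep(M, 2, s, `*`)
  r <- apply(abs(Ms), 1, max)
  x <- s * qr.solve(Ms / r, c(0, 0, omega_m) / r)
  list(v_um_s = x[1] / 1e-6, omega_flag_hz = x[2] / (2 * pi),
       omega_body_hz = x[3] / (2 * pi))
}

# Time-and-particle-averaged mean squared displacement from unwrapped
# trajectories (n_frames x n_particles x 2, um), at integer frame lags.
trajectory_msd <- function(traj, lags) {
  vapply(lags, function(lag) {
    nT <- dim(traj)[1]
    d <- traj[(lag + 1):nT, , , drop = FALSE] -
      traj[1:(nT - lag), , , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2)
  }, numeric(1))
}

# random valid model inputs for property-style sweeps
random_model_inputs <- function() {
  helix <- helix_geometry(
    helix_radius_um = runif(1, 0.15, 0.3),
    pitch_um = runif(1, 1.8, 2.8),
    axial_length_um = runif(1, 3, 9),
    filament_radius_um = runif(1, 0.008, 0.03)
  )
  body <- cell_body(
    body_length_um = runif(1, 2, 4.5),
    body_width_um = runif(1, 0.6, 1.1),
    wobble_angle_rad = runif(1, 0, 40 * pi / 180)
  )
  mu <- runif(1, 0.7e-3, 1.5e-3)
  variant <- sample(c("gray_hancock", "lighthill"), 1)
  fc <- friction_coefficients(helix, mu, variant)
  list(pm = propulsion_matrix(helix, fc), bd = body_drag(body, mu),
       motor_hz = runif(1, 120, 300), helix = helix, body = body, mu = mu)
}
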