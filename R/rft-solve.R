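#' Solve the force/torque balance under a constant motor speed
#'
#' The swimmer is force- and torque-free. With bundle propulsion matrix
#' (A, B, C), effective body drags (A0_eff, C0_eff) and angular velocities
#' omega (bundle) and Omega (body counter-rotation, reported as a magnitude),
#' the model solves the linear system
#' \deqn{(A + A_{0,eff}) v = B \omega}
#' \deqn{C \omega - B v = C_{0,eff} \Omega}
#' \deqn{\omega + \Omega = \omega_m}
#' where the kinematic constraint expresses that the flagellar motor rotates
#' the filament relative to the body at a fixed rate \eqn{\omega_m = 2\pi f_m}
#' independent of load and of the number of flagella. The bundle torque is
#' \eqn{\tau = C\omega - Bv}.
#'
#' Because every drag operator is linear in the viscosity, the kinematic
#' outputs (v, omega, Omega) are independent of mu at fixed motor frequency,
#' while forces and torques scale linearly with mu.
#'
#' @param pm A [propulsion_matrix()].
#' @param bd A [body_drag()].
#' @param motor_hz Motor rotation frequency f_m in Hz (default 220, the
#'   constant speed at which the motors are observed to operate).
#' @return An object of class `swim_solution` with `v_um_s`, `omega_flag_hz`,
#'   `omega_body_hz`, `bundle_torque_pN_um`, `motor_hz`, `mu`, and the
#'   relative force/torque residuals of the balance (<= 1e-10 by
#'   construction; a violation raises an error).
#' @examples
#' h <- helix_geometry(0.2, 2.26, 6, 0.01)
#' pm <- propulsion_matrix(h, friction_coefficients(h))
#' bd <- body_drag(cell_body(3, 0.9, 20 * pi / 180))
#' sol <- solve_swim(pm, bd)
#' sol$omega_flag_hz + sol$omega_body_hz  # = 220
#' @export
solve_swim <- function(pm, bd, motor_hz = 220) {
  stopifnot(inherits(pm, "propulsion_matrix"), inherits(bd, "body_drag"))
  .assert_scalar(motor_hz, "motor_hz", 0, strict_lower = TRUE)
  omega_m <- 2 * pi * motor_hz
  M <- matrix(c(
    pm$A + bd$A0_eff, -pm$B, 0,
    -pm$B, pm$C, -bd$C0_eff,
    0, 1, 1
  ), nrow = 3, byrow = TRUE)
  rhs <- c(0, 0, omega_m)
  # equilibrate: drag entries span ~14 decades in SI, so express v in units of
  # the helix radius per second (column scaling) and normalise each row;
  # neither changes the solution, both tame the condition number
  col_scale <- c(pm$helix$helix_radius_um * .UM, 1, 1)
  Ms <- sweep(M, 2, col_scale, `*`)
  row_scale <- apply(abs(Ms), 1, max)
  if (any(row_scale == 0)) {
    stop("singular force/torque balance (degenerate drag coefficients)",
         call. = FALSE)
  }
  Ms <- Ms / row_scale
  x <- tryCatch(col_scale * solve(Ms, rhs / row_scale),
                error = function(e) {
    stop("singular force/torque balance (degenerate drag coefficients): ",
         conditionMessage(e), call. = FALSE)
  })
  v <- x[1]
  om <- x[2]
  Om <- x[3]
  # relative residuals of the three balance equations
  r_force <- abs((pm$A + bd$A0_eff) * v - pm$B * om) /
    max(abs(pm$A + bd$A0_eff) * abs(v), abs(pm$B * om), .Machine$double.xmin)
  r_torque <- abs(pm$C * om - pm$B * v - bd$C0_eff * Om) /
    max(abs(pm$C * om), abs(pm$B * v), abs(bd$C0_eff * Om),
        .Machine$double.xmin)
  if (r_force > 1e-10 || r_torque > 1e-10) {
    stop("force/torque balance residuals exceed tolerance", call. = FALSE)
  }
  tau <- pm$C * om - pm$B * v
  structure(
    list(
      v_um_s = v / .UM,
      omega_flag_hz = om / (2 * pi),
      omega_body_hz = Om / (2 * pi),
      bundle_torque_pN_um = tau / .PN_UM,
      motor_hz = motor_hz,
      mu = pm$mu,
      force_residual = r_force,
      torque_residual = r_torque
    ),
    class = "swim_solution"
  )
}

#' @export
print.swim_solution <- function(x, ...) {
  cat(sprintf(
    "swim solution: v = %.2f um/s, omega_flag = %.1f Hz, omega_body = %.1f Hz\n",
    x$v_um_s, x$omega_flag_hz, x$omega_body_hz))
  cat(sprintf("  motor = %.1f Hz, bundle torque = %.3g pN um (mu = %g Pa s)\n",
              x$motor_hz, x$bundle_torque_pN_um, x$mu))
  invisible(x)
}

#' Torque load per flagellar motor
#'
#' The bundle torque is generated jointly by the N motors, so the load on
#' each is the bundle torque divided by N. Under the constant-motor-speed
#' model this per-motor load is low and decreases as flagella are added.
#'
#' @param sol A [solve_swim()] solution.
#' @param n_flagella Number of flagella sharing the load.
#' @return Torque per motor in pN um.
#' @export
torque_per_motor <- function(sol, n_flagella) {
  stopifnot(inherits(sol, "swim_solution"))
  .assert_scalar(n_flagella, "n_flagella", 1)
  sol$bundle_torque_pN_um / n_flagella
}

#' Default single-cell model configuration
#'
#' Bundles the geometry, fluid and motor parameters of the wild-type-like
#' swimmer into one list consumed by [velocity_vs_flagella()] and
#' [predict_population_curve()]. Defaults: normal left-handed filament
#' (R = 0.2 um, P = 2.26 um, a = 0.01 um), 3.0 x 0.9 um body wobbling at 20
#' degrees, motor at 220 Hz, mu = 1e-3 Pa s, Gray-Hancock coefficients,
#' sqrt(N) bundle thickening, and the default number/length couplings of
#' [coupling_model()].
#'
#' @param helix Base filament [helix_geometry()].
#' @param body [cell_body()] used for single-cell sweeps.
#' @param motor_hz Motor frequency (Hz).
#' @param mu Viscosity (Pa s).
#' @param variant Friction-coefficient variant.
#' @param thickness_exponent Bundle thickening exponent.
#' @param coupling A [coupling_model()] providing the length-versus-number
#'   rule.
#' @return A list of class `rft_config`.
#' @export
rft_config <- function(helix = helix_geometry(0.2, 2.26, 6, 0.01),
                       body = cell_body(3.0, 0.9, 20 * pi / 180),
                       motor_hz = 220,
                       mu = 1e-3,
                       variant = c("gray_hancock", "lighthill"),
                       thickness_exponent = 0.5,
                       coupling = coupling_model()) {
  variant <- match.arg(variant)
  stopifnot(inherits(helix, "helix_geometry"), inherits(body, "cell_body"),
            inherits(coupling, "coupling_model"))
  .assert_scalar(motor_hz, "motor_hz", 0, strict_lower = TRUE)
  .assert_scalar(mu, "mu", 0, strict_lower = TRUE)
  structure(
    list(helix = helix, body = body, motor_hz = motor_hz, mu = mu,
         variant = variant, thickness_exponent = thickness_exponent,
         coupling = coupling),
    class = "rft_config"
  )
}

#' Swimming kinematics as a function of flagellar number
#'
#' Sweeps the model over N: for each flagellar number the effective bundle is
#' built (thicker and, through the coupling, longer), its propulsion matrix
#' computed, and the force/torque balance solved at constant motor speed.
#' The velocity rises with N while the cell-body drag still dominates, then
#' saturates: once the flagellar drag dwarfs the body drag, extra thrust from
#' added filaments is offset by the identical increase in flagellar drag.
#'
#' @param config An [rft_config()].
#' @param n_range Integer vector of flagellar numbers (default 1:10).
#' @param length_rule Optional override of the length-versus-number rule; by
#'   default it is derived from `config$coupling` via [length_rule_fun()].
#' @return A data.frame with one row per N: `n_flagella`, `v_um_s`,
#'   `omega_flag_hz`, `omega_body_hz`, `bundle_torque_pN_um`,
#'   `torque_per_motor_pN_um`.
#' @examples
#' curve <- velocity_vs_flagella(rft_config(), 1:8)
#' curve$omega_flag_hz + curve$omega_body_hz  # all equal to 220
#' @export
velocity_vs_flagella <- function(config = rft_config(), n_range = 1:10,
                                 length_rule = NULL) {
  stopifnot(inherits(config, "rft_config"))
  if (length(n_range) < 1 || any(n_range < 1)) {
    stop("n_range must contain flagellar numbers >= 1", call. = FALSE)
  }
  rule <- length_rule %||% length_rule_fun(config$coupling)
  bd <- body_drag(config$body, config$mu)
  rows <- lapply(n_range, function(N) {
    b <- bundle_geometry(N, config$helix, rule, config$thickness_exponent)
    fc <- friction_coefficients(b, config$mu, config$variant)
    pm <- propulsion_matrix(b, fc)
    sol <- solve_swim(pm, bd, config$motor_hz)
    data.frame(
      n_flagella = N,
      v_um_s = sol$v_um_s,
      omega_flag_hz = sol$omega_flag_hz,
      omega_body_hz = sol$omega_body_hz,
      bundle_torque_pN_um = sol$bundle_torque_pN_um,
      torque_per_motor_pN_um = torque_per_motor(sol, N)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
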