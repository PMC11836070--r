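#' Resistive-force-theory friction coefficients of a filament
#'
#' Local anisotropic drag per unit length of a slender filament, in the two
#' canonical RFT variants. With pitch P, effective filament radius a and pitch
#' angle psi:
#' \describe{
#'   \item{gray_hancock}{\eqn{\xi_\parallel = 2\pi\mu / (\ln(2P/a) - 1/2)},
#'     \eqn{\xi_\perp = 4\pi\mu / (\ln(2P/a) + 1/2)}}
#'   \item{lighthill}{\eqn{\xi_\parallel = 2\pi\mu / \ln(0.18 P /(a\cos\psi))},
#'     \eqn{\xi_\perp = 4\pi\mu / (\ln(0.18 P /(a\cos\psi)) + 1/2)}}
#' }
#' Both satisfy the slender-body ordering
#' \eqn{0 < \xi_\parallel < \xi_\perp \le 2 \xi_\parallel}; inputs thick
#' enough to violate it (logarithm argument at or below 1, or a
#' non-positive/ill-ordered coefficient) raise an "out of slender-body regime"
#' error rather than returning nonsense.
#'
#' @param helix A [helix_geometry()] or [bundle_geometry()] object; for a
#'   bundle the effective (thickened) filament radius is used.
#' @param mu Dynamic viscosity (Pa s); water-like buffers are ~1e-3.
#' @param variant `"gray_hancock"` (default) or `"lighthill"`.
#' @return An object of class `friction_coefficients` with `xi_par`,
#'   `xi_perp` (Pa s), `variant`, `mu` and the logarithmic term used.
#' @examples
#' h <- helix_geometry(0.2, 2.26, 6, 0.01)
#' fc <- friction_coefficients(h, mu = 1e-3)
#' fc$xi_perp / fc$xi_par  # between 1 and 2
#' @export
friction_coefficients <- function(helix, mu = 1e-3,
                                  variant = c("gray_hancock", "lighthill")) {
  variant <- match.arg(variant)
  h <- .as_helix(helix)
  .assert_scalar(mu, "mu", 0, strict_lower = TRUE)
  a <- h$filament_radius_um
  P <- h$pitch_um
  log_arg <- switch(variant,
    gray_hancock = 2 * P / a,
    lighthill = 0.18 * P / (a * cos(h$psi_rad))
  )
  if (log_arg <= 1) {
    stop("filament too thick: out of slender-body regime (log argument <= 1)",
         call. = FALSE)
  }
  L <- log(log_arg)
  xi_par <- switch(variant,
    gray_hancock = 2 * pi * mu / (L - 0.5),
    lighthill = 2 * pi * mu / L
  )
  xi_perp <- 4 * pi * mu / (L + 0.5)
  if (!is.finite(xi_par) || xi_par <= 0 || xi_perp <= xi_par ||
      xi_perp > 2 * xi_par) {
    stop("friction coefficients out of slender-body regime ",
         "(require 0 < xi_par < xi_perp <= 2 xi_par)", call. = FALSE)
  }
  structure(
    list(xi_par = xi_par, xi_perp = xi_perp, variant = variant, mu = mu,
         log_term = L),
    class = "friction_coefficients"
  )
}

#' Propulsion matrix of the effective helix
#'
#' The 2x2 symmetric operator relating axial force and torque on the rotating
#' translating helix to its speed v and rotation rate omega:
#' \deqn{A = \Lambda(\xi_\parallel \cos^2\psi + \xi_\perp \sin^2\psi)}
#' \deqn{B = \pm \Lambda R \sin\psi \cos\psi (\xi_\perp - \xi_\parallel)}
#' \deqn{C = \Lambda R^2 (\xi_\perp \cos^2\psi + \xi_\parallel \sin^2\psi)}
#' with contour length Lambda and helix radius R in SI units, and the sign of
#' B set by handedness (positive for the default left-handed helix). The
#' identity \eqn{AC - B^2 = \Lambda^2 R^2 \xi_\parallel \xi_\perp > 0} holds
#' for all valid inputs.
#'
#' @param bundle A [helix_geometry()] or [bundle_geometry()].
#' @param coeffs A [friction_coefficients()] object.
#' @return An object of class `propulsion_matrix` with `A` (N s/m), `B`
#'   (N s), `C` (N s m), plus the geometry and viscosity used.
#' @export
propulsion_matrix <- function(bundle, coeffs) {
  stopifnot(inherits(coeffs, "friction_coefficients"))
  h <- .as_helix(bundle)
  psi <- h$psi_rad
  Lam <- h$contour_length_um * .UM
  R <- h$helix_radius_um * .UM
  s <- sin(psi)
  c <- cos(psi)
  sgn <- if (h$handedness == "left") 1 else -1
  structure(
    list(
      A = Lam * (coeffs$xi_par * c^2 + coeffs$xi_perp * s^2),
      B = sgn * Lam * R * s * c * (coeffs$xi_perp - coeffs$xi_par),
      C = Lam * R^2 * (coeffs$xi_perp * c^2 + coeffs$xi_par * s^2),
      helix = h, coeffs = coeffs, mu = coeffs$mu
    ),
    class = "propulsion_matrix"
  )
}

# Perrin friction factors of a prolate spheroid with semi-axes (len/2, wid/2),
# vectorised over cells. Returns SI drag coefficients. The e -> 0 spherical
# limit (all factors -> 1) is substituted below an eccentricity cutoff where
# the closed forms become 0/0.
.perrin_drags <- function(body_length_um, body_width_um, mu) {
  a <- body_length_um / 2 * .UM
  b <- body_width_um / 2 * .UM
  e2 <- pmax(0, 1 - (b / a)^2)
  e <- sqrt(e2)
  small <- e < 1e-6
  es <- ifelse(small, 0.5, e) # placeholder to avoid log(1/0-type) warnings
  L <- log((1 + es) / (1 - es))
  XA <- (8 / 3) * es^3 / (-2 * es + (1 + es^2) * L)
  YA <- (16 / 3) * es^3 / (2 * es + (3 * es^2 - 1) * L)
  XC <- (4 / 3) * es^3 * (1 - es^2) / (2 * es - (1 - es^2) * L)
  YC <- (4 / 3) * es^3 * (2 - es^2) / (-2 * es + (1 + es^2) * L)
  XA[small] <- 1; YA[small] <- 1; XC[small] <- 1; YC[small] <- 1
  list(
    A0_par = 6 * pi * mu * a * XA,
    A0_perp = 6 * pi * mu * a * YA,
    C0_axial = 8 * pi * mu * a^3 * XC,
    C0_transverse = 8 * pi * mu * a^3 * YC
  )
}

#' Stokes drag of the cell body with wobble projection
#'
#' Closed-form Perrin translational and rotational friction coefficients of a
#' prolate spheroid with semi-axes (length/2, width/2). A wobbling body at
#' angle theta to the swimming direction presents the projected effective
#' drags
#' \deqn{A_{0,eff} = A_{0,\parallel}\cos^2\theta + A_{0,\perp}\sin^2\theta}
#' \deqn{C_{0,eff} = C_{0,axial}\cos^2\theta + C_{0,transverse}\sin^2\theta}
#' which are what enter the force/torque balance. The spherical case
#' (length = width) reduces exactly to Stokes' \eqn{6\pi\mu r} and
#' \eqn{8\pi\mu r^3}.
#'
#' @param body A [cell_body()].
#' @param mu Dynamic viscosity (Pa s).
#' @return An object of class `body_drag` with fields `A0_par`, `A0_perp`
#'   (N s/m), `C0_axial`, `C0_transverse` (N s m), and the wobble-projected
#'   `A0_eff`, `C0_eff`.
#' @export
body_drag <- function(body, mu = 1e-3) {
  stopifnot(inherits(body, "cell_body"))
  .assert_scalar(mu, "mu", 0, strict_lower = TRUE)
  d <- .perrin_drags(body$body_length_um, body$body_width_um, mu)
  th <- body$wobble_angle_rad
  c2 <- cos(th)^2
  s2 <- sin(th)^2
  structure(
    c(d, list(
      A0_eff = d$A0_par * c2 + d$A0_perp * s2,
      C0_eff = d$C0_axial * c2 + d$C0_transverse * s2,
      body = body, mu = mu
    )),
    class = "body_drag"
  )
}
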