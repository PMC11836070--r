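#' Geometry of a helical flagellar filament
#'
#' Describes the rigid helix used by resistive force theory: a filament of
#' radius `filament_radius_um` wound into a helix of radius `helix_radius_um`
#' and pitch `pitch_um`, spanning an axial length `axial_length_um`. The pitch
#' angle is \eqn{\psi = \arctan(2\pi R / P)} and the contour length is
#' \eqn{\Lambda = \ell / \cos\psi}.
#'
#' The default convention is a left-handed helix (the normal form of the
#' flagellar filament), which together with counter-clockwise bundle rotation
#' viewed from behind gives forward thrust and a positive translation-rotation
#' coupling.
#'
#' @param helix_radius_um Helix radius R (um).
#' @param pitch_um Helix pitch P (um).
#' @param axial_length_um Axial (end-to-end) length of the helix (um).
#' @param filament_radius_um Filament (cross-section) radius a (um); must be
#'   smaller than the helix radius.
#' @param handedness `"left"` (default) or `"right"`.
#'
#' @return An object of class `helix_geometry` with the supplied fields plus
#'   `psi_rad` (pitch angle) and `contour_length_um`.
#' @examples
#' h <- helix_geometry(0.2, 2.26, 6, 0.01)
#' h$psi_rad * 180 / pi  # pitch angle in degrees, ~29
#' @export
helix_geometry <- function(helix_radius_um, pitch_um, axial_length_um,
                           filament_radius_um,
                           handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  .assert_scalar(helix_radius_um, "helix_radius_um", 0, strict_lower = TRUE)
  .assert_scalar(pitch_um, "pitch_um", 0, strict_lower = TRUE)
  .assert_scalar(axial_length_um, "axial_length_um", 0, strict_lower = TRUE)
  .assert_scalar(filament_radius_um, "filament_radius_um", 0,
                 strict_lower = TRUE)
  if (filament_radius_um >= helix_radius_um) {
    stop("filament radius must be smaller than the helix radius",
         call. = FALSE)
  }
  psi <- atan(2 * pi * helix_radius_um / pitch_um)
  structure(
    list(
      helix_radius_um = helix_radius_um,
      pitch_um = pitch_um,
      axial_length_um = axial_length_um,
      filament_radius_um = filament_radius_um,
      handedness = handedness,
      psi_rad = psi,
      contour_length_um = axial_length_um / cos(psi)
    ),
    class = "helix_geometry"
  )
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat(sprintf(
    "helix: R = %.3g um, P = %.3g um, ell = %.3g um, a = %.4g um (%s-handed)\n",
    x$helix_radius_um, x$pitch_um, x$axial_length_um, x$filament_radius_um,
    x$handedness))
  cat(sprintf("  pitch angle psi = %.1f deg, contour length = %.3g um\n",
              x$psi_rad * 180 / pi, x$contour_length_um))
  invisible(x)
}

#' Effective bundle of N flagellar filaments
#'
#' Multiple filaments are modelled as a single rigid helix of larger
#' thickness. The effective filament radius is `a * N^thickness_exponent`;
#' the default exponent 1/2 conserves the total cross-sectional area of N
#' close-packed filaments. The effective axial length comes from
#' `length_rule(N)` (typically derived from the length-versus-expression
#' coupling, see [length_rule_fun()]), or stays at the base helix length when no
#' rule is given.
#'
#' @param n_flagella Number of filaments N (integer >= 1).
#' @param base A [helix_geometry()] describing one filament.
#' @param length_rule `NULL` or a function of N returning the effective axial
#'   length in um.
#' @param thickness_exponent Exponent of the thickening rule (default 0.5).
#' @return An object of class `bundle_model` with fields `n_flagella`, `base`,
#'   and `helix` (the effective helix used for drag calculations).
#' @examples
#' b <- bundle_geometry(4, helix_geometry(0.2, 2.26, 6, 0.01))
#' b$helix$filament_radius_um  # 0.02 under the sqrt(N) rule
#' @export
bundle_geometry <- function(n_flagella, base, length_rule = NULL,
                            thickness_exponent = 0.5) {
  stopifnot(inherits(base, "helix_geometry"))
  .assert_scalar(n_flagella, "n_flagella", 1)
  .assert_scalar(thickness_exponent, "thickness_exponent", 0)
  a_b <- base$filament_radius_um * n_flagella^thickness_exponent
  ell_b <- if (is.null(length_rule)) {
    base$axial_length_um
  } else {
    as.numeric(length_rule(n_flagella))
  }
  if (!is.finite(ell_b) || ell_b <= 0) {
    stop("length rule returned a non-positive bundle length", call. = FALSE)
  }
  if (a_b >= base$helix_radius_um) {
    stop("effective bundle radius reaches the helix radius; ",
         "thickening rule out of range", call. = FALSE)
  }
  structure(
    list(
      n_flagella = n_flagella,
      base = base,
      helix = helix_geometry(base$helix_radius_um, base$pitch_um, ell_b, a_b,
                             base$handedness)
    ),
    class = "bundle_model"
  )
}

# Accept either a helix or a bundle wherever drag operators are computed.
.as_helix <- function(x) {
  if (inherits(x, "bundle_model")) x$helix
  else if (inherits(x, "helix_geometry")) x
  else stop("expected a 'helix_geometry' or 'bundle_model'", call. = FALSE)
}

#' Cell body as a counter-rotating rod
#'
#' The body is a prolate spheroid of length `body_length_um` and width
#' `body_width_um` that counter-rotates against the flagellar bundle. The
#' wobble angle theta is the angle between the body's long axis and the
#' swimming direction; it enters only through the projection of the
#' translational and rotational drags (see [body_drag()]).
#'
#' @param body_length_um Body length (um), must exceed the width.
#' @param body_width_um Body width (um).
#' @param wobble_angle_rad Wobble angle theta in radians, in `[0, pi/2)`.
#' @return An object of class `cell_body`.
#' @export
cell_body <- function(body_length_um = 3.0, body_width_um = 0.9,
                      wobble_angle_rad = 0) {
  .assert_scalar(body_length_um, "body_length_um", 0, strict_lower = TRUE)
  .assert_scalar(body_width_um, "body_width_um", 0, strict_lower = TRUE)
  .assert_scalar(wobble_angle_rad, "wobble_angle_rad", 0, pi / 2,
                 strict_upper = TRUE)
  if (body_length_um < body_width_um) {
    stop("body length must be >= body width", call. = FALSE)
  }
  structure(
    list(body_length_um = body_length_um, body_width_um = body_width_um,
         wobble_angle_rad = wobble_angle_rad),
    class = "cell_body"
  )
}
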