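#' Empirical expression-to-flagellation coupling
#'
#' Captures how flagellar gene expression E maps to flagellation: the mean
#' number of filaments grows approximately linearly,
#' \eqn{N(E) = k E + N_0}, while the filament length rises and then
#' saturates, \eqn{L(E) = L_{max} E / (K + E)}. Inverting the number
#' coupling gives the length-versus-number rule used by the swimming model
#' (cells with more flagella also have longer filaments).
#'
#' @param number_slope Flagella per expression unit (k).
#' @param number_intercept Flagella at zero expression (>= 0).
#' @param length_max_um Saturating filament length L_max (um).
#' @param length_halfsat Expression level K at which length reaches L_max/2.
#' @param length_model `"saturating"` (default) or `"linear"`; the linear
#'   form `length_intercept_um + length_slope_um * E` is the fallback when a
#'   saturating fit is not identifiable.
#' @param length_intercept_um,length_slope_um Parameters of the linear
#'   fallback length model.
#' @return An object of class `coupling_model`.
#' @export
coupling_model <- function(number_slope = 1, number_intercept = 0,
                           length_max_um = 8, length_halfsat = 2,
                           length_model = c("saturating", "linear"),
                           length_intercept_um = 0, length_slope_um = 0) {
  length_model <- match.arg(length_model)
  .assert_scalar(number_slope, "number_slope")
  .assert_scalar(number_intercept, "number_intercept", 0)
  if (length_model == "saturating") {
    .assert_scalar(length_max_um, "length_max_um", 0, strict_lower = TRUE)
    .assert_scalar(length_halfsat, "length_halfsat", 0, strict_lower = TRUE)
  }
  structure(
    list(number_slope = number_slope, number_intercept = number_intercept,
         length_max_um = length_max_um, length_halfsat = length_halfsat,
         length_model = length_model,
         length_intercept_um = length_intercept_um,
         length_slope_um = length_slope_um),
    class = "coupling_model"
  )
}

#' Mean flagellar number and length predicted by a coupling
#'
#' @param coupling A [coupling_model()].
#' @param expression Vector of expression levels (arbitrary units, >= 0).
#' @param integer_n If `TRUE`, round the predicted number to whole flagella
#'   (floored at 0); the default mean-field mode returns the real-valued
#'   mean, which is what curve plotting and fitting use.
#' @return A data.frame with columns `expression`, `n_flagella`, `length_um`.
#' @export
predict_coupling <- function(coupling, expression, integer_n = FALSE) {
  stopifnot(inherits(coupling, "coupling_model"))
  E <- expression
  n <- coupling$number_slope * E + coupling$number_intercept
  if (integer_n) n <- pmax(0, round(n))
  len <- if (coupling$length_model == "saturating") {
    coupling$length_max_um * E / (coupling$length_halfsat + E)
  } else {
    coupling$length_intercept_um + coupling$length_slope_um * E
  }
  data.frame(expression = E, n_flagella = n, length_um = pmax(len, 0))
}

#' Length-versus-number rule derived from a coupling
#'
#' Inverts the (linear) number coupling to obtain the expression level at
#' which a cell carries N flagella, then evaluates the length coupling there.
#' The result is the `length_rule` consumed by [bundle_geometry()] and
#' [velocity_vs_flagella()].
#'
#' @param coupling A [coupling_model()].
#' @return A function of N returning the bundle axial length in um,
#'   non-decreasing in N and bounded by `length_max_um`.
#' @export
length_rule_fun <- function(coupling) {
  stopifnot(inherits(coupling, "coupling_model"))
  if (coupling$number_slope == 0) {
    stop("number coupling has zero slope; cannot invert to a length rule",
         call. = FALSE)
  }
  force(coupling)
  function(n_flagella) {
    E <- pmax((n_flagella - coupling$number_intercept) /
                coupling$number_slope, 0)
    predict_coupling(coupling, E)$length_um
  }
}

#' Fit the expression-to-flagellation couplings
#'
#' Least-squares fits of the two couplings to per-cell (or per-condition)
#' records: an ordinary linear fit of flagellar number on expression, and a
#' saturating fit \eqn{L(E) = L_{max} E / (K + E)} of filament length via
#' bounded Levenberg-Marquardt. When the saturating fit is not identifiable
#' (no curvature in the data, e.g. constant length), it falls back to a
#' linear length model and flags this in the result.
#'
#' @param table A data.frame with columns `expression`, `n_flagella`,
#'   `length_um`, covering at least 3 distinct expression levels.
#' @return A [coupling_model()] with an attached `fit` attribute carrying
#'   residual summaries and the `length_fallback` flag.
#' @examples
#' tab <- generate_flagellation_table(seed = 1)$table
#' fit_couplings(tab)
#' @export
fit_couplings <- function(table) {
  need <- c("expression", "n_flagella", "length_um")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(table$expression)) < 3) {
    stop("need at least 3 distinct expression levels", call. = FALSE)
  }
  lin <- stats::lm(n_flagella ~ expression, data = table)
  k <- unname(stats::coef(lin)[2])
  n0 <- unname(stats::coef(lin)[1])

  # saturating length fit; deterministic starts from the data
  E <- table$expression
  L <- table$length_um
  Lmax0 <- max(L) * 1.05 + 1e-9
  half <- Lmax0 / 2
  above <- which(L >= half)
  K0 <- if (length(above) > 0) max(E[above[1]], 1e-6) else max(stats::median(E), 1e-6)
  sat <- tryCatch(
    minpack.lm::nlsLM(
      length_um ~ Lmax * expression / (K + expression),
      data = table, start = list(Lmax = Lmax0, K = K0),
      lower = c(1e-9, 1e-9), upper = c(Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  fallback <- FALSE
  if (!is.null(sat)) {
    cf <- stats::coef(sat)
    # declare the fit non-identifiable when K runs far beyond the data range
    # (the curve is then indistinguishable from a straight line)
    if (!all(is.finite(cf)) || cf["K"] > 100 * max(E)) sat <- NULL
  }
  if (is.null(sat)) {
    fallback <- TRUE
    linL <- stats::lm(length_um ~ expression, data = table)
    cm <- coupling_model(
      number_slope = k, number_intercept = max(n0, 0),
      length_model = "linear",
      length_intercept_um = unname(stats::coef(linL)[1]),
      length_slope_um = unname(stats::coef(linL)[2])
    )
    resid_len <- stats::resid(linL)
  } else {
    cf <- stats::coef(sat)
    cm <- coupling_model(
      number_slope = k, number_intercept = max(n0, 0),
      length_max_um = unname(cf["Lmax"]), length_halfsat = unname(cf["K"])
    )
    resid_len <- stats::resid(sat)
  }
  attr(cm, "fit") <- list(
    number_rss = sum(stats::resid(lin)^2),
    length_rss = sum(resid_len^2),
    length_fallback = fallback,
    n_records = nrow(table)
  )
  cm
}

#' Ensemble specification for modeled cells
#'
#' Describes the population over which the model is averaged: distributions
#' of cell-body length and width (lognormal by default, parameterised by mean
#' and coefficient of variation) and of the wobble angle (uniform between 0
#' and an upper bound, reflecting the random orientation of the motors on the
#' body). Degenerate (`"fixed"`) distributions collapse the ensemble onto a
#' single cell.
#'
#' @param n_cells Number of modeled cells (default 5000).
#' @param body_length_dist,body_width_dist Lists `list(name, mean, cv)` with
#'   `name` one of `"lognormal"`, `"normal"`, `"fixed"`; lengths in um.
#' @param wobble_dist List `list(name, min_deg, max_deg)` with `name`
#'   `"uniform"` or `"fixed"` (for `"fixed"`, give `value_deg`).
#' @param seed Integer seed making the ensemble reproducible.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_cells = 5000,
                          body_length_dist = list(name = "lognormal",
                                                  mean = 3.0, cv = 0.15),
                          body_width_dist = list(name = "lognormal",
                                                 mean = 0.9, cv = 0.10),
                          wobble_dist = list(name = "uniform",
                                             min_deg = 0, max_deg = 40),
                          seed = 1L) {
  .assert_scalar(n_cells, "n_cells", 1)
  structure(
    list(n_cells = as.integer(n_cells),
         body_length_dist = body_length_dist,
         body_width_dist = body_width_dist,
         wobble_dist = wobble_dist,
         seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

.sample_size_dist <- function(dist, n) {
  name <- dist$name %||% "fixed"
  switch(name,
    fixed = rep(dist$mean %||% dist$value, n),
    normal = stats::rnorm(n, dist$mean, dist$mean * dist$cv),
    lognormal = {
      if (dist$cv == 0) rep(dist$mean, n) else {
        sdlog <- sqrt(log(1 + dist$cv^2))
        stats::rlnorm(n, log(dist$mean) - sdlog^2 / 2, sdlog)
      }
    },
    stop("unknown distribution name '", name, "'", call. = FALSE)
  )
}

.sample_wobble_dist <- function(dist, n) {
  name <- dist$name %||% "fixed"
  deg <- switch(name,
    fixed = rep(dist$value_deg %||% 0, n),
    uniform = stats::runif(n, dist$min_deg %||% 0, dist$max_deg %||% 40),
    stop("unknown wobble distribution '", name, "'", call. = FALSE)
  )
  deg * pi / 180
}

#' Draw a population of cell bodies
#'
#' Samples `n_cells` bodies from the ensemble distributions, rejecting draws
#' that violate the cell-body invariants (positive sizes, length >= width,
#' wobble in `[0, pi/2)`). More than 1e4 consecutive rejections signal a
#' misconfigured distribution and raise an error. The draw is a pure
#' function of the spec (including its seed).
#'
#' @param spec An [ensemble_spec()].
#' @return A data.frame with `n_cells` rows and columns `body_length_um`,
#'   `body_width_um`, `wobble_rad`.
#' @export
sample_cells <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_cells
    out <- NULL
    consecutive_rejects <- 0
    while (is.null(out) || nrow(out) < n) {
      m <- n - if (is.null(out)) 0 else nrow(out)
      len <- .sample_size_dist(spec$body_length_dist, m)
      wid <- .sample_size_dist(spec$body_width_dist, m)
      th <- .sample_wobble_dist(spec$wobble_dist, m)
      ok <- is.finite(len) & is.finite(wid) & len > 0 & wid > 0 &
        len >= wid & th >= 0 & th < pi / 2
      if (!any(ok)) {
        consecutive_rejects <- consecutive_rejects + m
        if (consecutive_rejects > 1e4) {
          stop("ensemble distributions misconfigured: >1e4 consecutive ",
               "rejected draws", call. = FALSE)
        }
      } else {
        consecutive_rejects <- 0
      }
      keep <- data.frame(body_length_um = len[ok], body_width_um = wid[ok],
                         wobble_rad = th[ok])
      out <- if (is.null(out)) keep else rbind(out, keep)
    }
    rownames(out) <- NULL
    out
  })
}

#' Ensemble-averaged swimming velocity versus flagellar number
#'
#' For each flagellar number N, solves the RFT balance for every sampled cell
#' (bundle length from the coupling, per-cell body drag and wobble) and
#' returns the mean and standard deviation of the swimming speed over the
#' ensemble. The per-cell solve uses the closed-form solution of the 3x3
#' balance, vectorised over cells; it is algebraically identical to
#' [solve_swim()] (and is cross-checked against it in the tests).
#'
#' @param spec An [ensemble_spec()]; its seed makes the prediction
#'   deterministic.
#' @param coupling A [coupling_model()].
#' @param config An [rft_config()]; its `body` field is replaced by the
#'   sampled cells.
#' @param n_range Flagellar numbers to evaluate (default 1:10).
#' @return A data.frame with columns `n_flagella`, `v_mean_um_s`,
#'   `v_sd_um_s`, with the cells and seed recorded in attributes.
#' @examples
#' pp <- predict_population_curve(ensemble_spec(n_cells = 100), n_range = 1:5)
#' @export
predict_population_curve <- function(spec = ensemble_spec(),
                                     coupling = coupling_model(),
                                     config = rft_config(),
                                     n_range = 1:10) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(coupling, "coupling_model"),
            inherits(config, "rft_config"))
  cells <- sample_cells(spec)
  d <- .perrin_drags(cells$body_length_um, cells$body_width_um, config$mu)
  c2 <- cos(cells$wobble_rad)^2
  s2 <- sin(cells$wobble_rad)^2
  A0 <- d$A0_par * c2 + d$A0_perp * s2
  C0 <- d$C0_axial * c2 + d$C0_transverse * s2
  rule <- length_rule_fun(coupling)
  omega_m <- 2 * pi * config$motor_hz
  rows <- lapply(n_range, function(N) {
    b <- bundle_geometry(N, config$helix, rule, config$thickness_exponent)
    fc <- friction_coefficients(b, config$mu, config$variant)
    pm <- propulsion_matrix(b, fc)
    # closed form of the balance, vectorised over cells
    om <- C0 * omega_m / (pm$C + C0 - pm$B^2 / (pm$A + A0))
    v <- pm$B * om / (pm$A + A0)
    v_um <- v / .UM
    data.frame(
      n_flagella = N,
      v_mean_um_s = mean(v_um),
      v_sd_um_s = if (length(v_um) > 1) stats::sd(v_um) else 0
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cells") <- cells
  attr(out, "seed") <- spec$seed
  attr(out, "n_cells") <- spec$n_cells
  out
}

#' Population-averaged swimming velocity
#'
#' The population-averaged velocity is the product of the swimming fraction
#' and the mean swimming velocity of the motile cells: non-motile cells
#' contribute zero.
#'
#' @param fraction_motile Fraction of swimming cells in `[0, 1]`.
#' @param mean_speed_motile_um_s Mean speed of the motile cells (um/s).
#' @return Population-averaged velocity in um/s.
#' @export
population_average_velocity <- function(fraction_motile,
                                        mean_speed_motile_um_s) {
  .assert_scalar(fraction_motile, "fraction_motile", 0, 1)
  .assert_scalar(mean_speed_motile_um_s, "mean_speed_motile_um_s", 0)
  fraction_motile * mean_speed_motile_um_s
}

#' Single-parameter calibration of the model to observed velocities
#'
#' The model's absolute velocity scale is matched to data by one
#' multiplicative parameter, the least-structural single adjustable
#' parameter. The least-squares scale has the closed form
#' \eqn{s = \sum v_{obs} v_{pred} / \sum v_{pred}^2}.
#'
#' @param predicted Predicted velocities (um/s), e.g. `v_mean_um_s` from
#'   [predict_population_curve()] at the observed flagellar numbers.
#' @param observed Observed velocities (um/s), same length.
#' @return The calibration scale s (> 0 for sensible inputs).
#' @examples
#' calibrate_scale(c(10, 20, 30), 2 * c(10, 20, 30))  # 2
#' @export
calibrate_scale <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1) {
    stop("'predicted' and 'observed' must be equal-length, non-empty",
         call. = FALSE)
  }
  if (all(predicted == 0)) {
    stop("all predicted velocities are zero; scale is undefined",
         call. = FALSE)
  }
  sum(observed * predicted) / sum(predicted^2)
}
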