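# Ensembles over cell geometry, expression couplings, and calibration.

test_that("cell sampling is seeded and respects the body invariants", {
  spec <- ensemble_spec(n_cells = 500, seed = 7)
  a <- sample_cells(spec)
  b <- sample_cells(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_true(all(a$body_length_um >= a$body_width_um))
  expect_true(all(a$body_width_um > 0))
  expect_true(all(a$wobble_rad >= 0 & a$wobble_rad < pi / 2))
  # a different seed gives a different draw
  expect_false(identical(a, sample_cells(ensemble_spec(n_cells = 500,
                                                       seed = 8))))
})

test_that("degenerate distributions collapse onto the configured means", {
  spec <- ensemble_spec(
    n_cells = 10,
    body_length_dist = list(name = "fixed", mean = 3),
    body_width_dist = list(name = "fixed", mean = 0.9),
    wobble_dist = list(name = "fixed", value_deg = 15),
    seed = 1
  )
  cells <- sample_cells(spec)
  expect_true(all(cells$body_length_um == 3))
  expect_true(all(cells$body_width_um == 0.9))
  expect_true(all(cells$wobble_rad == 15 * pi / 180))
})

test_that("large-ensemble mean body length converges to the configured mean", {
  spec <- ensemble_spec(n_cells = 5000, seed = 3)
  cells <- sample_cells(spec)
  se <- sd(cells$body_length_um) / sqrt(nrow(cells))
  expect_lt(abs(mean(cells$body_length_um) - 3.0), 3 * se + 0.02)
})

test_that("misconfigured distributions error instead of looping", {
  bad <- ensemble_spec(
    n_cells = 10,
    body_length_dist = list(name = "fixed", mean = 0.5),  # < width, always
    body_width_dist = list(name = "fixed", mean = 0.9),
    seed = 1
  )
  expect_error(sample_cells(bad), "misconfigured")
})

test_that("coupling fits recover generating parameters from noiseless tables", {
  gen <- generate_flagellation_table(k = 0.8, intercept = 0.5, L_max = 7.2,
                                     K = 1.6, seed = 2)
  cm <- fit_couplings(gen$table)
  expect_equal(cm$number_slope, 0.8, tolerance = 0.01)
  expect_equal(cm$number_intercept, 0.5, tolerance = 0.01)
  expect_equal(cm$length_max_um, 7.2, tolerance = 0.01)
  expect_equal(cm$length_halfsat, 1.6, tolerance = 0.01)
  expect_false(attr(cm, "fit")$length_fallback)
})

test_that("rescaling expression rescales the fitted coupling as covariance dictates", {
  gen <- generate_flagellation_table(k = 1, intercept = 0, L_max = 8, K = 2,
                                     seed = 2)
  tab <- gen$table
  tab2 <- tab
  tab2$expression <- 2 * tab2$expression
  cm <- fit_couplings(tab)
  cm2 <- fit_couplings(tab2)
  expect_equal(cm2$number_slope, cm$number_slope / 2, tolerance = 1e-6)
  expect_equal(cm2$length_halfsat, 2 * cm$length_halfsat, tolerance = 1e-4)
  expect_equal(cm2$length_max_um, cm$length_max_um, tolerance = 1e-6)
})

test_that("constant filament length falls back to a zero-slope linear model", {
  tab <- data.frame(expression = rep(1:5, each = 3),
                    n_flagella = rep(1:5, each = 3),
                    length_um = 6)
  cm <- fit_couplings(tab)
  expect_true(attr(cm, "fit")$length_fallback)
  expect_equal(cm$length_model, "linear")
  expect_equal(cm$length_slope_um, 0, tolerance = 1e-10)
  expect_equal(cm$length_intercept_um, 6, tolerance = 1e-10)
})

test_that("length rule from the default coupling is saturating and monotone", {
  rule <- length_rule_fun(coupling_model())
  lens <- rule(1:12)
  expect_true(all(diff(lens) > 0))
  expect_true(all(lens <= 8))
  expect_equal(rule(2), 8 * 2 / (2 + 2))
})

test_that("degenerate one-cell ensemble reproduces the single-cell solve", {
  cfg <- rft_config()
  spec <- ensemble_spec(
    n_cells = 1,
    body_length_dist = list(name = "fixed", mean = 3),
    body_width_dist = list(name = "fixed", mean = 0.9),
    wobble_dist = list(name = "fixed", value_deg = 20),
    seed = 1
  )
  pp <- predict_population_curve(spec, coupling_model(), cfg, 1:6)
  single <- velocity_vs_flagella(cfg, 1:6)
  expect_equal(pp$v_mean_um_s, single$v_um_s, tolerance = 1e-10)
  expect_true(all(pp$v_sd_um_s == 0))
})

test_that("population curve is deterministic, saturating, and spread by body-size variance", {
  spec <- ensemble_spec(n_cells = 400, seed = 9)
  p1 <- predict_population_curve(spec, n_range = 1:10)
  p2 <- predict_population_curve(spec, n_range = 1:10)
  expect_identical(p1$v_mean_um_s, p2$v_mean_um_s)
  expect_true(all(diff(p1$v_mean_um_s) >= 0))
  expect_lt(p1$v_mean_um_s[10] / p1$v_mean_um_s[5], 1.10)
  expect_true(all(p1$v_sd_um_s > 0))
})

test_that("population-averaged velocity is the motile-fraction product", {
  expect_equal(population_average_velocity(0.6, 25), 15)
  expect_equal(population_average_velocity(0, 40), 0)
  expect_equal(population_average_velocity(1, 23.4), 23.4)
  expect_error(population_average_velocity(1.2, 10), "range")
})

test_that("calibration scale has the closed form and round-trips noise", {
  pred <- c(10, 18, 24, 27)
  expect_equal(calibrate_scale(pred, pred), 1)
  expect_equal(calibrate_scale(pred, 2 * pred), 2)
  expect_error(calibrate_scale(c(0, 0), c(1, 2)), "zero")
  # closed form agrees with a brute-force 1-D grid search
  set.seed(5)
  obs <- 1.3 * pred * (1 + rnorm(4, 0, 0.05))
  s_hat <- calibrate_scale(pred, obs)
  grid <- seq(0.5, 2.5, by = 1e-6)
  sse <- function(s) sum((obs - s * pred)^2)
  s_grid <- grid[which.min(vapply(grid, sse, numeric(1)))]
  expect_equal(s_hat, s_grid, tolerance = 1e-5)
  expect_gt(s_hat, 1.2)
  expect_lt(s_hat, 1.4)
})
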