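# The single-cell propulsion model: friction coefficients, propulsion
# matrix, body drag and the force/torque balance.

test_that("helix geometry derives pitch angle and contour length", {
  h <- helix_geometry(0.2, 2.26, 6, 0.01)
  expect_equal(h$psi_rad, atan(2 * pi * 0.2 / 2.26))
  expect_equal(h$contour_length_um, 6 / cos(h$psi_rad))
  expect_gte(h$contour_length_um, h$axial_length_um)
  expect_error(helix_geometry(0.2, 2.26, 6, 0.25), "smaller")
  expect_error(helix_geometry(-0.2, 2.26, 6, 0.01), "range")
})

test_that("Gray-Hancock coefficients follow the stated closed forms", {
  # choose pitch/radius so that ln(2P/a) = 10 exactly
  a <- 0.01
  P <- a * exp(10) / 2
  h <- helix_geometry(P / 4, P, 6, a)  # helix radius irrelevant here
  mu <- 1e-3
  fc <- friction_coefficients(h, mu, "gray_hancock")
  expect_equal(fc$xi_par, 2 * pi * mu / 9.5)
  expect_equal(fc$xi_perp, 4 * pi * mu / 10.5)
  expect_equal(fc$xi_perp / fc$xi_par, 19 / 10.5)
})

test_that("perpendicular-to-parallel drag ratio tends to 2 for thin filaments", {
  mu <- 1e-3
  ratios <- sapply(c(1e-3, 1e-5, 1e-8), function(a) {
    h <- helix_geometry(0.2, 2.26, 6, a)
    fc <- friction_coefficients(h, mu, "gray_hancock")
    fc$xi_perp / fc$xi_par
  })
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios < 2))
  expect_equal(ratios[3], 2, tolerance = 0.05)  # logarithmic approach
})

test_that("both friction variants stay in the slender-body regime", {
  h <- helix_geometry(0.2, 2.26, 6, 0.01)
  for (variant in c("gray_hancock", "lighthill")) {
    fc <- friction_coefficients(h, 1e-3, variant)
    r <- fc$xi_perp / fc$xi_par
    expect_gt(r, 1)
    expect_lte(r, 2)
  }
})

test_that("overly thick filaments raise an out-of-regime error", {
  h <- helix_geometry(0.45, 1.0, 6, 0.4)
  expect_error(friction_coefficients(h, 1e-3, "lighthill"), "slender-body")
})

test_that("bundle thickening follows the area-conserving sqrt(N) rule", {
  base <- helix_geometry(0.2, 2.26, 6, 0.01)
  b1 <- bundle_geometry(1, base)
  expect_equal(b1$helix$filament_radius_um, 0.01)
  expect_equal(b1$helix$axial_length_um, 6)
  b4 <- bundle_geometry(4, base)
  expect_equal(b4$helix$filament_radius_um, 0.02)
  radii <- sapply(1:10, function(N)
    bundle_geometry(N, base)$helix$filament_radius_um)
  expect_true(all(diff(radii) > 0))
  # length rule override is honoured
  b <- bundle_geometry(3, base, length_rule = function(N) 2 + N)
  expect_equal(b$helix$axial_length_um, 5)
})

test_that("propulsion matrix obeys its algebraic structure", {
  base <- helix_geometry(0.2, 2.26, 6, 0.01)
  fc <- friction_coefficients(base, 1e-3)
  pm <- propulsion_matrix(base, fc)
  h <- base
  Lam <- h$contour_length_um * 1e-6
  R <- h$helix_radius_um * 1e-6
  # positive-definiteness identity AC - B^2 = Lam^2 R^2 xi_par xi_perp
  expect_equal(pm$A * pm$C - pm$B^2,
               Lam^2 * R^2 * fc$xi_par * fc$xi_perp,
               tolerance = 1e-12)
  expect_gt(pm$A, 0)
  expect_gt(pm$C, 0)
  expect_gt(pm$B, 0)  # left-handed convention
  # right-handed helix flips the coupling sign only
  hr <- helix_geometry(0.2, 2.26, 6, 0.01, handedness = "right")
  pmr <- propulsion_matrix(hr, friction_coefficients(hr, 1e-3))
  expect_equal(pmr$B, -pm$B)
  expect_equal(pmr$A, pm$A)
  # doubling the contour length at fixed psi, R doubles A, B, C
  h2 <- helix_geometry(0.2, 2.26, 12, 0.01)
  pm2 <- propulsion_matrix(h2, friction_coefficients(h2, 1e-3))
  expect_equal(pm2$A / pm$A, 2, tolerance = 1e-12)
  expect_equal(pm2$B / pm$B, 2, tolerance = 1e-12)
  expect_equal(pm2$C / pm$C, 2, tolerance = 1e-12)
})

test_that("straight-filament limit has no translation-rotation coupling", {
  # psi -> 0 via a huge pitch
  h <- helix_geometry(0.2, 2e5, 6, 0.01)
  fc <- friction_coefficients(h, 1e-3)
  pm <- propulsion_matrix(h, fc)
  Lam <- h$contour_length_um * 1e-6
  R <- h$helix_radius_um * 1e-6
  expect_equal(pm$B / pm$A, 0, tolerance = 1e-4)
  expect_equal(pm$A, Lam * fc$xi_par, tolerance = 1e-6)
  expect_equal(pm$C, Lam * R^2 * fc$xi_perp, tolerance = 1e-6)
})

test_that("body drag reduces to the Stokes sphere and projects wobble", {
  mu <- 1e-3
  # sphere of diameter 1 um
  bd <- body_drag(cell_body(1, 1, 0), mu)
  expect_equal(bd$A0_par, 6 * pi * mu * 0.5e-6, tolerance = 1e-9)
  expect_equal(bd$A0_perp, 6 * pi * mu * 0.5e-6, tolerance = 1e-9)
  expect_equal(bd$C0_axial, 8 * pi * mu * (0.5e-6)^3, tolerance = 1e-9)
  # default rod: anisotropy within the slender range
  rod <- body_drag(cell_body(3.0, 0.9, 0), mu)
  expect_gt(rod$A0_perp / rod$A0_par, 1)
  expect_lt(rod$A0_perp / rod$A0_par, 2)
  expect_gt(rod$C0_transverse, rod$C0_axial)
  # zero wobble projects onto the axial drags
  expect_equal(rod$A0_eff, rod$A0_par)
  expect_equal(rod$C0_eff, rod$C0_axial)
  # the wobble projection formula
  th <- 0.5
  w <- body_drag(cell_body(3.0, 0.9, th), mu)
  expect_equal(w$A0_eff,
               rod$A0_par * cos(th)^2 + rod$A0_perp * sin(th)^2)
  expect_equal(w$C0_eff,
               rod$C0_axial * cos(th)^2 + rod$C0_transverse * sin(th)^2)
})

test_that("solver conserves the motor frequency and balances forces", {
  cfg <- rft_config()
  b <- bundle_geometry(4, cfg$helix, length_rule_fun(cfg$coupling))
  pm <- propulsion_matrix(b, friction_coefficients(b, cfg$mu))
  bd <- body_drag(cfg$body, cfg$mu)
  sol <- solve_swim(pm, bd, 220)
  expect_equal(sol$omega_flag_hz + sol$omega_body_hz, 220)
  expect_lte(sol$force_residual, 1e-10)
  expect_lte(sol$torque_residual, 1e-10)
  expect_gt(sol$v_um_s, 0)
})

test_that("solver matches the dense linear-algebra oracle on random draws", {
  set.seed(101)
  for (i in 1:100) {
    inp <- random_model_inputs()
    sol <- solve_swim(inp$pm, inp$bd, inp$motor_hz)
    orc <- swim_oracle(inp$pm, inp$bd, inp$motor_hz)
    expect_equal(sol$v_um_s, orc$v_um_s, tolerance = 1e-10)
    expect_equal(sol$omega_flag_hz, orc$omega_flag_hz, tolerance = 1e-10)
    expect_equal(sol$omega_body_hz, orc$omega_body_hz, tolerance = 1e-10)
    expect_equal(sol$omega_flag_hz + sol$omega_body_hz, inp$motor_hz,
                 tolerance = 1e-12)
    expect_lte(sol$force_residual, 1e-10)
    expect_lte(sol$torque_residual, 1e-10)
  }
})

test_that("achiral filament produces no thrust but partitions the motor rate", {
  h <- helix_geometry(0.2, 1e6, 6, 0.01)  # psi ~ 0
  pm <- propulsion_matrix(h, friction_coefficients(h, 1e-3))
  pm$B <- 0  # exact achirality
  bd <- body_drag(cell_body(), 1e-3)
  sol <- solve_swim(pm, bd, 220)
  expect_equal(sol$v_um_s, 0)
  expect_equal(sol$omega_flag_hz + sol$omega_body_hz, 220)
  expect_gt(sol$omega_flag_hz, 0)
  expect_gt(sol$omega_body_hz, 0)
  # torque balance fixes the partition: C omega = C0 Omega
  expect_equal(pm$C * sol$omega_flag_hz, bd$C0_eff * sol$omega_body_hz,
               tolerance = 1e-10)
})

test_that("kinematics are viscosity-invariant and torques scale with mu", {
  cfg <- rft_config()
  b <- bundle_geometry(3, cfg$helix, length_rule_fun(cfg$coupling))
  sols <- lapply(c(1e-3, 2e-3), function(mu) {
    pm <- propulsion_matrix(b, friction_coefficients(b, mu))
    solve_swim(pm, body_drag(cfg$body, mu), 220)
  })
  expect_equal(sols[[1]]$v_um_s, sols[[2]]$v_um_s, tolerance = 1e-12)
  expect_equal(sols[[1]]$omega_flag_hz, sols[[2]]$omega_flag_hz,
               tolerance = 1e-12)
  expect_equal(sols[[2]]$bundle_torque_pN_um,
               2 * sols[[1]]$bundle_torque_pN_um, tolerance = 1e-12)
})

test_that("kinematic outputs are proportional to the motor frequency", {
  cfg <- rft_config()
  b <- bundle_geometry(5, cfg$helix, length_rule_fun(cfg$coupling))
  pm <- propulsion_matrix(b, friction_coefficients(b, cfg$mu))
  bd <- body_drag(cfg$body, cfg$mu)
  s1 <- solve_swim(pm, bd, 110)
  s2 <- solve_swim(pm, bd, 220)
  expect_equal(s2$v_um_s, 2 * s1$v_um_s, tolerance = 1e-12)
  expect_equal(s2$omega_flag_hz, 2 * s1$omega_flag_hz, tolerance = 1e-12)
  expect_equal(s2$omega_body_hz, 2 * s1$omega_body_hz, tolerance = 1e-12)
})

test_that("torque per motor divides the bundle torque and falls with N", {
  cfg <- rft_config()
  curve <- velocity_vs_flagella(cfg, 1:8)
  expect_equal(curve$torque_per_motor_pN_um,
               curve$bundle_torque_pN_um / curve$n_flagella)
  expect_true(all(diff(curve$torque_per_motor_pN_um) < 0))
  b <- bundle_geometry(1, cfg$helix, length_rule_fun(cfg$coupling))
  pm <- propulsion_matrix(b, friction_coefficients(b, cfg$mu))
  sol <- solve_swim(pm, body_drag(cfg$body, cfg$mu), 220)
  expect_equal(torque_per_motor(sol, 1), sol$bundle_torque_pN_um)
})

test_that("velocity saturates with flagellar number", {
  curve <- velocity_vs_flagella(rft_config(), 1:10)
  v <- curve$v_um_s
  expect_true(all(diff(v) >= 0))
  expect_lt(v[10] / v[5], 1.10)
  expect_gt(v[2] / v[1], v[10] / v[9])
  # relative increments shrink monotonically at large N
  incr <- diff(v) / v[-10]
  expect_lt(incr[9], incr[1] / 10)
})

test_that("saturation mechanism: without body drag, v/omega is N-independent at fixed length", {
  # fixing the bundle length isolates the thickness effect; with A0 = 0 the
  # ratio v/omega = B/A must not depend on N (thrust and drag gains cancel)
  cfg <- rft_config()
  ratios <- sapply(c(1, 4, 8), function(N) {
    b <- bundle_geometry(N, cfg$helix, length_rule = function(n) 6)
    pm <- propulsion_matrix(b, friction_coefficients(b, cfg$mu))
    bd <- body_drag(cfg$body, cfg$mu)
    bd$A0_eff <- 0
    sol <- solve_swim(pm, bd, 220)
    (sol$v_um_s * 1e-6) / (2 * pi * sol$omega_flag_hz)  # = B/A in metres
  })
  b_over_a <- sapply(c(1, 4, 8), function(N) {
    b <- bundle_geometry(N, cfg$helix, length_rule = function(n) 6)
    pm <- propulsion_matrix(b, friction_coefficients(b, cfg$mu))
    pm$B / pm$A
  })
  expect_equal(ratios, b_over_a, tolerance = 1e-10)
  # ... and B/A varies only through the log term, weakly, but v/omega always
  # equals it exactly when the body is dragless
})

test_that("single-point sweep equals the direct solve", {
  cfg <- rft_config()
  curve <- velocity_vs_flagella(cfg, 1)
  b <- bundle_geometry(1, cfg$helix, length_rule_fun(cfg$coupling))
  pm <- propulsion_matrix(b, friction_coefficients(b, cfg$mu))
  sol <- solve_swim(pm, body_drag(cfg$body, cfg$mu), cfg$motor_hz)
  expect_equal(curve$v_um_s, sol$v_um_s)
  expect_equal(nrow(curve), 1)
})

test_that("RFT variants agree on the normalized velocity curve", {
  gh <- velocity_vs_flagella(rft_config(variant = "gray_hancock"), 1:10)
  lh <- velocity_vs_flagella(rft_config(variant = "lighthill"), 1:10)
  ngh <- gh$v_um_s / gh$v_um_s[1]
  nlh <- lh$v_um_s / lh$v_um_s[1]
  expect_lt(max(abs(ngh - nlh) / ngh), 0.15)
})
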