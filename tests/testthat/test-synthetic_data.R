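# Generators: seeded determinism, attached ground truth, and agreement with
# trajectory-level physics.

test_that("movie generation is a pure function of parameters and seed", {
  a <- generate_motility_movie(n_particles = 50, n_frames = 30, size_px = 64,
                               seed = 5)
  b <- generate_motility_movie(n_particles = 50, n_frames = 30, size_px = 64,
                               seed = 5)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$ground_truth$speeds_um_s, b$ground_truth$speeds_um_s)
  c <- generate_motility_movie(n_particles = 50, n_frames = 30, size_px = 64,
                               seed = 6)
  expect_false(identical(a$stack$frames, c$stack$frames))
  # ground truth records the generator parameters
  expect_equal(a$ground_truth$params$n_particles, 50)
  expect_equal(a$ground_truth$generator, "motility_movie")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(generate_motility_movie(n_particles = 10, n_frames = 5,
                                    size_px = 32, seed = 1))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("diffuser trajectories have MSD slope 4 D tau", {
  D <- 0.4
  m <- generate_motility_movie(n_particles = 200, alpha = 0, D_diff = D,
                               n_frames = 200, size_px = 64, noise_sigma = 0,
                               seed = 8, store_trajectories = TRUE)
  lags <- 1:20
  msd <- trajectory_msd(m$ground_truth$trajectories_um, lags)
  slope <- unname(coef(lm(msd ~ I(lags / 100) - 1))[1])
  expect_equal(slope, 4 * D, tolerance = 0.05)
})

test_that("a single noiseless swimmer advances at its drawn in-plane velocity", {
  m <- generate_motility_movie(n_particles = 1, alpha = 1, v_bar = 15, Z = 3,
                               D_diff = 0, noise_sigma = 0, n_frames = 12,
                               size_px = 64, pixel_size_um = 0.7, seed = 14,
                               store_trajectories = TRUE)
  vel <- m$ground_truth$velocity_xy_um_s[1, ]
  traj <- m$ground_truth$trajectories_um
  # trajectory is exactly ballistic
  step <- traj[2, 1, ] - traj[1, 1, ]
  expect_equal(step, vel * 0.01, tolerance = 1e-12)
  # and the rendered spot centroid tracks it; the field is periodic, so use
  # the circular (phase-angle) centroid, which is wrap-exact
  centroid <- function(img) {
    w <- pmax(img, 0)
    th <- 2 * pi * ((1:64) - 0.5) / 64
    ang <- c(
      atan2(sum(colSums(w) * sin(th)), sum(colSums(w) * cos(th))),
      atan2(sum(rowSums(w) * sin(th)), sum(rowSums(w) * cos(th)))
    )
    (ang %% (2 * pi)) / (2 * pi) * 64 * 0.7
  }
  wrap_diff <- function(a, b, L = 44.8) {
    d <- a - b
    d - L * round(d / L)
  }
  d_obs <- wrap_diff(centroid(m$stack$frames[5, , ]),
                     centroid(m$stack$frames[1, , ]))
  d_true <- vel * 0.04
  expect_equal(d_obs, d_true, tolerance = 0.05)
})

test_that("swimmer speeds follow the requested Schulz distribution", {
  m <- generate_motility_movie(n_particles = 4000, alpha = 1, v_bar = 20,
                               Z = 3, n_frames = 2, size_px = 32, seed = 10)
  sp <- m$ground_truth$speeds_um_s
  expect_equal(mean(sp), 20, tolerance = 0.05)
  # Schulz relative width 1/sqrt(Z+1)
  expect_equal(sd(sp) / mean(sp), 1 / 2, tolerance = 0.05)
})

test_that("flicker traces are seeded and concentrate energy at the tones", {
  a <- generate_flicker_trace(seed = 3)
  b <- generate_flicker_trace(seed = 3)
  expect_identical(a$trace$values, b$trace$values)
  clean <- generate_flicker_trace(body_freq_hz = 18, flag_freq_hz = 200,
                                  noise_sigma = 0, seed = 4)
  ps <- power_spectrum(clean$trace)
  in_tones <- abs(ps$freq - 18) <= 2 * ps$bin_width_hz |
    abs(ps$freq - 200) <= 2 * ps$bin_width_hz
  expect_gt(sum(ps$power[in_tones]) / sum(ps$power), 0.95)
  expect_error(generate_flicker_trace(flag_freq_hz = 500), "Nyquist")
})

test_that("flicker round trip at moderate noise recovers both tones", {
  gen <- generate_flicker_trace(body_freq_hz = 18, flag_freq_hz = 200,
                                body_amp = 1, flag_amp = 1,
                                noise_sigma = 0.2, seed = 15)
  est <- detect_rotation(gen$trace)
  expect_lt(abs(est$body_freq_hz - 18), est$bin_width_hz)
  expect_lt(abs(est$flagellar_freq_hz - 200), est$bin_width_hz)
})

test_that("noiseless flagellation tables lie exactly on the coupling curves", {
  gen <- generate_flagellation_table(k = 1.2, intercept = 0.3, L_max = 7,
                                     K = 1.5, seed = 1)
  tab <- gen$table
  expect_equal(tab$n_flagella, 1.2 * tab$expression + 0.3)
  expect_equal(tab$length_um, 7 * tab$expression / (1.5 + tab$expression))
  # zero slope: all counts equal the intercept
  flat <- generate_flagellation_table(k = 0, intercept = 2, seed = 1)$table
  expect_true(all(flat$n_flagella == 2))
})

test_that("noisy tables are seeded, integer-valued and non-negative", {
  a <- generate_flagellation_table(count_noise_sd = 0.8,
                                   length_noise_sd = 0.5, seed = 6)
  b <- generate_flagellation_table(count_noise_sd = 0.8,
                                   length_noise_sd = 0.5, seed = 6)
  expect_identical(a$table, b$table)
  expect_true(all(a$table$n_flagella == round(a$table$n_flagella)))
  expect_true(all(a$table$n_flagella >= 0))
  expect_true(all(a$table$length_um >= 0))
})
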