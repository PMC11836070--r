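# Seeded generators for every input the pipeline consumes. Each returns the
# dataset together with a `synthetic_ground_truth` object recording the
# generator name, seed and all parameters, sufficient to regenerate it
# bit-exactly.

.ground_truth <- function(generator, seed, params, extra = list()) {
  structure(
    c(list(generator = generator, seed = seed, params = params), extra),
    class = "synthetic_ground_truth"
  )
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat("synthetic ground truth:", x$generator, "(seed", x$seed, ")\n")
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

# bilinear scatter of unit-mass particles onto an n x n periodic grid;
# p_px holds continuous (x, y) positions in pixel units
.splat <- function(p_px, n) {
  x <- p_px[, 1] %% n
  y <- p_px[, 2] %% n
  i0 <- floor(x); j0 <- floor(y)
  fx <- x - i0; fy <- y - j0
  i1 <- (i0 + 1) %% n; j1 <- (j0 + 1) %% n
  idx <- c(i0 * n + j0, i1 * n + j0, i0 * n + j1, i1 * n + j1) + 1
  w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  img <- numeric(n * n)
  s <- rowsum(w, idx)
  img[as.integer(rownames(s))] <- s
  matrix(img, n, n)
}

#' Synthetic 2-D motility movie with ground truth
#'
#' Emulates a phase-contrast movie of a mixed population: a fraction `alpha`
#' of particles swim ballistically with per-particle speeds drawn from a
#' Schulz distribution (mean `v_bar`, shape `Z`) along fixed directions drawn
#' uniformly on the 3-D unit sphere and observed in 2-D projection (the
#' imaging geometry that makes the swimmer ISF the sinc average the DDM model
#' assumes); all particles additionally undergo Brownian motion with
#' diffusivity `D_diff`. Particles are rendered as Gaussian spots (bilinear
#' sub-pixel placement convolved with a Gaussian point-spread function) on a
#' periodic field of view, with additive Gaussian camera noise. The generator
#' is a pure function of its parameters and seed.
#'
#' An optional tumble rate is provided but defaults to 0: at the lag times
#' DDM probes here the swimmer decorrelation is dominated by ballistic
#' motion, matching the ISF model's straight-swimmer assumption.
#'
#' @param n_particles Number of particles.
#' @param alpha Swimming fraction; `round(alpha * n_particles)` particles are
#'   swimmers.
#' @param v_bar,Z Schulz speed distribution of the swimmers (um/s, shape).
#' @param D_diff Diffusivity of all particles (um^2/s).
#' @param psf_sigma_px Gaussian PSF width (pixels).
#' @param noise_sigma Additive Gaussian noise sd (spot peak amplitude = 1).
#' @param frame_rate_hz Frames per second (default 100).
#' @param n_frames Number of frames (default 1000).
#' @param size_px Field of view (pixels, square; default 256).
#' @param pixel_size_um Pixel size (default 0.7 um).
#' @param tumble_rate_hz Poisson rate of random direction changes for
#'   swimmers (default 0).
#' @param seed Integer seed.
#' @param store_trajectories Keep the unwrapped per-frame particle positions
#'   (um) in the ground truth; needed by trajectory-level oracles.
#' @return A list with `stack` (an [image_stack()]) and `ground_truth` (a
#'   `synthetic_ground_truth` carrying the parameters, swimmer flags, drawn
#'   speeds, a Nyquist warning flag, and optionally the trajectories).
#' @examples
#' m <- generate_motility_movie(n_particles = 20, n_frames = 20,
#'                              size_px = 64, seed = 1)
#' dim(m$stack$frames)
#' @export
generate_motility_movie <- function(n_particles = 2000, alpha = 0.5,
                                    v_bar = 20, Z = 3, D_diff = 0.3,
                                    psf_sigma_px = 1.5, noise_sigma = 0.05,
                                    frame_rate_hz = 100, n_frames = 1000,
                                    size_px = 256, pixel_size_um = 0.7,
                                    tumble_rate_hz = 0, seed = 1,
                                    store_trajectories = FALSE) {
  .assert_scalar(n_particles, "n_particles", 1)
  .assert_scalar(alpha, "alpha", 0, 1)
  .assert_scalar(v_bar, "v_bar", 0)
  .assert_scalar(Z, "Z", 0, strict_lower = TRUE)
  .assert_scalar(D_diff, "D_diff", 0)
  .assert_scalar(n_frames, "n_frames", 2)
  .assert_scalar(size_px, "size_px", 8)
  params <- list(n_particles = n_particles, alpha = alpha, v_bar = v_bar,
                 Z = Z, D_diff = D_diff, psf_sigma_px = psf_sigma_px,
                 noise_sigma = noise_sigma, frame_rate_hz = frame_rate_hz,
                 n_frames = n_frames, size_px = size_px,
                 pixel_size_um = pixel_size_um,
                 tumble_rate_hz = tumble_rate_hz)
  dt <- 1 / frame_rate_hz
  nyquist_warning <- v_bar * dt / pixel_size_um > 2
  .with_seed(seed, {
    n <- as.integer(size_px)
    L <- n * pixel_size_um
    np <- as.integer(n_particles)
    n_swim <- as.integer(round(alpha * np))
    is_swimmer <- seq_len(np) <= n_swim
    speeds <- numeric(np)
    if (n_swim > 0) {
      speeds[is_swimmer] <- stats::rgamma(n_swim, shape = Z + 1,
                                          rate = (Z + 1) / v_bar)
    }
    # isotropic 3-D directions; the movie records the in-plane projection
    phi <- stats::runif(np, 0, 2 * pi)
    cos_pol <- stats::runif(np, -1, 1)
    sin_pol <- sqrt(1 - cos_pol^2)
    dir <- cbind(sin_pol * cos(phi), sin_pol * sin(phi))
    pos <- cbind(stats::runif(np, 0, L), stats::runif(np, 0, L))  # um

    # PSF kernel (peak 1) in Fourier space, wrapped so the peak sits at (1,1)
    dd <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1)))
    ker <- exp(-outer(dd^2, dd^2, "+") / (2 * psf_sigma_px^2))
    Kf <- stats::fft(ker)

    frames <- array(0, dim = c(n_frames, n, n))
    traj <- if (store_trajectories) array(0, dim = c(n_frames, np, 2)) else NULL
    sig <- sqrt(2 * D_diff * dt)
    for (t in seq_len(n_frames)) {
      if (store_trajectories) traj[t, , ] <- pos
      img <- .splat(pos / pixel_size_um, n)
      img <- Re(stats::fft(stats::fft(img) * Kf, inverse = TRUE)) / (n * n)
      if (noise_sigma > 0) img <- img + stats::rnorm(n * n, 0, noise_sigma)
      frames[t, , ] <- img
      step <- dir * (speeds * dt)
      if (D_diff > 0) step <- step + matrix(stats::rnorm(2 * np, 0, sig),
                                            ncol = 2)
      pos <- pos + step
      if (tumble_rate_hz > 0 && n_swim > 0) {
        tumble <- is_swimmer & stats::runif(np) < tumble_rate_hz * dt
        if (any(tumble)) {
          k <- sum(tumble)
          nphi <- stats::runif(k, 0, 2 * pi)
          ncp <- stats::runif(k, -1, 1)
          nsp <- sqrt(1 - ncp^2)
          dir[tumble, ] <- cbind(nsp * cos(nphi), nsp * sin(nphi))
        }
      }
    }
    gt <- .ground_truth("motility_movie", seed, params, list(
      n_swimmers = n_swim, is_swimmer = is_swimmer, speeds_um_s = speeds,
      velocity_xy_um_s = dir * speeds,
      nyquist_warning = nyquist_warning,
      trajectories_um = traj
    ))
    list(stack = image_stack(frames, frame_rate_hz, pixel_size_um),
         ground_truth = gt)
  })
}

#' Synthetic dark-field flicker trace with ground truth
#'
#' Sum of two sinusoids - body rotation and flagellar rotation - with random
#' phases plus additive Gaussian noise, sampled at `sample_rate_hz`.
#' Frequencies at or above Nyquist are an error.
#'
#' @param body_freq_hz,flag_freq_hz Injected rotation frequencies (Hz).
#' @param body_amp,flag_amp Sinusoid amplitudes.
#' @param noise_sigma Gaussian noise sd.
#' @param sample_rate_hz Sampling rate (default 800 Hz).
#' @param duration_s Trace duration (default 10 s).
#' @param seed Integer seed.
#' @return A list with `trace` (an [intensity_trace()]) and `ground_truth`.
#' @export
generate_flicker_trace <- function(body_freq_hz = 22, flag_freq_hz = 178,
                                   body_amp = 1, flag_amp = 0.5,
                                   noise_sigma = 0.2, sample_rate_hz = 800,
                                   duration_s = 10, seed = 1) {
  .assert_scalar(body_freq_hz, "body_freq_hz", 0, strict_lower = TRUE)
  .assert_scalar(flag_freq_hz, "flag_freq_hz", 0, strict_lower = TRUE)
  if (max(body_freq_hz, flag_freq_hz) >= sample_rate_hz / 2) {
    stop("injected frequency violates Nyquist (sample_rate/2 = ",
         sample_rate_hz / 2, " Hz)", call. = FALSE)
  }
  params <- list(body_freq_hz = body_freq_hz, flag_freq_hz = flag_freq_hz,
                 body_amp = body_amp, flag_amp = flag_amp,
                 noise_sigma = noise_sigma, sample_rate_hz = sample_rate_hz,
                 duration_s = duration_s)
  .with_seed(seed, {
    tt <- seq(0, duration_s, by = 1 / sample_rate_hz)
    ph <- stats::runif(2, 0, 2 * pi)
    v <- body_amp * sin(2 * pi * body_freq_hz * tt + ph[1]) +
      flag_amp * sin(2 * pi * flag_freq_hz * tt + ph[2])
    if (noise_sigma > 0) v <- v + stats::rnorm(length(tt), 0, noise_sigma)
    list(trace = intensity_trace(v, sample_rate_hz),
         ground_truth = .ground_truth("flicker_trace", seed, params,
                                      list(phases = ph)))
  })
}

#' Synthetic flagellation-versus-expression table with ground truth
#'
#' Per-cell records emulating the measured couplings: flagellar counts around
#' the linear mean `k * E + intercept` and filament lengths around the
#' saturating mean `L_max * E / (K + E)`. With zero noise the table lies
#' exactly on the coupling curves (counts are then left as real-valued
#' means); with noise, counts are rounded to non-negative integers and
#' lengths truncated at zero.
#'
#' @param expression Expression grid (arbitrary units, >= 0).
#' @param n_cells_per_level Cells sampled at each expression level.
#' @param k,intercept Linear number coupling.
#' @param L_max,K Saturating length coupling (um, expression units).
#' @param count_noise_sd,length_noise_sd Gaussian noise on counts and lengths.
#' @param seed Integer seed.
#' @return A list with `table` (data.frame: `expression`, `n_flagella`,
#'   `length_um`) and `ground_truth`.
#' @export
generate_flagellation_table <- function(expression = seq(0.5, 10, by = 0.5),
                                        n_cells_per_level = 10,
                                        k = 1, intercept = 0,
                                        L_max = 8, K = 2,
                                        count_noise_sd = 0,
                                        length_noise_sd = 0,
                                        seed = 1) {
  if (any(expression < 0)) {
    stop("expression levels must be non-negative", call. = FALSE)
  }
  params <- list(expression = expression,
                 n_cells_per_level = n_cells_per_level, k = k,
                 intercept = intercept, L_max = L_max, K = K,
                 count_noise_sd = count_noise_sd,
                 length_noise_sd = length_noise_sd)
  .with_seed(seed, {
    E <- rep(expression, each = n_cells_per_level)
    n_mean <- k * E + intercept
    len_mean <- L_max * E / (K + E)
    if (count_noise_sd > 0) {
      n_obs <- pmax(0, round(n_mean + stats::rnorm(length(E), 0,
                                                   count_noise_sd)))
    } else {
      n_obs <- n_mean
    }
    if (length_noise_sd > 0) {
      len_obs <- pmax(0, len_mean + stats::rnorm(length(E), 0,
                                                 length_noise_sd))
    } else {
      len_obs <- len_mean
    }
    tab <- data.frame(expression = E, n_flagella = n_obs, length_um = len_obs)
    list(table = tab,
         ground_truth = .ground_truth("flagellation_table", seed, params))
  })
}
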