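#' Image stack container
#'
#' A grayscale time-lapse movie: a 3-D array indexed (time, y, x) with its
#' frame rate and pixel size. Frames must be square (the radial averaging of
#' the structure function assumes isotropic sampling).
#'
#' @param frames Numeric array, dim `(n_frames, ny, nx)` with `ny == nx`.
#' @param frame_rate_hz Acquisition rate (frames per second).
#' @param pixel_size_um Pixel size in the sample plane (um).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_rate_hz, pixel_size_um) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("'frames' must be a 3-D array (time, y, x)", call. = FALSE)
  }
  d <- dim(frames)
  if (d[1] < 2) stop("need at least 2 frames", call. = FALSE)
  if (d[2] != d[3]) stop("frames must be square", call. = FALSE)
  if (!all(is.finite(frames))) stop("non-finite intensities", call. = FALSE)
  .assert_scalar(frame_rate_hz, "frame_rate_hz", 0, strict_lower = TRUE)
  .assert_scalar(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um),
    class = "image_stack"
  )
}

# Default lag ladder: log-spaced, ~30 per decade, from 1 frame to max_lag.
.default_lags <- function(n_frames, max_lag = NULL) {
  max_lag <- max_lag %||% floor((n_frames - 1) / 2)
  max_lag <- max(1, min(max_lag, n_frames - 1))
  k <- ceiling(30 * log10(max(max_lag, 2)) + 1)
  unique(pmin(max_lag, round(10^seq(0, log10(max_lag), length.out = k))))
}

#' Image structure function (differential dynamic microscopy)
#'
#' The DDM observable: for each lag tau, the time-averaged power spectrum of
#' frame differences,
#' \eqn{D(q, \tau) = \langle |\hat I(q, t+\tau) - \hat I(q, t)|^2 \rangle_t},
#' radially averaged into isotropic annular bins of width one FFT pixel
#' (zero frequency excluded, bins up to just below Nyquist). The time
#' average runs over up to `n_pairs_max` start frames evenly spread through
#' the stack. Fully deterministic.
#'
#' @param stack An [image_stack()].
#' @param lags Integer frame lags; default log-spaced (~30 per decade) up to
#'   half the stack length.
#' @param n_pairs_max Maximum number of frame pairs averaged per lag.
#' @return An object of class `structure_function` with `q` (um^-1), `tau`
#'   (s), the `n_q x n_tau` matrix `D`, and bookkeeping fields (`bin_counts`,
#'   `total_power` for spectral sanity checks).
#' @export
image_structure_function <- function(stack, lags = NULL, n_pairs_max = 50) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  n_frames <- d[1]
  n <- d[2]
  lags <- lags %||% .default_lags(n_frames)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1) || any(lags > n_frames - 1)) {
    stop("lags must lie in [1, n_frames - 1]", call. = FALSE)
  }

  # FFT of every frame, kept as a complex (n, n, T) array
  Fs <- array(complex(real = 0), dim = c(n, n, n_frames))
  total_power <- 0
  for (t in seq_len(n_frames)) {
    ft <- stats::fft(stack$frames[t, , ])
    Fs[, , t] <- ft
    total_power <- total_power + sum(Mod(ft)^2)
  }
  total_power <- total_power / (n_frames * n * n)

  # radial q bins (units um^-1), bin width = one FFT pixel
  dq <- 2 * pi / (n * stack$pixel_size_um)
  fr <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1)))  # fft freq * n
  qmag <- sqrt(outer(fr^2, fr^2, "+")) * dq
  bin <- round(qmag / dq)
  n_bins <- n %/% 2 - 1
  keep <- bin >= 1 & bin <= n_bins
  bin_idx <- bin[keep]
  counts <- tabulate(bin_idx, nbins = n_bins)

  D <- matrix(0, nrow = n_bins, ncol = length(lags))
  for (j in seq_along(lags)) {
    lag <- lags[j]
    n_av <- n_frames - lag
    starts <- unique(round(seq(1, n_av, length.out = min(n_pairs_max, n_av))))
    acc <- matrix(0, n, n)
    for (t in starts) {
      dF <- Fs[, , t + lag] - Fs[, , t]
      acc <- acc + Re(dF * Conj(dF))
    }
    acc <- acc / (length(starts) * n * n)
    D[, j] <- .bin_sum(acc[keep], bin_idx, n_bins) / counts
  }
  structure(
    list(q = (1:n_bins) * dq, tau = lags / stack$frame_rate_hz, D = D,
         lags = lags, bin_counts = counts, total_power = total_power,
         frame_rate_hz = stack$frame_rate_hz,
         pixel_size_um = stack$pixel_size_um),
    class = "structure_function"
  )
}

# group sums of x by integer index (1..n_bins); rowsum() keeps this in C
.bin_sum <- function(x, idx, n_bins) {
  out <- numeric(n_bins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Intermediate scattering function of Schulz-distributed swimmers
#'
#' Ballistic swimmers with an isotropic direction distribution and speeds
#' drawn from a Schulz distribution (mean `v_bar`, shape `Z`) have the
#' closed-form ISF
#' \deqn{f_s(q,\tau) = \frac{\sin(Z \arctan\lambda)}{Z \lambda
#'   (1+\lambda^2)^{Z/2}}, \quad
#'   \lambda = \frac{q \bar v \tau}{Z+1}}
#' which equals the speed-distribution average of
#' \eqn{\mathrm{sinc}(q v \tau)}. It is 1 at tau = 0 and approaches the
#' single-speed sinc as Z grows large.
#'
#' @param q Spatial frequency (um^-1), vectorised.
#' @param tau Lag time (s), vectorised.
#' @param v_bar Mean swimmer speed (um/s).
#' @param Z Schulz shape parameter (> 0); larger Z means a narrower speed
#'   distribution (relative width \eqn{1/\sqrt{Z+1}}).
#' @return The ISF value(s) in `[-1, 1]`.
#' @export
schulz_swimmer_isf <- function(q, tau, v_bar, Z) {
  stopifnot(Z > 0)
  lam <- q * v_bar * tau / (Z + 1)
  ifelse(
    abs(lam) < 1e-8,
    1,
    sin(Z * atan(lam)) / (Z * lam * (1 + lam^2)^(Z / 2))
  )
}

#' Structure-function model for a mixed swimmer/diffuser population
#'
#' The fitted DDM model \eqn{D(q,\tau) = A (1 - f(q,\tau)) + B} with the
#' mixed-population ISF
#' \deqn{f(q,\tau) = e^{-q^2 D \tau}\left[(1-\alpha) +
#'   \alpha f_s(q,\tau)\right]}
#' where alpha is the swimming fraction, D the diffusivity (shared by
#' swimmers as Brownian jitter), and \eqn{f_s} the Schulz swimmer ISF. A(q)
#' is the signal amplitude and B(q) the camera-noise floor.
#'
#' @param q Spatial frequency (um^-1).
#' @param tau Lag time(s) (s).
#' @param A,B Amplitude and noise floor (same units as the structure
#'   function).
#' @param alpha Swimming fraction in `[0, 1]`.
#' @param v_bar Mean swimmer speed (um/s).
#' @param Z Schulz shape parameter.
#' @param D_diff Diffusivity (um^2/s).
#' @return Model structure-function values.
#' @export
isf_model <- function(q, tau, A, B, alpha, v_bar, Z, D_diff) {
  f <- exp(-q^2 * D_diff * tau) *
    ((1 - alpha) + alpha * schulz_swimmer_isf(q, tau, v_bar, Z))
  A * (1 - f) + B
}

# deterministic initial guess for v_bar: the first interior local maximum of
# D(tau) sits near the first minimum of the swimmer ISF, q v tau ~ 4.49
.v_bar_init <- function(q, tau, y) {
  if (length(y) >= 5) {
    ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    ys[is.na(ys)] <- y[is.na(ys)]
    dd <- diff(sign(diff(ys)))
    imax <- which(dd < 0) + 1
    if (length(imax) > 0) {
      v0 <- 4.49 / (q * tau[imax[1]])
      if (is.finite(v0) && v0 > 1 && v0 < 150) return(v0)
    }
  }
  15
}

.diffusion_prefit <- function(q, tau, y) {
  B0 <- max(min(y), 0)
  A0 <- max(max(y) - B0, 1e-12)
  thresh <- B0 + A0 * (1 - exp(-1))
  ihalf <- which(y >= thresh)[1]
  if (is.na(ihalf)) ihalf <- length(y)
  D0 <- min(max(1 / (q^2 * tau[ihalf]), 1e-4), 50)
  df <- data.frame(tau = tau, y = y, q = q)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-q^2 * D * tau)) + B, data = df,
                      start = list(A = A0, B = B0, D = D0),
                      lower = c(0, 0, 0), upper = c(Inf, Inf, 100),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    list(A = A0, B = B0, D = D0)
  } else {
    cf <- stats::coef(fit)
    list(A = unname(cf["A"]), B = unname(cf["B"]), D = unname(cf["D"]))
  }
}

#' Fit the mixed-population model to a structure function
#'
#' Per-q bounded nonlinear least squares of [isf_model()] over lag time, with
#' deterministic initialisation (amplitude from the large-lag plateau, noise
#' floor from the smallest lag, alpha = 0.5, swimmer speed from the
#' first-minimum heuristic, Z = 2, diffusivity from a diffusion-only prefit).
#' The aggregate motility parameters are medians of the per-q estimates over
#' the q window; per-q diagnostics (convergence flag, residual norm,
#' boundary hits on Z) are retained.
#'
#' @param sf A [image_structure_function()] result.
#' @param q_window Numeric `c(q_min, q_max)` in um^-1 (default 0.4-2.0).
#' @param v_max Upper bound on the swimmer speed (um/s).
#' @return An object of class `motility_estimate`: `alpha`, `v_bar_um_s`,
#'   `Z`, `D_um2_s`, the `per_q` data.frame, and `q_window`.
#' @export
fit_structure_function <- function(sf, q_window = c(0.4, 2.0), v_max = 150) {
  stopifnot(inherits(sf, "structure_function"))
  sel <- which(sf$q >= q_window[1] & sf$q <= q_window[2])
  if (length(sel) == 0) {
    stop("q window contains no structure-function bins", call. = FALSE)
  }
  lower <- c(0, 0, 0, 0.1, 0.5, 0)
  upper <- c(Inf, Inf, 1, v_max, 50, 100)
  rows <- lapply(sel, function(i) {
    q <- sf$q[i]
    y <- sf$D[i, ]
    tau <- sf$tau
    pre <- .diffusion_prefit(q, tau, y)
    v0 <- .v_bar_init(q, tau, y)
    resid_fn <- function(p) {
      isf_model(q, tau, p[1], p[2], p[3], p[4], p[5], p[6]) - y
    }
    # deterministic multi-start: the mixed model has local minima (alpha at a
    # bound with Z degenerate); keep the lowest-residual converged solution
    starts <- list(c(0.5, v0), c(0.25, 12), c(0.75, 12),
                   c(0.25, 25), c(0.75, 25))
    fit <- NULL
    best <- Inf
    for (s in starts) {
      start <- c(A = max(pre$A, 1e-12), B = pre$B, alpha = s[1],
                 v_bar = s[2], Z = 2, D_diff = max(pre$D, 1e-4))
      cand <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL
      )
      if (!is.null(cand) && cand$info %in% 1:4 && all(is.finite(cand$par))) {
        rss <- sum(cand$fvec^2)
        if (rss < best) {
          best <- rss
          fit <- cand
        }
      }
    }
    if (is.null(fit)) {
      data.frame(q = q, A = NA, B = NA, alpha = NA, v_bar = NA, Z = NA,
                 D_diff = NA, converged = FALSE, resid_norm = NA,
                 z_at_bound = NA)
    } else {
      p <- fit$par
      data.frame(q = q, A = p[["A"]], B = p[["B"]], alpha = p[["alpha"]],
                 v_bar = p[["v_bar"]], Z = p[["Z"]], D_diff = p[["D_diff"]],
                 converged = TRUE,
                 resid_norm = sqrt(sum(fit$fvec^2)),
                 z_at_bound = p[["Z"]] <= 0.5 + 1e-6 || p[["Z"]] >= 50 - 1e-6)
    }
  })
  per_q <- do.call(rbind, rows)
  ok <- per_q$converged
  if (!any(ok)) {
    stop("no q bin in the window produced a converged fit; diagnostics: ",
         nrow(per_q), " bins attempted", call. = FALSE)
  }
  structure(
    list(
      alpha = stats::median(per_q$alpha[ok]),
      v_bar_um_s = stats::median(per_q$v_bar[ok]),
      Z = stats::median(per_q$Z[ok]),
      D_um2_s = stats::median(per_q$D_diff[ok]),
      per_q = per_q,
      q_window = q_window
    ),
    class = "motility_estimate"
  )
}

#' @export
print.motility_estimate <- function(x, ...) {
  cat(sprintf(
    "motility estimate: alpha = %.3f, v_bar = %.2f um/s, Z = %.2f, D = %.3f um2/s\n",
    x$alpha, x$v_bar_um_s, x$Z, x$D_um2_s))
  cat(sprintf("  q window %.2f-%.2f um^-1, %d/%d bins converged\n",
              x$q_window[1], x$q_window[2], sum(x$per_q$converged),
              nrow(x$per_q)))
  invisible(x)
}

#' Population-averaged velocity from a motility estimate
#'
#' @param est A [fit_structure_function()] result.
#' @return `alpha * v_bar` in um/s, the population-averaged swimming
#'   velocity.
#' @export
population_velocity <- function(est) {
  stopifnot(inherits(est, "motility_estimate"))
  est$alpha * est$v_bar_um_s
}
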