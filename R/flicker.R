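#' Intensity time series container
#'
#' A per-cell dark-field intensity trace. Rotating anisotropic scatterers
#' (the cell body and the flagellar bundle) modulate the scattered intensity
#' at their rotation frequencies, so the trace carries a body-rotation peak
#' (~10-30 Hz) and a flagellar-rotation peak (~100-250 Hz); a sample rate of
#' 800 Hz keeps both well below Nyquist.
#'
#' @param values Numeric intensity values.
#' @param sample_rate_hz Sampling rate (Hz).
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(values, sample_rate_hz) {
  if (!is.numeric(values) || length(values) < 2 || !all(is.finite(values))) {
    stop("'values' must be a finite numeric vector of length >= 2",
         call. = FALSE)
  }
  .assert_scalar(sample_rate_hz, "sample_rate_hz", 0, strict_lower = TRUE)
  structure(list(values = as.numeric(values), sample_rate_hz = sample_rate_hz),
            class = "intensity_trace")
}

#' Averaged-periodogram power spectral density
#'
#' Welch-style estimate: the trace is split into overlapping segments, each
#' linearly detrended and Hann-windowed, and the one-sided periodograms are
#' averaged. Frequency resolution is `sample_rate / segment_length`. A
#' constant trace has exactly zero power at all non-zero frequencies.
#'
#' @param trace An [intensity_trace()].
#' @param segment_length Samples per segment (default 1024).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A list with `freq` (Hz) and `power` (PSD), plus `n_segments`.
#' @export
power_spectrum <- function(trace, segment_length = 1024, overlap = 0.5) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- trace$values
  fs <- trace$sample_rate_hz
  n <- length(x)
  segment_length <- as.integer(segment_length)
  if (segment_length < 8) stop("segment_length too small", call. = FALSE)
  if (n < segment_length) {
    stop("trace shorter than one segment", call. = FALSE)
  }
  .assert_scalar(overlap, "overlap", 0, 1, strict_upper = TRUE)
  hop <- max(1L, as.integer(floor(segment_length * (1 - overlap))))
  starts <- seq(1L, n - segment_length + 1L, by = hop)
  tt <- seq_len(segment_length)
  w <- 0.5 - 0.5 * cos(2 * pi * (tt - 1) / (segment_length - 1))  # Hann
  X <- cbind(1, tt)
  nf <- segment_length %/% 2
  acc <- numeric(nf + 1)
  for (s in starts) {
    seg <- x[s + tt - 1L]
    co <- stats::.lm.fit(X, seg)$coefficients  # linear detrend
    seg <- (seg - (co[1] + co[2] * tt)) * w
    sp <- stats::fft(seg)
    p <- Mod(sp[1:(nf + 1)])^2 / (fs * sum(w^2))
    if (nf > 1) p[2:nf] <- 2 * p[2:nf]  # one-sided
    acc <- acc + p
  }
  list(freq = (0:nf) * fs / segment_length, power = acc / length(starts),
       n_segments = length(starts),
       bin_width_hz = fs / segment_length)
}

.band_peak <- function(ps, band, prominence_k) {
  idx <- which(ps$freq >= band[1] & ps$freq <= band[2])  # closed interval
  if (length(idx) < 3) {
    stop("frequency band [", band[1], ", ", band[2],
         "] Hz contains too few spectral bins", call. = FALSE)
  }
  p <- ps$power[idx]
  med <- stats::median(p)
  i <- which.max(p)
  if (p[i] > 0 && p[i] >= prominence_k * med) {
    list(freq = ps$freq[idx[i]], power = p[i])
  } else {
    list(freq = NA_real_, power = NA_real_)
  }
}

#' Detect body and flagellar rotation frequencies
#'
#' Band-limited peak picking on the averaged periodogram: the highest
#' spectral peak in the body band and in the flagellar band is accepted only
#' if it is prominent (at least `prominence_k` times the median in-band
#' power); otherwise that band reports "no peak" (`NA`) rather than a guess.
#' The motor frequency - the rotation rate of the flagellum relative to the
#' body - is the sum of the two lab-frame rates, and is reported only when
#' both peaks are present.
#'
#' @param trace An [intensity_trace()].
#' @param body_band,flag_band Closed frequency intervals (Hz) searched for
#'   the body and flagellar peaks; defaults `[5, 40]` and `[50, 350]`. Both
#'   must lie below Nyquist.
#' @param prominence_k Peak prominence threshold relative to the in-band
#'   median power (default 5).
#' @param segment_length,overlap Passed to [power_spectrum()].
#' @return An object of class `rotation_estimate` with `body_freq_hz`,
#'   `flagellar_freq_hz`, `motor_freq_hz` (`NA` when a peak is missing),
#'   peak powers, the bands and the spectral bin width.
#' @examples
#' tr <- generate_flicker_trace(seed = 7)$trace
#' detect_rotation(tr)
#' @export
detect_rotation <- function(trace, body_band = c(5, 40),
                            flag_band = c(50, 350), prominence_k = 5,
                            segment_length = 1024, overlap = 0.5) {
  stopifnot(inherits(trace, "intensity_trace"))
  nyq <- trace$sample_rate_hz / 2
  if (max(body_band, flag_band) > nyq) {
    stop("search bands exceed the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  if (body_band[2] >= flag_band[1]) {
    stop("body and flagellar bands must be disjoint", call. = FALSE)
  }
  ps <- power_spectrum(trace, segment_length, overlap)
  body <- .band_peak(ps, body_band, prominence_k)
  flag <- .band_peak(ps, flag_band, prominence_k)
  motor <- if (is.na(body$freq) || is.na(flag$freq)) NA_real_ else
    body$freq + flag$freq
  structure(
    list(
      body_freq_hz = body$freq,
      flagellar_freq_hz = flag$freq,
      motor_freq_hz = motor,
      body_peak_power = body$power,
      flagellar_peak_power = flag$power,
      body_band = body_band,
      flag_band = flag_band,
      bin_width_hz = ps$bin_width_hz
    ),
    class = "rotation_estimate"
  )
}

#' @export
print.rotation_estimate <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "no peak" else sprintf("%.2f Hz", v)
  cat("rotation estimate: body =", fmt(x$body_freq_hz),
      "| flagellar =", fmt(x$flagellar_freq_hz),
      "| motor =", fmt(x$motor_freq_hz), "\n")
  invisible(x)
}
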