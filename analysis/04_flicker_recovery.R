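#!/usr/bin/env Rscript
# Flicker-spectroscopy validation: traces with injected body and flagellar
# rotation tones at decreasing signal-to-noise, analysed by band-limited
# periodogram peak detection. The reported motor frequency is the sum of the
# two recovered rates.

suppressPackageStartupMessages(library(swimRFT))

dir.create("results", showWarnings = FALSE)

cases <- expand.grid(
  body_freq = c(15, 22, 30),
  flag_freq = c(130, 178, 240),
  noise_sigma = c(0.2, 1 / 3)
)

rows <- lapply(seq_len(nrow(cases)), function(i) {
  cs <- cases[i, ]
  gen <- generate_flicker_trace(body_freq_hz = cs$body_freq,
                                flag_freq_hz = cs$flag_freq,
                                body_amp = 1, flag_amp = 1,
                                noise_sigma = cs$noise_sigma, seed = 100 + i)
  est <- detect_rotation(gen$trace)
  data.frame(
    body_true_hz = cs$body_freq, flag_true_hz = cs$flag_freq,
    noise_sigma = cs$noise_sigma,
    body_est_hz = est$body_freq_hz, flag_est_hz = est$flagellar_freq_hz,
    motor_est_hz = est$motor_freq_hz, bin_width_hz = est$bin_width_hz
  )
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/flicker_recovery.csv", row.names = FALSE)

ok <- abs(tab$body_est_hz - tab$body_true_hz) <= tab$bin_width_hz &
  abs(tab$flag_est_hz - tab$flag_true_hz) <= tab$bin_width_hz
cat(sprintf("recovered both tones within one spectral bin in %d/%d cases\n",
            sum(ok), nrow(tab)))
cat(sprintf("median reported motor frequency: %.1f Hz (true %.1f Hz)\n",
            median(tab$motor_est_hz),
            median(tab$body_true_hz + tab$flag_true_hz)))
cat("wrote results/flicker_recovery.csv\n")
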