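# Shared fixtures: small deterministic objects used across test files.

# hypnogram of one 24-h day from per-state epoch counts in each phase
toy_day <- function(light = c(W = 5400, NR = 4320, R = 1080),
                    dark = c(W = 8000, NR = 2500, R = 300),
                    epoch_s = 4) {
  per_phase <- 12 * 3600 / epoch_s
  stopifnot(sum(light) == per_phase, sum(dark) == per_phase)
  hypnogram(c(rep(names(light), light), rep(names(dark), dark)),
            epoch_s = epoch_s)
}

# epoch_spectra object built directly from a power matrix (bypasses FFT)
spectra_from_matrix <- function(power) {
  colnames(power) <- paste0("hz", seq_len(ncol(power)))
  structure(list(power = power, bins = seq_len(ncol(power)),
                 retained = rep(TRUE, nrow(power)), normalized = FALSE,
                 norm_const = NA_real_, fs = NA_real_, epoch_s = 4,
                 power_raw = power),
            class = "epoch_spectra")
}

# brute-force one-sided DFT periodogram in 1-Hz bins; independent of the
# package's FFT path (explicit O(n^2) DFT matrix)
brute_force_bins <- function(x, fs, n_bins) {
  n <- length(x)
  k <- 0:(n %/% 2)
  W <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  X <- as.vector(W %*% x)
  p <- Mod(X)^2 / n^2
  dbl <- rep(2, length(k)); dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(k)] <- 1
  p <- p * dbl
  freqs <- k * fs / n
  bin <- ceiling(freqs - 1e-9)
  vapply(seq_len(n_bins), function(f) sum(p[bin == f]), numeric(1))
}
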