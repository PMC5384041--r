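# Per-epoch EEG power spectra.
#
# The analysis signal is the bipolar difference of the frontal and parietal
# derivations, conditioned by a zero-phase Butterworth high-pass (0.55 Hz)
# plus a 60-Hz notch, then transformed epoch-by-epoch with a plain FFT
# periodogram. Powers are aggregated into 1-Hz bins: bin f collects FFT
# frequencies in (f-1, f] Hz, f = 1..56, so "1-56 Hz" is an exact partition
# of (0, 56] Hz. Normalization expresses every bin as a percentage of the
# mean total power (1-56 Hz) over the retained epochs of the recording;
# artifacted epochs are removed iteratively wherever any single bin exceeds
# a threshold (300% by default), re-normalizing between passes.

#' Bipolar EEG derivation
#'
#' Sample-wise difference `frontal - parietal`; common-mode (shared
#' reference) activity cancels.
#'
#' @param rec an [eeg_recording()].
#' @param frontal,parietal channel names.
#' @return numeric vector (microvolts).
#' @export
derive_bipolar <- function(rec, frontal = "EEG_F", parietal = "EEG_P") {
  stopifnot(inherits(rec, "eeg_recording"))
  for (ch in c(frontal, parietal))
    if (is.null(rec$channels[[ch]]))
      stop("derive_bipolar: channel not present: ", ch)
  rec$channels[[frontal]] - rec$channels[[parietal]]
}

#' EEG conditioning filter specification
#'
#' @param highpass_hz high-pass cutoff in Hz (default 0.55).
#' @param notch_hz line-noise band-stop center in Hz (default 60); `NA`
#'   disables the notch.
#' @param notch_q quality factor; the stop band spans
#'   `notch_hz * (1 +/- 1/(2 q))`.
#' @param order Butterworth order of the high-pass (the notch is order 2).
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 0.55, notch_hz = 60, notch_q = 12,
                        order = 4L) {
  structure(list(highpass_hz = highpass_hz, notch_hz = notch_hz,
                 notch_q = notch_q, order = as.integer(order)),
            class = "filter_spec")
}

# forward-backward (zero-phase) application of one IIR filter; the signal is
# extended by odd reflection about its endpoints so start-up transients decay
# inside the padding, not the data
zero_phase <- function(flt, x, pad = 3L * max(length(flt$b), length(flt$a))) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- iir_filter(flt$b, flt$a, c(front, x, back))
  y <- rev(iir_filter(flt$b, flt$a, rev(y)))
  y[pad + seq_len(n)]
}

#' Apply zero-phase conditioning filters
#'
#' Forward-backward (zero-phase) Butterworth high-pass followed by a
#' Butterworth band-stop around the line frequency. Output has the same
#' length as the input.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param spec a [filter_spec()].
#' @return filtered numeric vector.
#' @export
apply_filters <- function(x, fs, spec = filter_spec()) {
  nyq <- fs / 2
  if (spec$highpass_hz <= 0 || spec$highpass_hz >= nyq)
    stop("apply_filters: high-pass cutoff ", spec$highpass_hz,
         " Hz must lie in (0, Nyquist = ", nyq, " Hz)")
  hp <- signal::butter(spec$order, spec$highpass_hz / nyq, type = "high")
  y <- zero_phase(hp, x, pad = round(3 * fs / spec$highpass_hz))
  if (!is.na(spec$notch_hz)) {
    half_bw <- spec$notch_hz / (2 * spec$notch_q)
    edges <- c(spec$notch_hz - half_bw, spec$notch_hz + half_bw)
    if (edges[2] >= nyq)
      stop("apply_filters: notch band edge ", edges[2],
           " Hz reaches Nyquist (", nyq, " Hz)")
    bs <- signal::butter(2L, edges / nyq, type = "stop")
    y <- zero_phase(bs, y, pad = round(3 * fs / (edges[2] - edges[1])))
  }
  y
}

#' Per-epoch power spectra in 1-Hz bins
#'
#' Splits the signal into consecutive epochs and computes a one-sided
#' periodogram per epoch, aggregated into 1-Hz bins (bin f = FFT frequencies
#' in (f-1, f] Hz). With the default rectangular window, summing the full
#' one-sided periodogram recovers the epoch mean square exactly (Parseval).
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate, Hz; `epoch_s * fs` must be an integer.
#' @param epoch_s epoch length in seconds (default 4).
#' @param n_bins highest 1-Hz bin retained (default 56).
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return an object of class `epoch_spectra`: list with `power` (epochs x
#'   n_bins matrix, microvolt^2), `retained` (logical mask), `normalized`
#'   flag, `norm_const` (microvolt^2 mean total once normalized), `fs`,
#'   `epoch_s`, `bins`.
#' @export
epoch_power_spectrum <- function(x, fs, epoch_s = 4, n_bins = 56L,
                                 window = c("rectangular", "hann")) {
  window <- match.arg(window)
  n <- epoch_s * fs
  if (n != round(n)) stop("epoch_power_spectrum: epoch_s * fs must be an integer")
  n <- as.integer(round(n))
  rem <- length(x) %% n
  if (rem != 0L)
    stop("epoch_power_spectrum: signal length ", length(x),
         " is not a whole number of ", n, "-sample epochs (remainder ", rem, ")")
  n_epochs <- length(x) %/% n
  m <- matrix(x, nrow = n)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n) else rep(1, n)
  # scale so a white signal keeps its mean-square power under the taper
  w <- w / sqrt(mean(w^2))
  ft <- stats::mvfft(m * w)

  n_half <- n %/% 2L
  freqs <- (0:n_half) * fs / n
  p <- Mod(ft[1:(n_half + 1L), , drop = FALSE])^2 / n^2
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, n_half + 1L)
  dbl[1] <- 1
  if (n %% 2L == 0L) dbl[n_half + 1L] <- 1
  p <- p * dbl

  bin_of <- ceiling(freqs - 1e-9)          # frequency f -> bin (f-1, f]
  keep <- bin_of >= 1L & bin_of <= n_bins
  groups <- factor(bin_of[keep], levels = seq_len(n_bins))
  power <- t(rowsum(p[keep, , drop = FALSE], groups, reorder = TRUE))
  dimnames(power) <- list(NULL, paste0("hz", seq_len(n_bins)))

  structure(list(power = power, bins = seq_len(n_bins),
                 retained = rep(TRUE, n_epochs), normalized = FALSE,
                 norm_const = NA_real_, fs = fs, epoch_s = epoch_s,
                 power_raw = power),
            class = "epoch_spectra")
}

#' @export
print.epoch_spectra <- function(x, ...) {
  cat(sprintf("<epoch_spectra> %d epochs x %d bins (1-%d Hz), %d retained, %s\n",
              nrow(x$power), length(x$bins), max(x$bins), sum(x$retained),
              if (x$normalized) sprintf("normalized (mean total %.4g uV^2)", x$norm_const)
              else "raw (uV^2)"))
  invisible(x)
}

#' Normalize spectra to the retained-epoch mean total power
#'
#' Every bin of every epoch is expressed as a percentage of the mean, over
#' retained epochs, of the total power (sum over bins). After normalization
#' the retained epochs' total powers average exactly 100. Idempotent for an
#' unchanged retention mask; always computed from the raw powers, so
#' re-normalizing after mask updates is exact.
#'
#' @param spectra an `epoch_spectra`.
#' @return the `epoch_spectra` with `power` in percent units.
#' @export
normalize_spectra <- function(spectra) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  if (!any(spectra$retained)) stop("normalize_spectra: no retained epochs")
  tot <- rowSums(spectra$power_raw)
  m <- mean(tot[spectra$retained])
  if (m <= 0) stop("normalize_spectra: mean total power is zero")
  spectra$power <- 100 * spectra$power_raw / m
  spectra$normalized <- TRUE
  spectra$norm_const <- m
  spectra
}

#' Iterative normalized-power artifact rejection
#'
#' Repeats for `passes` iterations: normalize over the currently retained
#' epochs, then drop every retained epoch in which any single 1-Hz bin
#' exceeds `threshold` percent. The returned spectra are re-normalized over
#' the final retained set.
#'
#' @param spectra an `epoch_spectra`.
#' @param threshold rejection threshold in percent of the mean total power
#'   (default 300).
#' @param passes number of iterations (default 2).
#' @return list with `spectra` (re-normalized, updated mask) and `report`
#'   (data.frame: `pass`, `epochs_before`, `epochs_removed`, `fraction`),
#'   with attribute `overall_fraction`.
#' @export
reject_artifacts <- function(spectra, threshold = 300, passes = 2L) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  if (threshold <= 0) stop("reject_artifacts: threshold must be positive")
  if (passes < 1L) stop("reject_artifacts: passes must be >= 1")
  n0 <- sum(spectra$retained)
  report <- data.frame(pass = integer(0), epochs_before = integer(0),
                       epochs_removed = integer(0), fraction = numeric(0))
  for (k in seq_len(passes)) {
    spectra <- normalize_spectra(spectra)
    before <- sum(spectra$retained)
    bad <- spectra$retained & rowSums(spectra$power > threshold) > 0L
    if (all(bad[spectra$retained]))
      stop("reject_artifacts: every retained epoch exceeds ", threshold,
           "% in pass ", k)
    spectra$retained <- spectra$retained & !bad
    report <- rbind(report, data.frame(
      pass = k, epochs_before = before, epochs_removed = sum(bad),
      fraction = sum(bad) / before))
  }
  spectra <- normalize_spectra(spectra)
  attr(report, "overall_fraction") <- (n0 - sum(spectra$retained)) / n0
  list(spectra = spectra, report = report)
}
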