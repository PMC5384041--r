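# Band-power aggregation: per-epoch band powers, per-state 1-Hz spectral
# profiles, ZT-binned band time courses (per day, then averaged), and the
# within-state percent-of-24-h-mean normalization.

#' Per-epoch band powers
#'
#' Sums the normalized 1-Hz-bin powers of each band. Overlapping bands (the
#' default sigma/beta share of bin 15) are summed independently.
#'
#' @param spectra a normalized `epoch_spectra`.
#' @param bands named list of inclusive `c(lo, hi)` bin ranges.
#' @return epochs x bands numeric matrix (percent units) with attribute
#'   `retained` copied from the spectra; rows of non-retained epochs are
#'   `NA`.
#' @export
band_powers <- function(spectra, bands = default_bands()) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  if (!spectra$normalized)
    stop("band_powers: spectra must be normalized first (see normalize_spectra)")
  nb <- length(spectra$bins)
  out <- sapply(names(bands), function(nm) {
    r <- bands[[nm]]
    if (r[1] < 1L || r[2] > nb)
      stop("band_powers: band '", nm, "' (", r[1], "-", r[2],
           ") references bins outside 1-", nb)
    rowSums(spectra$power[, r[1]:r[2], drop = FALSE])
  })
  out <- matrix(out, ncol = length(bands),
                dimnames = list(NULL, names(bands)))
  out[!spectra$retained, ] <- NA_real_
  attr(out, "retained") <- spectra$retained
  out
}

#' Per-state mean spectral profile
#'
#' Mean normalized power of each 1-Hz bin over the retained epochs scored as
#' `state`.
#'
#' @param spectra a normalized `epoch_spectra`.
#' @param hyp a [hypnogram()] aligned epoch-for-epoch with the spectra.
#' @param state one of `"W"`, `"NR"`, `"R"`.
#' @return numeric vector of length `length(spectra$bins)` with attribute
#'   `n_epochs`; all-`NA` (with `n_epochs = 0`) if the state contributes no
#'   retained epochs.
#' @export
state_spectral_profile <- function(spectra, hyp, state) {
  stopifnot(inherits(spectra, "epoch_spectra"), inherits(hyp, "hypnogram"))
  state <- match.arg(state, STATES)
  if (length(hyp) != nrow(spectra$power))
    stop("state_spectral_profile: hypnogram (", length(hyp),
         " epochs) and spectra (", nrow(spectra$power), ") are misaligned")
  sel <- spectra$retained & unclass(hyp) == state
  if (!any(sel)) {
    out <- rep(NA_real_, length(spectra$bins))
  } else {
    out <- colMeans(spectra$power[sel, , drop = FALSE])
  }
  names(out) <- colnames(spectra$power)
  attr(out, "n_epochs") <- sum(sel)
  out
}

#' Band-power time course in ZT bins
#'
#' Mean band power per (state, band, ZT time bin), computed within each 24-h
#' day and then averaged across days. Recordings shorter than 24 h cover
#' only the ZT bins they reach; multi-day cells average the days that
#' contain them. Cells with no retained epochs in any day are `NA`.
#'
#' @param bp per-epoch band-power matrix from [band_powers()].
#' @param hyp a [hypnogram()] aligned with the band powers.
#' @param bin_width_h ZT bin width in hours; must divide 24 (default 3).
#' @return long data.frame: `state`, `band`, `zt_bin` (0-based bin index;
#'   bin b spans ZT `[b*w, (b+1)*w)`), `value`, `n_epochs`.
#' @export
band_timecourse <- function(bp, hyp, bin_width_h = 3) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (nrow(bp) != length(hyp))
    stop("band_timecourse: band table and hypnogram are misaligned")
  if (24 %% bin_width_h != 0) stop("band_timecourse: bin width must divide 24")
  epoch_s <- attr(hyp, "epoch_s")
  offset <- attr(hyp, "lights_on_offset_h")
  skip <- round(offset * 3600 / epoch_s)
  n <- length(hyp) - skip
  if (n <= 0) stop("band_timecourse: recording ends before the first lights-on")
  covered_h <- n * epoch_s / 3600
  n_days <- ceiling(covered_h / 24)
  n_bins <- as.integer(ceiling(min(covered_h, 24) / bin_width_h - 1e-9))

  idx <- skip + seq_len(n)
  elapsed_h <- (seq_len(n) - 1L) * epoch_s / 3600
  day <- 1L + elapsed_h %/% 24
  zt <- epoch_zt(length(hyp), epoch_s, offset)[idx]
  zt_bin <- floor(zt / bin_width_h)
  st <- unclass(hyp)[idx]
  retained <- attr(bp, "retained")[idx]
  bands <- colnames(bp)

  grid <- expand.grid(state = STATES, band = bands, zt_bin = 0:(n_bins - 1L),
                      stringsAsFactors = FALSE)
  grid$value <- NA_real_
  grid$n_epochs <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- retained & st == grid$state[i] & zt_bin == grid$zt_bin[i]
    if (!any(sel)) next
    v <- bp[idx, grid$band[i]][sel]
    d <- day[sel]
    per_day_means <- tapply(v, d, mean)
    grid$value[i] <- mean(per_day_means)   # days lacking the cell drop out
    grid$n_epochs[i] <- sum(sel)
  }
  attr(grid, "bin_width_h") <- bin_width_h
  attr(grid, "n_days") <- n_days
  grid
}

#' Within-state normalization to the 24-h mean
#'
#' Re-expresses each (state, band) time course as a percentage of its own
#' mean over the day's time bins, so every complete row averages exactly
#' 100. Requires complete cells for each (state, band) being normalized.
#'
#' @param tc data.frame from [band_timecourse()].
#' @return the data.frame with `value` rescaled.
#' @export
within_state_normalize <- function(tc) {
  stopifnot(all(c("state", "band", "zt_bin", "value") %in% names(tc)))
  out <- tc
  for (s in unique(tc$state)) for (b in unique(tc$band)) {
    sel <- tc$state == s & tc$band == b
    v <- tc$value[sel]
    if (anyNA(v))
      stop("within_state_normalize: missing cells for state ", s, ", band ", b)
    m <- mean(v)
    if (m <= 0)
      stop("within_state_normalize: zero 24-h mean for state ", s, ", band ", b)
    out$value[sel] <- 100 * v / m
  }
  out
}
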