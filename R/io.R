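# Core containers and file IO: recordings, hypnograms, run configuration.

STATES <- c("W", "NR", "R")

#' Construct an EEG/EMG recording
#'
#' @param channels named list of equal-length numeric sample vectors
#'   (microvolts).
#' @param fs sampling rate in Hz, common to all channels.
#' @param lights_on_offset_h hours from recording start to the first
#'   lights-on (ZT0), in `[0, 24)`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(channels, fs, lights_on_offset_h = 0) {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("eeg_recording: channels differ in length: ",
         paste(sprintf("%s=%d", names(channels), lens), collapse = ", "))
  if (fs <= 0) stop("eeg_recording: fs must be positive")
  if (lights_on_offset_h < 0 || lights_on_offset_h >= 24)
    stop("eeg_recording: lights_on_offset_h must lie in [0, 24)")
  structure(list(channels = channels, fs = fs,
                 lights_on_offset_h = lights_on_offset_h),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %.6g Hz, %.3f h\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$fs, n / x$fs / 3600))
  invisible(x)
}

#' Construct a hypnogram
#'
#' One vigilance-state label (`W`, `NR`, `R`) per fixed-length scoring epoch.
#'
#' @param states character vector of labels in `{W, NR, R}`.
#' @param epoch_s epoch length in seconds (default 4).
#' @param lights_on_offset_h hours from epoch 0 to ZT0, in `[0, 24)`.
#' @return an object of class `hypnogram` (a character vector with attributes
#'   `epoch_s` and `lights_on_offset_h`).
#' @export
hypnogram <- function(states, epoch_s = 4, lights_on_offset_h = 0) {
  states <- as.character(states)
  if (length(states) == 0L) stop("hypnogram: empty state vector")
  bad <- setdiff(unique(states), STATES)
  if (length(bad))
    stop("hypnogram: unknown state label(s): ", paste(bad, collapse = ", "))
  if (epoch_s <= 0) stop("hypnogram: epoch_s must be positive")
  structure(states, epoch_s = epoch_s,
            lights_on_offset_h = lights_on_offset_h, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = STATES))
  cat(sprintf("<hypnogram> %d epochs x %g s (%.2f h); W %d | NR %d | R %d\n",
              length(x), attr(x, "epoch_s"),
              length(x) * attr(x, "epoch_s") / 3600,
              tab["W"], tab["NR"], tab["R"]))
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i, ...) {
  hypnogram(unclass(x)[i], epoch_s = attr(x, "epoch_s"),
            lights_on_offset_h = attr(x, "lights_on_offset_h"))
}

# Zeitgeber time (hours since lights-on, mod 24) of each epoch start.
epoch_zt <- function(n_epochs, epoch_s, lights_on_offset_h) {
  ((seq_len(n_epochs) - 1L) * epoch_s / 3600 - lights_on_offset_h) %% 24
}

# light phase = ZT [0, 12), dark = ZT [12, 24)
epoch_phase <- function(n_epochs, epoch_s, lights_on_offset_h) {
  ifelse(epoch_zt(n_epochs, epoch_s, lights_on_offset_h) < 12, "light", "dark")
}

#' Read a recording from an EDF file
#'
#' @param path EDF file path.
#' @param lights_on_offset_h hours from recording start to ZT0.
#' @param require_eeg channel names that must be present (default the two
#'   EEG derivations used for the bipolar signal).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, lights_on_offset_h = 0,
                           require_eeg = c("EEG_F", "EEG_P")) {
  edf <- read_edf(path)
  missing <- setdiff(require_eeg, names(edf$channels))
  if (length(missing))
    stop("read_recording: required channel(s) absent from ", path, ": ",
         paste(missing, collapse = ", "))
  fs <- unique(edf$fs[require_eeg])
  if (length(fs) != 1L)
    stop("read_recording: EEG channels have mixed sampling rates: ",
         paste(sprintf("%s=%g", require_eeg, edf$fs[require_eeg]), collapse = ", "))
  eeg_recording(edf$channels, fs = fs, lights_on_offset_h = lights_on_offset_h)
}

#' Read a hypnogram from a two-column TSV file
#'
#' Expected format: `epoch_index<TAB>state`, 0-based contiguous indices,
#' states in `{W, NR, R}`. A header line `epoch_index\tstate` is permitted.
#'
#' @param path TSV file path.
#' @param epoch_s epoch length in seconds.
#' @param lights_on_offset_h hours from epoch 0 to ZT0.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 4, lights_on_offset_h = 0) {
  if (!file.exists(path)) stop("read_hypnogram: file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", col.names = c("epoch", "state"))
  if (nrow(df) && identical(df$epoch[1], "epoch_index")) df <- df[-1, , drop = FALSE]
  if (!nrow(df)) stop("read_hypnogram: no epochs in ", path)
  idx <- suppressWarnings(as.integer(df$epoch))
  if (anyNA(idx)) stop("read_hypnogram: non-integer epoch index in ", path)
  expect <- seq_len(nrow(df)) - 1L
  if (!identical(idx, expect)) {
    at <- which(idx != expect)[1]
    stop("read_hypnogram: epoch indices must be 0-based and contiguous; ",
         "found index ", idx[at], " at line ", at, " (expected ", expect[at], ")")
  }
  hypnogram(df$state, epoch_s = epoch_s, lights_on_offset_h = lights_on_offset_h)
}

#' Write a hypnogram as a two-column TSV file
#'
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.table(
    data.frame(epoch_index = seq_along(hyp) - 1L, state = unclass(hyp)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default spectral band definitions
#'
#' delta 1-4, theta 5-8, alpha 9-12, sigma 13-15, beta 15-30 Hz (inclusive
#' integer 1-Hz bins). Sigma and beta share bin 15 by convention; see
#' [default_bands_nonoverlap()] for a partition variant.
#'
#' @return named list of `c(lo, hi)` integer bin ranges.
#' @export
default_bands <- function() {
  list(delta = c(1L, 4L), theta = c(5L, 8L), alpha = c(9L, 12L),
       sigma = c(13L, 15L), beta = c(15L, 30L))
}

#' Non-overlapping band preset (beta starts at 16 Hz)
#' @return named list of `c(lo, hi)` integer bin ranges.
#' @export
default_bands_nonoverlap <- function() {
  b <- default_bands()
  b$beta <- c(16L, 30L)
  b
}

validate_bands <- function(bands, total_range) {
  for (nm in names(bands)) {
    r <- bands[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop("band '", nm, "' must be c(lo, hi) with lo <= hi")
    if (r[1] < total_range[1] || r[2] > total_range[2])
      stop("band '", nm, "' (", r[1], "-", r[2],
           " Hz) lies outside the total-power range ",
           total_range[1], "-", total_range[2], " Hz")
  }
  invisible(bands)
}

#' Build a validated run configuration
#'
#' @param bands named list of inclusive integer 1-Hz-bin ranges.
#' @param rejection_threshold_percent normalized-power rejection threshold
#'   (percent of cohort-mean total power; default 300).
#' @param rejection_passes number of normalize-and-reject iterations
#'   (default 2).
#' @param time_bin_h width of ZT time bins for band time courses (default 3).
#' @param total_power_range inclusive 1-Hz-bin range defining total power
#'   (default 1-56).
#' @param highpass_hz,notch_hz,filter_order EEG conditioning filter settings.
#' @param fft_window `"rectangular"` (default) or `"hann"`.
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed recorded with results.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(bands = default_bands(),
                       rejection_threshold_percent = 300,
                       rejection_passes = 2L,
                       time_bin_h = 3,
                       total_power_range = c(1L, 56L),
                       highpass_hz = 0.55,
                       notch_hz = 60,
                       filter_order = 4L,
                       fft_window = c("rectangular", "hann"),
                       alpha = 0.05,
                       seed = NULL) {
  fft_window <- match.arg(fft_window)
  if (rejection_threshold_percent <= 0)
    stop("run_config: rejection threshold must be positive")
  if (rejection_passes < 1L) stop("run_config: rejection_passes must be >= 1")
  if (time_bin_h <= 0 || 24 %% time_bin_h != 0)
    stop("run_config: time_bin_h must divide 24")
  if (total_power_range[1] < 1L || total_power_range[2] < total_power_range[1])
    stop("run_config: invalid total_power_range")
  if (alpha <= 0 || alpha >= 1) stop("run_config: alpha must lie in (0, 1)")
  validate_bands(bands, total_power_range)
  structure(list(bands = bands,
                 rejection_threshold_percent = rejection_threshold_percent,
                 rejection_passes = as.integer(rejection_passes),
                 time_bin_h = time_bin_h,
                 total_power_range = as.integer(total_power_range),
                 highpass_hz = highpass_hz, notch_hz = notch_hz,
                 filter_order = as.integer(filter_order),
                 fft_window = fft_window, alpha = alpha, seed = seed),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Absent keys take the defaults of [run_config()]; band entries are given as
#' `name: [lo, hi]`.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  args <- list()
  if (!is.null(y$bands))
    args$bands <- lapply(y$bands, function(r) as.integer(r))
  for (key in c("rejection_threshold_percent", "rejection_passes",
                "time_bin_h", "highpass_hz", "notch_hz", "filter_order",
                "fft_window", "alpha", "seed"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(y$total_power_range))
    args$total_power_range <- as.integer(y$total_power_range)
  do.call(run_config, args)
}
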