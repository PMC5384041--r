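# Minimal European Data Format (EDF) reader/writer.
#
# Covers the plain-EDF subset this pipeline needs: a fixed number of
# equal-rate signals, 16-bit little-endian samples, one-second data records.
# Physical units are microvolts throughout the package.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  raw <- charToRaw(x)
  c(raw, rep(charToRaw(" "), width - length(raw)))
}

# ASCII rendering of a number that fits the header field width; the string
# (not the double) is the authoritative value, so callers digitizing against
# it must reparse it (see .edf_num_str)
.edf_num_str <- function(x, width) {
  for (digits in seq(10, 1)) {
    s <- formatC(x, format = "g", digits = digits, width = -1)
    if (nchar(s) <= width) return(s)
  }
  stop("EDF header field overflow: ", x)
}

.edf_num <- function(x, width) .edf_pad(.edf_num_str(x, width), width)

#' Write signals to an EDF file
#'
#' Writes a set of equal-length, equal-rate channels as plain EDF with
#' one-second data records and 16-bit quantization over each channel's
#' observed physical range.
#'
#' @param path output file path.
#' @param channels named list of numeric vectors (microvolts), all the same
#'   length.
#' @param fs sampling rate in Hz; must be a positive integer (samples per
#'   one-second record).
#' @param start_date,start_time header date/time strings (`dd.mm.yy`,
#'   `hh.mm.ss`).
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(path, channels, fs,
                      start_date = "01.01.01", start_time = "00.00.00") {
  stopifnot(is.list(channels), length(channels) >= 1L, !is.null(names(channels)))
  fs <- as.numeric(fs)
  if (fs <= 0 || fs != round(fs))
    stop("write_edf: sampling rate must be a positive integer (got ", fs, ")")
  n <- unique(vapply(channels, length, integer(1)))
  if (length(n) != 1L)
    stop("write_edf: all channels must have equal length")
  if (n %% fs != 0L)
    stop("write_edf: signal length must be a whole number of 1-s records")
  n_rec <- n / fs
  ns <- length(channels)

  # physical range per channel, symmetric, padded 5% so extremes don't clip;
  # snapped to its 8-char ASCII header rendering so reader and writer agree
  pmax <- vapply(channels, function(x) max(abs(x), 1e-6), numeric(1)) * 1.05
  pmax <- vapply(pmax, function(p) as.numeric(.edf_num_str(p, 7L)), numeric(1))
  dig_max <- 32767L

  hdr <- c(
    .edf_pad("0", 8L),                       # version
    .edf_pad("X X X X", 80L),                # patient id
    .edf_pad("Startdate X X X X", 80L),      # recording id
    .edf_pad(start_date, 8L),
    .edf_pad(start_time, 8L),
    .edf_num(256L * (ns + 1L), 8L),          # header length
    .edf_pad("", 44L),                       # reserved
    .edf_num(n_rec, 8L),
    .edf_num(1L, 8L),                        # record duration (s)
    .edf_num(ns, 4L)
  )
  field <- function(f, width) unlist(lapply(seq_len(ns), function(i) .edf_pad(f(i), width)))
  hdr <- c(hdr,
    field(function(i) names(channels)[i], 16L),
    field(function(i) "", 80L),              # transducer
    field(function(i) "uV", 8L),
    unlist(lapply(pmax, function(p) .edf_num(-p, 8L))),
    unlist(lapply(pmax, function(p) .edf_num(p, 8L))),
    field(function(i) "-32768", 8L),
    field(function(i) "32767", 8L),
    field(function(i) "", 80L),              # prefilter
    field(function(i) as.character(fs), 8L),
    field(function(i) "", 32L)
  )

  # digitize with the same affine map the reader inverts:
  # physical [-p, p] <-> digital [-32768, 32767]
  dig <- mapply(function(x, p) {
    v <- as.integer(round((x + p) / (2 * p) * 65535 - 32768))
    pmin.int(pmax.int(v, -32768L), dig_max)
  }, channels, pmax, SIMPLIFY = FALSE)

  # interleave per record: record r holds fs samples of each channel in order
  mat <- matrix(0L, nrow = fs * ns, ncol = n_rec)
  for (i in seq_len(ns)) {
    mat[(i - 1L) * fs + seq_len(fs), ] <- matrix(dig[[i]], nrow = fs)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.integer(mat), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Parses plain EDF with equal record durations, returning each signal on its
#' physical scale (microvolts for signals written by [write_edf()]).
#'
#' @param path EDF file path.
#' @return list with `channels` (named list of numeric vectors), `fs` (named
#'   numeric vector of per-channel sampling rates, Hz), and `record_duration_s`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("read_edf: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd_num <- function(w) as.numeric(rd_str(w))

  version <- rd_str(8L)
  if (!identical(version, "0")) stop("read_edf: not an EDF file (version field '", version, "')")
  invisible(rd_str(80L)); invisible(rd_str(80L))  # patient, recording
  invisible(rd_str(8L)); invisible(rd_str(8L))    # date, time
  hdr_len <- rd_num(8L)
  invisible(rd_str(44L))
  n_rec <- rd_num(8L)
  rec_dur <- rd_num(8L)
  ns <- as.integer(rd_num(4L))
  if (is.na(ns) || ns < 1L) stop("read_edf: malformed header (signal count)")

  per <- function(w, numeric = FALSE) {
    out <- vapply(seq_len(ns), function(i) rd_str(w), character(1))
    if (numeric) as.numeric(out) else out
  }
  labels <- per(16L)
  invisible(per(80L))
  invisible(per(8L))        # physical dimension
  phys_min <- per(8L, TRUE)
  phys_max <- per(8L, TRUE)
  dig_min <- per(8L, TRUE)
  dig_max <- per(8L, TRUE)
  invisible(per(80L))
  spr <- as.integer(per(8L, TRUE))  # samples per record
  invisible(per(32L))

  seek(con, hdr_len)
  total <- sum(spr) * n_rec
  raw16 <- readBin(con, "integer", n = total, size = 2L, signed = TRUE, endian = "little")
  if (length(raw16) < total)
    stop("read_edf: truncated data section (expected ", total, " samples, got ", length(raw16), ")")

  offsets <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  channels <- vector("list", ns)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(offsets[i] + seq_len(spr[i]), (seq_len(n_rec) - 1L) * rec_len, "+"))
    d <- raw16[idx]
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    channels[[i]] <- phys_min[i] + (d - dig_min[i]) * scale
  }
  names(channels) <- labels
  list(channels = channels,
       fs = stats::setNames(spr / rec_dur, labels),
       record_duration_s = rec_dur)
}
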