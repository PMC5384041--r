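# Sleep-architecture metrics from scored hypnograms: state proportions per
# 12-h phase, hourly time-of-day profiles, and episode (bout) statistics.
# Multi-day recordings are analysed per day and averaged at the subject level.

#' Split a hypnogram into per-24-h day segments aligned to ZT0
#'
#' Epochs before the first lights-on are discarded; the remainder must cover
#' a whole number of 24-h days.
#'
#' @param hyp a [hypnogram()].
#' @return list of `hypnogram` segments, each starting at ZT0 and spanning
#'   24 h.
#' @export
split_days <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  epoch_s <- attr(hyp, "epoch_s")
  offset <- attr(hyp, "lights_on_offset_h")
  skip <- round(offset * 3600 / epoch_s)
  if (skip >= length(hyp))
    stop("split_days: recording ends before the first lights-on")
  n <- length(hyp) - skip
  per_day <- 24 * 3600 / epoch_s
  if (per_day != round(per_day) || n %% per_day != 0)
    stop(sprintf(
      "split_days: hypnogram covers %.3f h after ZT0 alignment; need a whole number of 24-h days",
      n * epoch_s / 3600))
  n_days <- n / per_day
  lapply(seq_len(n_days), function(d) {
    idx <- skip + (d - 1L) * per_day + seq_len(per_day)
    hypnogram(unclass(hyp)[idx], epoch_s = epoch_s, lights_on_offset_h = 0)
  })
}

#' State time proportions within a phase
#'
#' @param day a single-day `hypnogram` starting at ZT0 (from [split_days()]).
#' @param phase `"light"` (ZT 0-12), `"dark"` (ZT 12-24) or `"both"`.
#' @return named numeric `c(W=, NR=, R=)` summing to 1.
#' @export
state_proportions <- function(day, phase = c("light", "dark", "both")) {
  phase <- match.arg(phase)
  stopifnot(inherits(day, "hypnogram"))
  ph <- epoch_phase(length(day), attr(day, "epoch_s"), attr(day, "lights_on_offset_h"))
  keep <- if (phase == "both") rep(TRUE, length(day)) else ph == phase
  tab <- table(factor(unclass(day)[keep], levels = STATES))
  stats::setNames(as.numeric(tab) / sum(tab), STATES)
}

#' Hourly state-fraction profile over 24 h
#'
#' @param day a single-day `hypnogram` starting at ZT0.
#' @return 24 x 3 matrix; row `h` holds the W/NR/R fractions within
#'   ZT hour `h-1`.
#' @export
hourly_profile <- function(day) {
  stopifnot(inherits(day, "hypnogram"))
  epoch_s <- attr(day, "epoch_s")
  per_hour <- 3600 / epoch_s
  if (length(day) != 24 * per_hour)
    stop("hourly_profile: expected a full 24-h day segment")
  hour <- rep(0:23, each = per_hour)
  out <- t(vapply(0:23, function(h) {
    tab <- table(factor(unclass(day)[hour == h], levels = STATES))
    as.numeric(tab) / sum(tab)
  }, numeric(3)))
  dimnames(out) <- list(paste0("ZT", 0:23), STATES)
  out
}

#' Segment a hypnogram into episodes (bouts)
#'
#' An episode is a maximal run of consecutive epochs sharing one state; its
#' phase is the light/dark phase of its onset epoch.
#'
#' @param hyp a [hypnogram()].
#' @param min_epochs minimum episode length in epochs; shorter runs are
#'   merged into the preceding episode (default 1, i.e. no smoothing).
#' @return data.frame with columns `state`, `start` (1-based epoch index),
#'   `length` (epochs), `phase`.
#' @export
segment_episodes <- function(hyp, min_epochs = 1L) {
  stopifnot(inherits(hyp, "hypnogram"))
  r <- rle(as.vector(unclass(hyp)))
  if (min_epochs > 1L) {
    # merge sub-threshold runs into the run before them (first run is kept)
    while (length(r$lengths) > 1L && any(r$lengths[-1] < min_epochs)) {
      i <- which(r$lengths < min_epochs & seq_along(r$lengths) > 1L)[1]
      r$values[i] <- r$values[i - 1L]
      r <- rle(inverse.rle(r))
    }
  }
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  ph <- epoch_phase(length(hyp), attr(hyp, "epoch_s"),
                    attr(hyp, "lights_on_offset_h"))
  data.frame(state = r$values, start = start, length = r$lengths,
             phase = ph[start], stringsAsFactors = FALSE)
}

#' Episode counts and mean durations per state and phase
#'
#' @param episodes data.frame from [segment_episodes()].
#' @param epoch_s epoch length in seconds.
#' @return data.frame with one row per state x phase: `count` and
#'   `mean_duration_s` (`NA` where the state has no episodes in the phase).
#' @export
episode_stats <- function(episodes, epoch_s) {
  grid <- expand.grid(state = STATES, phase = c("light", "dark"),
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  grid$mean_duration_s <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- episodes$state == grid$state[i] & episodes$phase == grid$phase[i]
    grid$count[i] <- sum(sel)
    if (any(sel)) grid$mean_duration_s[i] <- mean(episodes$length[sel]) * epoch_s
  }
  grid
}

#' Per-subject sleep-architecture summary
#'
#' Computes phase proportions, the hourly profile, and episode statistics for
#' each 24-h day, then averages across days.
#'
#' @param hyp a [hypnogram()] covering whole days after ZT0 alignment.
#' @param min_epochs minimum episode length passed to [segment_episodes()].
#' @return list with `proportions` (data.frame state x phase x fraction),
#'   `hourly` (24 x 3 matrix), `episodes` (data.frame as [episode_stats()]),
#'   and `n_days`.
#' @export
architecture_summary <- function(hyp, min_epochs = 1L) {
  days <- split_days(hyp)
  epoch_s <- attr(hyp, "epoch_s")

  prop <- lapply(days, function(d) {
    rbind(light = state_proportions(d, "light"),
          dark  = state_proportions(d, "dark"))
  })
  prop_mean <- Reduce(`+`, prop) / length(prop)
  prop_df <- data.frame(
    phase = rep(rownames(prop_mean), times = 3),
    state = rep(STATES, each = 2),
    fraction = as.vector(prop_mean), stringsAsFactors = FALSE)

  hourly <- Reduce(`+`, lapply(days, hourly_profile)) / length(days)

  ep <- lapply(days, function(d) episode_stats(segment_episodes(d, min_epochs), epoch_s))
  ep_mean <- ep[[1]][c("state", "phase")]
  ep_mean$count <- rowMeans(sapply(ep, `[[`, "count"))
  dur <- sapply(ep, `[[`, "mean_duration_s")
  if (is.null(dim(dur))) dur <- matrix(dur, ncol = 1L)
  ep_mean$mean_duration_s <- rowMeans(dur)  # NA if absent in any day

  list(proportions = prop_df, hourly = hourly, episodes = ep_mean,
       n_days = length(days))
}
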