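# Synthetic polysomnography generator.
#
# Hypnograms come from a two-phase (light/dark) per-epoch Markov chain over
# {W, NR, R}. EEG is state-dependent colored noise: each state has a set of
# band-limited oscillators (white noise shaped by a second-order resonator,
# calibrated so the configured amplitude is the output RMS in microvolts)
# plus broadband noise. State streams are blended with a 0.25-s raised-
# cosine crossfade at transitions, so the composite is continuous and
# exactly stationary within state runs. Genotype effects multiply oscillator
# amplitudes by band membership, so generated band *power* scales with the
# squared multiplier. Two referential EEG channels share the signal with
# opposite polarity plus common-mode drift and line noise (which cancel in
# the bipolar derivation); EMG channels carry state-dependent muscle tone
# (W > NR > R). Artifacts are Poisson-placed high-amplitude transients added
# to both EEG channels with independent jitter so they survive subtraction.

#' Simulation configuration
#'
#' Defaults mirror a standard 48-h mouse study: 512 Hz sampling, 4-s scoring
#' epochs, 12:12 light-dark cycle, seven subjects per genotype.
#'
#' @param sampling_rate_hz sampling rate, Hz (default 512).
#' @param epoch_s scoring epoch, s (default 4).
#' @param duration_h recording length, h (default 48).
#' @param lights_on_offset_h hours from recording start to ZT0 (default 0).
#' @param n_per_group subjects per genotype (default 7).
#' @param seed master integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate_hz = 512, epoch_s = 4, duration_h = 48,
                       lights_on_offset_h = 0, n_per_group = 7L, seed = 1L) {
  if (sampling_rate_hz <= 0 || epoch_s <= 0 || duration_h <= 0)
    stop("sim_config: rates and durations must be positive")
  spe <- epoch_s * sampling_rate_hz
  if (abs(spe - round(spe)) > 1e-9 || round(spe) < 1)
    stop("sim_config: epoch_s * sampling_rate_hz must be a positive integer")
  n_ep <- duration_h * 3600 / epoch_s
  if (abs(n_ep - round(n_ep)) > 1e-9)
    stop("sim_config: duration must be a whole number of epochs")
  if (lights_on_offset_h < 0 || lights_on_offset_h >= 24)
    stop("sim_config: lights_on_offset_h must lie in [0, 24)")
  if (n_per_group < 1L) stop("sim_config: n_per_group must be >= 1")
  structure(list(sampling_rate_hz = sampling_rate_hz, epoch_s = epoch_s,
                 duration_h = duration_h,
                 lights_on_offset_h = lights_on_offset_h,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' State-dependent spectral model of the generated EEG/EMG
#'
#' Each state carries oscillator components (`freq` center Hz, `bw`
#' bandwidth Hz, `amp` output RMS in microvolts), a broadband-noise RMS, and
#' an EMG RMS. Defaults give high-amplitude slow (delta) activity mixed
#' with moderate theta and spindle-range (sigma) activity in NREM, regular
#' moderate theta in REM, and mixed theta/beta in wake, with muscle tone
#' W > NR > R.
#'
#' @param W,NR,R per-state lists with elements `components` (data.frame
#'   `freq`, `bw`, `amp`), `noise` (RMS, microvolts), `emg` (RMS,
#'   microvolts).
#' @return list of class `state_spectral_model`.
#' @export
state_spectral_model <- function(
    W = list(components = data.frame(freq = c(7, 20), bw = c(3, 10),
                                     amp = c(28, 12)),
             noise = 22, emg = 60),
    NR = list(components = data.frame(freq = c(2, 6.5, 13), bw = c(1.5, 2, 2),
                                      amp = c(45, 22, 12)),
              noise = 16, emg = 15),
    R = list(components = data.frame(freq = 7.5, bw = 1.2, amp = 30),
             noise = 14, emg = 2)) {
  model <- list(W = W, NR = NR, R = R)
  for (s in names(model)) {
    comp <- model[[s]]$components
    if (nrow(comp) && (any(comp$amp < 0) || any(comp$bw <= 0) || any(comp$freq <= 0)))
      stop("state_spectral_model: state ", s,
           ": amplitudes must be >= 0, bandwidths and frequencies > 0")
    if (model[[s]]$noise < 0 || model[[s]]$emg < 0)
      stop("state_spectral_model: state ", s, ": negative RMS")
  }
  structure(model, class = "state_spectral_model")
}

#' Multiplicative genotype effect on band amplitudes
#'
#' @param ... per-state named numeric vectors of amplitude multipliers keyed
#'   by band name, e.g. `NR = c(delta = 0.75)`. Unlisted (state, band) pairs
#'   default to 1. Band power scales as the squared amplitude multiplier.
#' @return list of class `genotype_effect`.
#' @export
genotype_effect <- function(...) {
  eff <- list(...)
  bad <- setdiff(names(eff), STATES)
  if (length(bad)) stop("genotype_effect: unknown state(s): ", paste(bad, collapse = ", "))
  for (s in names(eff))
    if (any(eff[[s]] <= 0)) stop("genotype_effect: multipliers must be > 0")
  structure(eff, class = "genotype_effect")
}

#' Genotype-effect preset emulating the knock-in spectral phenotype
#'
#' Amplitude multipliers reproducing the headline pattern of the modelled
#' study at its reported effect magnitude: suppressed NREM delta/theta/alpha,
#' elevated wake sigma/beta, reduced REM alpha with elevated REM beta.
#'
#' @return a [genotype_effect()].
#' @export
ki_effect_preset <- function() {
  genotype_effect(W = c(sigma = 1.15, beta = 1.15),
                  NR = c(delta = 0.75, theta = 0.73, alpha = 0.9),
                  R = c(alpha = 0.85, beta = 1.15))
}

# amplitude multiplier for an oscillator at center frequency `freq` in state
# `state`: product over the bands whose frequency range (lo-1, hi] contains
# the center frequency
effect_multiplier <- function(effect, state, freq, bands = default_bands()) {
  if (is.null(effect) || is.null(effect[[state]])) return(1)
  mult <- 1
  for (b in names(effect[[state]])) {
    r <- bands[[b]]
    if (is.null(r)) stop("effect_multiplier: unknown band '", b, "'")
    if (freq > r[1] - 1 && freq <= r[2]) mult <- mult * effect[[state]][[b]]
  }
  mult
}

#' Two-phase Markov transition model for vigilance states
#'
#' Row-stochastic per-epoch transition matrices (rows/columns ordered
#' W, NR, R), one for the light phase and one for the dark phase. Default
#' matrices give realistic 4-s-epoch dynamics: light phase roughly 40% wake
#' / 50% NREM / 10% REM with minute-scale bouts, dark phase wake-dominated
#' (about 70% wake) with consolidated waking.
#'
#' @param light,dark 3x3 row-stochastic matrices.
#' @param initial initial state label (default `"W"`).
#' @return list of class `transition_model`.
#' @export
transition_model <- function(light = NULL, dark = NULL, initial = "W") {
  if (is.null(light))
    light <- matrix(c(0.950, 0.048, 0.002,
                      0.022, 0.962, 0.016,
                      0.075, 0.005, 0.920), 3, 3, byrow = TRUE)
  if (is.null(dark))
    dark <- matrix(c(0.9850, 0.0145, 0.0005,
                     0.0400, 0.9450, 0.0150,
                     0.0750, 0.0050, 0.9200), 3, 3, byrow = TRUE)
  for (nm in c("light", "dark")) {
    m <- get(nm)
    if (!is.matrix(m) || !identical(dim(m), c(3L, 3L)))
      stop("transition_model: ", nm, " matrix must be 3x3")
    if (any(m < 0) || any(m > 1))
      stop("transition_model: ", nm, " matrix entries must lie in [0, 1]")
    rs <- rowSums(m)
    bad <- which(abs(rs - 1) > 1e-12)
    if (length(bad))
      stop("transition_model: ", nm, " matrix row ", bad[1], " (",
           STATES[bad[1]], ") sums to ", format(rs[bad[1]], digits = 15),
           ", not 1")
  }
  initial <- match.arg(initial, STATES)
  dimnames(light) <- dimnames(dark) <- list(STATES, STATES)
  structure(list(light = light, dark = dark, initial = initial),
            class = "transition_model")
}

# Vectorized simulation of many parallel phase-switching Markov chains.
# Returns an integer matrix (chains x epochs) of state codes 1=W, 2=NR, 3=R.
simulate_markov_chains <- function(n_chains, n_epochs, transitions,
                                   epoch_s, lights_on_offset_h = 0) {
  stopifnot(inherits(transitions, "transition_model"))
  cum <- list(light = t(apply(transitions$light, 1L, cumsum)),
              dark = t(apply(transitions$dark, 1L, cumsum)))
  phase <- epoch_phase(n_epochs, epoch_s, lights_on_offset_h)
  out <- matrix(0L, n_chains, n_epochs)
  state <- rep(match(transitions$initial, STATES), n_chains)
  out[, 1L] <- state
  for (e in seq_len(n_epochs - 1L)) {
    cm <- cum[[phase[e]]]
    u <- stats::runif(n_chains)
    state <- 1L + (u > cm[state, 1L]) + (u > cm[state, 2L])
    out[, e + 1L] <- state
  }
  out
}

#' Generate a scored hypnogram from the Markov model
#'
#' @param config a [sim_config()].
#' @param transitions a [transition_model()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return a [hypnogram()] with one label per epoch.
#' @export
generate_hypnogram <- function(config, transitions = transition_model(),
                               seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_epochs <- as.integer(round(config$duration_h * 3600 / config$epoch_s))
  codes <- simulate_markov_chains(1L, n_epochs, transitions, config$epoch_s,
                                  config$lights_on_offset_h)
  hypnogram(STATES[codes[1L, ]], epoch_s = config$epoch_s,
            lights_on_offset_h = config$lights_on_offset_h)
}

# fast Gaussian noise; seed drawn from the R stream keeps set.seed()
# reproducibility while the samples come from a dedicated compiled RNG
fast_rnorm <- function(n, sd = 1) {
  gauss_vec(n, sd, floor(stats::runif(1) * 2^31))
}

# Second-order resonator (poles at radius exp(-pi bw / fs), angle
# 2 pi f / fs) applied to unit white noise, pre-scaled so the output RMS is
# `amp`. Gain is calibrated from the impulse-response energy.
resonator_noise <- function(n, freq, bw, amp, fs) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * freq / fs
  a1 <- -2 * r * cos(theta)
  a2 <- r^2
  len <- min(max(256L, ceiling(12 * fs / bw)), 1e6)
  h <- ar2_filter(c(1, rep(0, len - 1L)), a1, a2)
  g <- sqrt(sum(h^2))
  warm <- min(len, 8192L)
  gauss_ar2(n, a1, a2, amp / g, warm, floor(stats::runif(1) * 2^31))
}

#' Generate one epoch of single-channel EEG for a state
#'
#' Sum of the state's resonator-shaped oscillators (amplitudes scaled by the
#' genotype multipliers of the bands each oscillator falls in) plus
#' broadband noise, mean-centered.
#'
#' @param state state label (`W`, `NR`, `R`).
#' @param model a [state_spectral_model()].
#' @param effect optional [genotype_effect()].
#' @param n_samples samples to generate (> 0).
#' @param fs sampling rate, Hz.
#' @param seed optional integer seed.
#' @param bands band definitions used for effect membership.
#' @return numeric vector of length `n_samples` (microvolts).
#' @export
generate_epoch_signal <- function(state, model = state_spectral_model(),
                                  effect = NULL, n_samples, fs, seed = NULL,
                                  bands = default_bands()) {
  state <- match.arg(state, STATES)
  if (n_samples <= 0) stop("generate_epoch_signal: n_samples must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sm <- model[[state]]
  x <- numeric(n_samples)
  comp <- sm$components
  for (i in seq_len(nrow(comp))) {
    if (comp$freq[i] >= fs / 2)
      stop("generate_epoch_signal: component at ", comp$freq[i],
           " Hz is at or above Nyquist (", fs / 2, " Hz)")
    a <- comp$amp[i] * effect_multiplier(effect, state, comp$freq[i], bands)
    if (a > 0) x <- x + resonator_noise(n_samples, comp$freq[i], comp$bw[i], a, fs)
  }
  if (sm$noise > 0) x <- x + stats::rnorm(n_samples, sd = sm$noise)
  x - mean(x)
}

# Continuous composite signal for a whole hypnogram: one stationary stream
# per state, blended with raised-cosine crossfades of `crossfade_s` seconds
# centered on state transitions. Returns list(eeg, emg).
compose_subject_signal <- function(hyp, model, effect, fs,
                                   crossfade_s = 0.25,
                                   bands = default_bands(), with_emg = TRUE) {
  epoch_s <- attr(hyp, "epoch_s")
  spe <- as.integer(round(epoch_s * fs))
  n <- length(hyp) * spe
  codes <- match(unclass(hyp), STATES)

  # per-state sample weights: state indicator with cosine ramps at changes
  L <- as.integer(round(crossfade_s * fs))
  ramp <- if (L > 0L) (1 - cos(pi * (seq_len(L) - 0.5) / L)) / 2 else numeric(0)
  w <- lapply(1:3, function(s) as.numeric(rep(codes == s, each = spe)))
  if (L > 0L) {
    changes <- which(diff(codes) != 0L)        # transition after epoch i
    for (ci in changes) {
      t0 <- ci * spe                            # first sample of the new state
      lo <- max(1L, t0 - L %/% 2L + 1L)
      hi <- min(n, lo + L - 1L)
      win <- lo:hi
      rw <- ramp[seq_along(win)]
      s_old <- codes[ci]; s_new <- codes[ci + 1L]
      w[[s_old]][win] <- 1 - rw
      w[[s_new]][win] <- rw
    }
  }

  eeg <- numeric(n)
  emg <- numeric(n)
  for (s in 1:3) {
    if (all(w[[s]] == 0)) next
    sm <- model[[STATES[s]]]
    stream <- numeric(n)
    comp <- sm$components
    for (i in seq_len(nrow(comp))) {
      a <- comp$amp[i] * effect_multiplier(effect, STATES[s], comp$freq[i], bands)
      if (a > 0)
        stream <- stream + resonator_noise(n, comp$freq[i], comp$bw[i], a, fs)
    }
    if (sm$noise > 0) stream <- stream + fast_rnorm(n, sd = sm$noise)
    eeg <- eeg + w[[s]] * stream
    if (with_emg && sm$emg > 0)
      emg <- emg + w[[s]] * fast_rnorm(n, sd = sm$emg)
  }
  list(eeg = eeg, emg = if (with_emg) emg else NULL)
}

#' Artifact model
#'
#' The default rate puts roughly 2% of epochs in contact with an artifact,
#' matching the fraction of data a typical rodent EEG study discards.
#'
#' @param rate expected artifacts per hour (>= 0; default 18).
#' @param amplitude transient amplitude as a multiple of the affected
#'   epoch's bipolar RMS (default 20).
#' @param duration_s transient duration, s (default 0.5).
#' @return list of class `artifact_model`.
#' @export
artifact_model <- function(rate = 18, amplitude = 20, duration_s = 0.5) {
  if (rate < 0) stop("artifact_model: rate must be >= 0")
  if (amplitude < 0) stop("artifact_model: amplitude must be >= 0")
  if (duration_s <= 0) stop("artifact_model: duration must be > 0")
  structure(list(rate = rate, amplitude = amplitude, duration_s = duration_s),
            class = "artifact_model")
}

#' Inject high-amplitude artifacts into a recording
#'
#' Poisson-placed transients (cosine-enveloped slow oscillation plus noise)
#' added to both EEG channels with independent jitter and unequal, opposite
#' polarity, so they are not cancelled by the bipolar derivation. Transients
#' shorter than an epoch are confined to a single epoch (jitter included),
#' making the returned log an exact ground truth for rejection checks.
#'
#' @param rec an [eeg_recording()] with channels `EEG_F`, `EEG_P`.
#' @param model an [artifact_model()]; rate 0 is a no-op.
#' @param seed optional integer seed.
#' @param epoch_s epoch length used for the artifact log (default 4).
#' @return list with `recording` and `artifact_epochs` (sorted 1-based
#'   indices of every epoch overlapping an artifact).
#' @export
inject_artifacts <- function(rec, model = artifact_model(), seed = NULL,
                             epoch_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(model, "artifact_model"))
  if (!is.null(seed)) set.seed(seed)
  fs <- rec$fs
  n <- length(rec$channels[[1]])
  duration_h <- n / fs / 3600
  n_art <- if (model$rate > 0) stats::rpois(1L, model$rate * duration_h) else 0L
  if (n_art == 0L || model$amplitude == 0)
    return(list(recording = rec, artifact_epochs = integer(0)))

  spe <- as.integer(round(epoch_s * fs))
  len <- as.integer(round(model$duration_s * fs))
  j <- as.integer(round(0.01 * fs))          # channel jitter, +/- 10 ms
  bipolar <- rec$channels$EEG_F - rec$channels$EEG_P
  n_epochs <- n %/% spe
  # transients that fit are confined to one epoch (with jitter margin) so
  # the ground-truth log is exact; longer ones start at a random sample
  within_epoch <- len + 2L * (j + 1L) <= spe
  if (within_epoch) {
    ep <- sample.int(n_epochs, n_art, replace = TRUE)
    offset <- sample.int(spe - len - 2L * (j + 1L), n_art, replace = TRUE)
    onsets <- sort((ep - 1L) * spe + j + 1L + offset)
  } else {
    onsets <- sort(sample.int(n - len - j, n_art, replace = TRUE) + j)
  }
  env <- (1 - cos(2 * pi * seq_len(len) / (len + 1L))) / 2
  hit <- integer(0)
  for (t0 in onsets) {
    tt <- t0:(t0 + len - 1L)
    ep0 <- (t0 - 1L) %/% spe
    ep_rms <- {
      ei <- ep0 * spe + seq_len(spe)
      ei <- ei[ei <= n]
      sqrt(mean(bipolar[ei]^2))
    }
    wav <- env * (sin(2 * pi * 2.5 * (tt - t0) / fs + stats::runif(1, 0, 2 * pi)) +
                    0.4 * stats::rnorm(len))
    wav <- wav / sqrt(mean(wav^2)) * model$amplitude * ep_rms
    jitter <- if (j > 0L) sample(seq.int(-j, j), 1L) else 0L
    kappa <- stats::runif(1, 0.2, 0.5)
    tt2 <- pmin(pmax(tt + jitter, 1L), n)
    rec$channels$EEG_F[tt] <- rec$channels$EEG_F[tt] + wav
    rec$channels$EEG_P[tt2] <- rec$channels$EEG_P[tt2] - kappa * wav
    hit <- c(hit, unique((c(tt, tt2) - 1L) %/% spe) + 1L)
  }
  list(recording = rec, artifact_epochs = sort(unique(hit)))
}

# One subject's full recording, drawn from the current RNG stream: Markov
# hypnogram, per-subject amplitude variability, composite EEG/EMG, two
# referential EEG channels sharing drift + line noise, injected artifacts.
simulate_subject_recording <- function(config, model, effect, transitions,
                                       artifacts, subject_cv,
                                       with_emg = TRUE) {
  fs <- config$sampling_rate_hz
  hyp <- generate_hypnogram(config, transitions, seed = NULL)

  m <- model
  sdlog <- sqrt(log(1 + subject_cv^2))
  for (s in STATES) {
    nc <- nrow(m[[s]]$components)
    m[[s]]$components$amp <- m[[s]]$components$amp *
      stats::rlnorm(nc, -sdlog^2 / 2, sdlog)
    m[[s]]$noise <- m[[s]]$noise * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }

  sig <- compose_subject_signal(hyp, m, effect, fs, with_emg = with_emg)
  n <- length(sig$eeg)
  common <- resonator_noise(n, 0.2, 0.15, 30, fs) +   # shared slow drift
    15 * sin(2 * pi * 60 * seq_len(n) / fs)            # shared line noise
  channels <- list(
    EEG_F = 0.55 * sig$eeg + common + fast_rnorm(n, sd = 2),
    EEG_P = -0.45 * sig$eeg + common + fast_rnorm(n, sd = 2))
  if (with_emg) {
    channels$EMG1 <- sig$emg + fast_rnorm(n, sd = 1)
    channels$EMG2 <- sig$emg * 0.9 + fast_rnorm(n, sd = 1)
  }
  rec <- eeg_recording(channels, fs = fs,
                       lights_on_offset_h = config$lights_on_offset_h)
  art <- inject_artifacts(rec, artifacts, seed = NULL, epoch_s = config$epoch_s)
  list(recording = art$recording, hypnogram = hyp,
       artifact_epochs = art$artifact_epochs)
}

#' Generate a full on-disk cohort (EDF + hypnograms + manifest)
#'
#' Simulates `n_per_group` subjects per genotype, writes one EDF (channels
#' `EEG_F`, `EEG_P`, `EMG1`, `EMG2`), one hypnogram TSV and one artifact-log
#' TSV per subject, plus a YAML manifest. Deterministic given
#' `config$seed`; per-subject seeds are derived from it.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param effects named list of [genotype_effect()] per genotype label
#'   (default wild type with no effect and a knock-in preset).
#' @param model a [state_spectral_model()].
#' @param transitions a [transition_model()].
#' @param artifacts an [artifact_model()].
#' @param subject_cv lognormal coefficient of variation applied per subject
#'   and component to oscillator/noise amplitudes (default 0.10,
#'   inter-animal variability).
#' @return path of the manifest file, invisibly; the manifest records
#'   subjects, genotypes, files and seeds.
#' @export
generate_cohort <- function(config, out_dir,
                            effects = list(WT = genotype_effect(),
                                           KI = ki_effect_preset()),
                            model = state_spectral_model(),
                            transitions = transition_model(),
                            artifacts = artifact_model(),
                            subject_cv = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("generate_cohort: cannot create output directory ", out_dir)
  fs <- config$sampling_rate_hz
  if (fs != round(fs)) stop("generate_cohort: EDF output needs an integer sampling rate")
  subjects <- list()
  k <- 0L
  for (gt in names(effects)) {
    for (i in seq_len(config$n_per_group)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", gt, i)
      subj_seed <- (config$seed + 7919L * k) %% .Machine$integer.max
      set.seed(subj_seed)
      subj <- simulate_subject_recording(config, model, effects[[gt]],
                                         transitions, artifacts, subject_cv)

      edf_path <- file.path(out_dir, paste0(id, ".edf"))
      hyp_path <- file.path(out_dir, paste0(id, "_hypnogram.tsv"))
      art_path <- file.path(out_dir, paste0(id, "_artifacts.tsv"))
      write_edf(edf_path, subj$recording$channels, fs)
      write_hypnogram(subj$hypnogram, hyp_path)
      utils::write.table(
        data.frame(epoch_index = subj$artifact_epochs - 1L),
        art_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      subjects[[id]] <- list(id = id, genotype = gt, seed = subj_seed,
                             edf = basename(edf_path),
                             hypnogram = basename(hyp_path),
                             artifacts = basename(art_path))
    }
  }
  manifest <- list(
    seed = config$seed,
    sampling_rate_hz = fs,
    epoch_s = config$epoch_s,
    duration_h = config$duration_h,
    lights_on_offset_h = config$lights_on_offset_h,
    n_per_group = config$n_per_group,
    genotypes = names(effects),
    subjects = unname(subjects))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a cohort manifest
#'
#' @param path manifest YAML written by [generate_cohort()].
#' @return the manifest as a list, with `dir` set to its directory.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest: file not found: ", path)
  m <- yaml::read_yaml(path)
  m$dir <- dirname(normalizePath(path))
  m
}
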