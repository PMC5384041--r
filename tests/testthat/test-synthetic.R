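test_that("absorbing transition matrices freeze the initial state", {
  tm <- transition_model(light = diag(3), dark = diag(3), initial = "W")
  cfg <- sim_config(sampling_rate_hz = 128, duration_h = 1, seed = 1)
  hyp <- generate_hypnogram(cfg, tm, seed = 4)
  expect_equal(unique(unclass(hyp)), "W")
  expect_length(hyp, 900L)
})

test_that("default configuration yields 43200 epochs over 48 h", {
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$duration_h * 3600 / cfg$epoch_s, 43200)
  h <- generate_hypnogram(sim_config(sampling_rate_hz = 128, seed = 2),
                          seed = 10)
  expect_length(h, 43200L)
})

test_that("hypnogram generation is deterministic given the seed", {
  cfg <- sim_config(sampling_rate_hz = 128, duration_h = 2, seed = 1)
  h1 <- generate_hypnogram(cfg, seed = 99)
  h2 <- generate_hypnogram(cfg, seed = 99)
  expect_identical(h1, h2)
})

test_that("invalid transition matrices name the offending row", {
  m <- diag(3); m[2, 2] <- 0.9
  expect_error(transition_model(light = m), "row 2 \\(NR\\)")
  m2 <- matrix(c(0.5, 0.6, -0.1), 3, 3)
  expect_error(transition_model(light = m2), "\\[0, 1\\]")
})

test_that("light-phase occupancy matches the stationary distribution", {
  # Metropolis construction: detailed balance w.r.t. pi = (.35, .55, .10)
  pi <- c(0.35, 0.55, 0.10)
  beta <- 0.15
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) if (i != j)
    P[i, j] <- beta * min(1, pi[j] / pi[i])
  diag(P) <- 1 - rowSums(P)
  # oracle: stationary distribution by eigen-decomposition
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  expect_equal(stat, pi, tolerance = 1e-10)

  tm <- transition_model(light = P, dark = P)
  cfg <- sim_config(sampling_rate_hz = 128, duration_h = 12, seed = 1)
  hyp <- generate_hypnogram(cfg, tm, seed = 123)    # 10800 light epochs
  emp <- table(factor(unclass(hyp), levels = c("W", "NR", "R"))) / length(hyp)
  expect_true(all(abs(as.numeric(emp) - pi) < 0.03))
})

test_that("epoch signals honour amplitudes and band placement", {
  model0 <- state_spectral_model(
    W = list(components = data.frame(freq = 7, bw = 2, amp = 0),
             noise = 0, emg = 0),
    NR = list(components = data.frame(freq = 2, bw = 1, amp = 40),
              noise = 0, emg = 0),
    R = list(components = data.frame(freq = 7.5, bw = 1, amp = 10),
             noise = 0, emg = 0))
  z <- generate_epoch_signal("W", model0, n_samples = 512, fs = 128, seed = 1)
  expect_equal(z, rep(0, 512))
  expect_error(generate_epoch_signal("N2", model0, n_samples = 512, fs = 128))

  # single 2-Hz NREM oscillator: >= 90% of power in 1-4 Hz
  x <- generate_epoch_signal("NR", model0, n_samples = 128 * 64, fs = 128,
                             seed = 2)
  es <- epoch_power_spectrum(x, 128, epoch_s = 64, n_bins = 56)
  expect_gt(sum(es$power[1, 1:4]) / sum(es$power[1, ]), 0.9)
})

test_that("band power scales as the squared genotype multiplier", {
  model0 <- state_spectral_model(
    NR = list(components = data.frame(freq = 2, bw = 1, amp = 40),
              noise = 5, emg = 0))
  eff <- genotype_effect(NR = c(delta = 0.8))
  delta_power <- function(effect, seed) {
    set.seed(seed)
    mean(replicate(250, {
      x <- generate_epoch_signal("NR", model0, effect = effect,
                                 n_samples = 512, fs = 128)
      sum(epoch_power_spectrum(x, 128, 4)$power[1, 1:4])
    }))
  }
  base <- delta_power(NULL, 60)
  mod <- delta_power(eff, 61)
  expect_equal(mod / base, 0.64, tolerance = 0.05)
})

test_that("artifact injection is Poisson with exact epoch logs", {
  set.seed(70)
  n <- 64 * 3600 * 2   # 2 h at 64 Hz
  rec <- eeg_recording(list(EEG_F = rnorm(n, sd = 30),
                            EEG_P = rnorm(n, sd = 30)), fs = 64)
  # rate 0 is a no-op
  out0 <- inject_artifacts(rec, artifact_model(rate = 0), seed = 1)
  expect_identical(out0$recording$channels, rec$channels)
  expect_length(out0$artifact_epochs, 0L)
  # expected count 96; within 3 sigma of Poisson(96)
  out <- inject_artifacts(rec, artifact_model(rate = 48, amplitude = 10),
                          seed = 2, epoch_s = 4)
  n_art <- length(out$artifact_epochs)
  expect_gt(n_art, 96 - 3 * sqrt(96))
  expect_lt(n_art, 96 + 3 * sqrt(96))
  # injected epochs differ from the original, others are untouched
  spe <- 64 * 4
  changed <- which(rec$channels$EEG_F != out$recording$channels$EEG_F)
  expect_true(all(unique((changed - 1) %/% spe + 1) %in% out$artifact_epochs))
})

test_that("a 30x-RMS artifact epoch exceeds 300% after normalization", {
  set.seed(71)
  fs <- 128
  n <- fs * 4 * 450    # 30 min
  rec <- eeg_recording(list(EEG_F = rnorm(n, sd = 30),
                            EEG_P = rnorm(n, sd = 30)), fs = fs)
  out <- inject_artifacts(rec, artifact_model(rate = 12, amplitude = 30),
                          seed = 3, epoch_s = 4)
  expect_gt(length(out$artifact_epochs), 0L)
  x <- derive_bipolar(out$recording)
  es <- normalize_spectra(epoch_power_spectrum(x, fs, 4))
  worst <- apply(es$power[out$artifact_epochs, , drop = FALSE], 1, max)
  expect_true(all(worst > 300))
})

test_that("generated cohorts are complete, deterministic and well-mixed", {
  cfg <- sim_config(sampling_rate_hz = 128, duration_h = 1, n_per_group = 1,
                    seed = 5)
  d1 <- withr::local_tempdir()
  man <- generate_cohort(cfg, d1)
  files <- list.files(d1)
  expect_length(grep("\\.edf$", files), 2L)
  expect_length(grep("hypnogram", files), 2L)
  expect_true("manifest.yaml" %in% files)
  m <- read_manifest(man)
  expect_equal(vapply(m$subjects, `[[`, "", "genotype"), c("WT", "KI"))

  # same seed twice: byte-identical hypnograms
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, d2)
  h1 <- readLines(file.path(d1, "WT_01_hypnogram.tsv"))
  h2 <- readLines(file.path(d2, "WT_01_hypnogram.tsv"))
  expect_identical(h1, h2)
  e1 <- readBin(file.path(d1, "WT_01.edf"), "raw", 1e6)
  e2 <- readBin(file.path(d2, "WT_01.edf"), "raw", 1e6)
  expect_identical(e1, e2)
})

test_that("48-h hypnograms reach every state in every 3-h bin", {
  cfg <- sim_config(sampling_rate_hz = 128, seed = 77)
  ok <- TRUE
  for (k in 1:4) {
    hyp <- generate_hypnogram(cfg, seed = 1000 + k)
    zt_bin <- floor(((seq_along(hyp) - 1) * 4 / 3600) %% 24 / 3)
    tab <- table(zt_bin, unclass(hyp))
    ok <- ok && all(tab > 0)
  }
  expect_true(ok)
})

test_that("subject signal generation is sample-identical under a fixed seed", {
  cfg <- sim_config(sampling_rate_hz = 128, duration_h = 0.5, seed = 1)
  gen <- function() {
    set.seed(202)
    sleepspectr:::simulate_subject_recording(
      cfg, state_spectral_model(), NULL, transition_model(),
      artifact_model(), 0.05)
  }
  a <- gen(); b <- gen()
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(unclass(a$hypnogram), unclass(b$hypnogram))
  expect_identical(a$artifact_epochs, b$artifact_epochs)
})

test_that("state-conditional spectra peak in the configured bands", {
  cfg <- sim_config(sampling_rate_hz = 128, duration_h = 1, seed = 8)
  set.seed(303)
  s <- sleepspectr:::simulate_subject_recording(
    cfg, state_spectral_model(), NULL, transition_model(),
    artifact_model(rate = 0), 0.05)
  x <- apply_filters(derive_bipolar(s$recording), 128)
  es <- normalize_spectra(epoch_power_spectrum(x, 128, 4))
  nr <- state_spectral_profile(es, s$hypnogram, "NR")
  expect_true(which.max(nr) <= 4)           # NREM peaks in delta
  r <- state_spectral_profile(es, s$hypnogram, "R")
  if (attr(r, "n_epochs") > 50)
    expect_true(which.max(r) %in% 6:9)      # REM peaks around theta
})
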