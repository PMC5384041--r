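test_that("bipolar derivation cancels common-mode and sums independent power", {
  set.seed(3)
  n <- 1024
  common <- rnorm(n); fr <- rnorm(n, sd = 2); pa <- rnorm(n, sd = 3)
  rec <- eeg_recording(list(EEG_F = common + fr, EEG_P = common + pa), fs = 128)
  d <- derive_bipolar(rec)
  expect_equal(d, fr - pa)
  same <- eeg_recording(list(EEG_F = common, EEG_P = common), fs = 128)
  expect_equal(derive_bipolar(same), rep(0, n))
  # independent components' variance adds
  expect_equal(var(d), var(fr) + var(pa) - 2 * cov(fr, pa))
  expect_error(derive_bipolar(rec, parietal = "EEG_X"), "EEG_X")
})

test_that("conditioning filters kill DC, pass 10 Hz, stop 60 Hz", {
  fs <- 512
  t <- seq_len(8 * fs) / fs
  dc <- rep(5, length(t))
  expect_lt(max(abs(mean(apply_filters(dc, fs)))), 1e-3 * 5)
  s10 <- sin(2 * pi * 10 * t)
  y10 <- apply_filters(s10, fs)
  mid <- seq(fs, length(t) - fs)          # ignore edge transients
  amp10 <- sqrt(2 * mean(y10[mid]^2))
  expect_lt(abs(amp10 - 1), 0.02)
  s60 <- sin(2 * pi * 60 * t)
  y60 <- apply_filters(s60, fs)
  amp60 <- sqrt(2 * mean(y60[mid]^2))
  expect_lt(amp60, 0.1)
  expect_error(apply_filters(s10, fs, filter_spec(highpass_hz = 300)),
               "Nyquist")
})

test_that("a pure on-grid sinusoid lands its power in one bin", {
  fs <- 512
  x <- sin(2 * pi * 10 * seq_len(2048) / fs)
  es <- epoch_power_spectrum(x, fs, epoch_s = 4)
  expect_equal(unname(es$power[1, 10]), 0.5, tolerance = 1e-12)
  expect_lt(sum(es$power[1, -10]), 1e-12)
  expect_equal(epoch_power_spectrum(rep(0, 2048), fs, 4)$power,
               matrix(0, 1, 56, dimnames = list(NULL, paste0("hz", 1:56))))
  expect_error(epoch_power_spectrum(rnorm(2049), fs, 4), "remainder 1")
})

test_that("binned epoch powers match a brute-force DFT oracle", {
  fs <- 512
  set.seed(21)
  x <- as.vector(replicate(3, rnorm(2048, sd = 30)))
  es <- epoch_power_spectrum(x, fs, epoch_s = 4)
  for (e in 1:3) {
    seg <- x[(e - 1) * 2048 + 1:2048]
    oracle <- brute_force_bins(seg, fs, 56)
    expect_equal(unname(es$power[e, ]), oracle, tolerance = 1e-6)
  }
})

test_that("Parseval holds for centered epochs", {
  fs <- 512
  set.seed(22)
  x <- rnorm(2048); x <- x - mean(x)
  es <- epoch_power_spectrum(x, fs, epoch_s = 4, n_bins = 256L)
  expect_equal(sum(es$power[1, ]), mean(x^2), tolerance = 1e-6)
  # bins 1-56 capture exactly the (0, 56] Hz share
  es56 <- epoch_power_spectrum(x, fs, epoch_s = 4, n_bins = 56L)
  oracle <- brute_force_bins(x, fs, 256)
  expect_equal(sum(es56$power[1, ]), sum(oracle[1:56]), tolerance = 1e-6)
})

test_that("normalization rescales to mean retained total 100", {
  set.seed(30)
  es <- spectra_from_matrix(matrix(rexp(40 * 56), 40, 56))
  ns <- normalize_spectra(es)
  expect_equal(mean(rowSums(ns$power)), 100, tolerance = 1e-9)
  # single epoch: row sums to exactly 100
  one <- normalize_spectra(spectra_from_matrix(matrix(runif(56), 1, 56)))
  expect_equal(sum(one$power), 100, tolerance = 1e-9)
  # totals T and 3T -> normalized totals 50 and 150
  two <- spectra_from_matrix(rbind(rep(1, 56), rep(3, 56)))
  nt <- rowSums(normalize_spectra(two)$power)
  expect_equal(unname(nt), c(50, 150))
  # idempotent with unchanged mask
  expect_equal(normalize_spectra(ns)$power, ns$power)
})

test_that("rejection removes the spiked epoch and respects monotonicity", {
  set.seed(31)
  p <- matrix(rgamma(200 * 56, shape = 4, rate = 4), 200, 56)
  p[57, 13] <- 900 * mean(p)   # one wild bin
  es <- spectra_from_matrix(p)
  out <- reject_artifacts(es, threshold = 300, passes = 2)
  expect_false(out$spectra$retained[57])
  expect_equal(sum(!out$spectra$retained), 1L)
  expect_equal(out$report$epochs_removed, c(1L, 0L))
  expect_equal(mean(rowSums(out$spectra$power[out$spectra$retained, ])),
               100, tolerance = 1e-9)
  # infinite threshold removes nothing
  keep <- reject_artifacts(es, threshold = Inf, passes = 2)
  expect_true(all(keep$spectra$retained))
  # higher threshold never removes more epochs
  lo <- reject_artifacts(es, threshold = 100, passes = 2)$spectra$retained
  hi <- reject_artifacts(es, threshold = 200, passes = 2)$spectra$retained
  expect_true(all(hi >= lo))
  # pass k+1 retained set is a subset of pass k
  r1 <- reject_artifacts(es, threshold = 150, passes = 1)$spectra$retained
  r2 <- reject_artifacts(es, threshold = 150, passes = 2)$spectra$retained
  expect_true(all(r1 >= r2))
})

test_that("normalized spectra and masks are scale invariant", {
  fs <- 128
  set.seed(32)
  x <- rnorm(fs * 4 * 50, sd = 20)
  a <- reject_artifacts(epoch_power_spectrum(x, fs, 4), 300, 2)
  b <- reject_artifacts(epoch_power_spectrum(3.7 * x, fs, 4), 300, 2)
  expect_equal(a$spectra$retained, b$spectra$retained)
  expect_equal(a$spectra$power, b$spectra$power, tolerance = 1e-9)
})

test_that("rejection errors when everything would be removed", {
  es <- spectra_from_matrix(matrix(1000, 3, 56))
  es$power_raw[, 1] <- c(1, 1, 1e6)  # epoch 3 dominates the mean
  expect_error(reject_artifacts(es, threshold = 1e-6, passes = 1), "every retained epoch")
})
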