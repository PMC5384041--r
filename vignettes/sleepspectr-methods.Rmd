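---
title: "Methods: spectral sleep analysis and its synthetic validation"
author: "sleepspectr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral sleep analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleepspectr)
```

# The analysis model

`sleepspectr` analyses two-group rodent sleep studies in which each animal
contributes a multi-day EEG/EMG recording scored into wakefulness (W),
NREM (NR) and REM (R) sleep on fixed 4-s epochs. The pipeline separates
cleanly into an architecture layer that consumes only the hypnogram, a
spectral layer that consumes the EEG, and a statistics layer that consumes
per-subject summaries only — group inference is always at the animal
level, never the epoch level.

## Architecture metrics

Zeitgeber time (ZT) is hours since lights-on; light phase is ZT [0, 12),
dark ZT [12, 24). Recordings covering several days are split at ZT0,
metrics are computed per day and averaged per subject (day-wise metrics on
two identical days provably equal the one-day metrics, which is tested).
Episodes are maximal runs of one state; an episode crossing the
light/dark boundary counts wholly toward its onset phase, which keeps
per-phase counts integral. No minimum episode duration is imposed by
default (`min_epochs = 1`); a merge threshold is available but brief
arousals are preserved as scored.

## Spectral layer

The bipolar signal (frontal minus parietal) is conditioned by a zero-phase
4th-order Butterworth high-pass at 0.55 Hz and a 60-Hz notch
(quality factor 12, order 2). The acquisition-software filter settings
that motivated these values name a second "band stop" at 0.45 Hz; a
high-pass at 0.55 Hz subsumes it, and the passband 1–56 Hz is untouched
either way. Zero-phase filtering uses forward-backward application with
odd-reflection padding (three time constants of the filter) so start-up
transients decay outside the data.

Each 4-s epoch is transformed with a plain rectangular-window FFT
(`fft_window = "hann"` is available). The one-sided periodogram is summed
into 1-Hz bins, bin $f$ covering $(f-1, f]$ Hz at the native 0.25-Hz
resolution, so bins 1–56 partition $(0, 56]$ Hz exactly and the total
power over all bins equals the epoch mean square (Parseval; asserted
against a brute-force $O(n^2)$ DFT in the tests).

Normalization divides every bin of every epoch by the recording's mean
total power over retained epochs (×100), so the retained epochs' totals
average exactly 100 — a fixed point of the operation, re-established after
every change of the retained set. Artifact rejection iterates (default
two passes): normalize, then drop every epoch in which *any* single 1-Hz
bin exceeds the threshold (default 300%). The first pass reads the
threshold against 1-Hz bins, like the second, which is the only reading
that makes the two passes commensurable. A final re-normalization makes
all downstream percent values refer to the analysed epoch set. Rejection
is pooled across the whole recording regardless of state or day;
normalized spectra and the rejection mask are invariant to rescaling the
raw signal, so gain differences between animals cannot influence which
epochs survive.

Band powers sum normalized bins over delta (1–4), theta (5–8), alpha
(9–12), sigma (13–15) and beta (15–30 Hz). Sigma and beta deliberately
share bin 15 — the bands are descriptive summaries, not a partition — and
a non-overlapping preset (`default_bands_nonoverlap()`, beta 16–30) is
provided. Time courses average band power per state within 3-h ZT bins,
per day, then across days; empty cells propagate as missing, never as
zero, because a zero would bias group contrasts. The within-state
normalization re-expresses each (subject, state, band) time course as a
percentage of its own mean across the day's bins, making every complete
row average exactly 100 and isolating time-of-day structure from level
differences.

## Statistics

Two-group comparisons of scalar metrics use pooled-variance two-sided
t-tests. Spectral comparisons use a split-plot repeated-measures ANOVA:
genotype between subjects, frequency bin (or ZT bin) within, subjects
nested in genotype. The between effect is tested against the
subject-within-group mean square (df $g-1$, $N-g$), the within and
interaction effects against the residual (df $w-1$ and $(g-1)(w-1)$, both
over $(N-g)(w-1)$). No sphericity correction is applied by default, and
p-values come from the F distribution. With a single within level the
design degrades, with a warning, to one-way ANOVA on subject means.
Per-bin post-hoc t-tests are Bonferroni-corrected with $m$ equal to the
number of bins tested (56 for full profiles — the most conservative
reading) and are *protected*: flags are only raised when the omnibus
genotype or interaction test is itself significant.

An independent oracle backs every statistical routine in the tests:
`aov(y ~ group * level + Error(subject))` for the split-plot decomposition
(agreement to 1e-8 relative on 100 random balanced designs), numerical
integration of the t density for p-values, and a label-permutation check
that the between-group p-value is uniform under the null.

# The synthetic-data generator

The generator exists so that every stage has ground truth: scored states,
spectral content, genotype effects and artifact positions are all known
exactly.

**Hypnograms** follow a two-phase first-order Markov chain on W/NR/R at
the epoch scale, one transition matrix per lighting phase. The defaults
give light-phase occupancy ≈ 39/50/11% (W/NR/R) and a wake-dominated dark
phase (≈ 75/20/4%) with minute-scale bouts — typical figures for
laboratory mice on a 12:12 cycle.

**EEG** is state-conditional colored noise: per state, a set of
oscillators (white noise shaped by a second-order resonator with poles at
radius $e^{-\pi\,\mathrm{bw}/f_s}$; the configured amplitude is the output
RMS, calibrated from the impulse-response energy) plus broadband noise.
Default content: NREM mixes high-amplitude 2-Hz delta with moderate
6.5-Hz theta and 13-Hz spindle-band activity; REM is regular moderate
theta (7.5 Hz); wake mixes theta with low-amplitude beta. Overall levels
keep NREM total power about twice wake — delta dominates NREM but not the
pooled total, which matters because the normalization constant would
otherwise absorb most of a delta effect. Per-state streams run the whole
recording and are blended with a 0.25-s raised-cosine crossfade at
transitions, so the signal is continuous and exactly stationary within
bouts. Two referential channels carry the signal with opposite polarity
(0.55/−0.45) plus shared slow drift and 60-Hz line noise that cancel in
the bipolar derivation, plus small independent sensor noise. EMG is
generated with state-dependent tone (W > NR > R ≈ 0) but consumed by no
analysis stage, since scoring is an input here, not a computation.

**Genotype effects** multiply oscillator amplitudes by band membership of
the center frequency, so band *power* scales with the squared multiplier
(verified by Monte-Carlo). The knock-in preset (`ki_effect_preset()`)
suppresses NREM delta (×0.75), theta (×0.73) and alpha (×0.9), raises wake
sigma/beta (×1.15), and lowers REM alpha while raising REM beta. The
multipliers and the between-subject amplitude variability (lognormal,
CV 0.05 per component) were set together so that a 7+7 cohort yields
between-genotype F statistics of the order 20–30 for NREM delta/theta —
the magnitude such studies report — rather than marginal effects;
normalized within-state band powers are among the most stable EEG
phenotypes, which is what a small inter-animal CV encodes.

**Artifacts** are Poisson-placed transients (cosine-enveloped 2.5-Hz
oscillation plus noise) added to both channels with independent jitter and
unequal opposite gains, so bipolar subtraction cannot cancel them. The
default rate (18/h) makes the two-pass 300% rule discard roughly 2% of
epochs, the fraction such recordings typically lose. Transients shorter
than an epoch are confined to one epoch (jitter included), so the
generator's artifact log is an exact ground truth for rejection.

What the generator does **not** emulate: cross-frequency coupling,
1/f-shaped broadband background, circadian drift beyond the two-phase
chain, scorer disagreement, and electrode drift. Passing tests therefore
demonstrate the correctness of the computations and the operating
characteristics of the statistics under a plausible signal model — not
that any particular biological result generalises.

# Numerical and design choices

* Units are µV and µV² throughout; percent after normalization.
* Epoch $i$ covers samples $[i\,n, (i+1)\,n)$, aligned sample-for-sample
  with hypnogram epochs; an epoch-count mismatch excludes the subject.
* The fast Gaussian streams in the generator use a dedicated compiled RNG
  (`std::mt19937_64`) seeded from the R stream, so `set.seed()` still
  makes every output bit-reproducible.
* Degenerate inputs: identical groups give F = 0 exactly (0/0 is resolved
  to 0 when the effect sum of squares is zero to rounding); a zero pooled
  variance with equal means gives t = 0, p = 1, with unequal means an
  error; all-epoch rejection and zero normalization constants are errors,
  not silent NAs.
* Rejection monotonicity (pass $k{+}1$ retains a subset of pass $k$;
  higher thresholds never remove more) and normalization idempotence are
  asserted as properties.

# Validation problem sizes

The test suite and `scripts/acceptance.R` use reduced but statistically
faithful scales, chosen once:

* spectral oracles: 2 048-sample epochs at 512 Hz against a brute-force
  DFT;
* rejection ground truth: one 1-h subject at 128 Hz with ~10 injected
  30×-RMS artifacts;
* type-I error: 1 000 null cohorts of 4+4 subjects, 6-h recordings —
  simulated at the generator's band-power summary level (Markov
  hypnograms; per-cell gamma epoch noise aggregated exactly via gamma
  additivity; lognormal subject effects) because the ANOVA's operating
  characteristics depend only on these summaries, and then run through the
  real `mixed_anova`;
* effect recovery: 20 seeded 7+7 cohorts, 3-h recordings at 128 Hz
  (~2 700 epochs/subject) through the complete signal pipeline, plus null
  cohorts confirming the protected post-hoc flags stay at zero.

# Known limitations

* The split-plot ANOVA assumes balanced complete data; unbalanced designs
  are rejected rather than approximated (no Type-III machinery).
* No sphericity correction by default; with 56 within levels the
  uncorrected interaction test is anticonservative under strong
  non-sphericity. A Greenhouse–Geisser option is a natural extension.
* Per-recording normalization couples bands: a genuine delta reduction
  inflates every other normalized band of the same animal. This is a
  property of the method itself, reproduced faithfully, and is worth
  remembering when interpreting "increases" in minor bands.
* The EDF writer emits plain EDF (16-bit, one-second records, equal
  rates); EDF+ annotations are out of scope.
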