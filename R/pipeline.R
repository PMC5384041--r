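# Cohort-level orchestration: per-subject architecture + spectral analysis,
# then the group-level statistical layer, with CSV outputs and a run log.

log_msg <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg[setdiff(names(cfg), "seed")], tf)
  unname(tools::md5sum(tf))
}

# per-subject spectral stage: bipolar -> filter -> epoch FFT -> reject/normalize
analyze_subject <- function(rec, hyp, cfg) {
  x <- derive_bipolar(rec)
  x <- apply_filters(x, rec$fs,
                     filter_spec(cfg$highpass_hz, cfg$notch_hz,
                                 order = cfg$filter_order))
  spe <- rec$fs * attr(hyp, "epoch_s")
  if (length(x) != length(hyp) * spe)
    stop("signal covers ", length(x) / spe, " epochs but hypnogram has ",
         length(hyp))
  es <- epoch_power_spectrum(x, rec$fs, attr(hyp, "epoch_s"),
                             n_bins = cfg$total_power_range[2],
                             window = cfg$fft_window)
  reject_artifacts(es, cfg$rejection_threshold_percent, cfg$rejection_passes)
}

# Full analysis over in-memory subjects.
# subjects: named list of list(recording, hypnogram, genotype).
analyze_cohort <- function(subjects, cfg, log_con = NULL) {
  hash <- config_hash(cfg)
  arch <- list(); profiles <- list(); tc_raw <- list(); tc_within <- list()
  rejection <- list(); genotype <- character(0); excluded <- list()

  for (id in names(subjects)) {
    s <- subjects[[id]]
    res <- tryCatch({
      rej <- analyze_subject(s$recording, s$hypnogram, cfg)
      es <- rej$spectra
      bp <- band_powers(es, cfg$bands)
      tc <- band_timecourse(bp, s$hypnogram, cfg$time_bin_h)
      # architecture needs whole 24-h days; optional for short recordings
      arch_s <- tryCatch(architecture_summary(s$hypnogram),
                         error = function(e) NULL)
      list(arch = arch_s,
           rej = rej$report,
           prof = lapply(stats::setNames(STATES, STATES), function(st)
             state_spectral_profile(es, s$hypnogram, st)),
           tc = tc, tcw = within_state_normalize(tc),
           frac = attr(rej$report, "overall_fraction"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[id]] <- conditionMessage(res)
      log_msg(log_con, "subject %s EXCLUDED: %s", id, conditionMessage(res))
      next
    }
    log_msg(log_con, "subject %s (%s): rejected %.2f%% of epochs",
            id, s$genotype, 100 * res$frac)
    arch[id] <- list(res$arch)   # keeps NULL placeholders for short recordings
    profiles[[id]] <- res$prof
    tc_raw[[id]] <- res$tc
    tc_within[[id]] <- res$tcw
    rejection[[id]] <- cbind(subject = id, res$rej,
                             overall_fraction = res$frac)
    genotype[id] <- s$genotype
  }
  ids <- names(profiles)
  gt <- factor(genotype[ids])

  result <- list(
    subjects = ids, genotype = gt, excluded = excluded,
    rejection = if (length(rejection))
      do.call(rbind, c(rejection, list(make.row.names = FALSE))) else NULL,
    architecture = arch, profiles = profiles,
    timecourse = tc_raw, timecourse_within = tc_within,
    config_hash = hash, seed = cfg$seed, alpha = cfg$alpha)

  enough <- nlevels(gt) == 2L && all(table(gt) >= 2L)
  if (!enough) {
    warning("analyze_cohort: fewer than 2 subjects per genotype; statistics skipped")
  } else {
    have_arch <- !vapply(arch, is.null, logical(1))
    if (length(arch) && all(have_arch))
      result$architecture_tests <- architecture_tests(arch, gt)
    result$profile_anova <- profile_anova(profiles, gt, alpha = cfg$alpha)
    result$band_anova <- band_anova(tc_raw, gt)
    result$band_anova_within <- band_anova(tc_within, gt)
  }
  class(result) <- "cohort_result"
  result
}

#' Run the full cohort analysis from a manifest
#'
#' For every subject in the manifest: architecture metrics from the
#' hypnogram; bipolar derivation, filtering and per-epoch FFT; cohort-mean
#' normalization with iterative threshold rejection; per-state 1-Hz spectral
#' profiles and band-power time courses (raw-normalized and within-state
#' percent-of-24-h-mean). Then across subjects: pooled t-tests on
#' architecture metrics, a genotype x frequency split-plot ANOVA per state
#' with protected Bonferroni per-bin post-hoc tests, and a genotype x time
#' split-plot ANOVA per state and band.
#'
#' Subjects whose signal and hypnogram disagree on the epoch count (or fail
#' any per-subject stage) are excluded with a logged reason; statistics are
#' skipped with a warning if fewer than two subjects per genotype remain.
#'
#' @param manifest_path cohort manifest (see [generate_cohort()]).
#' @param cfg a [run_config()].
#' @param out_dir output directory for CSV tables and the run log; `NULL`
#'   writes nothing.
#' @return an object of class `cohort_result` (list of result tables).
#' @export
run_analysis <- function(manifest_path, cfg = run_config(), out_dir = NULL) {
  man <- read_manifest(manifest_path)
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "run.log"), "w")
    on.exit(close(log_con))
  }
  log_msg(log_con, "run_analysis: %d subjects, config %s",
          length(man$subjects), config_hash(cfg))

  subjects <- list()
  load_errors <- list()
  for (s in man$subjects) {
    loaded <- tryCatch(list(
      recording = read_recording(file.path(man$dir, s$edf),
                                 lights_on_offset_h = man$lights_on_offset_h),
      hypnogram = read_hypnogram(file.path(man$dir, s$hypnogram),
                                 epoch_s = man$epoch_s,
                                 lights_on_offset_h = man$lights_on_offset_h),
      genotype = s$genotype), error = function(e) e)
    if (inherits(loaded, "error")) {
      load_errors[[s$id]] <- conditionMessage(loaded)
      log_msg(log_con, "subject %s EXCLUDED at load: %s",
              s$id, conditionMessage(loaded))
    } else {
      subjects[[s$id]] <- loaded
    }
  }
  result <- analyze_cohort(subjects, cfg, log_con)
  result$excluded <- c(load_errors, result$excluded)
  if (!is.null(out_dir)) write_result_csvs(result, out_dir, result$config_hash)
  result
}

# pooled t-tests, per state x phase, on architecture summaries
architecture_tests <- function(arch, gt) {
  ids <- names(arch)
  ga <- levels(gt)[1]
  rows <- list()
  for (metric in c("fraction", "count", "mean_duration_s")) {
    src <- if (metric == "fraction") "proportions" else "episodes"
    for (st in STATES) for (ph in c("light", "dark")) {
      vals <- vapply(ids, function(id) {
        df <- arch[[id]][[src]]
        df[df$state == st & df$phase == ph, metric]
      }, numeric(1))
      if (anyNA(vals)) next
      tt <- students_t(vals[gt == ga], vals[gt != ga])
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, state = st, phase = ph,
        mean_a = mean(vals[gt == ga]), mean_b = mean(vals[gt != ga]),
        t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# genotype x frequency split-plot ANOVA per state, with Bonferroni per-bin
# post-hoc t-tests protected by the omnibus genotype/interaction test
profile_anova <- function(profiles, gt, alpha = 0.05) {
  out <- list()
  for (st in STATES) {
    mat <- t(vapply(profiles, function(p) as.numeric(p[[st]]),
                    numeric(length(profiles[[1]][[st]]))))
    colnames(mat) <- names(profiles[[1]][[st]])
    keep <- stats::complete.cases(mat)
    if (sum(keep) < 4L || any(table(droplevels(gt[keep])) < 2L) ||
        length(unique(gt[keep])) < 2L) next
    fit <- mixed_anova(mat[keep, , drop = FALSE], droplevels(gt[keep]))
    tab <- fit$table
    omnibus_sig <- isTRUE(any(
      tab$p[tab$effect %in% c("group", "interaction")] < alpha, na.rm = TRUE))
    ph <- bonferroni_posthoc(mat[keep, , drop = FALSE], droplevels(gt[keep]),
                             alpha = alpha, m = ncol(mat))
    if (!omnibus_sig) ph$significant <- FALSE   # protected testing
    out[[st]] <- list(anova = fit, posthoc = ph, omnibus_sig = omnibus_sig,
                      n = sum(keep))
  }
  out
}

# genotype x time split-plot ANOVA per state x band on a time-course list;
# a single time bin degrades to one-way ANOVA on subject means
band_anova <- function(tcs, gt) {
  template <- tcs[[1]]
  rows <- list()
  for (st in unique(template$state)) for (bd in unique(template$band)) {
    nlv <- sum(template$state == st & template$band == bd)
    vals <- vapply(tcs, function(tc) {
      sel <- tc$state == st & tc$band == bd
      tc$value[sel][order(tc$zt_bin[sel])]
    }, numeric(nlv))
    mat <- if (nlv == 1L) matrix(vals, ncol = 1L) else t(vals)
    keep <- stats::complete.cases(mat)
    if (sum(keep) < 4L || length(unique(gt[keep])) < 2L ||
        any(table(droplevels(gt[keep])) < 2L)) next
    fit <- suppressWarnings(
      mixed_anova(mat[keep, , drop = FALSE], droplevels(gt[keep])))
    rows[[paste(st, bd)]] <- cbind(state = st, band = bd, fit$table,
                                   n_subjects = sum(keep))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate cohorts and measure recovery of a genotype spectral effect
#'
#' Repeatedly simulates an in-memory cohort (no EDF round trip), runs the
#' full spectral pipeline and statistics, and records per run: the
#' between-genotype p-values for each NREM band time course, and the number
#' of Bonferroni-flagged 1-Hz bins in the NREM spectral-profile comparison,
#' split into low-frequency (1-8 Hz) and other bins.
#'
#' @param n_runs number of simulated cohorts.
#' @param config a [sim_config()]; run `r` uses seed `config$seed + r - 1`.
#' @param effects genotype effect list as in [generate_cohort()].
#' @param cfg a [run_config()].
#' @param model,transitions,artifacts,subject_cv generator settings as in
#'   [generate_cohort()].
#' @return data.frame with one row per run: `seed`, per-band `p_nrem_*`
#'   columns, `flagged_low` (flagged NREM bins in 1-8 Hz), `flagged_other`,
#'   `flag_rate` (flagged fraction of all NREM bins).
#' @export
effect_recovery_sim <- function(n_runs = 20L,
                                config = sim_config(sampling_rate_hz = 128,
                                                    duration_h = 3,
                                                    n_per_group = 7L),
                                effects = list(WT = genotype_effect(),
                                               KI = ki_effect_preset()),
                                cfg = run_config(),
                                model = state_spectral_model(),
                                transitions = transition_model(),
                                artifacts = artifact_model(),
                                subject_cv = 0.05) {
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- config$seed + r - 1L
    subjects <- list()
    k <- 0L
    for (gt in names(effects)) for (i in seq_len(config$n_per_group)) {
      k <- k + 1L
      set.seed((run_seed + 7919L * k) %% .Machine$integer.max)
      subj <- simulate_subject_recording(config, model, effects[[gt]],
                                         transitions, artifacts, subject_cv,
                                         with_emg = FALSE)
      subjects[[sprintf("%s_%02d", gt, i)]] <-
        list(recording = subj$recording, hypnogram = subj$hypnogram,
             genotype = gt)
    }
    res <- suppressMessages(analyze_cohort(subjects, cfg))
    ba <- res$band_anova
    ps <- vapply(names(cfg$bands), function(bd) {
      sel <- ba$state == "NR" & ba$band == bd & ba$effect == "group"
      if (any(sel)) ba$p[sel] else NA_real_
    }, numeric(1))
    ph <- res$profile_anova[["NR"]]$posthoc
    low <- ph$significant[1:8]
    rows[[r]] <- data.frame(
      seed = run_seed, t(stats::setNames(ps, paste0("p_nrem_", names(ps)))),
      flagged_low = sum(low), flagged_other = sum(ph$significant[-(1:8)]),
      flag_rate = mean(ph$significant))
  }
  do.call(rbind, rows)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects (%s), %d excluded; config %s\n",
              length(x$subjects),
              if (length(x$subjects))
                paste(sprintf("%s n=%d", levels(x$genotype), table(x$genotype)),
                      collapse = ", ") else "none",
              length(x$excluded), x$config_hash))
  if (!is.null(x$rejection)) {
    cat(sprintf("mean rejected fraction: %.3f%%\n",
                100 * mean(x$rejection$overall_fraction[x$rejection$pass == 1])))
  }
  if (!is.null(x$band_anova)) {
    sig <- x$band_anova[x$band_anova$effect == "group" & x$band_anova$p < x$alpha, ]
    cat("significant genotype effects (band time courses):",
        if (nrow(sig)) paste(sig$state, sig$band, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

write_result_csvs <- function(result, out_dir, hash) {
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    path <- file.path(out_dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  have_arch <- vapply(result$subjects, function(id)
    !is.null(result$architecture[[id]]), logical(1))
  if (length(result$subjects) && all(have_arch)) {
    prop <- do.call(rbind, lapply(result$subjects, function(id) {
      df <- result$architecture[[id]]$proportions
      ep <- result$architecture[[id]]$episodes
      m <- merge(df, ep, by = c("state", "phase"))
      cbind(subject = id, genotype = as.character(result$genotype[id]), m)
    }))
    wr(prop, "architecture")
    hourly <- do.call(rbind, lapply(result$subjects, function(id) {
      h <- result$architecture[[id]]$hourly
      data.frame(subject = id, zt_hour = rep(0:23, 3),
                 state = rep(STATES, each = 24), fraction = as.vector(h))
    }))
    wr(hourly, "hourly_profiles")
  }
  wr(result$rejection, "rejection_report")
  if (length(result$subjects)) {
    prof <- do.call(rbind, lapply(result$subjects, function(id) {
      do.call(rbind, lapply(STATES, function(st) {
        p <- result$profiles[[id]][[st]]
        data.frame(subject = id, state = st, bin_hz = seq_along(p),
                   power = as.numeric(p), n_epochs = attr(p, "n_epochs"))
      }))
    }))
    wr(prof, "state_spectral_profiles")
    tc <- do.call(rbind, lapply(result$subjects, function(id)
      cbind(subject = id, genotype = as.character(result$genotype[id]),
            result$timecourse[[id]])))
    wr(tc, "band_timecourse")
    tcw <- do.call(rbind, lapply(result$subjects, function(id)
      cbind(subject = id, genotype = as.character(result$genotype[id]),
            result$timecourse_within[[id]])))
    wr(tcw, "band_timecourse_within_state")
  }
  wr(result$band_anova, "band_anova")
  wr(result$band_anova_within, "band_anova_within_state")
  wr(result$architecture_tests, "architecture_tests")
  if (!is.null(result$profile_anova) && length(result$profile_anova)) {
    pa <- do.call(rbind, lapply(names(result$profile_anova), function(st) {
      z <- result$profile_anova[[st]]
      cbind(state = st, z$anova$table, n_subjects = z$n)
    }))
    wr(pa, "profile_anova")
    ph <- do.call(rbind, lapply(names(result$profile_anova), function(st)
      cbind(state = st, result$profile_anova[[st]]$posthoc)))
    wr(ph, "profile_posthoc")
  }
  invisible(out_dir)
}
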