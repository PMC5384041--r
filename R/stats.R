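# Statistical layer: pooled two-sample t-tests, split-plot (one between-
# subject factor, one within-subject factor) repeated-measures ANOVA with
# subjects nested in groups, and Bonferroni-corrected post-hoc t-tests.
#
# Split-plot decomposition for balanced data (g groups of n subjects each,
# w within levels):
#   between groups      SS_G,  df g-1,     tested against subject-in-group
#   subjects in groups  SS_S,  df N-g
#   within levels       SS_W,  df w-1,     tested against residual
#   interaction         SS_GW, df (g-1)(w-1), tested against residual
#   residual            SS_E,  df (N-g)(w-1)
# No sphericity correction is applied by default.

#' Pooled-variance two-sample Student's t-test
#'
#' Two-sided, equal-variance t with `df = n_a + n_b - 2`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
students_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("students_t: each group needs n >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("students_t: non-finite values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    stop("students_t: zero pooled variance with unequal means")
  }
  t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Split-plot repeated-measures ANOVA
#'
#' One between-subject factor (e.g. genotype) and one within-subject factor
#' (e.g. frequency bin or time bin), subjects nested in groups, balanced
#' complete data.
#'
#' @param y numeric matrix, subjects x within levels; every subject must
#'   have every level.
#' @param groups factor or vector of group labels, one per row of `y`.
#' @return object of class `split_anova`: data.frame `table` with one row
#'   per effect (`group`, `within`, `interaction`): `SS`, `df1`, `df2`, `F`,
#'   `p`; plus `error` (error-term SS/df) and design metadata.
#' @export
mixed_anova <- function(y, groups) {
  y <- as.matrix(y)
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)
    stop("mixed_anova: missing cells (subject, level): ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  }
  groups <- factor(groups)
  if (length(groups) != nrow(y))
    stop("mixed_anova: one group label per subject row required")
  g <- nlevels(groups)
  if (g < 2L) stop("mixed_anova: need >= 2 groups")
  ng <- table(groups)
  if (any(ng < 2L)) stop("mixed_anova: need >= 2 subjects per group")
  if (length(unique(ng)) != 1L)
    stop("mixed_anova: unbalanced group sizes (", paste(ng, collapse = ", "), ")")
  N <- nrow(y); w <- ncol(y)

  if (w == 1L) {
    warning("mixed_anova: single within level; reducing to one-way ANOVA on subject means")
    fit <- stats::anova(stats::aov(y[, 1] ~ groups))
    scale <- max(sum(fit$`Sum Sq`), nrow(y) * mean(y)^2, .Machine$double.xmin)
    f1 <- if (fit$`Sum Sq`[1] <= 1e-12 * scale) 0 else fit$`F value`[1]
    tab <- data.frame(effect = "group", SS = fit$`Sum Sq`[1],
                      df1 = fit$Df[1], df2 = fit$Df[2],
                      F = f1,
                      p = stats::pf(f1, fit$Df[1], fit$Df[2],
                                    lower.tail = FALSE))
    return(structure(list(table = tab,
                          error = data.frame(term = "subjects_in_groups",
                                             SS = fit$`Sum Sq`[2], df = fit$Df[2]),
                          n_per_group = as.vector(ng), within_levels = 1L),
                     class = "split_anova"))
  }

  grand <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(subj_mean, groups, mean)        # mean over subjects & levels
  lvl_mean <- colMeans(y)
  cell_mean <- apply(y, 2L, function(col) tapply(col, groups, mean))  # g x w

  n <- ng[1]
  ss_group <- w * n * sum((grp_mean - grand)^2)
  ss_subj <- w * sum((subj_mean - grp_mean[groups])^2)
  ss_within <- N * sum((lvl_mean - grand)^2)
  ss_inter <- n * sum((cell_mean -
                         outer(grp_mean, rep(1, w)) -
                         outer(rep(1, g), lvl_mean) + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_group - ss_subj - ss_within - ss_inter

  df <- list(group = g - 1L, subj = N - g, within = w - 1L,
             inter = (g - 1L) * (w - 1L), resid = (N - g) * (w - 1L))
  ms_subj <- ss_subj / df$subj
  ms_resid <- ss_resid / df$resid
  Fv <- c(group = (ss_group / df$group) / ms_subj,
          within = (ss_within / df$within) / ms_resid,
          interaction = (ss_inter / df$inter) / ms_resid)
  # an effect SS that is zero to rounding is F = 0 even when the error term
  # vanishes (identical groups give 0/0 otherwise)
  tol <- 1e-12 * max(ss_total, N * w * grand^2, .Machine$double.xmin)
  Fv[c(ss_group, ss_within, ss_inter) <= tol] <- 0
  tab <- data.frame(
    effect = c("group", "within", "interaction"),
    SS = c(ss_group, ss_within, ss_inter),
    df1 = c(df$group, df$within, df$inter),
    df2 = c(df$subj, df$resid, df$resid),
    F = as.numeric(Fv),
    p = stats::pf(as.numeric(Fv),
                  c(df$group, df$within, df$inter),
                  c(df$subj, df$resid, df$resid), lower.tail = FALSE))
  structure(list(table = tab,
                 error = data.frame(term = c("subjects_in_groups", "residual"),
                                    SS = c(ss_subj, ss_resid),
                                    df = c(df$subj, df$resid)),
                 n_per_group = as.vector(ng), within_levels = w),
            class = "split_anova")
}

#' @export
print.split_anova <- function(x, ...) {
  cat(sprintf("Split-plot ANOVA (%s subjects/group, %d within level%s)\n",
              paste(x$n_per_group, collapse = "+"), x$within_levels,
              if (x$within_levels == 1L) "" else "s"))
  tab <- x$table
  tab$F <- sprintf("%.4g", tab$F)
  tab$p <- format.pval(tab$p, digits = 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected per-level post-hoc t-tests
#'
#' A pooled two-group t-test per within level; adjusted p-values are
#' `min(1, m * p)`.
#'
#' @param y subjects x within levels matrix.
#' @param groups two-level group labels per subject.
#' @param alpha significance level for flags (default 0.05).
#' @param m number of comparisons corrected for (default `ncol(y)`).
#' @return data.frame: `level`, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
bonferroni_posthoc <- function(y, groups, alpha = 0.05, m = ncol(y)) {
  y <- as.matrix(y)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("bonferroni_posthoc: exactly 2 groups required")
  if (m < 1L) stop("bonferroni_posthoc: m must be >= 1")
  ga <- groups == levels(groups)[1]
  res <- lapply(seq_len(ncol(y)), function(j) {
    tt <- students_t(y[ga, j], y[!ga, j])
    data.frame(level = if (!is.null(colnames(y))) colnames(y)[j] else as.character(j),
               t = tt$t, df = tt$df, p = tt$p,
               p_adj = min(1, m * tt$p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_adj < alpha
  out
}

#' Empirical type-I error of the between-group test under the null
#'
#' Simulates many null cohorts at the generator's summary level — Markov
#' hypnograms, gamma epoch-to-epoch band-power noise (aggregated exactly via
#' gamma additivity), lognormal subject effects, equal group means — runs
#' the split-plot ANOVA on the (subject x ZT-bin) NREM band-power table of
#' each cohort, and reports the fraction of cohorts whose between-group
#' effect has `p < alpha`.
#'
#' @param n_per_group subjects per group (default 4).
#' @param duration_h recording hours per subject (default 6).
#' @param bin_width_h ZT bin width (default 3).
#' @param epoch_s epoch length, s (default 4).
#' @param n_reps number of simulated cohorts (>= 100).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param effect_multiplier group-2 mean multiplier on band power (1 = null).
#' @param subject_cv lognormal coefficient of variation of subject effects
#'   (default 0.15).
#' @param epoch_shape gamma shape of per-epoch band-power noise (default 3).
#' @param transitions [transition_model()] used for the hypnograms.
#' @return list with `rate`, `n_reps`, `rejections`, `alpha`.
#' @export
type_i_error_sim <- function(n_per_group = 4L, duration_h = 6, bin_width_h = 3,
                             epoch_s = 4, n_reps = 1000L, alpha = 0.05,
                             seed = 1L, effect_multiplier = 1,
                             subject_cv = 0.15, epoch_shape = 3,
                             transitions = transition_model()) {
  if (n_reps < 100L) stop("type_i_error_sim: n_reps must be >= 100")
  set.seed(seed)
  n_epochs <- as.integer(duration_h * 3600 / epoch_s)
  n_bins <- as.integer(duration_h / bin_width_h)
  if (n_bins < 2L) stop("type_i_error_sim: need >= 2 ZT bins for the within factor")
  per_bin <- n_epochs %/% n_bins
  n_subj <- 2L * n_per_group
  chains <- n_subj * n_reps

  # all hypnograms at once: `chains` parallel Markov chains
  states <- simulate_markov_chains(chains, n_epochs, transitions, epoch_s)

  sdlog <- sqrt(log(1 + subject_cv^2))
  subj_eff <- stats::rlnorm(chains, -sdlog^2 / 2, sdlog)
  grp2 <- rep(rep(c(FALSE, TRUE), each = n_per_group), n_reps)
  mu <- ifelse(grp2, effect_multiplier, 1) * subj_eff

  # NREM epoch count per (chain, bin); bin-mean of k iid Gamma(a, a) noises
  # is Gamma(k a, k a), so each cell needs one draw
  bin_id <- rep(seq_len(n_bins), each = per_bin)
  rejected <- logical(n_reps)
  is_nr <- states == 2L
  counts <- matrix(0L, chains, n_bins)
  for (b in seq_len(n_bins))
    counts[, b] <- rowSums(is_nr[, bin_id == b, drop = FALSE])
  if (any(counts == 0L))
    counts[counts == 0L] <- 1L  # degenerate cell: single pseudo-epoch draw
  shp <- counts * epoch_shape
  cells <- matrix(stats::rgamma(chains * n_bins, shape = shp, rate = shp),
                  chains, n_bins) * mu

  p_between <- vapply(seq_len(n_reps), function(r) {
    rows <- (r - 1L) * n_subj + seq_len(n_subj)
    fit <- mixed_anova(cells[rows, , drop = FALSE],
                       rep(c("g1", "g2"), each = n_per_group))
    fit$table$p[fit$table$effect == "group"]
  }, numeric(1))
  rejected <- p_between < alpha
  list(rate = mean(rejected), n_reps = n_reps,
       rejections = sum(rejected), alpha = alpha)
}
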