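test_that("pooled t-test matches closed form and t.test", {
  r <- students_t(c(1, 2), c(3, 4))
  expect_equal(r$t, -2 / sqrt(0.5 * (1 / 2 + 1 / 2)), tolerance = 1e-12)
  expect_equal(r$t, -2.828427, tolerance = 1e-6)
  expect_equal(r$df, 2L)
  ref <- t.test(c(1, 2), c(3, 4), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(students_t(rep(2, 3), rep(2, 4))$p, 1)
  expect_error(students_t(rep(1, 3), rep(2, 3)), "zero pooled variance")
  expect_error(students_t(1, c(1, 2)), "n >= 2")
})

test_that("t p-value matches numerical integration of the t density", {
  set.seed(50)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(6, mean = 0.8)
    r <- students_t(a, b)
    dens <- function(x) dt(x, r$df)
    p_num <- 2 * integrate(dens, abs(r$t), Inf, rel.tol = 1e-10)$value
    expect_equal(r$p, p_num, tolerance = 1e-8)
  }
})

test_that("split-plot ANOVA matches the aov error-stratum oracle", {
  set.seed(51)
  for (i in 1:100) {
    g <- sample(2:3, 1)
    n <- sample(3:5, 1)
    w <- sample(2:6, 1)
    y <- matrix(rnorm(g * n * w), g * n, w)
    groups <- rep(letters[1:g], each = n)
    fit <- mixed_anova(y, groups)
    d <- data.frame(y = as.vector(y),
                    subj = factor(rep(seq_len(g * n), w)),
                    grp = factor(rep(groups, w)),
                    lvl = factor(rep(seq_len(w), each = g * n)))
    a <- summary(stats::aov(y ~ grp * lvl + Error(subj), data = d))
    s1 <- a[["Error: subj"]][[1]]
    s2 <- a[["Error: Within"]][[1]]
    tab <- fit$table
    expect_equal(tab$F[tab$effect == "group"], s1[["F value"]][1],
                 tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "within"], s2[["F value"]][1],
                 tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "interaction"], s2[["F value"]][2],
                 tolerance = 1e-8)
    expect_equal(tab$p[tab$effect == "group"], s1[["Pr(>F)"]][1],
                 tolerance = 1e-8)
    # SS decomposition is exhaustive
    total <- sum((y - mean(y))^2)
    expect_equal(sum(tab$SS) + sum(fit$error$SS), total, tolerance = 1e-8)
    # stated df structure
    N <- g * n
    expect_equal(tab$df1, c(g - 1L, w - 1L, (g - 1L) * (w - 1L)))
    expect_equal(tab$df2, c(N - g, (N - g) * (w - 1L), (N - g) * (w - 1L)))
  }
})

test_that("identical groups give zero between and interaction F", {
  y_half <- matrix(rnorm(12), 3, 4)
  y <- rbind(y_half, y_half)
  fit <- mixed_anova(y, rep(c("a", "b"), each = 3))
  tab <- fit$table
  expect_equal(tab$F[tab$effect == "group"], 0)
  expect_equal(tab$F[tab$effect == "interaction"], 0)
})

test_that("single within level reduces to one-way ANOVA", {
  set.seed(52)
  y <- matrix(rnorm(8), 8, 1)
  g <- rep(c("a", "b"), each = 4)
  expect_warning(fit <- mixed_anova(y, g), "one-way")
  ref <- stats::anova(stats::aov(y[, 1] ~ factor(g)))
  expect_equal(fit$table$F, ref$`F value`[1])
  expect_equal(fit$table$p, ref$`Pr(>F)`[1])
})

test_that("missing cells and degenerate designs are rejected", {
  y <- matrix(rnorm(12), 4, 3)
  y[2, 3] <- NA
  expect_error(mixed_anova(y, rep(c("a", "b"), each = 2)), "missing cells")
  expect_error(mixed_anova(matrix(rnorm(9), 3, 3), c("a", "a", "b")),
               "2 subjects per group")
  expect_error(mixed_anova(matrix(rnorm(12), 4, 3), rep("a", 4)),
               "2 groups")
})

test_that("genotype label permutation yields uniform p-values", {
  set.seed(53)
  n <- 8; w <- 4
  y <- matrix(rnorm(2 * n * w), 2 * n, w) +
    rnorm(2 * n)                 # subject random effect
  p <- replicate(400, {
    g <- sample(rep(c("a", "b"), each = n))
    fit <- mixed_anova(y, g)
    fit$table$p[fit$table$effect == "group"]
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni adjustment caps at 1 and is monotone in m", {
  y <- rbind(matrix(rnorm(10), 2, 5), matrix(rnorm(10, 3), 2, 5))
  g <- rep(c("a", "b"), each = 2)
  r5 <- bonferroni_posthoc(y, g, m = 5)
  expect_equal(r5$p_adj, pmin(1, 5 * r5$p))
  r1 <- bonferroni_posthoc(y, g, m = 1)
  expect_equal(r1$p_adj, r1$p)
  r56 <- bonferroni_posthoc(y, g, m = 56)
  expect_true(all(r56$p_adj >= r5$p_adj))
  expect_true(all(r56$p_adj <= 1))
  expect_equal(unname(pmin(1, 56 * 0.5)), 1)  # capping arithmetic
})
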