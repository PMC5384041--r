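test_that("split_days cuts whole ZT-aligned days and rejects partial ones", {
  h48 <- hypnogram(rep("W", 43200), epoch_s = 4)
  days <- split_days(h48)
  expect_length(days, 2L)
  expect_length(days[[1]], 21600L)
  h24 <- hypnogram(rep("NR", 21600), epoch_s = 4)
  expect_length(split_days(h24), 1L)
  h36 <- hypnogram(rep("W", 32400), epoch_s = 4)
  expect_error(split_days(h36), "36.000 h")
})

test_that("state proportions match construction exactly", {
  day <- toy_day(light = c(W = 5400, NR = 4320, R = 1080))
  expect_equal(state_proportions(day, "light"),
               c(W = 0.5, NR = 0.4, R = 0.1))
  allw <- hypnogram(rep("W", 21600), epoch_s = 4)
  expect_equal(state_proportions(allw, "light"), c(W = 1, NR = 0, R = 0))
  expect_equal(state_proportions(allw, "dark"), c(W = 1, NR = 0, R = 0))
  # light half NR, dark half W
  half <- hypnogram(c(rep("NR", 10800), rep("W", 10800)), epoch_s = 4)
  expect_equal(state_proportions(half, "light"), c(W = 0, NR = 1, R = 0))
  expect_equal(state_proportions(half, "dark"), c(W = 1, NR = 0, R = 0))
})

test_that("hourly profile rows are per-hour fractions summing to 1", {
  allr <- hypnogram(rep("R", 21600), epoch_s = 4)
  hp <- hourly_profile(allr)
  expect_equal(unname(hp[, "R"]), rep(1, 24))
  alt <- hypnogram(rep(c("W", "NR"), 10800), epoch_s = 4)
  hp2 <- hourly_profile(alt)
  expect_equal(unname(hp2[, "W"]), rep(0.5, 24))
  set.seed(11)
  rnd <- hypnogram(sample(c("W", "NR", "R"), 21600, replace = TRUE),
                   epoch_s = 4)
  expect_equal(unname(rowSums(hourly_profile(rnd))), rep(1, 24))
})

test_that("episode segmentation finds maximal runs", {
  h <- hypnogram(c("W", "W", "NR", "NR", "NR", "R", "W"), epoch_s = 4)
  ep <- segment_episodes(h)
  expect_equal(ep$state, c("W", "NR", "R", "W"))
  expect_equal(ep$length, c(2L, 3L, 1L, 1L))
  expect_equal(segment_episodes(hypnogram(rep("NR", 50)))$length, 50L)
})

test_that("episode count equals 1 + label changes on random hypnograms", {
  set.seed(42)
  for (i in 1:20) {
    states <- sample(c("W", "NR", "R"), 500, replace = TRUE)
    ep <- segment_episodes(hypnogram(states, epoch_s = 4))
    expect_equal(nrow(ep), 1L + sum(states[-1] != states[-500]))
    expect_equal(sum(ep$length), 500L)
  }
})

test_that("episode statistics match hand-computed values", {
  h <- hypnogram(c("W", "W", "NR", "NR", "NR", "R", "W"), epoch_s = 4)
  st <- episode_stats(segment_episodes(h), epoch_s = 4)
  get <- function(s, p, col) st[st$state == s & st$phase == p, col]
  expect_equal(get("W", "light", "count"), 2L)
  expect_equal(get("W", "light", "mean_duration_s"), 6)
  expect_equal(get("NR", "light", "count"), 1L)
  expect_equal(get("NR", "light", "mean_duration_s"), 12)
  expect_equal(get("R", "light", "count"), 1L)
  expect_equal(get("R", "light", "mean_duration_s"), 4)
  expect_equal(get("R", "dark", "count"), 0L)
  expect_true(is.na(get("R", "dark", "mean_duration_s")))
})

test_that("episode time is conserved per phase", {
  set.seed(9)
  h <- hypnogram(sample(c("W", "NR", "R"), 21600, replace = TRUE), epoch_s = 4)
  ep <- segment_episodes(h)
  st <- episode_stats(ep, epoch_s = 4)
  covered <- sum(st$count * ifelse(is.na(st$mean_duration_s), 0,
                                   st$mean_duration_s))
  expect_equal(covered, 21600 * 4)
})

test_that("relabeling states permutes architecture outputs accordingly", {
  set.seed(5)
  states <- sample(c("W", "NR", "R"), 21600, replace = TRUE,
                   prob = c(0.5, 0.35, 0.15))
  perm <- c(W = "NR", NR = "R", R = "W")
  p1 <- state_proportions(hypnogram(states, epoch_s = 4), "light")
  p2 <- state_proportions(hypnogram(unname(perm[states]), epoch_s = 4), "light")
  expect_equal(unname(p1["W"]), unname(p2["NR"]))
  expect_equal(unname(p1["NR"]), unname(p2["R"]))
  expect_equal(unname(p1["R"]), unname(p2["W"]))
})

test_that("two identical days average to the single-day metrics", {
  set.seed(13)
  day <- sample(c("W", "NR", "R"), 21600, replace = TRUE)
  one <- architecture_summary(hypnogram(day, epoch_s = 4))
  two <- architecture_summary(hypnogram(c(day, day), epoch_s = 4))
  expect_equal(two$proportions, one$proportions)
  expect_equal(two$hourly, one$hourly)
  expect_equal(two$episodes, one$episodes)
  expect_equal(two$n_days, 2L)
})

test_that("minimum episode length merges brief interruptions", {
  h <- hypnogram(c(rep("NR", 20), "W", rep("NR", 20)), epoch_s = 4)
  expect_equal(nrow(segment_episodes(h)), 3L)
  merged <- segment_episodes(h, min_epochs = 2L)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$length, 41L)
})
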