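# Simulated observers: populations, designs, scanpaths, trials, reports.

test_that("observer parameters are validated", {
  expect_error(observer_params(w_het = 1.3), "w_het")
  expect_error(observer_params(detect_radius_easy = 1, detect_radius_hard = 2))
  expect_error(observer_params(giveup_fix = 0))
  p <- observer_params(w_het = 0.25, upper_bias = 2)
  expect_equal(p$w_het_passive, 0.25)   # defaults mirror the search values
})

test_that("population sampling honours its hyperparameters", {
  pop <- sample_population(10000, population_hyperparams(w_het = c(1, 1)), seed = 1)
  w <- vapply(pop, `[[`, numeric(1), "w_het")
  se <- sqrt(1 / 12 / 10000)            # Beta(1,1) = Uniform
  expect_lt(abs(mean(w) - 0.5), 3 * se)

  pt <- sample_population(5, population_hyperparams(w_het = 0.7,
                                                    w_het_passive = 0.7,
                                                    upper_bias_passive = 1),
                          seed = 2)
  expect_true(all(vapply(pt, `[[`, numeric(1), "w_het") == 0.7))
  expect_identical(lapply(pt, `[`, c("w_het", "upper_bias")),
                   lapply(pt, `[`, c("w_het", "upper_bias")))

  expect_equal(sample_population(4, seed = 3), sample_population(4, seed = 3))
  expect_error(sample_population(3, population_hyperparams(w_het = c(-1, 2))),
               "w_het")
})

test_that("exp1 design has the stated trial structure", {
  d <- make_design("exp1", seed = 1)
  search <- d[d$phase == "search", ]
  expect_equal(nrow(search), 160)
  expect_equal(sum(!search$target_present), 80)
  expect_equal(sum(search$target_half == "easy"), 40)
  expect_equal(sum(search$target_half == "hard"), 40)
  expect_equal(table(search$block), table(rep(1:4, 40)), ignore_attr = TRUE)

  # 10 passive trials strictly precede all search trials
  expect_equal(sum(d$phase == "passive"), 10)
  expect_lt(max(which(d$phase == "passive")), min(which(d$phase == "search")))

  # different seeds permute the same trial multiset
  d2 <- make_design("exp1", seed = 2)
  key <- function(x) sort(paste(x$phase, x$condition, x$target_half))
  expect_identical(key(d), key(d2))
  expect_false(identical(d$target_half, d2$target_half))
})

test_that("exp2 design balances conditions within blocks", {
  d <- make_design("exp2", seed = 5)
  expect_equal(nrow(d), 100)
  expect_equal(unname(table(d$condition)), rep(25L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(d$block)), rep(25L, 4), ignore_attr = TRUE)
  for (b in 1:4) {
    expect_gt(length(unique(d$condition[d$block == b])), 1)
  }
  tp <- table(d$condition, d$target_present)
  expect_true(all(tp[, "TRUE"] == 12))
  expect_true(all(d$configuration[d$condition == "split_half"] %in%
                    c("hard_left", "hard_right")))
})

test_that("next_fixation follows the two-stage preference model", {
  stim <- make_split_half(hard_side = "up", seed = 1)
  centre <- list(cell = c(11, 8))

  # degenerate mixture: always the hard (upper) half
  p1 <- observer_params(w_het = 1, amp_scale = Inf)
  set.seed(2)
  for (i in 1:50) {
    fx <- next_fixation(centre, stim, p1)
    expect_lt(fx$cell[2], 8)
  }

  # w_het = 0.5, no distance penalty: P(hard half) = 0.5 within MC error
  p2 <- observer_params(w_het = 0.5, amp_scale = Inf)
  set.seed(3)
  hard <- replicate(10000, next_fixation(centre, stim, p2)$cell[2] < 8)
  expect_lt(abs(mean(hard) - 0.5), 3 * sqrt(0.25 / 10000))

  # upper_bias = 3 on a uniform-difficulty array: P(upper) = 3/4
  ustim <- make_uniform_array(grid = exp1_grid(), condition = "hard", seed = 4)
  p3 <- observer_params(w_het = 0.5, upper_bias = 3, amp_scale = Inf)
  set.seed(5)
  up <- replicate(10000, next_fixation(centre, ustim, p3)$cell[2] < 8)
  expect_lt(abs(mean(up) - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))

  # the current cell is never revisited
  set.seed(6)
  same <- replicate(200, all(next_fixation(centre, stim, p2)$cell == centre$cell))
  expect_false(any(same))
})

test_that("peripheral detection interpolates the radius in target difficulty", {
  g <- exp1_grid()
  big <- observer_params(detect_radius_easy = 100, detect_radius_hard = 0)
  s_easy <- make_split_half(grid = g, hard_side = "up", target_half = "easy", seed = 1)
  expect_true(peripheral_detect(c(1, 1), s_easy, big))     # ceiling from anywhere

  s_hard <- make_split_half(grid = g, hard_side = "up", target_half = "hard", seed = 2)
  expect_true(peripheral_detect(s_hard$target$cell, s_hard, big))
  off <- s_hard$target$cell + c(1, 0)
  expect_false(peripheral_detect(off, s_hard, big))        # chance periphery

  # d = 0.5: radius is the mean of the two radii
  s <- s_hard
  s$cell_difficulty[s$target$cell[2] + 1, s$target$cell[1] + 1] <- 0.5
  p <- observer_params(detect_radius_easy = 6, detect_radius_hard = 2)
  r_expect <- (6 + 2) / 2
  expect_true(peripheral_detect(s$target$cell + c(r_expect, 0), s, p))
  expect_false(peripheral_detect(s$target$cell + c(r_expect + 1, 0), s, p))

  expect_error(peripheral_detect(c(1, 1), make_split_half(seed = 3), p),
               "present target")
})

test_that("simulated trials respond, give up and time out correctly", {
  g <- exp1_grid()
  row_tp <- list(phase = "search", target_present = TRUE)
  row_ta <- list(phase = "search", target_present = FALSE)

  # huge detection radius: found on fixation 1, RT = one fixation duration
  stim <- make_split_half(grid = g, target_half = "easy", seed = 1)
  p <- observer_params(detect_radius_easy = 100)
  set.seed(2)
  tr <- simulate_trial(row_tp, stim, p)
  expect_equal(tr$response, "present")
  expect_true(tr$correct)
  expect_equal(nrow(tr$fixations), 1)
  expect_equal(tr$rt_ms, tr$fixations$dur_ms)

  # give-up RT matches the closed-form expectation of the duration sum
  ta_stim <- make_split_half(grid = g, seed = 3)
  p20 <- observer_params(giveup_fix = 20, fix_dur_median_ms = 250,
                         fix_dur_sigma = 0.3)
  set.seed(4)
  rts <- replicate(150, simulate_trial(row_ta, ta_stim, p20)$rt_ms)
  mu1 <- 250 * exp(0.3^2 / 2)
  sd1 <- mu1 * sqrt(exp(0.3^2) - 1)
  se <- sqrt(20) * sd1 / sqrt(150)
  expect_lt(abs(mean(rts) - 20 * mu1), 3 * se)
  expect_true(all(replicate(5, simulate_trial(row_ta, ta_stim, p20)$response) ==
                    "absent"))

  # all durations beyond the budget: timeout, incorrect, RT capped
  slow <- observer_params(fix_dur_median_ms = 1e6, fix_dur_sigma = 0)
  set.seed(5)
  tr <- simulate_trial(row_ta, ta_stim, slow)
  expect_equal(tr$response, "timeout")
  expect_false(tr$correct)
  expect_equal(tr$rt_ms, 60000)
})

test_that("passive trials fixate for the stimulus duration with no response", {
  stim <- make_split_half(seed = 6)
  p <- observer_params()
  set.seed(7)
  tr <- simulate_trial(list(phase = "passive", target_present = FALSE), stim, p)
  expect_true(is.na(tr$response))
  expect_true(is.na(tr$correct))
  expect_equal(sum(tr$fixations$dur_ms), 5000, tolerance = 1e-6)
})

test_that("fixation reports round-trip through write/read", {
  d <- make_design("exp1", seed = 1)
  p <- observer_params(w_het = 0.6, id = 7)
  report <- simulate_session(d[1:30, ], p, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_fixation_report(report, f)
  back <- read_fixation_report(f)
  attr(report, "stimuli") <- NULL
  expect_equal(back, report, tolerance = 1e-12)

  # empty report -> header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_fixation_report(report[0, ], f2)
  expect_equal(length(readLines(f2)), 1)
  expect_equal(nrow(read_fixation_report(f2)), 0)

  # recount oracle: one row per fixation over the full exp1 session
  full <- simulate_session(d, p, seed = 3)
  per_trial <- tapply(full$fix_index, full$trial, max)
  expect_equal(nrow(full), sum(per_trial))
  expect_equal(length(unique(full$trial)), 175)
  expect_equal(full$fix_index[full$trial == full$trial[1]],
               seq_len(per_trial[[as.character(full$trial[1])]]))
})

test_that("sessions are reproducible from their seed", {
  d <- make_design("exp1", seed = 9)[16:35, ]
  p <- observer_params(w_het = 0.4)
  r1 <- simulate_session(d, p, seed = 11)
  r2 <- simulate_session(d, p, seed = 11)
  expect_equal(r1, r2)
})
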