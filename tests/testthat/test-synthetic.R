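test_that("stimulus manifest has the requested split and rating bounds", {
  m <- make_stimulus_manifest(32, 32, seed = 1)
  expect_equal(nrow(m), 64)
  expect_equal(sum(m$target_present), 32)
  expect_true(all(m$clutter_rating >= 1 & m$clutter_rating <= 7))

  expect_equal(nrow(make_stimulus_manifest(0, 0, seed = 1)), 0)
  expect_error(make_stimulus_manifest(-1, 3), "non-negative")

  # Monte-Carlo check of the truncated-normal rating moments
  big <- make_stimulus_manifest(5000, 3000, seed = 2)
  expect_equal(nrow(big), 8000)
  # truncation barely moves a N(4.1, 0.3) mean within [1, 7]
  expect_equal(mean(big$clutter_rating), 4.1, tolerance = 0.01)
  expect_equal(sd(big$confidence_rating), 0.6, tolerance = 0.05)
})

test_that("largest-remainder allocation matches the enumeration oracle", {
  expect_equal(unname(largest_remainder(320, c(0.5, 0.1, 0.4))),
               c(160L, 32L, 128L))
  counts <- largest_remainder(64, c(hit = 0.5, correct_rejection = 0.1,
                                    false_alarm = 0.4))
  expect_equal(unname(counts), c(32L, 6L, 26L))

  # oracle: among all integer allocations summing to n, largest remainder
  # minimizes the total absolute deviation from n * p
  p <- c(0.5, 0.1, 0.4); n <- 64
  best <- Inf
  for (a in 0:n) for (b in 0:(n - a)) {
    alloc <- c(a, b, n - a - b)
    best <- min(best, sum(abs(alloc - n * p)))
  }
  expect_equal(sum(abs(counts - n * p)), best)

  expect_error(largest_remainder(10, c(0.5, 0.4)), "sum to 1")
})

test_that("jitter generator honours bounds and mean", {
  expect_equal(generate_jitter(1, 1, 7, 4, seed = 1), 4)
  j <- generate_jitter(10000, 1, 7, 4, seed = 2)
  expect_gte(min(j), 1)
  expect_lte(max(j), 7)
  expect_lt(abs(mean(j) - 4), 0.05)
  expect_lt(abs(sum(generate_jitter(3, 1, 7, 4, seed = 3)) - 12), 1e-4)
  expect_error(generate_jitter(5, 3, 7, 2), "infeasible")
})

test_that("trial schedules realize the printed composition and timing", {
  sch <- generate_trial_schedule(64, runs = 2, seed = 1)
  tab <- table(sch$advice_type)
  expect_equal(unname(tab[c("hit", "correct_rejection", "false_alarm")]),
               c(32L, 6L, 26L), ignore_attr = TRUE)
  # good fraction is hits + correct rejections
  expect_equal(mean(sch$advice_label == "good"), 38 / 64)
  expect_equal(unname(table(sch$run)), c(32L, 32L), ignore_attr = TRUE)

  # per-run per-type counts differ by at most 1 (even dealing)
  per_run <- table(sch$advice_type, sch$run)
  expect_true(all(abs(per_run[, 1] - per_run[, 2]) <= 1))

  # phases contiguous and non-overlapping within each trial
  for (i in c(1, 20, 64)) {
    row <- sch[i, ]
    phases <- c("fixation", "advice", "bag", "decision", "jitter1",
                "feedback", "jitter2")
    on <- sapply(phases, function(p) row[[paste0("onset_", p)]])
    du <- sapply(phases, function(p) row[[paste0("dur_", p)]])
    expect_equal(unname(on[-1]), unname(on[-7] + du[-7]))
  }

  # fits within 330 volumes at TR = 2
  expect_true(all(run_duration(sch) <= 330 * 2))

  # degenerate composition
  all_fa <- generate_trial_schedule(10, c(hit = 0, correct_rejection = 0,
                                          false_alarm = 1), runs = 1,
                                    seed = 4)
  expect_true(all(all_fa$advice_type == "false_alarm"))
  expect_true(all(all_fa$advice_label == "bad"))

  expect_error(generate_trial_schedule(64, c(hit = 0.6, correct_rejection =
                                               0.1, false_alarm = 0.4)),
               "sum to 1")
  expect_error(generate_trial_schedule(63, runs = 2), "divisible")

  # determinism
  expect_identical(generate_trial_schedule(64, runs = 2, seed = 9),
                   generate_trial_schedule(64, runs = 2, seed = 9))
})

test_that("event schedules survive a TSV round trip", {
  sch <- generate_trial_schedule(16, runs = 2, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_event_schedule(sch, path)
  back <- read_event_schedule(path)
  expect_equal(back$advice_type, sch$advice_type)
  expect_equal(back$onset_decision, sch$onset_decision, tolerance = 1e-8)
  expect_equal(back$dur_jitter1, sch$dur_jitter1, tolerance = 1e-8)
})

test_that("agent decision matrix is consistent for all advice x decision", {
  # exhaustive: accepting good advice is correct, accepting bad is not
  grid <- expand.grid(advice_type = c("hit", "correct_rejection",
                                      "false_alarm"),
                      decision = c("accept", "reject"),
                      stringsAsFactors = FALSE)
  grid$advice_label <- ifelse(grid$advice_type == "false_alarm", "bad",
                              "good")
  for (i in seq_len(nrow(grid))) {
    want <- (grid$advice_label[i] == "good") == (grid$decision[i] == "accept")
    got <- effconn:::decision_correct(grid$advice_label[i], grid$decision[i])
    expect_identical(got, want)
  }
})

test_that("agent simulation reproduces expectation and learning contrast", {
  sch <- generate_trial_schedule(64, runs = 2, seed = 6)
  p_all <- agent_params("human")
  p_all$initial_accept_prob <- 1
  p_all$disconfirmation_sensitivity <- 0
  rec <- simulate_agent_responses(sch, p_all, seed = 1)
  expect_true(all(rec$decision == "accept"))
  expect_true(all(rec$deduction %in% c(0, 0.30)))
  expect_equal(rec$correct, rec$advice_label == "good")

  # no learning, p = 0.5: binomial expectation
  p_half <- p_all
  p_half$initial_accept_prob <- 0.5
  big_sch <- generate_trial_schedule(10000, runs = 1, seed = 7)
  rec2 <- simulate_agent_responses(big_sch, p_half, seed = 2)
  expect_lt(abs(mean(rec2$decision == "accept") - 0.5), 0.02)

  # higher disconfirmation sensitivity lowers run-2 bad-advice utilization
  util_run2_bad <- function(params, seed) {
    r <- simulate_agent_responses(sch, params, seed = seed)
    cell <- r[r$run == 2 & r$advice_label == "bad", ]
    mean(cell$decision == "accept")
  }
  set.seed(3)
  hum <- mean(sapply(1:200, function(s) util_run2_bad(agent_params("human"),
                                                      s)))
  mac <- mean(sapply(1:200, function(s) util_run2_bad(agent_params("machine"),
                                                      s + 5000)))
  expect_lt(hum, mac)

  expect_error(simulate_agent_responses(sch, list(
    initial_accept_prob = 1.2, disconfirmation_sensitivity = 0,
    agent = "human", rt_meanlog = 0, rt_sdlog = 0.1)), "\\[0, 1\\]")
})
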