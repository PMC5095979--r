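make_records <- function(seed = 1, n_trials = 64) {
  sch <- generate_trial_schedule(n_trials, runs = 2, seed = seed)
  simulate_agent_responses(sch, agent_params("human"), seed = seed)
}

test_that("behavioural summary computes payout and utilization cells", {
  rec <- make_records(seed = 1)
  rec$decision <- ifelse(rec$advice_label == "good", "accept", "reject")
  rec$correct <- TRUE
  s <- summarize_behavior(rec)
  expect_equal(s$accuracy, 1)
  expect_equal(s$total_deduction, 0)
  expect_equal(s$remaining, 40)
  expect_equal(s$utilization_good_run1, 1)
  expect_equal(s$utilization_bad_run2, 0)

  # 7 errors at $0.30
  rec2 <- make_records(seed = 2)
  rec2$correct <- TRUE
  rec2$correct[1:7] <- FALSE
  s2 <- summarize_behavior(rec2)
  expect_equal(s2$total_deduction, 7 * 0.30)
  expect_equal(s2$remaining, 40 - 2.10)
  # brute-force: deduction equals the sum over records
  rec2$deduction <- ifelse(rec2$correct, 0, 0.30)
  expect_equal(s2$total_deduction, sum(rec2$deduction))

  # an empty advice x run cell is NA and flagged, not silently 0
  rec3 <- make_records(seed = 3)
  rec3 <- rec3[!(rec3$advice_label == "bad" & rec3$run == 1), ]
  s3 <- summarize_behavior(rec3)
  expect_true(is.na(s3$utilization_bad_run1))
  expect_match(attr(s3, "missing_cells"), "bad run 1")
})

test_that("one-way ANOVA matches the two-group t-test identity", {
  set.seed(22)
  g1 <- rnorm(12); g2 <- rnorm(12, 0.5)
  tab <- oneway_anova(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(tab$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(tab$df, c(1, 22))

  tab0 <- oneway_anova(list(rep(2, 5), rep(2, 6)))
  expect_equal(tab0$F[1], 0)  # no variability anywhere

  expect_error(oneway_anova(list(g1)), "at least 2 groups")
  expect_error(oneway_anova(list(g1, 1)), "at least 2 observations")
})

test_that("mixed ANOVA reproduces hand-computed sums of squares", {
  # 4-subject toy, 2 groups x 2 x 2 within, values chosen for hand checking
  toy <- expand.grid(subject = 1:4, advice = c("good", "bad"),
                     time = c("run1", "run2"))
  toy$agent <- ifelse(toy$subject <= 2, "human", "machine")
  # pure between-group shift of +2 for machine, no within effects
  base <- c(1, 2, 3, 4)  # subject intercepts
  toy$value <- base[toy$subject] + ifelse(toy$agent == "machine", 2, 0)
  tab <- mixed_anova(toy, within = c("advice", "time"), between = "agent")
  get <- function(eff) tab[tab$effect == eff, ]
  # between main effect: 16 obs, group means differ by 3 (intercepts+shift)
  gm <- tapply(toy$value, toy$agent, mean)
  ss_between_hand <- 8 * sum((gm - mean(toy$value))^2)
  expect_equal(get("agent")$sum_sq, ss_between_hand, tolerance = 1e-10)
  # all within effects carry zero variability
  for (eff in c("advice", "time", "advice x time", "advice x agent",
                "time x agent", "advice x time x agent"))
    expect_equal(get(eff)$sum_sq, 0, tolerance = 1e-10)
  expect_equal(get("agent")$df, 1)

  # sums of squares additivity against the total on random data
  set.seed(23)
  toy$value <- rnorm(16)
  tab2 <- mixed_anova(toy, within = c("advice", "time"), between = "agent")
  total_ss <- sum((toy$value - mean(toy$value))^2)
  expect_equal(sum(tab2$sum_sq), total_ss, tolerance = 1e-10)

  # missing cells are rejected
  expect_error(mixed_anova(toy[-1, ], within = c("advice", "time"),
                           between = "agent"), "balanced")
})

test_that("collapsing the between factor gives the pure repeated-measures fit", {
  set.seed(24)
  d <- expand.grid(subject = 1:8, advice = c("good", "bad"),
                   time = c("run1", "run2"))
  d$agent <- "human"
  d$value <- rnorm(32)
  tab <- mixed_anova(d, within = c("advice", "time"), between = "agent")
  # oracle: aov on the same design without a between factor
  fit <- stats::aov(value ~ advice * time +
                      Error(factor(subject) / (advice * time)), data = d)
  s <- summary(fit)
  f_adv <- s[["Error: factor(subject):advice"]][[1]][["F value"]][1]
  expect_equal(tab$F[tab$effect == "advice"], f_adv, tolerance = 1e-10)
})

test_that("t-test wrapper covers the three kinds with exact df", {
  x <- c(61, 62, 63)
  one <- ttests(x, 62, kind = "one_sample")
  expect_equal(one$t, 0)
  expect_equal(one$df, 2)
  expect_equal(one$p, 1)

  pr <- ttests(x, x, kind = "paired")
  expect_equal(pr$t, 0); expect_equal(pr$p, 1)

  # hand computation on a 3-subject toy
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  got <- ttests(a, b, kind = "independent")
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 4)

  expect_error(ttests(rep(1, 5), 2, kind = "one_sample"), "zero variance")
  expect_error(ttests(rep(1, 4), rep(2, 4), kind = "independent"),
               "zero variance")
  one_sided <- ttests(c(1, 2, 3), 4, kind = "one_sample",
                      alternative = "less")
  expect_lt(one_sided$p, ttests(c(1, 2, 3), 4, kind = "one_sample")$p)
})

test_that("distributional diagnostics are advisory and well-formed", {
  set.seed(25)
  d <- behavior_diagnostics(list(rnorm(30), rnorm(30, 1)))
  expect_equal(nrow(d), 3)
  expect_true(all(d$p >= 0 & d$p <= 1))
})
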