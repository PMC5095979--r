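make_fit <- function(T_ = 300, n = 3, seed = 1) {
  A <- hub_network_matrix(n, 1, 0.4, 0.3)
  x <- sim_var1(A, T_, seed = seed)
  dmvar(x)
}

test_that("aggregation selects exactly the labelled time points", {
  fit <- make_fit()
  T_ <- nrow(fit$coef) + 1
  lab_all <- rep("bad", T_)
  pw <- aggregate_condition_weights(fit, lab_all, "bad")
  expect_length(pw$samples[[1]], T_ - 1)     # full selection
  expect_equal(length(pw$samples), 6)        # 3 x 2 directed edges
  expect_false(any(grepl("^(R1->R1|R2->R2|R3->R3)$", names(pw$samples))))

  # two disjoint conditions partition the samples
  lab2 <- rep(c("good", "bad"), length.out = T_)
  pg <- aggregate_condition_weights(fit, lab2, "good")
  pb <- aggregate_condition_weights(fit, lab2, "bad")
  expect_equal(length(pg$samples[[1]]) + length(pb$samples[[1]]), T_ - 1)

  expect_error(aggregate_condition_weights(fit, lab_all, "absent"),
               "absent")
  expect_error(aggregate_condition_weights(fit, lab_all[-1], "bad"),
               "one entry per input time point")
})

test_that("per-condition sample means recover piecewise generating values", {
  set.seed(9)
  T_ <- 4000
  x <- matrix(0, T_, 2)
  lab <- rep(rep(c("lo", "hi"), each = 200), length.out = T_)
  a_of <- c(lo = 0.1, hi = 0.6)
  for (t in 2:T_) {
    a <- a_of[[lab[t]]]
    x[t, 1] <- 0.3 * x[t - 1, 1] + rnorm(1)
    x[t, 2] <- 0.3 * x[t - 1, 2] + a * x[t - 1, 1] + rnorm(1)
  }
  fit <- dmvar(x, lambda = 0.95)
  lo <- aggregate_condition_weights(fit, lab, "lo")
  hi <- aggregate_condition_weights(fit, lab, "hi")
  k <- which(lo$edges$name == "R1->R2")
  expect_lt(abs(mean(hi$samples[[k]]) - 0.6), 0.07)
  expect_lt(abs(mean(lo$samples[[k]]) - 0.1), 0.07)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)                  # single p
  expect_equal(bh_fdr(rep(0.05, 7)), rep(0.05, 7))  # ties
  set.seed(10)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_brute_force(p))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.2, -0.1)), "\\[0, 1\\]")
})

test_that("identical groups produce no significant differences", {
  fit <- make_fit(seed = 11)
  lab <- rep("bad", nrow(fit$coef) + 1)
  a <- aggregate_condition_weights(fit, lab, "bad", group = "g1")
  b <- aggregate_condition_weights(fit, lab, "bad", group = "g2")
  cmp <- compare_path_weights(a, b)
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p == 1))
  expect_false(any(cmp$significant))
  expect_true(all(cmp$q >= cmp$p))
})

test_that("zero-variance edges are flagged and excluded from the family", {
  fit1 <- make_fit(seed = 12)
  T_ <- nrow(fit1$coef) + 1
  lab <- rep("bad", T_)
  # fabricate a zero-variance edge in both groups
  fit2 <- fit1
  fit1$coef[, 2, 1] <- 0.5
  fit2$coef[, 2, 1] <- 0.5
  a <- aggregate_condition_weights(fit1, lab, "bad")
  b <- aggregate_condition_weights(fit2, lab, "bad")
  expect_warning(cmp <- compare_path_weights(a, b), "zero variance")
  bad_row <- cmp$source == "R1" & cmp$target == "R2"
  expect_true(is.na(cmp$t[bad_row]))
  expect_false(cmp$significant[bad_row])
})

test_that("a single differing edge is detected against matched nulls", {
  # groups identical except R1 -> R2 coupling differs by 0.3
  set.seed(13)
  mk <- function(a21, seed) {
    A <- matrix(c(0.3, a21, 0, 0.3), 2, 2)
    fits <- lapply(1:8, function(s) dmvar(sim_var1(A, 400,
                                                   seed = seed + s)))
    aggregate_condition_weights(fits, rep(list(rep("c", 400)), 8), "c",
                                subjects = 1:8)
  }
  a <- mk(0.45, 100)
  b <- mk(0.15, 200)
  cmp <- compare_path_weights(a, b, method = "subject")
  expect_true(cmp$significant[cmp$source == "R1" & cmp$target == "R2"])
  # sign matches the injected direction (group a larger)
  expect_gt(cmp$t[cmp$source == "R1" & cmp$target == "R2"], 0)

  # path weights in the printed-table style: larger human mean gives t > 0
  set.seed(14)
  pi_pcc_h <- rnorm(200, 0.27, 0.1)
  pi_pcc_m <- rnorm(200, 0.18, 0.1)
  tt <- t.test(pi_pcc_h, pi_pcc_m, var.equal = TRUE)
  expect_gt(tt$statistic, 0)
})

test_that("driver summary identifies two reciprocal hubs and matches the oracle", {
  labels <- c("PI", "LaPreC", "RaPreC", "PCC", "rlPFC", "pTPJ")
  # build a comparison whose significant set is hubs-to-all (10 edges)
  fit <- dmvar(sim_var1(hub_network_matrix(6), 400, seed = 15))
  lab <- rep("bad", 400)
  a <- aggregate_condition_weights(fit, lab, "bad")
  b <- aggregate_condition_weights(fit, lab, "bad")
  cmp <- compare_path_weights(a, b)
  attr(cmp, "labels") <- labels
  lab_of <- function(idx) labels[match(idx, paste0("R", 1:6))]
  cmp$source <- lab_of(cmp$source); cmp$target <- lab_of(cmp$target)
  cmp$significant <- cmp$source %in% c("PI", "LaPreC")
  smry <- summarize_network(cmp)
  expect_setequal(smry$drivers, c("PI", "LaPreC"))
  expect_equal(unname(smry$out_degree[c("PI", "LaPreC")]), c(5L, 5L))
  expect_true(any(smry$reciprocal_pairs$node1 == "LaPreC" &
                    smry$reciprocal_pairs$node2 == "PI" |
                  smry$reciprocal_pairs$node1 == "PI" &
                    smry$reciprocal_pairs$node2 == "LaPreC"))

  # no significant edges: no drivers
  cmp$significant <- rep(FALSE, nrow(cmp))
  smry0 <- summarize_network(cmp)
  expect_length(smry0$drivers, 0)
  expect_equal(nrow(smry0$edges), 0)

  # random sparse significant sets agree with the brute-force driver check
  set.seed(16)
  for (i in 1:50) {
    cmp$significant <- runif(nrow(cmp)) < 0.3
    smry_i <- summarize_network(cmp)
    oracle <- drivers_brute_force(cmp[cmp$significant, ], labels)
    expect_setequal(smry_i$drivers, oracle)
  }
})

test_that("brainnet export writes node and edge files", {
  fit <- dmvar(sim_var1(hub_network_matrix(3, 1, 0.4), 400, seed = 17))
  lab <- rep("bad", 400)
  a <- aggregate_condition_weights(fit, lab, "bad")
  fit2 <- dmvar(sim_var1(hub_network_matrix(3, 1, 0.1), 400, seed = 18))
  b <- aggregate_condition_weights(fit2, lab, "bad")
  cmp <- compare_path_weights(a, b)
  coords <- data.frame(label = c("R1", "R2", "R3"),
                       x = c(36, -6, -3), y = c(-15, -42, -63),
                       z = c(21, 51, 15))
  prefix <- tempfile()
  paths <- write_brainnet(cmp, coords, prefix)
  expect_true(all(file.exists(paths)))
  node <- read.delim(paths[1], header = FALSE)
  expect_equal(nrow(node), 3)
  edge <- as.matrix(read.delim(paths[2], header = FALSE))
  expect_equal(dim(edge), c(3, 3))
})

test_that("behaviour-connectivity rank correlations behave as rank statistics", {
  w <- matrix(seq(0.1, 1.2, length.out = 12), ncol = 1,
              dimnames = list(NULL, "R1->R2"))
  out <- correlate_behavior_connectivity(w[, 1], w)
  expect_equal(out$rho, 1)
  out2 <- correlate_behavior_connectivity(exp(-w[, 1]), w)  # decreasing map
  expect_equal(out2$rho, -1)
  expect_error(correlate_behavior_connectivity(w[1:3, 1],
                                               w[1:3, , drop = FALSE]),
               "at least 4")

  # Monte-Carlo: bivariate normal with rank correlation ~ 0.5 at n = 12
  set.seed(19)
  r <- 2 * sin(pi * 0.5 / 6)  # Pearson rho giving Spearman 0.5
  rhos <- replicate(400, {
    z <- matrix(rnorm(24), 12, 2) %*% chol(matrix(c(1, r, r, 1), 2, 2))
    suppressWarnings(cor.test(z[, 1], z[, 2],
                              method = "spearman")$estimate)
  })
  expect_lt(abs(mean(rhos) - 0.48), 0.06)
  # at n = 12 the sampling spread is wide; the bulk stays in [0, 0.9]
  expect_gte(mean(rhos >= 0 & rhos <= 0.9), 0.9)
})
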