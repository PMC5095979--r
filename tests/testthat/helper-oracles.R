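# Independent oracles used across the suite.

# brute-force Benjamini-Hochberg step-up adjustment straight from the
# definition: q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j)
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- seq_len(m)
  q_sorted <- sapply(ranks, function(i) {
    min(pmin(1, p[ord][i:m] * m / ranks[i:m]))
  })
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# ordinary least-squares VAR(1) fit (no intercept; inputs are centred)
ols_var1 <- function(x) {
  T_ <- nrow(x)
  X <- x[1:(T_ - 1), , drop = FALSE]
  Y <- x[2:T_, , drop = FALSE]
  t(solve(crossprod(X), crossprod(X, Y)))
}

# simulate a stationary VAR(1) realization
sim_var1 <- function(A, T_, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  x <- matrix(0, T_, n)
  for (t in 2:T_) x[t, ] <- A %*% x[t - 1, ] + stats::rnorm(n, 0, sd)
  x
}

# reachability-style driver check by direct enumeration: a node is a driver
# iff it has a significant edge to every other node
drivers_brute_force <- function(edges, labels) {
  labels[vapply(labels, function(v) {
    targets <- edges$target[edges$source == v]
    all(setdiff(labels, v) %in% targets)
  }, logical(1))]
}

# boxcar-through-balloon round trip used by deconvolution tests
make_roundtrip <- function(seed, nvol = 330, TR = 2, dt = 0.1,
                           params = hemodynamic_params(),
                           noise_frac = 0.1) {
  set.seed(seed)
  sub <- TR / dt
  tt <- seq(0, by = dt, length.out = nvol * sub)
  u <- as.numeric((tt %% 20.5) < 4)  # decision-phase-like boxcar train
  y <- hemodynamic_forward(u, params, dt = dt, TR = TR)[1:nvol]
  y <- y + stats::rnorm(nvol, 0, noise_frac * stats::sd(y))
  list(y = y, u_tr = u[seq(1, length(u), by = sub)])
}
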