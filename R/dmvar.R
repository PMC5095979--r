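#' Fit a time-varying first-order multivariate autoregressive (dMVAR) model
#'
#' Estimates a VAR(1) model whose coefficient matrix is allowed to vary over
#' time, by recursive least squares with a forgetting factor: the vectorized
#' coefficients are treated as a slowly varying state and updated at every
#' time step, down-weighting past observations geometrically by `lambda`.
#' With `lambda = 1` and a stationary generating process the time-averaged
#' coefficients converge to the ordinary least-squares VAR(1) solution.
#'
#' The coefficient `a[t, i, j]` is the directed influence of channel `j` at
#' time `t - 1` on channel `i` at time `t` — a Granger path weight at that
#' time instant.
#'
#' @param x numeric matrix, time x channels (ROIs). No missing values.
#' @param order model order; only 1 is supported (neural delays of interest
#'   are below one sampling interval).
#' @param lambda forgetting factor in (0, 1]; 1 = no forgetting.
#' @param p0 initial state covariance scale of the RLS recursion.
#' @param p_max regularization bound: if the RLS covariance trace exceeds
#'   this, it is rescaled (recorded in diagnostics).
#' @return object of class `"dmvar"` with elements `coef` (array
#'   `(T-1) x n x n`), `labels`, `lambda`, `residuals`, `Sigma` (innovation
#'   covariance estimate), `fitted`, `diagnostics`, `x`.
#' @seealso [coef.dmvar()], [aggregate_condition_weights()],
#'   [granger_causality()]
#' @export
dmvar <- function(x, order = 1, lambda = 0.98, p0 = 100, p_max = 1e6) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (order != 1) stop("only order 1 is supported")
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  n <- ncol(x)
  T_ <- nrow(x)
  if (T_ <= 10 * n)
    stop("series too short: need more than 10 x n_channels time points")
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))

  A <- matrix(0, n, n)
  P <- diag(p0, n)
  coefs <- array(0, dim = c(T_ - 1, n, n),
                 dimnames = list(NULL, labels, labels))
  resid <- matrix(0, T_ - 1, n, dimnames = list(NULL, labels))
  fitted <- matrix(0, T_ - 1, n, dimnames = list(NULL, labels))
  n_regularized <- 0L
  for (t in 2:T_) {
    phi <- x[t - 1, ]
    Pphi <- P %*% phi
    denom <- lambda + sum(phi * Pphi)
    k <- Pphi / denom
    pred <- A %*% phi
    err <- x[t, ] - pred
    A <- A + tcrossprod(err, k)
    P <- (P - tcrossprod(k, Pphi)) / lambda
    P <- (P + t(P)) / 2  # enforce symmetry; drift here destabilizes RLS
    if (sum(diag(P)) > p_max) {
      P <- P * (p_max / sum(diag(P)))
      n_regularized <- n_regularized + 1L
    }
    coefs[t - 1, , ] <- A
    resid[t - 1, ] <- err
    fitted[t - 1, ] <- pred
  }
  if (n_regularized > 0)
    warning(sprintf("RLS covariance rescaled %d times (ill-conditioned update)",
                    n_regularized))
  structure(list(coef = coefs, labels = labels, lambda = lambda,
                 order = order, residuals = resid, fitted = fitted,
                 Sigma = stats::cov(resid),
                 diagnostics = list(n_regularized = n_regularized),
                 x = x),
            class = "dmvar")
}

#' Extract dMVAR coefficients
#'
#' @param object a [dmvar()] fit.
#' @param type `"mean"` for the time-averaged coefficient matrix,
#'   `"array"` for the full `(T-1) x n x n` trajectory.
#' @param ... unused.
#' @return matrix or array; `[i, j]` is the influence `j -> i`.
#' @export
coef.dmvar <- function(object, type = c("mean", "array"), ...) {
  type <- match.arg(type)
  if (type == "array") return(object$coef)
  apply(object$coef, c(2, 3), mean)
}

#' @export
print.dmvar <- function(x, ...) {
  cat(sprintf(
    "Time-varying VAR(%d) fit: %d channels, %d time points, lambda = %g\n",
    x$order, length(x$labels), nrow(x$coef) + 1, x$lambda))
  cat("Time-averaged coefficients (column -> row):\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
summary.dmvar <- function(object, ...) {
  cm <- coef(object)
  csd <- apply(object$coef, c(2, 3), stats::sd)
  structure(list(coef_mean = cm, coef_sd = csd, Sigma = object$Sigma,
                 lambda = object$lambda, n_time = nrow(object$coef),
                 labels = object$labels,
                 diagnostics = object$diagnostics),
            class = "summary.dmvar")
}

#' @export
print.summary.dmvar <- function(x, ...) {
  cat(sprintf("dMVAR summary: %d channels, %d coefficient time points\n",
              length(x$labels), x$n_time))
  cat("Time-averaged coefficients:\n"); print(round(x$coef_mean, 3))
  cat("Coefficient temporal SD:\n"); print(round(x$coef_sd, 3))
  cat("Innovation covariance:\n"); print(round(x$Sigma, 3))
  invisible(x)
}

#' @export
residuals.dmvar <- function(object, ...) object$residuals

#' @export
fitted.dmvar <- function(object, ...) object$fitted

#' One-step-ahead predictions from a dMVAR fit
#'
#' With no `newdata`, returns the in-sample one-step-ahead predictions. With
#' `newdata` (time x channels), applies the final coefficient matrix.
#'
#' @param object a [dmvar()] fit.
#' @param newdata optional matrix of new observations.
#' @param ... unused.
#' @export
predict.dmvar <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  stopifnot(is.matrix(newdata), ncol(newdata) == length(object$labels))
  A <- object$coef[dim(object$coef)[1], , ]
  out <- newdata[-nrow(newdata), , drop = FALSE] %*% t(A)
  colnames(out) <- object$labels
  out
}

#' Simulate from a fitted dMVAR model
#'
#' Generates a stationary VAR(1) series from the time-averaged coefficient
#' matrix and the innovation covariance estimate.
#'
#' @param object a [dmvar()] fit.
#' @param nsim number of time points to simulate.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @export
simulate.dmvar <- function(object, nsim = nrow(object$x), seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  A <- coef(object)
  n <- ncol(A)
  L <- chol(object$Sigma + diag(1e-12, n))
  x <- matrix(0, nsim, n, dimnames = list(NULL, object$labels))
  for (t in 2:nsim)
    x[t, ] <- A %*% x[t - 1, ] + drop(stats::rnorm(n) %*% L)
  x
}

#' @export
plot.dmvar <- function(x, edges = NULL, ...) {
  n <- length(x$labels)
  if (is.null(edges)) {
    off <- which(diag(n) == 0, arr.ind = TRUE)
    edges <- off[seq_len(min(6, nrow(off))), , drop = FALSE]
  }
  traj <- sapply(seq_len(nrow(edges)), function(k)
    x$coef[, edges[k, 1], edges[k, 2]])
  graphics::matplot(traj, type = "l", lty = 1, xlab = "time index",
                    ylab = "coefficient", ...)
  graphics::legend("topright",
                   legend = apply(edges, 1, function(e)
                     sprintf("%s → %s", x$labels[e[2]], x$labels[e[1]])),
                   col = seq_len(nrow(edges)), lty = 1, cex = 0.7,
                   bty = "n")
  invisible(x)
}

#' Static conditional Granger causality (test oracle)
#'
#' Classical conditional Granger causality by nested least squares: for each
#' directed pair `j -> i`, the full VAR regression of channel `i` on all
#' channels' lags is compared with the reduced regression excluding channel
#' `j`'s lags, via an F test. Used as an independent oracle for direction
#' detection; the time-varying model is fitted with [dmvar()].
#'
#' @param x numeric matrix, time x channels.
#' @param order VAR order.
#' @return data.frame with columns `source`, `target`, `F`, `df1`, `df2`,
#'   `p`.
#' @export
granger_causality <- function(x, order = 1) {
  stopifnot(is.matrix(x), order >= 1)
  n <- ncol(x)
  T_ <- nrow(x)
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  Teff <- T_ - order
  # lagged design matrix: [x_{t-1}, ..., x_{t-order}, 1]
  X <- do.call(cbind, lapply(seq_len(order), function(l)
    x[(order - l + 1):(T_ - l), , drop = FALSE]))
  X <- cbind(X, 1)
  Y <- x[(order + 1):T_, , drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient lagged design matrix (collinear channels?)")
  rss <- function(M, y) {
    fit <- stats::lm.fit(M, y)
    sum(fit$residuals^2)
  }
  out <- expand.grid(source = seq_len(n), target = seq_len(n))
  out <- out[out$source != out$target, ]
  df2 <- Teff - ncol(X)
  res <- lapply(seq_len(nrow(out)), function(k) {
    j <- out$source[k]; i <- out$target[k]
    drop_cols <- j + n * (seq_len(order) - 1)
    r_full <- rss(X, Y[, i])
    r_red <- rss(X[, -drop_cols, drop = FALSE], Y[, i])
    Fstat <- ((r_red - r_full) / order) / (r_full / df2)
    data.frame(source = labels[j], target = labels[i], F = Fstat,
               df1 = order, df2 = df2,
               p = stats::pf(Fstat, order, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
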