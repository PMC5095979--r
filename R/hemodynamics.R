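#' Balloon-model hemodynamic parameters
#'
#' Parameters of the balloon-type neurovascular observation model used both as
#' the forward model in simulation and as the state-space model inside the
#' blind deconvolution filter. Defaults are standard literature values.
#'
#' @param epsilon neural efficacy (dimensionless).
#' @param tau_s signal decay time constant, s.
#' @param tau_f autoregulation (feedback) time constant, s.
#' @param tau_0 mean transit time, s.
#' @param alpha vessel stiffness exponent, in (0, 1).
#' @param E0 resting oxygen extraction fraction, in (0, 1).
#' @param V0 resting blood volume fraction, in (0, 1).
#' @param obs_sd observation noise SD on the BOLD (% signal change) scale.
#' @return list of class `"hemodynamic_params"`.
#' @export
hemodynamic_params <- function(epsilon = 0.54, tau_s = 1.54, tau_f = 2.46,
                               tau_0 = 0.98, alpha = 0.33, E0 = 0.34,
                               V0 = 0.02, obs_sd = 0.01) {
  stopifnot(tau_s > 0, tau_f > 0, tau_0 > 0,
            alpha > 0, alpha < 1, E0 > 0, E0 < 1, V0 > 0, V0 < 1,
            obs_sd >= 0)
  structure(list(epsilon = epsilon, tau_s = tau_s, tau_f = tau_f,
                 tau_0 = tau_0, alpha = alpha, E0 = E0, V0 = V0,
                 obs_sd = obs_sd),
            class = "hemodynamic_params")
}

#' Draw region-variable hemodynamic parameters
#'
#' Samples `n` balloon parameter sets whose time constants (and efficacy) vary
#' lognormally around the canonical defaults, emulating spatial variability of
#' the HRF across regions.
#'
#' @param n number of parameter sets.
#' @param cv coefficient of variation of the lognormal jitter.
#' @param seed optional RNG seed.
#' @return list of `n` [hemodynamic_params()] objects.
#' @export
draw_hemodynamic_params <- function(n, cv = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- hemodynamic_params()
  sdlog <- sqrt(log(1 + cv^2))
  lapply(seq_len(n), function(i) {
    j <- function(x) x * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    hemodynamic_params(epsilon = j(base$epsilon), tau_s = j(base$tau_s),
                       tau_f = j(base$tau_f), tau_0 = j(base$tau_0),
                       alpha = base$alpha, E0 = base$E0, V0 = base$V0,
                       obs_sd = base$obs_sd)
  })
}

#' Balloon-model forward simulation of BOLD from neural input
#'
#' Integrates the hemodynamic state equations by forward Euler at step `dt`
#' and returns the BOLD signal (% signal change) sampled every `TR` seconds.
#' States: vasodilatory signal `s`, normalized flow `f`, volume `v`, and
#' deoxyhemoglobin `q`, with dynamics
#' \deqn{\dot s = \epsilon u - s/\tau_s - (f-1)/\tau_f, \quad \dot f = s,}
#' \deqn{\tau_0 \dot v = f - v^{1/\alpha}, \quad
#'       \tau_0 \dot q = f \frac{1-(1-E_0)^{1/f}}{E_0} - v^{1/\alpha} q / v,}
#' and observation
#' \deqn{y = V_0 (k_1 (1-q) + k_2 (1-q/v) + k_3 (1-v)) \times 100}
#' with \eqn{k_1 = 7 E_0}, \eqn{k_2 = 2}, \eqn{k_3 = 2 E_0 - 0.2}. A zero
#' input leaves the system at its baseline fixed point and yields exactly
#' zero output.
#'
#' @param u neural input series sampled at `dt`.
#' @param params a [hemodynamic_params()] object.
#' @param dt integration step, s (must not exceed `TR`).
#' @param TR output sampling interval, s (multiple of `dt`).
#' @return BOLD series in % signal change, sampled at `TR`, starting at t = 0.
#' @export
hemodynamic_forward <- function(u, params = hemodynamic_params(), dt = 0.1,
                                TR = 2) {
  stopifnot(inherits(params, "hemodynamic_params"), dt > 0, dt <= TR)
  sub <- round(TR / dt)
  if (abs(sub * dt - TR) > 1e-8) stop("TR must be a multiple of dt")
  N <- length(u)
  k1 <- 7 * params$E0; k2 <- 2; k3 <- 2 * params$E0 - 0.2
  # integrate f, v, q in log space: the same ODEs, discretized so the
  # positivity of flow, volume and deoxyhemoglobin is preserved exactly
  s <- 0; lf <- 0; lv <- 0; lq <- 0
  ia <- 1 / params$alpha
  out_idx <- seq(1, N, by = sub)
  y <- numeric(length(out_idx))
  oi <- 1
  for (t in seq_len(N)) {
    f <- exp(lf); v <- exp(lv); q <- exp(lq)
    if (oi <= length(out_idx) && t == out_idx[oi]) {
      y[oi] <- 100 * params$V0 *
        (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
      oi <- oi + 1
    }
    ds <- params$epsilon * u[t] - s / params$tau_s - (f - 1) / params$tau_f
    dlf <- s / f
    dlv <- (f - v^ia) / (params$tau_0 * v)
    dlq <- (f * (1 - (1 - params$E0)^(1 / f)) / params$E0 -
              v^ia * q / v) / (params$tau_0 * q)
    # saturation bounds: flow, volume and dHb stay within an order of
    # magnitude of baseline (e^2.5 ~ 12x), as vasculature cannot collapse
    # or dilate without limit; also keeps the explicit scheme stable
    s <- max(-8, min(8, s + dt * ds))
    lf <- max(-2.5, min(2.5, lf + dt * dlf))
    lv <- max(-2.5, min(2.5, lv + dt * dlv))
    lq <- max(-2.5, min(2.5, lq + dt * dlq))
    if (!is.finite(s) || !is.finite(lf) || !is.finite(lv) || !is.finite(lq))
      stop(sprintf("hemodynamic integration blew up at step %d (t = %.2f s)",
                   t, t * dt))
  }
  y
}

#' Canonical dual-gamma HRF kernel
#'
#' The canonical hemodynamic response function modelled as the difference of
#' two gamma densities (response peak minus undershoot), sampled at `dt` and
#' normalized to unit peak.
#'
#' @param dt sampling step, s.
#' @param length kernel duration, s.
#' @param peak_shape,undershoot_shape gamma shape parameters of the peak and
#'   undershoot lobes (rate 1/s each).
#' @param undershoot_ratio amplitude ratio of undershoot to peak lobe.
#' @return numeric kernel of `floor(length/dt) + 1` samples starting at t = 0.
#' @export
canonical_hrf <- function(dt, length = 32, peak_shape = 6,
                          undershoot_shape = 16, undershoot_ratio = 1 / 6) {
  stopifnot(dt > 0)
  t <- seq(0, length, by = dt)
  h <- stats::dgamma(t, shape = peak_shape, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_shape, rate = 1)
  h / max(h)
}

#' Wiener deconvolution
#'
#' Frequency-domain regularized inverse of a convolution: given
#' `y = conv(u, kernel) + noise`, returns the Wiener estimate of `u` with
#' noise-to-signal regularization `noise_ratio`. Serves as the linear
#' baseline/oracle for the nonlinear blind deconvolution filter.
#'
#' @param y observed series.
#' @param kernel convolution kernel (first sample at lag 0).
#' @param noise_ratio scalar regularizer (0 = naive inverse filter).
#' @return estimate of the latent input, same length as `y`.
#' @export
wiener_deconvolve <- function(y, kernel, noise_ratio = 0.01) {
  if (all(kernel == 0)) stop("kernel must be nonzero")
  n <- length(y)
  # zero-pad to n + kernel length so a linear convolution is not wrapped
  # around by the circular frequency-domain inverse
  m <- n + length(kernel)
  k <- c(kernel, numeric(m - length(kernel)))
  yp <- c(y, numeric(m - n))
  K <- stats::fft(k)
  Y <- stats::fft(yp)
  U <- Conj(K) * Y / (Mod(K)^2 + noise_ratio)
  Re(stats::fft(U, inverse = TRUE))[seq_len(n)] / m
}
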