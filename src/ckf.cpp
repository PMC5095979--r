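// Square-root cubature Kalman filter and RTS smoother for blind hemodynamic
// deconvolution. The augmented state holds the balloon-model hemodynamic
// states (vasodilatory signal s and log flow/volume/deoxyhemoglobin), the
// latent neural input u as a random walk, and log-transformed balloon
// parameters (epsilon, tau_s, tau_f, tau_0, alpha) as slow random walks.
// Square-root (Cholesky-factor) propagation keeps the covariance
// positive-definite by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NS = 10; // state dimension
// indices: 0 s, 1 log f, 2 log v, 3 log q, 4 u,
//          5 log eps, 6 log tau_s, 7 log tau_f, 8 log tau_0, 9 log alpha

// lower-triangular factor from QR of [A]' with positive diagonal
static mat tria(const mat& A) {
  mat Q, R;
  qr_econ(Q, R, A.t());
  mat S = R.t();
  for (uword i = 0; i < S.n_cols; ++i)
    if (S(i, i) < 0) S.col(i) *= -1.0;
  return S;
}

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// propagate one cubature point over one TR by Euler substeps; states and
// log-parameters are clamped to a physiological box so that outlying
// cubature points cannot drive the stiff balloon dynamics to overflow
static void propagate(vec& x, double dt, int nsub, double E0) {
  double s = clamp(x(0), -5.0, 5.0);
  double lf = clamp(x(1), -1.5, 1.5);
  double lv = clamp(x(2), -1.5, 1.5);
  double lq = clamp(x(3), -1.5, 1.5);
  double u = clamp(x(4), -10.0, 10.0);
  double eps = std::exp(clamp(x(5), -3.0, 1.0));
  double tau_s = std::exp(clamp(x(6), -0.5, 2.0));
  double tau_f = std::exp(clamp(x(7), -0.5, 2.0));
  double tau_0 = std::exp(clamp(x(8), -0.5, 2.0));
  double alpha = std::exp(clamp(x(9), -3.0, -0.05));
  double ia = 1.0 / alpha;
  for (int k = 0; k < nsub; ++k) {
    double f = std::exp(lf), v = std::exp(lv), q = std::exp(lq);
    double ds = eps * u - s / tau_s - (f - 1.0) / tau_f;
    double dlf = s / f;
    double dlv = (f - std::pow(v, ia)) / (tau_0 * v);
    double dlq = (f * (1.0 - std::pow(1.0 - E0, 1.0 / f)) / E0 -
                  std::pow(v, ia) * q / v) / (tau_0 * q);
    s = clamp(s + dt * ds, -5.0, 5.0);
    lf = clamp(lf + dt * dlf, -1.5, 1.5);
    lv = clamp(lv + dt * dlv, -1.5, 1.5);
    lq = clamp(lq + dt * dlq, -1.5, 1.5);
  }
  x(0) = s; x(1) = lf; x(2) = lv; x(3) = lq;
}

static double observe(const vec& x, double E0, double V0, double gain) {
  double v = std::exp(x(2)), q = std::exp(x(3));
  double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  return gain * 100.0 * V0 *
         (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
}

// [[Rcpp::export(name = ".ckf_filter_smooth")]]
Rcpp::List ckf_filter_smooth(const arma::vec& y, double TR, int nsub,
                             const arma::vec& x0, const arma::vec& P0_diag,
                             const arma::vec& Q_diag, double R_meas,
                             double E0, double V0, double gain,
                             bool smooth) {
  const int T = y.n_elem;
  const int n = NS, m = 2 * NS;
  const double dt = TR / nsub;
  const double w = 1.0 / m;        // cubature weight
  const double sq = std::sqrt((double)n);
  const double cw = std::sqrt(w);  // centering weight 1/sqrt(2n)

  mat SQ = diagmat(sqrt(Q_diag));
  double SR = std::sqrt(R_meas);

  vec xf = x0;
  mat Sf = diagmat(sqrt(P0_diag));

  // storage for smoother
  cube Xcf_store(n, m, T), Chi_store(n, m, T);
  mat xf_store(n, T), xp_store(n, T);
  cube Sp_store(n, n, T);
  mat Sf_last;
  vec innov(T), innov_var(T), u_filt(T);

  for (int t = 0; t < T; ++t) {
    // --- cubature points from filtered estimate (state at t-1) ---
    mat X(n, m);
    for (int i = 0; i < n; ++i) {
      X.col(i) = xf + sq * Sf.col(i);
      X.col(n + i) = xf - sq * Sf.col(i);
    }
    mat Xc0 = X;
    Xc0.each_col() -= xf;
    Xcf_store.slice(t) = cw * Xc0;   // centered filtered points at t-1
    xf_store.col(t) = xf;            // filtered mean at t-1 (prev step)

    // --- time update ---
    for (int i = 0; i < m; ++i) {
      vec col = X.col(i);
      propagate(col, dt, nsub, E0);
      X.col(i) = col;
    }
    if (!X.is_finite())
      Rcpp::stop("cubature point propagation diverged at step %d", t + 1);
    vec xp = mean(X, 1);
    mat Chi = X;
    Chi.each_col() -= xp;
    Chi *= cw;
    Chi_store.slice(t) = Chi;
    mat Sp = tria(join_rows(Chi, SQ));
    xp_store.col(t) = xp;
    Sp_store.slice(t) = Sp;

    // --- measurement update ---
    mat Xu(n, m);
    for (int i = 0; i < n; ++i) {
      Xu.col(i) = xp + sq * Sp.col(i);
      Xu.col(n + i) = xp - sq * Sp.col(i);
    }
    rowvec Z(m);
    for (int i = 0; i < m; ++i) Z(i) = observe(Xu.col(i), E0, V0, gain);
    double zp = mean(Z);
    rowvec Zc = cw * (Z - zp);
    mat Xuc = Xu;
    Xuc.each_col() -= xp;
    Xuc *= cw;
    // scalar measurement: S_zz from norm
    double Szz = std::sqrt(dot(Zc, Zc) + SR * SR);
    vec Pxz = Xuc * Zc.t();
    vec K = Pxz / (Szz * Szz);
    double e = y(t) - zp;
    innov(t) = e;
    innov_var(t) = Szz * Szz;
    if (!std::isfinite(Szz) || Szz * Szz > 1e6 * R_meas)
      Rcpp::stop("filter divergence (innovation variance explosion) at step %d",
                 t + 1);
    xf = xp + K * e;
    Sf = tria(join_rows(Xuc - K * Zc, K * SR));
    if (!Sf.is_finite())
      Rcpp::stop("covariance factor lost finiteness at step %d", t + 1);
    u_filt(t) = xf(4);
  }
  Sf_last = Sf;

  mat xs_store(n, T + 1);
  if (smooth) {
    // square-root cubature RTS smoother
    vec xs = xf;
    mat Ss = Sf_last;
    xs_store.col(T) = xs;
    for (int t = T - 1; t >= 0; --t) {
      const mat& Xcf = Xcf_store.slice(t);
      const mat& Chi = Chi_store.slice(t);
      const mat& Sp = Sp_store.slice(t);
      mat D = Xcf * Chi.t();
      // G = D * inv(Sp * Sp') via two triangular solves
      mat G = solve(trimatu(Sp.t()), solve(trimatl(Sp), D.t())).t();
      xs = xf_store.col(t) + G * (xs - xp_store.col(t));
      Ss = tria(join_rows(join_rows(Xcf - G * Chi, G * SQ), G * Ss));
      if (!xs.is_finite())
        Rcpp::stop("smoother diverged at step %d", t + 1);
      xs_store.col(t) = xs;
    }
  }

  // smoothed (or filtered) state trajectory aligned with observations:
  // xs_store.col(t+1) is the smoothed state at observation t
  mat states(T, n);
  vec u_out(T);
  for (int t = 0; t < T; ++t) {
    vec st = smooth ? vec(xs_store.col(t + 1)) : vec();
    if (smooth) {
      states.row(t) = st.t();
      u_out(t) = st(4);
    } else {
      u_out(t) = u_filt(t);
    }
  }
  if (!smooth) states.fill(datum::nan);

  return Rcpp::List::create(
      Rcpp::Named("u") = u_out,
      Rcpp::Named("states") = states,
      Rcpp::Named("innovation") = innov,
      Rcpp::Named("innovation_variance") = innov_var,
      Rcpp::Named("final_state") = xf,
      Rcpp::Named("final_sd") = vec(sqrt(diagvec(Sf_last * Sf_last.t()))));
}
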