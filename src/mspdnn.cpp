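#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat symm(const mat& A) { return 0.5 * (A + A.t()); }

// logm of (the symmetric part of) S; returns false when S is not PD
static bool spd_logm(const mat& S, mat& out, double& mineig) {
  vec d;
  mat U;
  if (!eig_sym(d, U, symm(S))) return false;
  mineig = d.min();
  if (mineig <= 0.0) return false;
  out = symm(U * diagmat(log(d)) * U.t());
  return true;
}

// Loewner matrix of divided differences of log at eigenvalues lam:
// K(i,j) = (log li - log lj)/(li - lj), K(i,i) = 1/li.
static mat loewner_log(const vec& lam) {
  const uword P = lam.n_elem;
  mat K(P, P);
  const double tol = 1e-12 * lam.max();
  for (uword i = 0; i < P; ++i) {
    for (uword j = 0; j <= i; ++j) {
      double v;
      if (std::abs(lam(i) - lam(j)) <= tol) {
        v = 2.0 / (lam(i) + lam(j));
      } else {
        v = (std::log(lam(i)) - std::log(lam(j))) / (lam(i) - lam(j));
      }
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  return K;
}

// weighted condition-fit loss (1/P^2) || sum_n w_n logm(V G_n V) ||_F^2
// returns NaN when any congruence is not PD
static double full_loss(const cube& G, const mat& V, const vec& wn) {
  const uword P = G.n_rows, N = G.n_slices;
  mat M(P, P, fill::zeros), L;
  double mineig;
  for (uword n = 0; n < N; ++n) {
    if (!spd_logm(V * G.slice(n) * V, L, mineig)) return datum::nan;
    M += wn(n) * L;
  }
  return accu(square(M)) / double(P * P);
}

// mSPD-NN training loop: Adam on W for the loss above, with V = (W +
// lambda I)(W + lambda I)^T. batch: per-sample steps ("stochastic") on the
// separable Frechet objective, or one full-batch step per epoch on the
// matrix-normal loss itself.
// [[Rcpp::export]]
Rcpp::List mspdnn_train_cpp(const arma::cube& G, const arma::mat& W0,
                            const arma::vec& w, double lr, double decay,
                            int decay_every, int warmup, int max_epochs,
                            double tol, double lambda, bool full_batch) {
  const uword P = G.n_rows, N = G.n_slices;
  const mat I = eye(P, P);
  mat W = W0;
  mat mAd(P, P, fill::zeros), vAd(P, P, fill::zeros);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double ts = 0.0;
  vec wn = w / accu(w);
  std::vector<double> trace;
  trace.reserve(max_epochs);
  bool converged = false;
  int fail_epoch = 0;
  double L = datum::nan, mineig;

  for (int ep = 1; ep <= max_epochs; ++ep) {
    double cur = (ep <= warmup)
      ? lr
      : lr * std::pow(decay, std::floor(double(ep - 1 - warmup) / decay_every));
    mat gW(P, P, fill::zeros);
    bool ok = true;

    if (!full_batch) {
      // per-sample loss w_n * (1/P^2) ||logm(V G_n V)||^2; these terms sum
      // to the full matrix-normal objective
      for (uword n = 0; n < N && ok; ++n) {
        mat Wt = W + lambda * I;
        mat V = symm(Wt * Wt.t());
        mat M;
        if (!spd_logm(V * G.slice(n) * V, M, mineig)) { ok = false; break; }
        mat Vi;
        if (!inv_sympd(Vi, V)) { ok = false; break; }
        mat gV = (2.0 / double(P * P)) * symm(Vi * M + M * Vi);
        gW = 2.0 * (double(N) * wn(n)) * gV * Wt;
        ts += 1.0;
        mAd = b1 * mAd + (1 - b1) * gW;
        vAd = b2 * vAd + (1 - b2) * square(gW);
        W -= cur * (mAd / (1 - std::pow(b1, ts))) /
             (sqrt(vAd / (1 - std::pow(b2, ts))) + eps);
      }
    } else {
      mat Wt = W + lambda * I;
      mat V = symm(Wt * Wt.t());
      // eigendecompositions of all congruences, weighted mean log
      std::vector<mat> Us(N);
      std::vector<vec> lams(N);
      mat Mbar(P, P, fill::zeros);
      for (uword n = 0; n < N && ok; ++n) {
        vec d;
        mat U;
        if (!eig_sym(d, U, symm(V * G.slice(n) * V)) || d.min() <= 0.0) {
          ok = false;
          break;
        }
        Us[n] = U;
        lams[n] = d;
        Mbar += wn(n) * symm(U * diagmat(log(d)) * U.t());
      }
      if (ok) {
        mat gV(P, P, fill::zeros);
        for (uword n = 0; n < N; ++n) {
          mat K = loewner_log(lams[n]);
          mat Gn = symm(Us[n] * (K % (Us[n].t() * Mbar * Us[n])) * Us[n].t());
          gV += wn(n) * (G.slice(n) * V * Gn + Gn * V * G.slice(n));
        }
        gV = (2.0 / double(P * P)) * symm(gV);
        gW = 2.0 * gV * Wt;
        ts += 1.0;
        mAd = b1 * mAd + (1 - b1) * gW;
        vAd = b2 * vAd + (1 - b2) * square(gW);
        W -= cur * (mAd / (1 - std::pow(b1, ts))) /
             (sqrt(vAd / (1 - std::pow(b2, ts))) + eps);
      }
    }

    if (!ok || !W.is_finite()) {
      fail_epoch = ep;
      break;
    }
    mat Wt = W + lambda * I;
    L = full_loss(G, symm(Wt * Wt.t()), wn);
    trace.push_back(L);
    if (!std::isfinite(L)) {
      fail_epoch = ep;
      break;
    }
    if (L < tol) {
      converged = true;
      break;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("loss_trace") = trace,
    Rcpp::Named("n_epochs") = (int)trace.size(),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("fail_epoch") = fail_epoch);
}

// condition fit (1/P^2) || mean_n w_n logm(G^{-1/2} Gamma_n G^{-1/2}) ||_F^2
// [[Rcpp::export]]
double condition_fit_cpp(const arma::cube& G, const arma::mat& Gref,
                         const arma::vec& w) {
  vec d;
  mat U;
  if (!eig_sym(d, U, symm(Gref)) || d.min() <= 0.0) {
    Rcpp::stop("reference matrix is not SPD");
  }
  mat ih = U * diagmat(1.0 / sqrt(d)) * U.t();
  const uword P = G.n_rows, N = G.n_slices;
  vec wn = w / accu(w);
  mat M(P, P, fill::zeros), L;
  double mineig;
  for (uword n = 0; n < N; ++n) {
    if (!spd_logm(ih * G.slice(n) * ih, L, mineig)) {
      Rcpp::stop("congruence of matrix %d is not positive definite "
                 "(smallest eigenvalue %g)", (int)n + 1, mineig);
    }
    M += wn(n) * L;
  }
  return accu(square(M)) / double(P * P);
}

// full-batch weighted loss and gradient at W (for quasi-Newton polish)
// [[Rcpp::export]]
Rcpp::List mspdnn_loss_grad_cpp(const arma::cube& G, const arma::mat& W,
                                const arma::vec& w, double lambda) {
  const uword P = G.n_rows, N = G.n_slices;
  vec wn = w / accu(w);
  mat Wt = W + lambda * eye(P, P);
  mat V = symm(Wt * Wt.t());
  std::vector<mat> Us(N);
  std::vector<vec> lams(N);
  mat Mbar(P, P, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    vec d;
    mat U;
    if (!eig_sym(d, U, symm(V * G.slice(n) * V)) || d.min() <= 0.0) {
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("loss") = datum::inf,
                                Rcpp::Named("grad") = mat(P, P, fill::zeros));
    }
    Us[n] = U;
    lams[n] = d;
    Mbar += wn(n) * symm(U * diagmat(log(d)) * U.t());
  }
  double L = accu(square(Mbar)) / double(P * P);
  mat gV(P, P, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    mat K = loewner_log(lams[n]);
    mat Gn = symm(Us[n] * (K % (Us[n].t() * Mbar * Us[n])) * Us[n].t());
    gV += wn(n) * (G.slice(n) * V * Gn + Gn * V * G.slice(n));
  }
  gV = (2.0 / double(P * P)) * symm(gV);
  mat gW = 2.0 * gV * Wt;
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("loss") = L,
                            Rcpp::Named("grad") = gW);
}
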