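// Core CTMC machinery for discrete-trait models on phylogenies:
// matrix exponentials and the Felsenstein pruning likelihood.
//
// Trees arrive as ape-style edge matrices already sorted in postorder
// (every child row precedes its parent's row), tips numbered 1..ntip,
// root = ntip + 1.
//
// The state count is small (2-7 here), so P(t) is assembled from the
// spectral projectors of Q: P(t) = sum_j exp(lambda_j t) V e_j V^{-1},
// precomputed once per likelihood call, with allocation-free inner loops.
// Constrained Q matrices can be defective; when the eigenvector matrix is
// ill-conditioned we fall back to scaling-and-squaring (Pade) per branch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct QCache {
  int k;
  bool use_eig;
  std::vector<std::complex<double>> eval;  // k eigenvalues
  std::vector<std::complex<double>> proj;  // k projectors, row-major k*k
  mat Q;
};

static QCache decompose_q(const mat& Q) {
  QCache d;
  d.k = Q.n_rows;
  d.Q = Q;
  d.use_eig = false;
  cx_vec eval;
  cx_mat V;
  if (eig_gen(eval, V, Q)) {
    cx_mat Vinv;
    if (inv(Vinv, V)) {
      double kappa = norm(V, 2) * norm(Vinv, 2);
      if (std::isfinite(kappa) && kappa < 1e8) {
        d.use_eig = true;
        d.eval.resize(d.k);
        d.proj.assign((size_t)d.k * d.k * d.k, {0.0, 0.0});
        for (int j = 0; j < d.k; ++j) {
          d.eval[j] = eval(j);
          for (int i = 0; i < d.k; ++i)
            for (int l = 0; l < d.k; ++l)
              d.proj[(size_t)j * d.k * d.k + (size_t)i * d.k + l] =
                V(i, j) * Vinv(j, l);
        }
      }
    }
  }
  return d;
}

// fill P (row-major, k*k) with exp(Q t); clamps rounding negatives and
// renormalises rows
static void pmat_fill(const QCache& d, double t, double* P) {
  const int k = d.k;
  if (t == 0.0) {
    for (int i = 0; i < k; ++i)
      for (int l = 0; l < k; ++l) P[i * k + l] = (i == l) ? 1.0 : 0.0;
    return;
  }
  if (d.use_eig) {
    std::complex<double> w[8];
    for (int j = 0; j < k; ++j) w[j] = std::exp(d.eval[j] * t);
    for (int i = 0; i < k; ++i)
      for (int l = 0; l < k; ++l) {
        std::complex<double> s(0.0, 0.0);
        for (int j = 0; j < k; ++j)
          s += w[j] * d.proj[(size_t)j * k * k + (size_t)i * k + l];
        P[i * k + l] = s.real();
      }
  } else {
    mat M = expmat(d.Q * t);
    for (int i = 0; i < k; ++i)
      for (int l = 0; l < k; ++l) P[i * k + l] = M(i, l);
  }
  for (int i = 0; i < k; ++i) {
    double rs = 0.0;
    for (int l = 0; l < k; ++l) {
      if (P[i * k + l] < 0) P[i * k + l] = 0;
      rs += P[i * k + l];
    }
    if (rs > 0)
      for (int l = 0; l < k; ++l) P[i * k + l] /= rs;
  }
}

// [[Rcpp::export]]
arma::mat expm_q_cpp(const arma::mat& Q, double t) {
  QCache d = decompose_q(Q);
  const int k = d.k;
  std::vector<double> buf((size_t)k * k);
  pmat_fill(d, t, buf.data());
  mat P(k, k);
  for (int i = 0; i < k; ++i)
    for (int l = 0; l < k; ++l) P(i, l) = buf[(size_t)i * k + l];
  return P;
}

// Pruning likelihood with per-node rescaling (fast path, no details).
// [[Rcpp::export]]
double mk_loglik_cpp(const arma::imat& edge, const arma::vec& elen,
                     int ntip, int nnode, const arma::mat& tipL,
                     const arma::mat& Q, const arma::vec& rootp,
                     bool fitzjohn) {
  const int k = Q.n_rows;
  const int ntot = ntip + nnode;
  const int ne = edge.n_rows;
  if (k > 8) Rcpp::stop("state spaces larger than 8 are not supported");
  QCache d = decompose_q(Q);

  std::vector<double> D((size_t)ntot * k);
  std::vector<double> logsc(ntot, 0.0);
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < k; ++s) D[(size_t)i * k + s] = tipL(s, i);
  for (int i = ntip; i < ntot; ++i)
    for (int s = 0; s < k; ++s) D[(size_t)i * k + s] = 1.0;

  double P[64], v[8];
  for (int e = 0; e < ne; ++e) {
    const int p = edge(e, 0) - 1;
    const int c = edge(e, 1) - 1;
    pmat_fill(d, elen(e), P);
    const double* Dc = &D[(size_t)c * k];
    double m = 0.0;
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int l = 0; l < k; ++l) s += P[i * k + l] * Dc[l];
      v[i] = s;
      if (s > m) m = s;
    }
    if (!(m > 0) || !std::isfinite(m)) return -datum::inf;
    double* Dp = &D[(size_t)p * k];
    for (int i = 0; i < k; ++i) Dp[i] *= v[i] / m;
    logsc[p] += logsc[c] + std::log(m);
    double mp = 0.0;
    for (int i = 0; i < k; ++i) if (Dp[i] > mp) mp = Dp[i];
    if (mp > 0 && mp < 1e-100) {
      for (int i = 0; i < k; ++i) Dp[i] /= mp;
      logsc[p] += std::log(mp);
    }
  }

  const double* Dr = &D[(size_t)ntip * k];
  double lik = 0.0;
  if (fitzjohn) {
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += Dr[i];
    if (s > 0) for (int i = 0; i < k; ++i) lik += Dr[i] / s * Dr[i];
  } else {
    for (int i = 0; i < k; ++i) lik += rootp(i) * Dr[i];
  }
  return (lik > 0) ? std::log(lik) + logsc[ntip] : -datum::inf;
}

// Full pruning pass returning the scaled partials and per-edge P(t),
// used by marginal reconstruction and stochastic mapping.
// [[Rcpp::export]]
Rcpp::List mk_pruning_cpp(const arma::imat& edge, const arma::vec& elen,
                          int ntip, int nnode, const arma::mat& tipL,
                          const arma::mat& Q, const arma::vec& rootp,
                          bool fitzjohn, bool details) {
  const int k = Q.n_rows;
  const int ntot = ntip + nnode;
  const int ne = edge.n_rows;
  if (k > 8) Rcpp::stop("state spaces larger than 8 are not supported");
  QCache d = decompose_q(Q);

  mat D(k, ntot, fill::ones);
  D.cols(0, ntip - 1) = tipL;
  vec logsc(ntot, fill::zeros);
  cube Pc;
  if (details) Pc.set_size(k, k, ne);

  double P[64];
  bool impossible = false;
  for (int e = 0; e < ne && !impossible; ++e) {
    const int p = edge(e, 0) - 1;
    const int c = edge(e, 1) - 1;
    pmat_fill(d, elen(e), P);
    if (details)
      for (int i = 0; i < k; ++i)
        for (int l = 0; l < k; ++l) Pc(i, l, e) = P[i * k + l];
    vec v(k);
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int l = 0; l < k; ++l) s += P[i * k + l] * D(l, c);
      v(i) = s;
    }
    double m = v.max();
    if (!(m > 0) || !std::isfinite(m)) { impossible = true; break; }
    v /= m;
    logsc(p) += logsc(c) + std::log(m);
    D.col(p) %= v;
    double mp = D.col(p).max();
    if (mp > 0 && mp < 1e-100) {
      D.col(p) /= mp;
      logsc(p) += std::log(mp);
    }
  }

  double loglik;
  if (impossible) {
    loglik = -datum::inf;
  } else {
    vec Dr = D.col(ntip);
    double lik;
    if (fitzjohn) {
      double s = accu(Dr);
      lik = (s > 0) ? dot(Dr / s, Dr) : 0.0;
    } else {
      lik = dot(rootp, Dr);
    }
    loglik = (lik > 0) ? std::log(lik) + logsc(ntip) : -datum::inf;
  }
  if (!details)
    return Rcpp::List::create(Rcpp::Named("loglik") = loglik);
  return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("D") = D,
                            Rcpp::Named("logsc") = logsc,
                            Rcpp::Named("P") = Pc);
}
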