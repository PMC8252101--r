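// Endpoint-conditioned history sampling (stochastic character mapping).
// Node states are drawn by a down-pass over the pruning partials; branch
// paths by uniformization. Uses R's RNG stream so results are reproducible
// under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static int draw_cat(const double* w, int k) {
  double tot = 0.0;
  for (int i = 0; i < k; ++i) tot += w[i];
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (int i = 0; i < k; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return k - 1;
}

// [[Rcpp::export]]
Rcpp::List simmap_sample_cpp(const arma::imat& edge, const arma::vec& elen,
                             int ntip, int nnode, const arma::mat& D,
                             const arma::cube& P, const arma::vec& rootw,
                             const arma::mat& Q, int nsim) {
  const int k = Q.n_rows;
  const int ne = edge.n_rows;
  const int ntot = ntip + nnode;
  if (k > 8) Rcpp::stop("state spaces larger than 8 are not supported");

  double mu = 0.0;
  for (int i = 0; i < k; ++i) mu = std::max(mu, -Q(i, i));
  mu *= 1.05;
  mat R(k, k, fill::eye);
  if (mu > 0) R += Q / mu;
  std::vector<mat> Rpow;  // Rpow[n] = R^n
  Rpow.push_back(mat(k, k, fill::eye));
  auto rp = [&](int n) -> const mat& {
    while ((int)Rpow.size() <= n) Rpow.push_back(Rpow.back() * R);
    return Rpow[n];
  };

  // child-state sampling weights: B(i,j,e) = P(i,j,e) * D(j, child(e))
  cube B(k, k, ne);
  for (int e = 0; e < ne; ++e)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        B(i, j, e) = P(i, j, e) * D(j, edge(e, 1) - 1);
  vec rootp = rootw % D.col(ntip);
  double rsum = accu(rootp);
  if (!(rsum > 0)) Rcpp::stop("zero root posterior mass");
  rootp /= rsum;

  Rcpp::List out(nsim);
  std::vector<int> st(ntot);
  std::vector<double> evbuf;  // rows of (edge, time, from, to)
  std::vector<double> times;
  std::vector<int> path;

  for (int s = 0; s < nsim; ++s) {
    evbuf.clear();
    st[ntip] = draw_cat(rootp.memptr(), k);
    for (int e = ne - 1; e >= 0; --e) {  // preorder
      const int pnode = edge(e, 0) - 1;
      const int cnode = edge(e, 1) - 1;
      const int a = st[pnode];
      double w[8];
      for (int j = 0; j < k; ++j) w[j] = B(a, j, e);
      const int b = draw_cat(w, k);
      st[cnode] = b;
      const double t = elen(e);
      // number of uniformized jumps
      int n = 0;
      if (mu > 0 && t > 0) {
        const double pab = P(a, b, e);
        const double mt = mu * t;
        const double u = unif_rand() * pab;
        double acc = 0.0;
        int cap = (int)std::ceil(mt + 10 * std::sqrt(mt) + 20);
        if (cap < 50) cap = 50;
        int m = -1;
        double lmt = std::log(mt);
        while (true) {
          ++m;
          double lw = -mt + m * lmt - std::lgamma(m + 1.0);
          acc += std::exp(lw) * rp(m)(a, b);
          if (acc >= u || m >= cap) break;
        }
        n = m;
      } else if (a != b) {
        Rcpp::stop("impossible endpoint pair on a zero-rate branch");
      }
      if (n == 0) continue;
      times.resize(n);
      for (int m = 0; m < n; ++m) times[m] = unif_rand() * t;
      std::sort(times.begin(), times.end());
      path.resize(n + 1);
      path[0] = a; path[n] = b;
      for (int m = 1; m < n; ++m) {
        double pw[8];
        const mat& Rb = rp(n - m);
        for (int x = 0; x < k; ++x) pw[x] = R(path[m - 1], x) * Rb(x, b);
        path[m] = draw_cat(pw, k);
      }
      for (int m = 1; m <= n; ++m) {
        if (path[m] != path[m - 1]) {
          evbuf.push_back(e + 1.0);
          evbuf.push_back(times[m - 1]);
          evbuf.push_back(path[m - 1] + 1.0);
          evbuf.push_back(path[m] + 1.0);
        }
      }
    }
    const int nev = evbuf.size() / 4;
    Rcpp::NumericMatrix ev(nev, 4);
    for (int r = 0; r < nev; ++r)
      for (int cidx = 0; cidx < 4; ++cidx)
        ev(r, cidx) = evbuf[(size_t)r * 4 + cidx];
    colnames(ev) = Rcpp::CharacterVector::create("edge", "time", "from",
                                                 "to");
    Rcpp::IntegerVector stv(ntot);
    for (int i = 0; i < ntot; ++i) stv[i] = st[i] + 1;
    out[s] = Rcpp::List::create(Rcpp::Named("states") = stv,
                                Rcpp::Named("events") = ev);
  }
  return out;
}
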