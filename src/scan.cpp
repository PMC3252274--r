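// Genome-wide LMM association scan under a fixed correction covariance.
//
// All computations run in the eigenbasis of the covariance K = U L U', so a
// profiled-likelihood evaluation at a given variance ratio delta costs O(N).
// The grid stage shares weighted cross-products across tests through dense
// matrix products; golden-section refinement then polishes delta per test.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ProfEval {
  double ll;
  double beta;  // SNP coefficient (alt model only)
};

// Profiled log-likelihood of y ~ N(F b, s2 (K + delta I)) from weighted
// sufficient statistics; one- or two-column design (intercept [, snp]).
inline double ll_from_rss(const double rss, const double sld, const int N,
                          const double c0) {
  const double r = rss > 1e-300 ? rss : 1e-300;
  return c0 - 0.5 * N * std::log(r / N) - 0.5 * sld;
}

// Evaluate null (intercept-only) model at arbitrary delta.
inline double null_at(const double delta, const vec& lambda, const vec& one_v,
                      const vec& y, const double c0) {
  const int N = lambda.n_elem;
  double sld = 0, a11 = 0, b1 = 0, yy = 0;
  for (int i = 0; i < N; ++i) {
    const double li = lambda[i] + delta;
    const double w = 1.0 / li;
    sld += std::log(li);
    a11 += w * one_v[i] * one_v[i];
    b1 += w * one_v[i] * y[i];
    yy += w * y[i] * y[i];
  }
  const double beta = b1 / a11;
  return ll_from_rss(yy - beta * b1, sld, N, c0);
}

// Evaluate alternative (intercept + snp) model at arbitrary delta.
inline ProfEval alt_at(const double delta, const vec& lambda, const vec& one_v,
                       const vec& g, const vec& y, const double c0) {
  const int N = lambda.n_elem;
  double sld = 0, a11 = 0, a12 = 0, a22 = 0, b1 = 0, b2 = 0, yy = 0;
  for (int i = 0; i < N; ++i) {
    const double li = lambda[i] + delta;
    const double w = 1.0 / li;
    sld += std::log(li);
    a11 += w * one_v[i] * one_v[i];
    a12 += w * one_v[i] * g[i];
    a22 += w * g[i] * g[i];
    b1 += w * one_v[i] * y[i];
    b2 += w * g[i] * y[i];
    yy += w * y[i] * y[i];
  }
  const double det = a11 * a22 - a12 * a12;
  ProfEval out;
  if (det <= 1e-12 * a11 * a22) {  // SNP collinear with intercept
    const double beta0 = b1 / a11;
    out.ll = ll_from_rss(yy - beta0 * b1, sld, N, c0);
    out.beta = 0.0;
    return out;
  }
  const double bg = (a11 * b2 - a12 * b1) / det;
  const double b0 = (a22 * b1 - a12 * b2) / det;
  out.ll = ll_from_rss(yy - b0 * b1 - bg * b2, sld, N, c0);
  out.beta = bg;
  return out;
}

// Golden-section maximisation of f over log-delta in [lo, hi].
template <typename F>
double golden(F f, double lo, double hi, const int iters, double* best_ll) {
  if (hi - lo < 1e-12) {
    *best_ll = f(std::exp(lo));
    return std::exp(lo);
  }
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c1 = b - gr * (b - a), d1 = a + gr * (b - a);
  double fc = f(std::exp(c1)), fd = f(std::exp(d1));
  for (int it = 0; it < iters; ++it) {
    if (fc > fd) {
      b = d1; d1 = c1; fd = fc;
      c1 = b - gr * (b - a);
      fc = f(std::exp(c1));
    } else {
      a = c1; c1 = d1; fc = fd;
      d1 = a + gr * (b - a);
      fd = f(std::exp(d1));
    }
  }
  if (fc > fd) { *best_ll = fc; return std::exp(c1); }
  *best_ll = fd; return std::exp(d1);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List scan_cpp(const arma::mat& Yrot, const arma::mat& Grot,
                    const arma::vec& one_rot, const arma::vec& lambda,
                    const arma::vec& grid, const int golden_iters) {
  const int N = Yrot.n_rows;
  const int G = Yrot.n_cols;
  const int P = Grot.n_cols;
  const int D = grid.n_elem;
  const double c0 = -0.5 * N * (std::log(2.0 * M_PI) + 1.0);

  // shared weighted cross-products on the delta grid
  mat W(N, D), WOne(N, D);
  vec sld(D), a11(D);
  for (int d = 0; d < D; ++d) {
    const vec li = lambda + grid[d];
    const vec w = 1.0 / li;
    W.col(d) = w;
    sld[d] = accu(log(li));
    WOne.col(d) = w % one_rot;
    a11[d] = dot(one_rot, WOne.col(d));
  }
  const mat B1 = Yrot.t() * WOne;          // G x D
  const mat YY = square(Yrot).t() * W;     // G x D
  const mat A12 = Grot.t() * WOne;         // P x D
  const mat A22 = square(Grot).t() * W;    // P x D

  // null model per gene: grid + golden refinement
  vec null_ll(G), null_delta(G);
  for (int g = 0; g < G; ++g) {
    double best = -datum::inf;
    int bi = 0;
    for (int d = 0; d < D; ++d) {
      const double beta = B1(g, d) / a11[d];
      const double ll = ll_from_rss(YY(g, d) - beta * B1(g, d), sld[d], N, c0);
      if (ll > best) { best = ll; bi = d; }
    }
    const vec y = Yrot.col(g);
    auto f = [&](double delta) { return null_at(delta, lambda, one_rot, y, c0); };
    double gll;
    const double gd = golden(f, std::log(grid[std::max(bi - 1, 0)]),
                             std::log(grid[std::min(bi + 1, D - 1)]),
                             golden_iters, &gll);
    if (gll > best) { null_ll[g] = gll; null_delta[g] = gd; }
    else { null_ll[g] = best; null_delta[g] = grid[bi]; }
  }

  // alternative model: grid stage shared via per-delta dense products
  mat best_ll(G, P);
  best_ll.fill(-datum::inf);
  Mat<int> best_d(G, P, fill::zeros);
  for (int d = 0; d < D; ++d) {
    const mat WG = Grot.each_col() % W.col(d);  // N x P
    const mat B2 = WG.t() * Yrot;               // P x G
    for (int p = 0; p < P; ++p) {
      const double a11d = a11[d], a12d = A12(p, d), a22d = A22(p, d);
      const double det = a11d * a22d - a12d * a12d;
      if (det <= 1e-12 * a11d * a22d) continue;
      for (int g = 0; g < G; ++g) {
        const double b1 = B1(g, d), b2 = B2(p, g);
        const double bg = (a11d * b2 - a12d * b1) / det;
        const double b0 = (a22d * b1 - a12d * b2) / det;
        const double ll =
            ll_from_rss(YY(g, d) - b0 * b1 - bg * b2, sld[d], N, c0);
        if (ll > best_ll(g, p)) { best_ll(g, p) = ll; best_d(g, p) = d; }
      }
    }
  }

  // per-test golden refinement + warm start at the null's optimum, then LRT
  mat lrt(G, P), beta(G, P);
  for (int p = 0; p < P; ++p) {
    const vec g_col = Grot.col(p);
    for (int g = 0; g < G; ++g) {
      const vec y = Yrot.col(g);
      const int bi = best_d(g, p);
      auto f = [&](double delta) {
        return alt_at(delta, lambda, one_rot, g_col, y, c0).ll;
      };
      double gll;
      const double gd = golden(f, std::log(grid[std::max(bi - 1, 0)]),
                               std::log(grid[std::min(bi + 1, D - 1)]),
                               golden_iters, &gll);
      double alt_best_ll = best_ll(g, p);
      double alt_best_delta = grid[bi];
      if (gll > alt_best_ll) { alt_best_ll = gll; alt_best_delta = gd; }
      const ProfEval at_null =
          alt_at(null_delta[g], lambda, one_rot, g_col, y, c0);
      if (at_null.ll > alt_best_ll) {
        alt_best_ll = at_null.ll;
        alt_best_delta = null_delta[g];
      }
      const ProfEval fin = alt_at(alt_best_delta, lambda, one_rot, g_col, y, c0);
      lrt(g, p) = std::max(2.0 * (alt_best_ll - null_ll[g]), 0.0);
      beta(g, p) = fin.beta;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("lrt") = lrt, Rcpp::Named("beta") = beta,
      Rcpp::Named("null_ll") = null_ll, Rcpp::Named("null_delta") = null_delta);
}
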