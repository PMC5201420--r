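// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Redundancy down-weighting: weight of row r = 1 / (# rows with fractional
// identity >= theta to r, including r itself). Identity is computed over all
// columns with the gap treated as an ordinary 21st symbol.
// codes: N x L integer matrix, values 0..(q-1).
// [[Rcpp::export]]
NumericVector cpp_identity_weights(const IntegerMatrix& codes, double theta) {
  const int n = codes.nrow(), L = codes.ncol();
  IntegerVector nbr(n, 1);  // self counts
  const int cutoff = (int)std::ceil(theta * L - 1e-9);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int match = 0;
      for (int c = 0; c < L; ++c)
        if (codes(a, c) == codes(b, c)) ++match;
      if (match >= cutoff) { ++nbr[a]; ++nbr[b]; }
    }
  }
  NumericVector w(n);
  for (int i = 0; i < n; ++i) w[i] = 1.0 / nbr[i];
  return w;
}

// Weighted single-column and pair counts over a q-letter alphabet.
// codes holds 1-based state indices (1..q). Returns fi (q x L) and fij
// (q*q x L*(L-1)/2; pairs i<j in row-wise upper-triangle order; within a
// pair, the state of column i varies fastest). Counts are raw weighted
// sums; pseudocounts are added in R.
// [[Rcpp::export]]
List cpp_weighted_counts(const IntegerMatrix& codes, const NumericVector& w,
                         int q) {
  const int n = codes.nrow(), L = codes.ncol();
  NumericMatrix fi(q, L);
  const int npair = L * (L - 1) / 2;
  NumericMatrix fij(q * q, npair);
  for (int r = 0; r < n; ++r) {
    const double wr = w[r];
    for (int c = 0; c < L; ++c) fi(codes(r, c) - 1, c) += wr;
    int p = 0;
    for (int i = 0; i < L; ++i) {
      const int ai = codes(r, i) - 1;
      for (int j = i + 1; j < L; ++j, ++p)
        fij(ai + q * (codes(r, j) - 1), p) += wr;
    }
  }
  return List::create(_["fi"] = fi, _["fij"] = fij);
}

// Pairwise fractional-identity distance over a column region.
// d(a,b) = 1 - matches / (# columns where either row has a residue);
// both-gap columns are unscored; pairs with zero scored columns get
// distance 1 (flagged in `nocov`). gap_code marks the gap symbol.
// [[Rcpp::export]]
List cpp_identity_distance(const IntegerMatrix& codes, int gap_code) {
  const int n = codes.nrow(), L = codes.ncol();
  NumericMatrix d(n, n);
  int nocov = 0;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int match = 0, denom = 0;
      for (int c = 0; c < L; ++c) {
        const int x = codes(a, c), y = codes(b, c);
        if (x == gap_code && y == gap_code) continue;
        ++denom;
        if (x == y) ++match;
      }
      double dist = 1.0;
      if (denom > 0) dist = 1.0 - (double)match / denom;
      else ++nocov;
      d(a, b) = dist;
      d(b, a) = dist;
    }
  }
  return List::create(_["d"] = d, _["n_no_overlap"] = nocov);
}

// Graphical lasso (Friedman block coordinate descent) for a sparse inverse
// covariance estimate. Returns the precision matrix Theta, the estimated
// covariance W, and convergence diagnostics.
// [[Rcpp::export]]
List cpp_glasso(const arma::mat& S, double rho, int max_sweeps, double tol,
                int inner_max) {
  const int p = S.n_rows;
  arma::mat W = S;
  W.diag() += rho;
  arma::mat B(p, p, arma::fill::zeros);  // B.col(j): lasso coefs for column j
  const double offmean = (p > 1)
      ? (arma::accu(arma::abs(S)) - arma::accu(arma::abs(S.diag()))) /
            ((double)p * (p - 1))
      : 1.0;
  const double wtol = tol * std::max(offmean, 1e-12);
  bool converged = false;
  int sweeps_done = 0;
  double last_delta = NA_REAL;
  std::vector<double> history;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double sumdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      arma::vec beta = B.col(j);
      beta(j) = 0.0;
      arma::vec v = W * beta;  // v(k) = sum_m W(k,m) beta(m)
      for (int it = 0; it < inner_max; ++it) {
        double del = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          const double bold = beta(k);
          const double grad = S(k, j) - (v(k) - W(k, k) * bold);
          double bnew = 0.0;
          const double t = std::abs(grad) - rho;
          if (t > 0.0) bnew = std::copysign(t, grad) / W(k, k);
          const double diff = bnew - bold;
          if (diff != 0.0) {
            v += W.col(k) * diff;
            beta(k) = bnew;
            const double ad = std::abs(diff);
            if (ad > del) del = ad;
          }
        }
        if (del < tol) break;
      }
      arma::vec w12 = v;
      w12(j) = S(j, j) + rho;
      sumdiff += arma::accu(arma::abs(w12 - W.col(j)));
      W.col(j) = w12;
      W.row(j) = w12.t();
      B.col(j) = beta;
    }
    ++sweeps_done;
    // standard glasso criterion: average absolute change of the working
    // covariance per sweep, relative to the mean off-diagonal |S|
    last_delta = sumdiff / ((double)p * p);
    history.push_back(last_delta);
    if (last_delta < wtol) { converged = true; break; }
  }
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    arma::vec beta = B.col(j);
    beta(j) = 0.0;
    const double denom = W(j, j) - arma::dot(W.col(j), beta);
    const double t22 = 1.0 / denom;
    Theta(j, j) = t22;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -beta(k) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());
  return List::create(_["theta"] = Theta, _["w"] = W,
                      _["converged"] = converged,
                      _["sweeps"] = sweeps_done, _["last_delta"] = last_delta,
                      _["tol_used"] = wtol,
                      _["delta_history"] = wrap(history));
}
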