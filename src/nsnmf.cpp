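#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative KL-divergence updates for non-smooth NMF, V ~ W * S * H
// with smoothing matrix S = (1-theta) I + (theta/k) 11'. The H update uses
// the effective basis W*S, the W update the effective coefficients S*H
// (Lee-Seung KL update form); ratios are floored at eps to guard 0/0.
// The loss trace records KL(V || W S H) after each full iteration.

static double kl_loss(const mat& V, const mat& P, const uvec& idx,
                      double vlogv, double sumV, double eps) {
  vec p = P.elem(idx);
  p.transform([eps](double x) { return x < eps ? eps : x; });
  return vlogv - accu(V.elem(idx) % log(p)) + accu(P) - sumV;
}

// [[Rcpp::export]]
Rcpp::List nsnmf_engine(const arma::mat& V, arma::mat W, arma::mat H,
                        double theta, int max_iter, double tol, double eps) {
  const uword k = W.n_cols;
  const uvec idx = find(V > 0);
  const double sumV = accu(V);
  const double vlogv = accu(V.elem(idx) % log(V.elem(idx)));

  std::vector<double> loss;
  loss.reserve(max_iter);
  bool converged = false;
  double prev = datum::inf;

  for (int it = 0; it < max_iter; ++it) {
    // effective basis A = W S  (column mixing by the smoothing matrix)
    mat A = (1.0 - theta) * W;
    A.each_col() += (theta / k) * sum(W, 1);

    mat AH = A * H;
    AH.transform([eps](double x) { return x < eps ? eps : x; });
    H %= A.t() * (V / AH);
    vec ha = sum(A, 0).t();
    ha.transform([eps](double x) { return x < eps ? eps : x; });
    H.each_col() /= ha;

    // effective coefficients B = S H
    mat B = (1.0 - theta) * H;
    B.each_row() += (theta / k) * sum(H, 0);

    mat WB = W * B;
    WB.transform([eps](double x) { return x < eps ? eps : x; });
    W %= (V / WB) * B.t();
    rowvec wb = sum(B, 1).t();
    wb.transform([eps](double x) { return x < eps ? eps : x; });
    W.each_row() /= wb;

    mat A2 = (1.0 - theta) * W;
    A2.each_col() += (theta / k) * sum(W, 1);
    double l = kl_loss(V, A2 * H, idx, vlogv, sumV, eps);
    loss.push_back(l);
    if (it > 0 &&
        std::fabs(prev - l) / std::max(std::fabs(prev), 1e-12) < tol) {
      converged = true;
      break;
    }
    prev = l;
  }

  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("loss_trace") = loss,
                            Rcpp::Named("converged") = converged);
}
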