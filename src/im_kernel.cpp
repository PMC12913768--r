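// Hot path of the IM fit: propagate the 3-state transient lineage chain
// (BOTH_IN_1, BOTH_IN_2, SPLIT) across one grid interval and return the
// per-start survival before/after, via dense matrix exponentials.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static arma::mat transient_rates(double N1, double N2, double m) {
  const double c1 = 1.0 / (2.0 * N1);
  const double c2 = 1.0 / (2.0 * N2);
  arma::mat A(3, 3, arma::fill::zeros);
  A(0, 2) = 2.0 * m;  A(0, 0) = -(2.0 * m + c1);
  A(1, 2) = 2.0 * m;  A(1, 1) = -(2.0 * m + c2);
  A(2, 0) = m;        A(2, 1) = m;   A(2, 2) = -2.0 * m;
  return A;
}

static arma::mat clamp01(arma::mat P) {
  P.clamp(0.0, 1.0);
  return P;
}

// [[Rcpp::export]]
arma::mat transient_propagator_cpp(double N1, double N2, double m,
                                   double dt) {
  return clamp01(arma::expmat(transient_rates(N1, N2, m) * dt));
}

// Structured-coalescent CTMC sampler for one starting configuration.
// States: 0 = BOTH_IN_1, 1 = BOTH_IN_2, 2 = SPLIT. Waiting times are
// piecewise exponential across epochs; transitions use R's RNG so draws
// are reproducible under set.seed().
// [[Rcpp::export]]
Rcpp::List sample_tmrca_cpp(const arma::vec& starts, const arma::vec& N1,
                            const arma::vec& N2, const arma::vec& m,
                            int s0, int n, double horizon) {
  const int ne = starts.n_elem;
  arma::vec c1 = 1.0 / (2.0 * N1);
  arma::vec c2 = 1.0 / (2.0 * N2);
  arma::mat out_rate(3, ne);
  for (int e = 0; e < ne; ++e) {
    out_rate(0, e) = 2.0 * m(e) + c1(e);
    out_rate(1, e) = 2.0 * m(e) + c2(e);
    out_rate(2, e) = 2.0 * m(e);
  }
  Rcpp::NumericVector time(n);
  Rcpp::LogicalVector censored(n);
  const double inf = std::numeric_limits<double>::infinity();
  long long jumps = 0;
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    int s = s0, ep = 0;
    for (;;) {
      if (++jumps > 200000000LL)
        Rcpp::stop("simulation exceeded the jump budget");
      double E = R::exp_rand();
      double tev = inf;
      int e = ep;
      double tcur = t;
      while (e < ne) {
        double r = out_rate(s, e);
        double seg_end = (e < ne - 1) ? starts(e + 1) : inf;
        double len = seg_end - tcur;
        if (r > 0.0 && E <= r * len) { tev = tcur + E / r; break; }
        if (r > 0.0) E -= r * len;
        tcur = seg_end;
        ++e;
      }
      if (tev > horizon) { time[i] = horizon; censored[i] = true; break; }
      t = tev;
      ep = e;
      double u = R::unif_rand();
      if (s == 2) {
        s = (u < 0.5) ? 0 : 1;
      } else {
        double rm = 2.0 * m(ep);
        double rc = (s == 0) ? c1(ep) : c2(ep);
        if (u < rm / (rm + rc)) s = 2;
        else { time[i] = t; censored[i] = false; break; }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("time") = time,
                            Rcpp::Named("censored") = censored);
}

// [[Rcpp::export]]
Rcpp::List interval_survival_cpp(const arma::mat& P_in, double N1, double N2,
                                 double m, double dt, double head_dt) {
  arma::mat A = transient_rates(N1, N2, m);
  arma::mat P0 = P_in;
  if (head_dt > 0) P0 = clamp01(P_in * clamp01(arma::expmat(A * head_dt)));
  arma::mat P_out = clamp01(P0 * clamp01(arma::expmat(A * dt)));
  return Rcpp::List::create(
    Rcpp::Named("S0") = arma::sum(P0, 1),
    Rcpp::Named("S_out") = arma::sum(P_out, 1),
    Rcpp::Named("P_out") = P_out);
}
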