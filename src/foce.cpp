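// Per-subject FOCE inner problem for the one-compartment fast path.
//
// The conditional objective g(eta) (penalised weighted RSS with
// eta-dependent residual variance) is minimised by damped Newton with a
// Gauss-Newton Hessian; predictions are closed-form one-compartment
// superposition evaluated on the log scale so many-half-life troughs stay
// finite. Mirrors the R reference implementation in estimation.R, which
// remains the fallback for multi-compartment models.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// log(1 - exp(-x)) for x > 0, stable near both ends
static double pk_log1mexp(double x) {
  if (x <= 0.0) return R_NegInf;
  return (x < M_LN2) ? std::log(-std::expm1(-x)) : std::log1p(-std::exp(-x));
}

// log central concentration by superposition over dose events.
// type: 0 = iv bolus, 1 = iv infusion, 2 = oral first-order
static arma::vec logpred_1cmt(const arma::mat& TAU, const arma::ivec& type,
                              const arma::vec& amt, const arma::vec& rate,
                              const arma::vec& dur, double CL, double V,
                              double ka, double F) {
  const int nt = TAU.n_rows, nd = TAU.n_cols;
  const double ke = CL / V;
  arma::vec out(nt);
  std::vector<double> lc(nd);
  for (int i = 0; i < nt; ++i) {
    double mx = R_NegInf;
    for (int d = 0; d < nd; ++d) {
      double tau = TAU(i, d), v = R_NegInf;
      if (tau >= 0.0) {
        if (type[d] == 0) {
          v = std::log(amt[d] / V) - ke * tau;
        } else if (type[d] == 1) {
          double T = dur[d];
          v = (tau <= T)
            ? std::log(rate[d] / CL) + pk_log1mexp(ke * tau)
            : std::log(rate[d] / CL) + pk_log1mexp(ke * T) - ke * (tau - T);
        } else if (tau > 0.0) {
          double dk = ka - ke;
          if (std::fabs(dk) < 1e-8 * ke)
            v = std::log(F * amt[d] * ke / V) + std::log(tau) - ke * tau;
          else if (dk > 0.0)
            v = std::log(F * amt[d] * ka / (V * dk)) - ke * tau +
                pk_log1mexp(dk * tau);
          else
            v = std::log(F * amt[d] * ka / (V * (-dk))) - ka * tau +
                pk_log1mexp(-dk * tau);
        }
      }
      lc[d] = v;
      if (v > mx) mx = v;
    }
    if (!std::isfinite(mx)) { out[i] = R_NegInf; continue; }
    double acc = 0.0;
    for (int d = 0; d < nd; ++d)
      if (std::isfinite(lc[d])) acc += std::exp(lc[d] - mx);
    out[i] = mx + std::log(acc);
  }
  return out;
}

struct ErrModel {
  bool logscale;
  double v0, sa2, sp2;   // constant variance (log scale) / linear components
  arma::vec variance(const arma::vec& f) const {
    if (logscale) return arma::vec(f.n_elem, arma::fill::value(v0));
    return sa2 + sp2 * arma::square(f);
  }
  arma::vec dvar_df(const arma::vec& f) const {
    if (logscale) return arma::vec(f.n_elem, arma::fill::zeros);
    return 2.0 * sp2 * f;
  }
};

// prediction on the fitting scale for given eta
static arma::vec predict_eta(const arma::mat& TAU, const arma::ivec& type,
                             const arma::vec& amt, const arma::vec& rate,
                             const arma::vec& dur, const arma::vec& base,
                             const arma::ivec& eta_map, const arma::vec& eta,
                             bool logscale) {
  double p[4] = {base[0], base[1], base[2], base[3]}; // CL V ka F
  for (arma::uword k = 0; k < eta.n_elem; ++k)
    p[eta_map[k]] *= std::exp(eta[k]);
  arma::vec f = logpred_1cmt(TAU, type, amt, rate, dur, p[0], p[1], p[2], p[3]);
  return logscale ? f : arma::exp(f);
}

// [[Rcpp::export(name = ".inner_foce_cpp")]]
Rcpp::List inner_foce_cpp(const arma::mat& TAU, const arma::ivec& type,
                          const arma::vec& amt, const arma::vec& rate,
                          const arma::vec& dur, const arma::vec& y,
                          const arma::vec& base, const arma::ivec& eta_map,
                          const arma::mat& Oinv, bool logscale, double v0,
                          double sa2, double sp2, int max_iter, double h) {
  const int q = eta_map.n_elem;
  const int n = y.n_elem;
  ErrModel em{logscale, v0, sa2, sp2};
  auto fn = [&](const arma::vec& eta) {
    return predict_eta(TAU, type, amt, rate, dur, base, eta_map, eta,
                       logscale);
  };
  auto gval = [&](const arma::vec& eta, const arma::vec& f) {
    arma::vec v = em.variance(f);
    double g = arma::accu(arma::square(y - f) / v + arma::log(v));
    if (q > 0) g += arma::as_scalar(eta.t() * Oinv * eta);
    return g;
  };

  arma::vec eta(q, arma::fill::zeros);
  arma::vec f0 = fn(eta);
  double g0 = gval(eta, f0);
  bool converged = (q == 0);
  arma::mat G(n, q);

  for (int iter = 0; iter < max_iter && q > 0; ++iter) {
    arma::vec v = em.variance(f0), vp = em.dvar_df(f0);
    arma::vec r = y - f0;
    for (int k = 0; k < q; ++k) {
      arma::vec ek = eta; ek[k] += h;
      G.col(k) = (fn(ek) - f0) / h;
    }
    arma::vec grad = -2.0 * G.t() * (r / v) +
      G.t() * ((1.0 / v - arma::square(r) / arma::square(v)) % vp) +
      2.0 * Oinv * eta;
    arma::mat Hhalf = Oinv + G.t() * (G.each_col() / v);
    if (arma::abs(grad).max() < 1e-8 * (1.0 + std::fabs(g0))) {
      converged = true; break;
    }
    arma::vec step;
    if (!arma::solve(step, 2.0 * Hhalf, -grad, arma::solve_opts::no_approx))
      step = -grad / 2.0;
    double lam = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 25; ++ls) {
      arma::vec etry = eta + lam * step;
      arma::vec ftry = fn(etry);
      double gtry = gval(etry, ftry);
      if (std::isfinite(gtry) && gtry < g0) {
        eta = etry; f0 = ftry; g0 = gtry; improved = true; break;
      }
      lam *= 0.5;
    }
    if (!improved) { converged = true; break; } // numerical floor
  }

  arma::vec v = em.variance(f0);
  for (int k = 0; k < q; ++k) {
    arma::vec ek = eta; ek[k] += h;
    G.col(k) = (fn(ek) - f0) / h;
  }
  arma::mat Hhalf = Oinv + G.t() * (G.each_col() / v);
  double ld = 0.0, sign = 1.0;
  if (q > 0) arma::log_det(ld, sign, Hhalf);
  return Rcpp::List::create(
    Rcpp::Named("eta") = eta, Rcpp::Named("g") = g0,
    Rcpp::Named("f") = f0, Rcpp::Named("v") = v,
    Rcpp::Named("G") = G, Rcpp::Named("Hhalf") = Hhalf,
    Rcpp::Named("logdetH") = ld, Rcpp::Named("converged") = converged);
}
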