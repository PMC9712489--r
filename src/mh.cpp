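// Random-walk Metropolis kernel for the cline posterior. Parameters are
// sampled on an unconstrained scale and mapped through a logistic
// transform to their uniform-prior bounds; the Jacobian is included in
// the target. Uses R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double plogis_(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// full layout: 0 center, 1 width, 2 deltaL, 3 tauL, 4 deltaR, 5 tauR,
// 6 pmin, 7 pmax, 8 sigma
struct ClineSpec {
  NumericVector lo, hi, fixed;
  IntegerVector slot_idx, slot_src;   // 0-based
  bool has_pgap; int i_pmin, i_pgap;  // 0-based
  bool mirror;
  int tc;                             // 0 none,1 right,2 left,3 mirror,4 both
  bool quantitative;
  double hi_p;
  NumericVector x, n, k, m, ss0;      // data; ss0 = (n-1)sd^2
};

static void z_to_full(const ClineSpec& S, const double* z, double* full,
                      double* jac) {
  double J = 0.0;
  int d = S.lo.size();
  std::vector<double> v(d);
  for (int j = 0; j < d; ++j) {
    double s = plogis_(z[j]);
    v[j] = S.lo[j] + (S.hi[j] - S.lo[j]) * s;
    J += std::log(S.hi[j] - S.lo[j]) + std::log(s) + std::log1p(-s);
  }
  for (int j = 0; j < 9; ++j) full[j] = S.fixed[j];
  for (int j = 0; j < S.slot_idx.size(); ++j)
    full[S.slot_idx[j]] = v[S.slot_src[j]];
  if (S.has_pgap) {
    full[6] = v[S.i_pmin];
    full[7] = full[6] + (S.hi_p - full[6]) * v[S.i_pgap];
  }
  if (S.mirror) { full[4] = full[2]; full[5] = full[3]; }
  *jac = J;
}

static double shape_at(const ClineSpec& S, const double* th, double x) {
  double f = plogis_(4.0 * (x - th[0]) / th[1]);
  if (S.tc == 2 || S.tc == 3 || S.tc == 4) {
    double xl = th[0] - th[2];
    if (x < xl) {
      double fl = plogis_(4.0 * (xl - th[0]) / th[1]);
      f = std::pow(fl, 1.0 - th[3]) * std::pow(f, th[3]);
    }
  }
  if (S.tc == 1 || S.tc == 3 || S.tc == 4) {
    double xr = th[0] + th[4];
    if (x > xr) {
      double fr = plogis_(4.0 * (xr - th[0]) / th[1]);
      f = 1.0 - std::pow(1.0 - fr, 1.0 - th[5]) * std::pow(1.0 - f, th[5]);
    }
  }
  return f;
}

static double loglik_full(const ClineSpec& S, const double* th) {
  int nl = S.x.size();
  double ll = 0.0;
  if (!S.quantitative) {
    for (int i = 0; i < nl; ++i) {
      double p = th[6] + (th[7] - th[6]) * shape_at(S, th, S.x[i]);
      if (p < 1e-9) p = 1e-9;
      if (p > 1.0 - 1e-9) p = 1.0 - 1e-9;
      ll += S.k[i] * std::log(p) + (S.n[i] - S.k[i]) * std::log1p(-p);
    }
  } else {
    double sigma = th[8];
    if (!(sigma > 0.0) || !std::isfinite(sigma)) return R_NegInf;
    double s2 = sigma * sigma;
    for (int i = 0; i < nl; ++i) {
      double mu = th[6] + (th[7] - th[6]) * shape_at(S, th, S.x[i]);
      double dm = S.m[i] - mu;
      ll += -0.5 * S.n[i] * std::log(2.0 * M_PI * s2)
            - (S.ss0[i] + S.n[i] * dm * dm) / (2.0 * s2);
    }
  }
  return ll;
}

static ClineSpec make_spec(List ps) {
  ClineSpec S;
  S.lo = ps["lo"]; S.hi = ps["hi"];
  S.fixed = ps["fixed_num"];
  IntegerVector si = ps["slot_idx"], ss = ps["slot_src"];
  S.slot_idx = clone(si); S.slot_src = clone(ss);
  for (int j = 0; j < S.slot_idx.size(); ++j) {
    S.slot_idx[j] -= 1; S.slot_src[j] -= 1;
  }
  S.has_pgap = as<bool>(ps["has_pgap"]);
  S.i_pmin = S.has_pgap ? as<int>(ps["i_pmin"]) - 1 : -1;
  S.i_pgap = S.has_pgap ? as<int>(ps["i_pgap"]) - 1 : -1;
  S.mirror = as<bool>(ps["mirror"]);
  std::string tc = as<std::string>(ps["tail_config"]);
  S.tc = tc == "none" ? 0 : tc == "right" ? 1 : tc == "left" ? 2 :
         tc == "mirror" ? 3 : 4;
  S.quantitative = as<bool>(ps["quantitative"]);
  S.hi_p = as<double>(ps["hi_p"]);
  S.x = ps["x"]; S.n = ps["n"];
  if (!S.quantitative) {
    S.k = ps["k"];
  } else {
    S.m = ps["mean"];
    NumericVector sdv = ps["sd"], nv = ps["n"];
    S.ss0 = NumericVector(sdv.size());
    for (int i = 0; i < sdv.size(); ++i)
      S.ss0[i] = nv[i] > 1 ? (nv[i] - 1.0) * sdv[i] * sdv[i] : 0.0;
  }
  return S;
}

// [[Rcpp::export(name = ".cpp_cline_loglik")]]
double cpp_cline_loglik(List ps, NumericVector z) {
  ClineSpec S = make_spec(ps);
  double full[9], jac;
  z_to_full(S, z.begin(), full, &jac);
  return loglik_full(S, full);
}

// Run n_steps of RW-MH with fixed proposal cholesky U (upper triangular,
// proposal = z + scale * t(U) %*% eps). Returns thinned draws, counts and
// the best-likelihood state visited.
// [[Rcpp::export(name = ".cpp_mh_chain")]]
List cpp_mh_chain(List ps, NumericVector z0, NumericMatrix U,
                  double scale, int n_steps, int thin) {
  ClineSpec S = make_spec(ps);
  int d = z0.size();
  std::vector<double> z(z0.begin(), z0.end()), zp(d), eps(d);
  double full[9], jac;
  z_to_full(S, z.data(), full, &jac);
  double ll = loglik_full(S, full);
  double lp = ll + jac;
  double best_ll = ll;
  std::vector<double> best_z(z);
  int n_keep = thin > 0 ? n_steps / thin : 0;
  NumericMatrix draws(n_keep, d);
  int ki = 0, acc = 0;
  RNGScope scope;
  for (int i = 1; i <= n_steps; ++i) {
    for (int j = 0; j < d; ++j) eps[j] = norm_rand();
    // zp = z + scale * t(U) * eps ; U upper => (t(U) e)_j = sum_{r<=j} U(r,j)e_r
    for (int j = 0; j < d; ++j) {
      double s = 0.0;
      for (int r = 0; r <= j; ++r) s += U(r, j) * eps[r];
      zp[j] = z[j] + scale * s;
    }
    z_to_full(S, zp.data(), full, &jac);
    double llp = loglik_full(S, full);
    double lpp = llp + jac;
    if (std::isfinite(lpp) && std::log(unif_rand()) < lpp - lp) {
      z = zp; lp = lpp; ll = llp; ++acc;
      if (ll > best_ll) { best_ll = ll; best_z = z; }
    }
    if (thin > 0 && i % thin == 0) {
      for (int j = 0; j < d; ++j) draws(ki, j) = z[j];
      ++ki;
    }
  }
  return List::create(_["draws"] = draws, _["accept"] = acc,
                      _["z"] = NumericVector(z.begin(), z.end()),
                      _["lp"] = lp, _["best_ll"] = best_ll,
                      _["best_z"] = NumericVector(best_z.begin(),
                                                  best_z.end()));
}
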