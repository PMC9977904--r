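// Nested Gauss-Legendre likelihood kernels for the bi-factor and
// second-order copula models.
//
// Layout conventions (shared with the R reference implementation):
//   * quadrature columns c = q1 + nq * q2 (q1 = common-factor node index,
//     fastest; q2 = group-factor node index), C = nq * nq columns in total;
//   * per-item cell arrays P_j of size K * C, entry k + K * c;
//   * per-group inner sums A_g of size n * nq, entry i + n * q1.
//
// The gradient is a central finite difference on the native parameter
// scale.  Perturbing one item parameter only changes that item's cell
// array, so leave-one-out products of the group factors are cached and a
// single array multiplication recovers the perturbed likelihood.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double UEPS = 1e-10;
static const double PMF_FLOOR = 1e-300;

static inline double clamp01(double u) {
  if (u < UEPS) return UEPS;
  if (u > 1.0 - UEPS) return 1.0 - UEPS;
  return u;
}

static inline double clamp_rho(double th) {
  if (th > 1.0 - 1e-12) return 1.0 - 1e-12;
  if (th < -(1.0 - 1e-12)) return -(1.0 - 1e-12);
  return th;
}

// Gumbel h-function h(u | v) = dC(u, v)/dv
static inline double hGumbel(double u, double v, double th) {
  double x = -std::log(clamp01(u)), y = -std::log(clamp01(v));
  double s = std::pow(x, th) + std::pow(y, th);
  return std::exp(-std::pow(s, 1.0 / th) + y + (1.0 / th - 1.0) * std::log(s) +
                  (th - 1.0) * std::log(y));
}

static double hfun(int fam, double par, double nu, double u, double v) {
  switch (fam) {
  case 1: { // bvn
    double th = clamp_rho(par);
    double x = R::qnorm(clamp01(u), 0.0, 1.0, 1, 0);
    double y = R::qnorm(clamp01(v), 0.0, 1.0, 1, 0);
    return R::pnorm((x - th * y) / std::sqrt(1.0 - th * th), 0.0, 1.0, 1, 0);
  }
  case 2: { // t
    double th = clamp_rho(par);
    double x = R::qt(clamp01(u), nu, 1, 0);
    double y = R::qt(clamp01(v), nu, 1, 0);
    return R::pt((x - th * y) *
                     std::sqrt((nu + 1.0) / ((nu + y * y) * (1.0 - th * th))),
                 nu + 1.0, 1, 0);
  }
  case 3: return hGumbel(u, v, par);
  case 4: return 1.0 - hGumbel(1.0 - u, 1.0 - v, par);
  case 5: return 1.0 - hGumbel(1.0 - u, v, par);
  case 6: return hGumbel(u, 1.0 - v, par);
  }
  return NA_REAL;
}

static double qcondGumbel(double p, double v, double th) {
  double lo = UEPS, hi = 1.0 - UEPS;
  for (int i = 0; i < 52; ++i) {
    double mid = 0.5 * (lo + hi);
    if (hGumbel(mid, v, th) < p) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

static double qcondfun(int fam, double par, double nu, double p, double v) {
  p = clamp01(p); v = clamp01(v);
  switch (fam) {
  case 1: {
    double th = clamp_rho(par);
    return R::pnorm(std::sqrt(1.0 - th * th) * R::qnorm(p, 0.0, 1.0, 1, 0) +
                        th * R::qnorm(v, 0.0, 1.0, 1, 0),
                    0.0, 1.0, 1, 0);
  }
  case 2: {
    double th = clamp_rho(par);
    double y = R::qt(v, nu, 1, 0);
    double x = th * y + std::sqrt((1.0 - th * th) * (nu + y * y) / (nu + 1.0)) *
                            R::qt(p, nu + 1.0, 1, 0);
    return R::pt(x, nu, 1, 0);
  }
  case 3: return qcondGumbel(p, v, par);
  case 4: return 1.0 - qcondGumbel(1.0 - p, 1.0 - v, par);
  case 5: return 1.0 - qcondGumbel(1.0 - p, v, par);
  case 6: return qcondGumbel(p, 1.0 - v, par);
  }
  return NA_REAL;
}

// generic conditional-cdf evaluation over a u-grid x v-grid with the
// quantile/log transforms of both arguments hoisted out of the inner loop.
// uvals has nu_cols columns of Km1 entries; the output column index is
// c = cu + nu_cols' pairing defined by the caller through `pair_mode`:
//   pair_mode = true : all combinations, c = cu + nu_cols * cv (grid case)
//   pair_mode = false: matched pairs, cu = cv = c (node-vector case)
static void cond_boundaries(int fam, double par, double nu,
                            const std::vector<double>& uvals, int Km1,
                            int nu_cols,
                            const std::vector<double>& vvals,
                            bool pair_mode, std::vector<double>& T) {
  int nv = (int)vvals.size();
  size_t C = pair_mode ? (size_t)nu_cols * nv : vvals.size();
  T.resize((size_t)Km1 * C);
  size_t nu_tot = uvals.size();

  std::vector<double> ut(nu_tot), vt(nv);
  int base = fam;  // underlying family after reflection bookkeeping
  bool flip_u = false, flip_v = false, flip_out = false;
  if (fam == 4) { flip_u = flip_v = flip_out = true; base = 3; }
  else if (fam == 5) { flip_u = true; flip_out = true; base = 3; }
  else if (fam == 6) { flip_v = true; base = 3; }

  double th = par, s12 = 0.0, thc = 0.0;
  if (base == 1 || base == 2) {
    th = clamp_rho(par);
    s12 = std::sqrt(1.0 - th * th);
  }
  for (size_t i = 0; i < nu_tot; ++i) {
    double u = clamp01(flip_u ? 1.0 - uvals[i] : uvals[i]);
    ut[i] = (base == 1) ? R::qnorm(u, 0.0, 1.0, 1, 0)
          : (base == 2) ? R::qt(u, nu, 1, 0)
          : std::pow(-std::log(u), par);        // x^theta for Gumbel
  }
  for (int i = 0; i < nv; ++i) {
    double v = clamp01(flip_v ? 1.0 - vvals[i] : vvals[i]);
    vt[i] = (base == 1) ? R::qnorm(v, 0.0, 1.0, 1, 0)
          : (base == 2) ? R::qt(v, nu, 1, 0)
          : -std::log(v);                        // y for Gumbel
  }
  thc = 1.0 / par;  // 1/theta (Gumbel only)

  for (size_t c = 0; c < C; ++c) {
    size_t cu = pair_mode ? c % nu_cols : (nu_cols == 1 ? 0 : c);
    size_t cv = pair_mode ? c / nu_cols : c;
    double y = vt[cv];
    double ypow = 0.0, ylog = 0.0;
    if (base == 3) { ypow = std::pow(y, par); ylog = std::log(y); }
    for (int k = 0; k < Km1; ++k) {
      double x = ut[k + Km1 * cu];
      double h;
      if (base == 1) {
        h = R::pnorm((x - th * y) / s12, 0.0, 1.0, 1, 0);
      } else if (base == 2) {
        h = R::pt((x - th * y) *
                      std::sqrt((nu + 1.0) / ((nu + y * y) * s12 * s12)),
                  nu + 1.0, 1, 0);
      } else {
        double s = x + ypow;  // x^theta + y^theta
        h = std::exp(-std::pow(s, thc) + y + (thc - 1.0) * std::log(s) +
                     (par - 1.0) * ylog);
      }
      T[k + (size_t)Km1 * c] = flip_out ? 1.0 - h : h;
    }
  }
}

// boundaries -> cell probabilities, P (K x C)
static void boundaries_to_cells(const std::vector<double>& T, int K, size_t C,
                                std::vector<double>& P) {
  int Km1 = K - 1;
  P.resize((size_t)K * C);
  for (size_t c = 0; c < C; ++c) {
    double prev = 0.0;
    for (int k = 0; k < Km1; ++k) {
      double t = T[k + (size_t)Km1 * c];
      double cell = t - prev;
      P[k + (size_t)K * c] = cell > 0.0 ? cell : 0.0;
      prev = t;
    }
    double last = 1.0 - prev;
    P[Km1 + (size_t)K * c] = last > 0.0 ? last : 0.0;
  }
}

struct Engine {
  int n, d, K, G, nq, kind;
  size_t C;
  const IntegerMatrix& y;
  const NumericMatrix& acut;  // (K-1) x d
  std::vector<int> grp;       // 0-based item -> group
  std::vector<int> fam1; std::vector<double> par1, nu1;   // d
  std::vector<int> fam2; std::vector<double> par2, nu2;   // d (bif) or G (so)
  std::vector<double> v, w;   // nq
  std::vector<std::vector<int>> members;

  std::vector<std::vector<double>> P;     // d arrays K*C
  std::vector<std::vector<double>> vdep;  // G arrays C (kind 2)
  std::vector<std::vector<double>> A;     // G arrays n*nq
  std::vector<std::vector<double>> LOO;   // d arrays n*C (grad only)
  std::vector<std::vector<double>> Aother; // G arrays n*nq: prod of other groups
  std::vector<double> scratchT, scratchP, scratchL, scratchA, scratchV;

  Engine(const IntegerMatrix& y_, const NumericMatrix& acut_, int kind_)
      : y(y_), acut(acut_), kind(kind_) {
    n = y.nrow(); d = y.ncol(); K = acut.nrow() + 1;
  }

  void compute_vdep(int g, double del, std::vector<double>& out) const {
    out.resize(C);
    for (int q2 = 0; q2 < nq; ++q2) {
      for (int q1 = 0; q1 < nq; ++q1) {
        out[q1 + (size_t)nq * q2] =
            qcondfun(fam2[g], del, nu2[g], v[q2], v[q1]);
      }
    }
  }

  // item cell array under given parameters (bi-factor)
  void compute_P_bif(int j, double th, double del, std::vector<double>& Pout) {
    int Km1 = K - 1;
    std::vector<double> a(Km1);
    for (int k = 0; k < Km1; ++k) a[k] = acut(k, j);
    // level 1: U[k + Km1*q1] = h(a_k | v_q1) under the item->V0 copula
    std::vector<double> U;
    cond_boundaries(fam1[j], th, nu1[j], a, Km1, 1, v, false, U);
    // level 2: all (q1, q2) combinations under the item->Vg|V0 copula
    cond_boundaries(fam2[j], del, nu2[j], U, Km1, nq, v, true, scratchT);
    boundaries_to_cells(scratchT, K, C, Pout);
  }

  // item cell array (second-order), given the group's dependent nodes
  void compute_P_so(int j, double th, const std::vector<double>& vg,
                    std::vector<double>& Pout) {
    int Km1 = K - 1;
    std::vector<double> a(Km1);
    for (int k = 0; k < Km1; ++k) a[k] = acut(k, j);
    cond_boundaries(fam1[j], th, nu1[j], a, Km1, 1, vg, false, scratchT);
    boundaries_to_cells(scratchT, K, C, Pout);
  }

  void compute_item_P(int j, std::vector<double>& Pout) {
    if (kind == 1) compute_P_bif(j, par1[j], par2[j], Pout);
    else compute_P_so(j, par1[j], vdep[grp[j]], Pout);
  }

  // group row-products and inner sums; optionally fill LOO arrays
  void group_pass(int g, bool want_loo) {
    const std::vector<int>& mem = members[g];
    int m = (int)mem.size();
    std::vector<double> L((size_t)n * C, 1.0);
    if (want_loo) {
      // prefix products
      std::vector<std::vector<double>> pre(m);
      std::vector<double> run((size_t)n * C, 1.0);
      for (int t = 0; t < m; ++t) {
        pre[t] = run;  // product of items before t
        mult_rows(run, mem[t]);
      }
      L = run;
      // suffix sweep
      std::fill(run.begin(), run.end(), 1.0);
      for (int t = m - 1; t >= 0; --t) {
        LOO[mem[t]] = pre[t];
        mult_arrays(LOO[mem[t]], run);
        mult_rows(run, mem[t]);
      }
    } else {
      for (int t = 0; t < m; ++t) mult_rows(L, mem[t]);
    }
    inner_sum(L, A[g]);
  }

  // L *= P_j[y_ij] rowwise
  void mult_rows(std::vector<double>& L, int j) const {
    const std::vector<double>& Pj = P[j];
    const int* yj = &y(0, j);        // column-major, contiguous
    for (size_t c = 0; c < C; ++c) {
      const double* col = &Pj[(size_t)K * c];
      double* Lc = &L[(size_t)n * c];
      for (int i = 0; i < n; ++i) Lc[i] *= col[yj[i]];
    }
  }

  static void mult_arrays(std::vector<double>& a, const std::vector<double>& b) {
    for (size_t i = 0; i < a.size(); ++i) a[i] *= b[i];
  }

  // A[i + n*q1] = sum_q2 w[q2] L[i + n*(q1 + nq*q2)]
  void inner_sum(const std::vector<double>& L, std::vector<double>& Aout) const {
    Aout.assign((size_t)n * nq, 0.0);
    for (int q2 = 0; q2 < nq; ++q2) {
      double wq = w[q2];
      const double* Lq = &L[(size_t)n * nq * q2];
      for (size_t t = 0; t < (size_t)n * nq; ++t) Aout[t] += wq * Lq[t];
    }
  }

  // log-likelihood from the group inner sums, substituting `Asub` for group
  // gsub (gsub < 0: no substitution); optionally store per-row log pmf
  double loglik_from_A(int gsub, const std::vector<double>* Asub,
                       double* rowlog = nullptr) const {
    if (gsub >= 0 && Asub && !Aother.empty()) {
      // fast path: product over the other groups is cached
      const std::vector<double>& Ao = Aother[gsub];
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        double p = 0.0;
        for (int q1 = 0; q1 < nq; ++q1) {
          size_t t = i + (size_t)n * q1;
          p += w[q1] * Ao[t] * (*Asub)[t];
        }
        if (p < PMF_FLOOR) p = PMF_FLOOR;
        ll += std::log(p);
      }
      return ll;
    }
    double ll = 0.0;
    std::vector<double> prod((size_t)n * nq, 1.0);
    for (int g = 0; g < G; ++g) {
      const std::vector<double>& Ag = (g == gsub && Asub) ? *Asub : A[g];
      for (size_t t = 0; t < prod.size(); ++t) prod[t] *= Ag[t];
    }
    for (int i = 0; i < n; ++i) {
      double p = 0.0;
      for (int q1 = 0; q1 < nq; ++q1) p += w[q1] * prod[i + (size_t)n * q1];
      if (p < PMF_FLOOR) p = PMF_FLOOR;
      double lp = std::log(p);
      if (rowlog) rowlog[i] = lp;
      ll += lp;
    }
    return ll;
  }

  // prefix/suffix products of the A_g arrays over groups
  void compute_Aother() {
    Aother.assign(G, std::vector<double>((size_t)n * nq, 1.0));
    std::vector<double> run((size_t)n * nq, 1.0);
    for (int g = 0; g < G; ++g) {
      Aother[g] = run;
      for (size_t t = 0; t < run.size(); ++t) run[t] *= A[g][t];
    }
    std::fill(run.begin(), run.end(), 1.0);
    for (int g = G - 1; g >= 0; --g) {
      for (size_t t = 0; t < run.size(); ++t) Aother[g][t] *= run[t];
      for (size_t t = 0; t < run.size(); ++t) run[t] *= A[g][t];
    }
  }

  // perturbed log-likelihood for a single item's parameter (uses LOO cache)
  double loglik_item_perturbed(int j, double th, double del) {
    int g = grp[j];
    if (kind == 1) compute_P_bif(j, th, del, scratchP);
    else compute_P_so(j, th, vdep[g], scratchP);
    // A'_g from LOO_j * P'_j
    scratchA.assign((size_t)n * nq, 0.0);
    const std::vector<double>& Lj = LOO[j];
    const int* yj = &y(0, j);
    for (int q2 = 0; q2 < nq; ++q2) {
      double wq = w[q2];
      for (int q1 = 0; q1 < nq; ++q1) {
        size_t c = (size_t)q1 + (size_t)nq * q2;
        const double* col = &scratchP[(size_t)K * c];
        const double* Lc = &Lj[(size_t)n * c];
        double* Ac = &scratchA[(size_t)n * q1];
        for (int i = 0; i < n; ++i) Ac[i] += wq * Lc[i] * col[yj[i]];
      }
    }
    return loglik_from_A(g, &scratchA);
  }

  // perturbed log-likelihood for a second-order group parameter delta_g
  double loglik_group_perturbed(int g, double del) {
    compute_vdep(g, del, scratchV);
    const std::vector<int>& mem = members[g];
    scratchL.assign((size_t)n * C, 1.0);
    for (int j : mem) {
      compute_P_so(j, par1[j], scratchV, scratchP);
      const int* yj = &y(0, j);
      for (size_t c = 0; c < C; ++c) {
        const double* col = &scratchP[(size_t)K * c];
        double* Lc = &scratchL[(size_t)n * c];
        for (int i = 0; i < n; ++i) Lc[i] *= col[yj[i]];
      }
    }
    inner_sum(scratchL, scratchA);
    return loglik_from_A(g, &scratchA);
  }
};

// step that stays inside the parameter domain
static void domain_step(int fam, double par, double eps, double* lo, double* hi) {
  if (fam == 1 || fam == 2) {
    double e = std::min(eps, (1.0 - std::fabs(par)) / 3.0);
    if (e < 1e-9) e = 1e-9;
    *lo = clamp_rho(par - e); *hi = clamp_rho(par + e);
  } else {
    double e = std::min(eps, (par - 1.0) / 3.0 + 1e-9);
    if (e < 1e-9) e = 1e-9;
    *lo = std::max(par - e, 1.0 + 1e-12); *hi = par + e;
  }
}

// [[Rcpp::export(name = ".loglik_kernel")]]
List loglik_kernel(IntegerMatrix y, IntegerVector item_group,
                   NumericMatrix acut,
                   IntegerVector fam1, NumericVector par1, NumericVector nu1,
                   IntegerVector fam2, NumericVector par2, NumericVector nu2,
                   NumericVector nodes, NumericVector weights,
                   int kind, bool grad, double eps, bool rowwise) {
  Engine E(y, acut, kind);
  E.G = 0;
  E.grp.resize(E.d);
  for (int j = 0; j < E.d; ++j) {
    E.grp[j] = item_group[j] - 1;
    if (E.grp[j] + 1 > E.G) E.G = E.grp[j] + 1;
  }
  E.members.assign(E.G, {});
  for (int j = 0; j < E.d; ++j) E.members[E.grp[j]].push_back(j);
  E.nq = nodes.size();
  E.C = (size_t)E.nq * E.nq;
  E.v.assign(nodes.begin(), nodes.end());
  E.w.assign(weights.begin(), weights.end());
  E.fam1.assign(fam1.begin(), fam1.end());
  E.par1.assign(par1.begin(), par1.end());
  E.nu1.assign(nu1.begin(), nu1.end());
  E.fam2.assign(fam2.begin(), fam2.end());
  E.par2.assign(par2.begin(), par2.end());
  E.nu2.assign(nu2.begin(), nu2.end());

  if (kind == 2) {
    E.vdep.resize(E.G);
    for (int g = 0; g < E.G; ++g) E.compute_vdep(g, E.par2[g], E.vdep[g]);
  }
  E.P.resize(E.d);
  for (int j = 0; j < E.d; ++j) E.compute_item_P(j, E.P[j]);
  E.A.resize(E.G);
  if (grad) E.LOO.resize(E.d);
  for (int g = 0; g < E.G; ++g) E.group_pass(g, grad);

  NumericVector rowlog;
  double ll;
  if (rowwise) {
    rowlog = NumericVector(E.n);
    ll = E.loglik_from_A(-1, nullptr, rowlog.begin());
  } else {
    ll = E.loglik_from_A(-1, nullptr);
  }

  List out = List::create(Named("loglik") = ll);
  if (rowwise) out["rowlog"] = rowlog;

  if (grad) {
    E.compute_Aother();
    int n1 = E.par1.size(), n2 = E.par2.size();
    NumericVector gr(n1 + n2);
    for (int j = 0; j < n1; ++j) {
      double lo, hi;
      domain_step(E.fam1[j], E.par1[j], eps, &lo, &hi);
      double llp = (kind == 1)
        ? E.loglik_item_perturbed(j, hi, E.par2[j])
        : E.loglik_item_perturbed(j, hi, 0.0);
      double llm = (kind == 1)
        ? E.loglik_item_perturbed(j, lo, E.par2[j])
        : E.loglik_item_perturbed(j, lo, 0.0);
      gr[j] = (llp - llm) / (hi - lo);
    }
    for (int p = 0; p < n2; ++p) {
      double lo, hi;
      domain_step(E.fam2[p], E.par2[p], eps, &lo, &hi);
      double llp, llm;
      if (kind == 1) {
        llp = E.loglik_item_perturbed(p, E.par1[p], hi);
        llm = E.loglik_item_perturbed(p, E.par1[p], lo);
      } else {
        llp = E.loglik_group_perturbed(p, hi);
        llm = E.loglik_group_perturbed(p, lo);
      }
      gr[n1 + p] = (llp - llm) / (hi - lo);
    }
    out["grad"] = gr;
  }
  return out;
}

// [[Rcpp::export(name = ".qcond_kernel")]]
NumericVector qcond_kernel(NumericVector p, NumericVector v, int fam,
                           double par, double nu) {
  int n = p.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = qcondfun(fam, par, nu, p[i], v[i]);
  return out;
}
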