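#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical Poisson model
//
//   O_it ~ Poisson(E_it * exp(eta_it))
//   eta_it = alpha + beta*x_it + (beta^2/2)*s2_it + Z_it'gamma + u_i + v_i
//
// with u_i iid N(0, 1/tau_u), v an intrinsic CAR (ICAR) field with
// precision tau_v on the sum-to-zero subspace of each connected component,
// N(0, sd_fixed^2) priors on alpha/beta/gamma and Gamma(a, b) priors on
// the precisions (conjugate Gibbs steps).  The (beta^2/2)*s2 term is the
// pure-specification-bias correction: its coefficient is tied to the
// current beta draw, never a free parameter.
//
// Random-walk proposals are adapted towards 0.44 acceptance during
// burn-in only, so the post-burn-in kernel satisfies detailed balance.
// All randomness comes from R's RNG: set.seed() upstream gives
// bit-identical chains.

static const int ADAPT_WINDOW = 50;
static const double ADAPT_TARGET = 0.44;
static const double SCALE_MIN = 1e-4;
static const double SCALE_MAX = 25.0;

static inline void adapt_scale(double &scale, int &acc) {
  double rate = (double)acc / ADAPT_WINDOW;
  scale *= std::exp(rate - ADAPT_TARGET);
  if (scale < SCALE_MIN) scale = SCALE_MIN;
  if (scale > SCALE_MAX) scale = SCALE_MAX;
  acc = 0;
}

// [[Rcpp::export]]
List bym_mcmc_cpp(IntegerVector O, NumericVector logE,
                  NumericVector x, NumericVector s2, NumericMatrix Z,
                  IntegerVector area,          // 0-based area index per record
                  List nbrs,                   // 0-based neighbour ids per area
                  IntegerVector comp,          // 0-based component id, -1 = isolated
                  int n_comp,
                  bool spatial, bool variance_term,
                  double sd_fixed, double prior_a, double prior_b,
                  int iterations, int burn_in, int thin, bool adapt,
                  NumericVector init_fixed,    // alpha, beta, gamma[p]
                  NumericVector init_u, NumericVector init_v,
                  double init_tau_u, double init_tau_v,
                  double init_step) {
  const int n_rec = O.size();
  const int n_area = nbrs.size();
  const int p = Z.ncol();

  // records per area
  std::vector< std::vector<int> > arec(n_area);
  for (int r = 0; r < n_rec; ++r) arec[area[r]].push_back(r);

  // neighbour lists and unique edges
  std::vector< std::vector<int> > nb(n_area);
  std::vector< std::pair<int,int> > edges;
  for (int i = 0; i < n_area; ++i) {
    IntegerVector ni = nbrs[i];
    for (int k = 0; k < ni.size(); ++k) {
      nb[i].push_back(ni[k]);
      if (ni[k] > i) edges.push_back(std::make_pair(i, ni[k]));
    }
  }
  int n_sp = 0;                      // areas participating in the ICAR field
  for (int i = 0; i < n_area; ++i) if (comp[i] >= 0) ++n_sp;

  // state
  double alpha = init_fixed[0], beta = init_fixed[1];
  std::vector<double> gam(p);
  for (int j = 0; j < p; ++j) gam[j] = init_fixed[2 + j];
  std::vector<double> u(init_u.begin(), init_u.end());
  std::vector<double> v(init_v.begin(), init_v.end());
  double tau_u = init_tau_u, tau_v = init_tau_v;
  if (!spatial) for (int i = 0; i < n_area; ++i) v[i] = 0.0;

  std::vector<double> eta(n_rec);
  for (int r = 0; r < n_rec; ++r) {
    double e = alpha + beta * x[r] + u[area[r]] + v[area[r]];
    if (variance_term) e += 0.5 * beta * beta * s2[r];
    for (int j = 0; j < p; ++j) e += Z(r, j) * gam[j];
    eta[r] = e;
  }

  // proposal scales and acceptance counters
  double s_alpha = init_step, s_beta = init_step;
  std::vector<double> s_gam(p, init_step), s_u(n_area, init_step),
                      s_v(n_area, init_step);
  int a_alpha = 0, a_beta = 0;
  std::vector<int> a_gam(p, 0), a_u(n_area, 0), a_v(n_area, 0);

  const double pv = 2.0 * sd_fixed * sd_fixed;   // 2 * prior variance
  std::vector<double> delta(n_rec);

  const int n_keep = (iterations - burn_in + thin - 1) / thin;
  const int n_par = 2 + p + n_area + (spatial ? n_area : 0) + 1 +
                    (spatial ? 1 : 0) + 1;
  NumericMatrix out(n_keep, n_par);
  int kept = 0;

  for (int it = 0; it < iterations; ++it) {
    // --- alpha (constant shift of eta) ---
    {
      double d = s_alpha * norm_rand();
      double prop = alpha + d;
      double lr = (alpha * alpha - prop * prop) / pv;
      double em1 = std::exp(d) - 1.0;
      for (int r = 0; r < n_rec; ++r)
        lr += O[r] * d - std::exp(logE[r] + eta[r]) * em1;
      if (std::log(unif_rand()) < lr) {
        alpha = prop;
        for (int r = 0; r < n_rec; ++r) eta[r] += d;
        ++a_alpha;
      }
    }
    // --- beta (shifts eta through x and, if tied, through s2) ---
    {
      double prop = beta + s_beta * norm_rand();
      double lr = (beta * beta - prop * prop) / pv;
      double db = prop - beta;
      double dq = variance_term ? 0.5 * (prop * prop - beta * beta) : 0.0;
      for (int r = 0; r < n_rec; ++r) {
        double d = db * x[r] + dq * s2[r];
        delta[r] = d;
        lr += O[r] * d - std::exp(logE[r] + eta[r]) * (std::exp(d) - 1.0);
      }
      if (std::log(unif_rand()) < lr) {
        beta = prop;
        for (int r = 0; r < n_rec; ++r) eta[r] += delta[r];
        ++a_beta;
      }
    }
    // --- gamma_j ---
    for (int j = 0; j < p; ++j) {
      double dg = s_gam[j] * norm_rand();
      double prop = gam[j] + dg;
      double lr = (gam[j] * gam[j] - prop * prop) / pv;
      for (int r = 0; r < n_rec; ++r) {
        double d = dg * Z(r, j);
        delta[r] = d;
        lr += O[r] * d - std::exp(logE[r] + eta[r]) * (std::exp(d) - 1.0);
      }
      if (std::log(unif_rand()) < lr) {
        gam[j] = prop;
        for (int r = 0; r < n_rec; ++r) eta[r] += delta[r];
        ++a_gam[j];
      }
    }
    // --- u_i, exchangeable N(0, 1/tau_u) ---
    for (int i = 0; i < n_area; ++i) {
      double d = s_u[i] * norm_rand();
      double prop = u[i] + d;
      double lr = 0.5 * tau_u * (u[i] * u[i] - prop * prop);
      double em1 = std::exp(d) - 1.0;
      const std::vector<int> &idx = arec[i];
      for (size_t k = 0; k < idx.size(); ++k) {
        int r = idx[k];
        lr += O[r] * d - std::exp(logE[r] + eta[r]) * em1;
      }
      if (std::log(unif_rand()) < lr) {
        u[i] = prop;
        for (size_t k = 0; k < idx.size(); ++k) eta[idx[k]] += d;
        ++a_u[i];
      }
    }
    // --- v_i, ICAR (skip isolated areas) ---
    if (spatial) {
      for (int i = 0; i < n_area; ++i) {
        if (comp[i] < 0) continue;
        double d = s_v[i] * norm_rand();
        double prop = v[i] + d;
        double lr = 0.0;
        for (size_t k = 0; k < nb[i].size(); ++k) {
          double vj = v[nb[i][k]];
          lr -= 0.5 * tau_v * ((prop - vj) * (prop - vj) -
                               (v[i] - vj) * (v[i] - vj));
        }
        double em1 = std::exp(d) - 1.0;
        const std::vector<int> &idx = arec[i];
        for (size_t k = 0; k < idx.size(); ++k) {
          int r = idx[k];
          lr += O[r] * d - std::exp(logE[r] + eta[r]) * em1;
        }
        if (std::log(unif_rand()) < lr) {
          v[i] = prop;
          for (size_t k = 0; k < idx.size(); ++k) eta[idx[k]] += d;
          ++a_v[i];
        }
      }
      // re-centre per connected component (sum-to-zero constraint)
      std::vector<double> m(n_comp, 0.0);
      std::vector<int> cnt(n_comp, 0);
      for (int i = 0; i < n_area; ++i)
        if (comp[i] >= 0) { m[comp[i]] += v[i]; ++cnt[comp[i]]; }
      for (int c = 0; c < n_comp; ++c) m[c] /= cnt[c];
      for (int i = 0; i < n_area; ++i) if (comp[i] >= 0) v[i] -= m[comp[i]];
      for (int r = 0; r < n_rec; ++r)
        if (comp[area[r]] >= 0) eta[r] -= m[comp[area[r]]];
    }
    // --- precisions, conjugate Gibbs ---
    {
      double ssu = 0.0;
      for (int i = 0; i < n_area; ++i) ssu += u[i] * u[i];
      tau_u = R::rgamma(prior_a + 0.5 * n_area, 1.0 / (prior_b + 0.5 * ssu));
      if (spatial) {
        double ssv = 0.0;
        for (size_t e = 0; e < edges.size(); ++e) {
          double dv = v[edges[e].first] - v[edges[e].second];
          ssv += dv * dv;
        }
        tau_v = R::rgamma(prior_a + 0.5 * (n_sp - n_comp),
                          1.0 / (prior_b + 0.5 * ssv));
      }
    }
    // --- adaptation, burn-in only ---
    if (adapt && it < burn_in && (it + 1) % ADAPT_WINDOW == 0) {
      adapt_scale(s_alpha, a_alpha);
      adapt_scale(s_beta, a_beta);
      for (int j = 0; j < p; ++j) adapt_scale(s_gam[j], a_gam[j]);
      for (int i = 0; i < n_area; ++i) adapt_scale(s_u[i], a_u[i]);
      if (spatial) for (int i = 0; i < n_area; ++i) adapt_scale(s_v[i], a_v[i]);
    }
    // --- store ---
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      int c = 0;
      out(kept, c++) = alpha;
      out(kept, c++) = beta;
      for (int j = 0; j < p; ++j) out(kept, c++) = gam[j];
      for (int i = 0; i < n_area; ++i) out(kept, c++) = u[i];
      if (spatial) for (int i = 0; i < n_area; ++i) out(kept, c++) = v[i];
      out(kept, c++) = tau_u;
      if (spatial) out(kept, c++) = tau_v;
      double dev = 0.0;
      for (int r = 0; r < n_rec; ++r) {
        double lmu = logE[r] + eta[r];
        dev += O[r] * lmu - std::exp(lmu) - R::lgammafn(O[r] + 1.0);
      }
      out(kept, c) = -2.0 * dev;
      ++kept;
    }
  }

  return List::create(_["draws"] = out,
                      _["step_alpha"] = s_alpha, _["step_beta"] = s_beta);
}
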