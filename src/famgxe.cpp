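// Compiled core: log-posterior and analytic gradient of the Bernoulli-logit
// liability models, a No-U-Turn sampler with dual-averaging step-size and
// diagonal mass-matrix adaptation, and a mean-field ADVI optimizer used for
// chain initialization. All randomness flows through R's RNG so that
// set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::vec;
using arma::mat;
using arma::uvec;

static inline double log1p_exp(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// ---------------------------------------------------------------------------
// Target interface: anything NUTS/ADVI can sample from.
struct Target {
  virtual double logp_grad(const vec& theta, vec& grad) = 0;
  virtual int dim() const = 0;
  virtual ~Target() {}
};

// ---------------------------------------------------------------------------
// The liability model.
//
// Unconstrained parameter layout (in order):
//   z_beta (p) | log_lambda (p-1) | log_tau (1)
//   [geo] log_s2P, log_ell, u_P (m)
//   log_s2G, u_G (n)
//   per included environment in F,C,S,E order: log_s2, u (ngroups)
//   per included interaction in GF,GC,GS,GE order: k (1)
struct Model : Target {
  mat X;            // n x p fixed-effect design
  vec y;            // binary phenotype
  arma::sp_mat LG, LGt;  // Cholesky factor of the GRM and transpose
  bool use_geo;
  mat D2;           // m x m squared distances between unique locations
  uvec loc;         // 0-based location index per individual
  std::vector<std::string> envs;        // subset of F,C,S,E (ordered)
  std::vector<uvec> groups;             // 0-based group id per individual
  std::vector<int> ngroups;
  std::vector<std::string> inters;      // subset of GF,GC,GS,GE (ordered)
  // priors
  double hs_scale, beta0_sd, gam_shape, gam_rate, k_sd, ell_a, ell_b, jitter;

  int n, p, m, d;
  // layout offsets
  int o_z, o_llam, o_ltau, o_ls2P, o_lell, o_uP, o_ls2G, o_uG;
  std::vector<int> o_ls2e, o_ue;
  std::vector<int> o_k;

  Model(const List& data) {
    X = as<mat>(data["X"]);
    y = as<vec>(data["y"]);
    LG = as<arma::sp_mat>(data["LG"]);
    LGt = LG.t();
    use_geo = as<bool>(data["use_geo"]);
    if (use_geo) {
      D2 = as<mat>(data["D2"]);
      loc = as<uvec>(data["loc"]) - 1;
      m = D2.n_rows;
    } else m = 0;
    CharacterVector ec = data["env_codes"];
    List gl = data["groups"];
    for (int i = 0; i < ec.size(); ++i) {
      envs.push_back(as<std::string>(ec[i]));
      uvec g = as<uvec>(gl[i]) - 1;
      groups.push_back(g);
      ngroups.push_back(g.max() + 1);
    }
    CharacterVector ic = data["interactions"];
    for (int i = 0; i < ic.size(); ++i)
      inters.push_back(as<std::string>(ic[i]));
    List pr = data["priors"];
    hs_scale = as<double>(pr["hs_scale"]);
    beta0_sd = as<double>(pr["beta0_sd"]);
    gam_shape = as<double>(pr["gam_shape"]);
    gam_rate = as<double>(pr["gam_rate"]);
    k_sd = as<double>(pr["k_sd"]);
    ell_a = as<double>(pr["ell_a"]);
    ell_b = as<double>(pr["ell_b"]);
    jitter = as<double>(pr["jitter"]);

    n = X.n_rows; p = X.n_cols;
    int pos = 0;
    o_z = pos; pos += p;
    o_llam = pos; pos += p - 1;
    o_ltau = pos; pos += 1;
    if (use_geo) {
      o_ls2P = pos; pos += 1;
      o_lell = pos; pos += 1;
      o_uP = pos; pos += m;
    } else { o_ls2P = o_lell = o_uP = -1; }
    o_ls2G = pos; pos += 1;
    o_uG = pos; pos += n;
    for (size_t e = 0; e < envs.size(); ++e) {
      o_ls2e.push_back(pos); pos += 1;
      o_ue.push_back(pos); pos += ngroups[e];
    }
    for (size_t i = 0; i < inters.size(); ++i) {
      o_k.push_back(pos); pos += 1;
    }
    d = pos;
  }

  int dim() const { return d; }

  int env_index(const std::string& e) const {
    for (size_t i = 0; i < envs.size(); ++i) if (envs[i] == e) return i;
    return -1;
  }

  // zero-avoiding Gamma prior on sigma^2 expressed on log sigma^2
  inline double gam_lp(double ls2, double s2) const {
    return gam_shape * ls2 - gam_rate * s2;
  }
  inline double gam_grad(double ls2, double s2) const {
    return gam_shape - gam_rate * s2;
  }

  double logp_grad(const vec& theta, vec& grad) {
    grad.zeros(d);
    double lp = 0.0;

    // ---- fixed effects (horseshoe, intercept exempt) ----
    vec z = theta.subvec(o_z, o_z + p - 1);
    vec llam = (p > 1) ? theta.subvec(o_llam, o_llam + p - 2) : vec();
    double ltau = theta(o_ltau);
    vec lam = arma::exp(llam);
    double tau = std::exp(ltau);
    vec beta(p);
    beta(0) = beta0_sd * z(0);
    for (int j = 1; j < p; ++j)
      beta(j) = hs_scale * tau * lam(j - 1) * z(j);
    lp += -0.5 * arma::dot(z, z);
    for (int j = 0; j < p - 1; ++j)
      lp += llam(j) - std::log1p(lam(j) * lam(j));
    lp += ltau - std::log1p(tau * tau);

    // ---- spatial GP (non-centered) ----
    double s2P = 0, sP = 0, ell = 0;
    vec fp, wu, uP;
    mat Lk, K0;
    if (use_geo) {
      s2P = std::exp(theta(o_ls2P)); sP = std::sqrt(s2P);
      ell = std::exp(theta(o_lell));
      uP = theta.subvec(o_uP, o_uP + m - 1);
      K0 = arma::exp(-D2 / (2.0 * ell * ell));
      K0.diag() += jitter;
      if (!arma::chol(Lk, K0, "lower"))
        return -arma::datum::inf;
      wu = Lk * uP;
      fp.set_size(n);
      for (int i = 0; i < n; ++i) fp(i) = sP * wu(loc(i));
      lp += gam_lp(theta(o_ls2P), s2P);
      lp += -ell_a * theta(o_lell) - ell_b / ell;
      lp += -0.5 * arma::dot(uP, uP);
    }

    // ---- genetic effect ----
    double s2G = std::exp(theta(o_ls2G)), sG = std::sqrt(s2G);
    vec uG = theta.subvec(o_uG, o_uG + n - 1);
    vec vG = LG * uG;
    vec G = sG * vG;
    lp += gam_lp(theta(o_ls2G), s2G);
    lp += -0.5 * arma::dot(uG, uG);

    // ---- shared/individual environments ----
    size_t ne = envs.size();
    std::vector<vec> comp(ne);
    std::vector<double> s2e(ne), se(ne);
    for (size_t e = 0; e < ne; ++e) {
      s2e[e] = std::exp(theta(o_ls2e[e])); se[e] = std::sqrt(s2e[e]);
      vec u = theta.subvec(o_ue[e], o_ue[e] + ngroups[e] - 1);
      vec c(n);
      for (int i = 0; i < n; ++i) c(i) = se[e] * u(groups[e](i));
      comp[e] = c;
      lp += gam_lp(theta(o_ls2e[e]), s2e[e]);
      lp += -0.5 * arma::dot(u, u);
    }

    // ---- interaction scale factors ----
    // prior: k | sigmas ~ N(0, c^2 / (s2G * s2e)) with c = k_sd, so the
    // implied interaction variance k^2 s2G s2e is a priori on the scale
    // of a single variance component rather than a product of two
    std::vector<double> kv(ne, 0.0);    // k indexed by environment
    std::vector<int> k_of_env(ne, -1);
    for (size_t q = 0; q < inters.size(); ++q) {
      int e = env_index(inters[q].substr(1, 1));
      double k = theta(o_k[q]);
      kv[e] = k; k_of_env[e] = q;
      double c2 = k_sd * k_sd;
      lp += -0.5 * k * k * s2G * s2e[e] / c2
            + 0.5 * (theta(o_ls2G) + theta(o_ls2e[e]));
    }

    // ---- liability and likelihood ----
    vec l = X * beta + G;
    if (use_geo) l += fp;
    for (size_t e = 0; e < ne; ++e) {
      l += comp[e];
      if (kv[e] != 0.0 || k_of_env[e] >= 0) l += kv[e] * (G % comp[e]);
    }
    vec r(n);
    for (int i = 0; i < n; ++i) {
      lp += y(i) * l(i) - log1p_exp(l(i));
      r(i) = y(i) - 1.0 / (1.0 + std::exp(-l(i)));
    }
    if (!std::isfinite(lp)) return -arma::datum::inf;

    // ---- gradients ----
    // fixed effects
    vec gbeta = X.t() * r;
    grad(o_z) = beta0_sd * gbeta(0) - z(0);
    double gt = 0.0;
    for (int j = 1; j < p; ++j) {
      grad(o_z + j) = hs_scale * tau * lam(j - 1) * gbeta(j) - z(j);
      double bg = beta(j) * gbeta(j);
      grad(o_llam + j - 1) = bg + 1.0
        - 2.0 * lam(j - 1) * lam(j - 1) / (1.0 + lam(j - 1) * lam(j - 1));
      gt += bg;
    }
    grad(o_ltau) = gt + 1.0 - 2.0 * tau * tau / (1.0 + tau * tau);

    // dl/dG includes the interaction products
    vec aG(n, arma::fill::ones);
    for (size_t e = 0; e < ne; ++e)
      if (k_of_env[e] >= 0) aG += kv[e] * comp[e];
    vec gG = r % aG;
    grad.subvec(o_uG, o_uG + n - 1) = sG * (LGt * gG) - uG;
    grad(o_ls2G) = gam_grad(theta(o_ls2G), s2G) + 0.5 * arma::dot(gG, G);

    for (size_t e = 0; e < ne; ++e) {
      vec gc = (k_of_env[e] >= 0) ? vec(r % (1.0 + kv[e] * G)) : r;
      vec acc(ngroups[e], arma::fill::zeros);
      for (int i = 0; i < n; ++i) acc(groups[e](i)) += gc(i);
      vec u = theta.subvec(o_ue[e], o_ue[e] + ngroups[e] - 1);
      grad.subvec(o_ue[e], o_ue[e] + ngroups[e] - 1) = se[e] * acc - u;
      grad(o_ls2e[e]) = gam_grad(theta(o_ls2e[e]), s2e[e])
        + 0.5 * arma::dot(gc, comp[e]);
      if (k_of_env[e] >= 0) {
        double c2 = k_sd * k_sd;
        double kpen = -0.5 * kv[e] * kv[e] * s2G * s2e[e] / c2;
        grad(o_k[k_of_env[e]]) = arma::dot(r, G % comp[e])
          - kv[e] * s2G * s2e[e] / c2;
        grad(o_ls2G) += kpen + 0.5;
        grad(o_ls2e[e]) += kpen + 0.5;
      }
    }

    if (use_geo) {
      vec acc(m, arma::fill::zeros);
      for (int i = 0; i < n; ++i) acc(loc(i)) += r(i);
      grad.subvec(o_uP, o_uP + m - 1) = sP * (Lk.t() * acc) - uP;
      double dfp = 0.0;
      for (int i = 0; i < n; ++i) dfp += r(i) * fp(i);
      grad(o_ls2P) = gam_grad(theta(o_ls2P), s2P) + 0.5 * dfp;
      // d log ell through the Cholesky factor (Murray-style backprop)
      mat dK = (K0 - jitter * arma::eye(m, m)) % (D2 / (ell * ell));
      mat M1 = arma::solve(arma::trimatl(Lk), dK);
      mat A = arma::solve(arma::trimatl(Lk), M1.t()).t();
      mat Phi = arma::trimatl(A);
      Phi.diag() *= 0.5;
      vec dwu = (Lk * Phi) * uP;
      double gell = 0.0;
      for (int j = 0; j < m; ++j) gell += acc(j) * sP * dwu(j);
      grad(o_lell) = -ell_a + ell_b / ell + gell;
    }
    return lp;
  }
};

// R-function target for generic sampling (toy oracles, calibration tests)
struct RTarget : Target {
  Function f;
  int d;
  RTarget(Function fn, int dd) : f(fn), d(dd) {}
  int dim() const { return d; }
  double logp_grad(const vec& theta, vec& grad) {
    List out = f(NumericVector(theta.begin(), theta.end()));
    grad = as<vec>(out["grad"]);
    return as<double>(out["lp"]);
  }
};

// ---------------------------------------------------------------------------
// NUTS (Hoffman & Gelman, slice variant) with dual averaging and diagonal
// mass-matrix adaptation on a Stan-like warmup window schedule.

struct Hamiltonian {
  Target& tg;
  vec inv_mass;     // diagonal inverse metric
  Hamiltonian(Target& t) : tg(t), inv_mass(t.dim(), arma::fill::ones) {}
  double H(double lp, const vec& mom) const {
    return -lp + 0.5 * arma::dot(mom % inv_mass, mom);
  }
  vec draw_mom() const {
    vec r(tg.dim());
    for (int i = 0; i < tg.dim(); ++i) r(i) = norm_rand();
    return r / arma::sqrt(inv_mass);
  }
};

struct LeapState {
  vec q, p, grad;
  double lp;
};

static void leapfrog(Hamiltonian& ham, LeapState& s, double eps) {
  s.p += 0.5 * eps * s.grad;
  s.q += eps * (ham.inv_mass % s.p);
  s.lp = ham.tg.logp_grad(s.q, s.grad);
  s.p += 0.5 * eps * s.grad;
}

struct TreeResult {
  LeapState minus, plus, prop;
  int n_valid;
  bool ok;          // no U-turn, no divergence
  double sum_accept;
  int n_accept;
  bool divergent;
};

static bool no_uturn(const Hamiltonian& ham, const LeapState& mn,
                     const LeapState& pl) {
  vec dq = pl.q - mn.q;
  return arma::dot(dq, ham.inv_mass % mn.p) >= 0 &&
         arma::dot(dq, ham.inv_mass % pl.p) >= 0;
}

static TreeResult build_tree(Hamiltonian& ham, const LeapState& s, double logu,
                             int dir, int depth, double eps, double H0) {
  TreeResult res;
  if (depth == 0) {
    LeapState s1 = s;
    leapfrog(ham, s1, dir * eps);
    double Hn = std::isfinite(s1.lp) ? ham.H(s1.lp, s1.p)
                                     : arma::datum::inf;
    res.minus = res.plus = res.prop = s1;
    res.n_valid = (logu <= -Hn) ? 1 : 0;
    res.divergent = (logu - 1000.0) > -Hn;
    res.ok = !res.divergent;
    double a = std::exp(std::min(0.0, H0 - Hn));
    if (!std::isfinite(a)) a = 0.0;
    res.sum_accept = a;
    res.n_accept = 1;
    return res;
  }
  TreeResult r1 = build_tree(ham, s, logu, dir, depth - 1, eps, H0);
  if (!r1.ok) return r1;
  TreeResult r2 = build_tree(ham, dir == -1 ? r1.minus : r1.plus, logu, dir,
                             depth - 1, eps, H0);
  TreeResult res2 = r1;
  if (dir == -1) res2.minus = r2.minus; else res2.plus = r2.plus;
  int ntot = r1.n_valid + r2.n_valid;
  if (r2.n_valid > 0 &&
      unif_rand() < (double)r2.n_valid / std::max(ntot, 1))
    res2.prop = r2.prop;
  res2.n_valid = ntot;
  res2.sum_accept = r1.sum_accept + r2.sum_accept;
  res2.n_accept = r1.n_accept + r2.n_accept;
  res2.divergent = r1.divergent || r2.divergent;
  res2.ok = r2.ok && !res2.divergent &&
            no_uturn(ham, res2.minus, res2.plus);
  return res2;
}

static double find_initial_eps(Hamiltonian& ham, const LeapState& s0) {
  double eps = 1.0;
  LeapState s = s0;
  s.p = ham.draw_mom();
  double H0 = ham.H(s.lp, s.p);
  LeapState s1 = s;
  leapfrog(ham, s1, eps);
  double H1 = std::isfinite(s1.lp) ? ham.H(s1.lp, s1.p) : arma::datum::inf;
  double dH = H0 - H1;
  int a = (dH > std::log(0.5)) ? 1 : -1;
  for (int it = 0; it < 50; ++it) {
    eps = std::pow(2.0, a) * eps;
    s1 = s;
    leapfrog(ham, s1, eps);
    H1 = std::isfinite(s1.lp) ? ham.H(s1.lp, s1.p) : arma::datum::inf;
    dH = H0 - H1;
    if (a == 1 && !(dH > std::log(0.5))) break;
    if (a == -1 && !(dH < std::log(0.5))) break;
  }
  return eps;
}

static List nuts_run(Target& tg, vec theta0, int n_warmup, int n_draws,
                     double target_accept, int max_treedepth) {
  int d = tg.dim();
  Hamiltonian ham(tg);
  LeapState cur;
  cur.q = theta0;
  cur.grad.set_size(d);
  cur.lp = tg.logp_grad(cur.q, cur.grad);
  if (!std::isfinite(cur.lp))
    stop("initial point has non-finite log-density");

  double eps = find_initial_eps(ham, cur);
  // dual averaging state
  double mu = std::log(10.0 * eps), log_eps_bar = 0.0, Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // warmup window schedule
  int init_buf = std::min(75, (int)(0.15 * n_warmup));
  int term_buf = std::min(50, (int)(0.10 * n_warmup));
  int win = std::max(1, std::min(25, n_warmup - init_buf - term_buf));
  int win_start = init_buf, win_end = std::min(win_start + win, n_warmup - term_buf);
  vec wm_mean(d, arma::fill::zeros), wm_m2(d, arma::fill::zeros);
  int wm_n = 0;

  int total = n_warmup + n_draws;
  mat draws(n_draws, d);
  IntegerVector divergent(n_draws), treedepth(n_draws);
  NumericVector accept_stat(n_draws), energy(n_draws);

  for (int it = 0; it < total; ++it) {
    bool warm = it < n_warmup;
    cur.p = ham.draw_mom();
    double H0 = ham.H(cur.lp, cur.p);
    double logu = -H0 + std::log(unif_rand());
    LeapState smin = cur, splus = cur, prop = cur;
    int n_valid = 1, depth = 0;
    bool div_this = false;
    double sum_a = 0.0; int n_a = 0;
    while (depth < max_treedepth) {
      int dir = unif_rand() < 0.5 ? -1 : 1;
      TreeResult r = build_tree(ham, dir == -1 ? smin : splus, logu, dir,
                                depth, eps, H0);
      if (dir == -1) smin = r.minus; else splus = r.plus;
      sum_a += r.sum_accept; n_a += r.n_accept;
      if (r.divergent) div_this = true;
      if (!r.ok) break;
      if (r.n_valid > 0 &&
          unif_rand() < std::min(1.0, (double)r.n_valid / n_valid))
        prop = r.prop;
      n_valid += r.n_valid;
      ++depth;
      if (!no_uturn(ham, smin, splus)) break;
    }
    cur.q = prop.q; cur.lp = prop.lp; cur.grad = prop.grad;

    double astat = n_a > 0 ? sum_a / n_a : 0.0;
    if (warm) {
      // dual averaging
      ++da_count;
      double w = 1.0 / (da_count + t0);
      Hbar = (1 - w) * Hbar + w * (target_accept - astat);
      double log_eps = mu - std::sqrt((double)da_count) / gamma * Hbar;
      double w2 = std::pow((double)da_count, -kappa);
      log_eps_bar = w2 * log_eps + (1 - w2) * log_eps_bar;
      eps = std::exp(log_eps);
      // mass-matrix accumulation within the current window
      if (it >= win_start && it < win_end) {
        ++wm_n;
        vec delta = cur.q - wm_mean;
        wm_mean += delta / wm_n;
        wm_m2 += delta % (cur.q - wm_mean);
      }
      if (it + 1 == win_end && win_end < n_warmup - term_buf + 1 && wm_n > 1) {
        vec v = wm_m2 / (wm_n - 1);
        ham.inv_mass = ((double)wm_n / (wm_n + 5.0)) * v
          + 1e-3 * (5.0 / (wm_n + 5.0));
        wm_mean.zeros(); wm_m2.zeros(); wm_n = 0;
        win *= 2;
        win_start = it + 1;
        win_end = std::min(win_start + win, n_warmup - term_buf);
        if (n_warmup - term_buf - win_end < win) win_end = n_warmup - term_buf;
        // restart step-size adaptation around the current value
        eps = find_initial_eps(ham, cur);
        mu = std::log(10.0 * eps);
        Hbar = 0.0; log_eps_bar = std::log(eps); da_count = 0;
      }
      if (it + 1 == n_warmup) eps = std::exp(log_eps_bar);
    } else {
      int k = it - n_warmup;
      draws.row(k) = cur.q.t();
      divergent[k] = div_this ? 1 : 0;
      treedepth[k] = depth;
      accept_stat[k] = astat;
      energy[k] = H0;
    }
  }
  return List::create(_["draws"] = draws, _["divergent"] = divergent,
                      _["treedepth"] = treedepth,
                      _["accept_stat"] = accept_stat,
                      _["energy"] = energy, _["stepsize"] = eps);
}

// ---------------------------------------------------------------------------
// Mean-field ADVI with Adam, one-sample reparameterization gradient.
static List advi_run(Target& tg, int iters, int n_mc, double lr) {
  int d = tg.dim();
  vec muv(d, arma::fill::zeros), om(d, arma::fill::ones);
  om *= std::log(0.1);   // start tight around zero
  vec m_mu(d, arma::fill::zeros), v_mu(d, arma::fill::zeros);
  vec m_om(d, arma::fill::zeros), v_om(d, arma::fill::zeros);
  const double b1 = 0.9, b2 = 0.999, epsA = 1e-8;
  double elbo = -arma::datum::inf;
  bool ok = true;
  vec grad(d);
  for (int it = 1; it <= iters; ++it) {
    vec g_mu(d, arma::fill::zeros), g_om(d, arma::fill::zeros);
    double acc = 0.0;
    for (int s = 0; s < n_mc; ++s) {
      vec epsv(d);
      for (int i = 0; i < d; ++i) epsv(i) = norm_rand();
      vec theta = muv + arma::exp(om) % epsv;
      double lp = tg.logp_grad(theta, grad);
      if (!std::isfinite(lp)) { lp = -1e10; grad.zeros(); }
      acc += lp;
      g_mu += grad;
      g_om += grad % epsv % arma::exp(om);
    }
    g_mu /= n_mc; g_om /= n_mc;
    g_om += 1.0;                       // entropy term
    acc = acc / n_mc + arma::accu(om); // ELBO estimate
    elbo = (it == 1) ? acc : 0.9 * elbo + 0.1 * acc;
    // Adam ascent
    m_mu = b1 * m_mu + (1 - b1) * g_mu;  v_mu = b2 * v_mu + (1 - b2) * arma::square(g_mu);
    m_om = b1 * m_om + (1 - b1) * g_om;  v_om = b2 * v_om + (1 - b2) * arma::square(g_om);
    double c1 = 1 - std::pow(b1, it), c2 = 1 - std::pow(b2, it);
    muv += lr * (m_mu / c1) / (arma::sqrt(v_mu / c2) + epsA);
    om += lr * (m_om / c1) / (arma::sqrt(v_om / c2) + epsA);
    if (!muv.is_finite() || !om.is_finite()) { ok = false; break; }
  }
  if (!std::isfinite(elbo)) ok = false;
  return List::create(_["mu"] = muv, _["omega"] = om, _["elbo"] = elbo,
                      _["converged"] = ok);
}

// ---------------------------------------------------------------------------
// Exports

// [[Rcpp::export]]
SEXP fg_build(List data) {
  XPtr<Model> ptr(new Model(data), true);
  return ptr;
}

// [[Rcpp::export]]
int fg_dim(SEXP mp) {
  XPtr<Model> ptr(mp);
  return ptr->dim();
}

// [[Rcpp::export]]
List fg_layout(SEXP mp) {
  XPtr<Model> ptr(mp);
  Model& mdl = *ptr;
  std::vector<std::string> nm;
  std::vector<int> st, len;
  nm.push_back("z_beta"); st.push_back(mdl.o_z + 1); len.push_back(mdl.p);
  nm.push_back("log_lambda"); st.push_back(mdl.o_llam + 1); len.push_back(mdl.p - 1);
  nm.push_back("log_tau"); st.push_back(mdl.o_ltau + 1); len.push_back(1);
  if (mdl.use_geo) {
    nm.push_back("log_sigma2_P"); st.push_back(mdl.o_ls2P + 1); len.push_back(1);
    nm.push_back("log_ell"); st.push_back(mdl.o_lell + 1); len.push_back(1);
    nm.push_back("u_P"); st.push_back(mdl.o_uP + 1); len.push_back(mdl.m);
  }
  nm.push_back("log_sigma2_G"); st.push_back(mdl.o_ls2G + 1); len.push_back(1);
  nm.push_back("u_G"); st.push_back(mdl.o_uG + 1); len.push_back(mdl.n);
  for (size_t e = 0; e < mdl.envs.size(); ++e) {
    nm.push_back("log_sigma2_" + mdl.envs[e]);
    st.push_back(mdl.o_ls2e[e] + 1); len.push_back(1);
    nm.push_back("u_" + mdl.envs[e]);
    st.push_back(mdl.o_ue[e] + 1); len.push_back(mdl.ngroups[e]);
  }
  for (size_t q = 0; q < mdl.inters.size(); ++q) {
    nm.push_back("k_" + mdl.inters[q]);
    st.push_back(mdl.o_k[q] + 1); len.push_back(1);
  }
  return List::create(_["block"] = nm, _["start"] = st, _["length"] = len);
}

// [[Rcpp::export]]
List fg_logp_grad(SEXP mp, NumericVector theta) {
  XPtr<Model> ptr(mp);
  vec th(theta.begin(), theta.size());
  vec grad;
  double lp = ptr->logp_grad(th, grad);
  return List::create(_["lp"] = lp,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export]]
List fg_nuts(SEXP mp, NumericVector theta0, int n_warmup, int n_draws,
             double target_accept, int max_treedepth) {
  XPtr<Model> ptr(mp);
  vec th(theta0.begin(), theta0.size());
  RNGScope scope;
  return nuts_run(*ptr, th, n_warmup, n_draws, target_accept, max_treedepth);
}

// [[Rcpp::export]]
List fg_nuts_generic(Function logp_grad_fn, NumericVector theta0,
                     int n_warmup, int n_draws, double target_accept,
                     int max_treedepth) {
  RTarget tg(logp_grad_fn, theta0.size());
  vec th(theta0.begin(), theta0.size());
  RNGScope scope;
  return nuts_run(tg, th, n_warmup, n_draws, target_accept, max_treedepth);
}

// [[Rcpp::export]]
List fg_advi(SEXP mp, int iters, int n_mc, double lr) {
  XPtr<Model> ptr(mp);
  RNGScope scope;
  return advi_run(*ptr, iters, n_mc, lr);
}
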