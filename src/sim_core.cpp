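// Core engine: per-cell metabolism/growth ODEs, bursty protein production,
// chemostat substrate dynamics, washout, division, and the one-minute
// scheduler. All randomness goes through R's RNG so set.seed() replays runs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

// gene indices (column order of the protein count matrix)
enum Gene { GI = 0, AI = 1, LG = 2, AN = 3, CRA = 4, NGENE = 5 };

struct Kinetics {
  double B0, c;
  double V_Gi, K_Gi;               // glucose uptake, K in mM
  double V_Ai, K_Ai;               // acetate uptake, K in mM
  double V_Lg, K_Lg;               // lower glycolysis, K in mmol g^-1 (pep)
  double V_An, K_fbp_An, K_pep_An, n_An, m_pep_An, L_An;  // MWC anabolism
  double n_Cra, K_Cra_fbp_ref;     // Hill repression of Cra by fbp
  double K_CraA_DNA;               // molecules g^-1
  double alpha_Ai_on, alpha_Ai_off;
  double e_ref;                    // reference enzyme copies per newborn
};

static Kinetics kin_from_list(const List& kl) {
  Kinetics k;
  k.B0 = as<double>(kl["B0"]);
  k.c = as<double>(kl["c"]);
  k.V_Gi = as<double>(kl["V_Gi"]); k.K_Gi = as<double>(kl["K_Gi"]);
  k.V_Ai = as<double>(kl["V_Ai"]); k.K_Ai = as<double>(kl["K_Ai"]);
  k.V_Lg = as<double>(kl["V_Lg"]); k.K_Lg = as<double>(kl["K_Lg"]);
  k.V_An = as<double>(kl["V_An"]);
  k.K_fbp_An = as<double>(kl["K_fbp_An"]);
  k.K_pep_An = as<double>(kl["K_pep_An"]);
  k.n_An = as<double>(kl["n_An"]);
  k.m_pep_An = as<double>(kl["m_pep_An"]);
  k.L_An = as<double>(kl["L_An"]);
  k.n_Cra = as<double>(kl["n_Cra"]);
  k.K_Cra_fbp_ref = as<double>(kl["K_Cra_fbp"]);
  k.K_CraA_DNA = as<double>(kl["K_CraA_DNA"]);
  k.alpha_Ai_on = as<double>(kl["alpha_Ai_on"]);
  k.alpha_Ai_off = as<double>(kl["alpha_Ai_off"]);
  k.e_ref = as<double>(kl["e_ref"]);
  return k;
}

struct Rates { double J_Gi, J_Ai, J_Lg, J_An, mu; };

// specific reaction rates (mmol g^-1 h^-1); enzyme activity scales with
// copy-number concentration relative to e_ref copies per newborn mass
static inline Rates reaction_rates(const Kinetics& k, double pep, double fbp,
                                   double B, const double* counts,
                                   double glc, double ace) {
  const double cref = k.e_ref / k.B0;  // reference molecules g^-1
  Rates r;
  r.J_Gi = k.V_Gi * (counts[GI] / B / cref) * glc / (k.K_Gi + glc);
  r.J_Ai = k.V_Ai * (counts[AI] / B / cref) * ace / (k.K_Ai + ace);
  r.J_Lg = k.V_Lg * (counts[LG] / B / cref) * pep / (k.K_Lg + pep);
  const double f = fbp / k.K_fbp_An;
  const double Lp = k.L_An / std::pow(1.0 + pep / k.K_pep_An, k.m_pep_An);
  r.J_An = k.V_An * (counts[AN] / B / cref) *
           f * std::pow(1.0 + f, k.n_An - 1.0) /
           (std::pow(1.0 + f, k.n_An) + Lp);
  r.mu = k.c * r.J_An;
  return r;
}

static inline double cra_activity(double cra, double fbp, double K, double n) {
  if (cra <= 0.0) return 0.0;
  const double Kn = std::pow(K, n);
  return cra * Kn / (std::pow(fbp, n) + Kn);
}

static inline double promoter_occupancy(const Kinetics& k, double craA, double B) {
  const double conc = craA / B;
  return conc / (conc + k.K_CraA_DNA);
}

// ---- adaptive Cash-Karp RK45 for one cell over dt ------------------------
// state y = (pep, fbp, B, uptake_glc, uptake_ace); proteins and external
// substrate concentrations held fixed within the step (operator splitting)

struct CellODE {
  const Kinetics* k;
  const double* counts;
  double glc, ace;
  void deriv(const double* y, double* dy) const {
    double pep = y[0] > 0 ? y[0] : 0.0;
    double fbp = y[1] > 0 ? y[1] : 0.0;
    double B = y[2];
    Rates r = reaction_rates(*k, pep, fbp, B, counts, glc, ace);
    dy[0] = 0.5 * r.J_Ai - r.J_Lg - r.mu * pep;
    dy[1] = r.J_Gi + 0.5 * r.J_Lg - r.J_An - r.mu * fbp;
    dy[2] = r.mu * B;
    dy[3] = r.J_Gi * B;
    dy[4] = r.J_Ai * B;
  }
};

static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0/5, 0, 0, 0, 0},
  {3.0/40, 9.0/40, 0, 0, 0},
  {3.0/10, -9.0/10, 6.0/5, 0, 0},
  {-11.0/54, 5.0/2, -70.0/27, 35.0/27, 0},
  {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}};
static const double CK_C5[6] = {37.0/378, 0, 250.0/621, 125.0/594, 0, 512.0/1771};
static const double CK_C4[6] = {2825.0/27648, 0, 18575.0/48384, 13525.0/55296,
                                277.0/14336, 1.0/4};

// returns false on failure (step size underflow)
static bool integrate_cell_ode(const CellODE& ode, double* y, double dt,
                               double B0) {
  const int NS = 5;
  double t = 0.0, h = dt;
  // error scales: concentrations ~O(1), mass and uptakes ~O(B0)
  double scale[NS] = {1e-9, 1e-9, 1e-9 * B0, 1e-9 * B0, 1e-9 * B0};
  double rtol = 1e-8;
  int iter = 0;
  while (t < dt) {
    if (h > dt - t) h = dt - t;
    double kst[6][NS], ytmp[NS], dy[NS];
    ode.deriv(y, kst[0]);
    for (int s = 1; s < 6; ++s) {
      for (int i = 0; i < NS; ++i) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += CK_B[s][j] * kst[j][i];
        ytmp[i] = y[i] + h * acc;
      }
      ode.deriv(ytmp, kst[s]);
    }
    double err = 0.0;
    double y5[NS];
    for (int i = 0; i < NS; ++i) {
      double a5 = 0.0, a4 = 0.0;
      for (int s = 0; s < 6; ++s) {
        a5 += CK_C5[s] * kst[s][i];
        a4 += CK_C4[s] * kst[s][i];
      }
      y5[i] = y[i] + h * a5;
      double e = std::fabs(h * (a5 - a4)) /
                 (scale[i] + rtol * std::fabs(y[i]));
      if (e > err) err = e;
    }
    if (err <= 1.0 || h < dt * 1e-8) {
      t += h;
      for (int i = 0; i < NS; ++i) y[i] = y5[i];
      // clip tiny solver undershoots of the metabolite pools
      for (int i = 0; i < 2; ++i) if (y[i] < 0) y[i] = 0.0;
      double grow = err > 1e-12 ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (grow > 5.0) grow = 5.0;
      h *= grow;
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.25));
    }
    if (++iter > 100000) return false;
  }
  return true;
}

// ---- population containers ----------------------------------------------

struct Pop {
  std::vector<double> B, pep, fbp;
  std::vector<double> counts;      // NGENE per cell, row-major [cell*NGENE+g]
  std::vector<int> group;
  std::vector<double> lineage;
  size_t n() const { return B.size(); }
};

struct GroupPars {
  // per group: allele (K_Cra_fbp) and per-gene expression parameters
  std::vector<double> K_cra;                 // length n_groups
  std::vector<double> alpha, beta, gamma;    // n_groups x NGENE, row-major
  int n_groups;
  double a(int g, int gene) const { return alpha[g * NGENE + gene]; }
  double b(int g, int gene) const { return beta[g * NGENE + gene]; }
  double gp(int g, int gene) const { return gamma[g * NGENE + gene]; }
};

static Pop pop_from_list(const List& pl) {
  Pop p;
  NumericVector B = pl["B"], pep = pl["pep"], fbp = pl["fbp"], lin = pl["lineage"];
  IntegerVector grp = pl["group"];
  NumericMatrix cnt = pl["counts"];
  size_t n = B.size();
  p.B.assign(B.begin(), B.end());
  p.pep.assign(pep.begin(), pep.end());
  p.fbp.assign(fbp.begin(), fbp.end());
  p.group.assign(grp.begin(), grp.end());
  p.lineage.assign(lin.begin(), lin.end());
  p.counts.resize(n * NGENE);
  for (size_t i = 0; i < n; ++i)
    for (int g = 0; g < NGENE; ++g) p.counts[i * NGENE + g] = cnt(i, g);
  return p;
}

static List pop_to_list(const Pop& p) {
  size_t n = p.n();
  NumericMatrix cnt(n, NGENE);
  for (size_t i = 0; i < n; ++i)
    for (int g = 0; g < NGENE; ++g) cnt(i, g) = p.counts[i * NGENE + g];
  colnames(cnt) = CharacterVector::create("Gi", "Ai", "Lg", "An", "Cra");
  return List::create(_["B"] = NumericVector(p.B.begin(), p.B.end()),
                      _["pep"] = NumericVector(p.pep.begin(), p.pep.end()),
                      _["fbp"] = NumericVector(p.fbp.begin(), p.fbp.end()),
                      _["counts"] = cnt,
                      _["group"] = IntegerVector(p.group.begin(), p.group.end()),
                      _["lineage"] = NumericVector(p.lineage.begin(), p.lineage.end()));
}

static GroupPars groups_from_list(const List& gl) {
  GroupPars g;
  NumericVector K = gl["K_cra_fbp"];
  NumericMatrix a = gl["alpha"], b = gl["beta"], gm = gl["gamma"];
  g.n_groups = K.size();
  g.K_cra.assign(K.begin(), K.end());
  g.alpha.resize(g.n_groups * NGENE);
  g.beta.resize(g.n_groups * NGENE);
  g.gamma.resize(g.n_groups * NGENE);
  for (int i = 0; i < g.n_groups; ++i)
    for (int j = 0; j < NGENE; ++j) {
      g.alpha[i * NGENE + j] = a(i, j);
      g.beta[i * NGENE + j] = b(i, j);
      g.gamma[i * NGENE + j] = gm(i, j);
    }
  return g;
}

// ---- stochastic protein kernels -----------------------------------------

// one burst: geometric on {0,1,2,...} with mean beta, the burst law under
// which the stationary copy-number distribution is exactly NB(alpha, beta)
// with variance alpha*beta*(beta+1)
static inline double burst_size(double beta) {
  return R::rgeom(1.0 / (1.0 + beta));
}

static inline double sample_production(double k1, double beta, double dt) {
  if (k1 <= 0.0) return 0.0;
  int m = (int)R::rpois(k1 * dt);
  double inc = 0.0;
  for (int i = 0; i < m; ++i) inc += burst_size(beta);
  return inc;
}

// ---- scheduler sub-steps -------------------------------------------------

struct StepCounters { int n_wash = 0, n_div = 0, n_clip = 0; };

// (i) integrate all cells, return summed uptake (mmol) per substrate
static void integrate_all(const Kinetics& k, Pop& p, double glc, double ace,
                          double dt, double& upG, double& upA) {
  upG = 0.0; upA = 0.0;
  for (size_t i = 0; i < p.n(); ++i) {
    CellODE ode{&k, &p.counts[i * NGENE], glc, ace};
    double y[5] = {p.pep[i], p.fbp[i], p.B[i], 0.0, 0.0};
    if (!integrate_cell_ode(ode, y, dt, k.B0))
      stop("cell ODE integration failed (cell %d, B=%g, pep=%g, fbp=%g)",
           (int)i + 1, p.B[i], p.pep[i], p.fbp[i]);
    p.pep[i] = y[0]; p.fbp[i] = y[1]; p.B[i] = y[2];
    upG += y[3]; upA += y[4];
  }
}

// substrate balance: exact exponential relaxation toward inflow plus the
// per-step debit of the summed cellular uptake
static void substrate_update(double& S, double S_in_active, double D,
                             double kappa, double uptake, double dt,
                             StepCounters& sc) {
  double relaxed = S_in_active + (S - S_in_active) * std::exp(-D * dt);
  double out = relaxed - kappa * uptake;
  if (out < 0.0) {
    if (-out > 0.01 * (S + 1e-12))
      stop("substrate overshoot: uptake exceeds pool by >1%% in one step");
    out = 0.0;
    sc.n_clip++;
  }
  S = out;
}

// (ii) stochastic protein production (+ optional active degradation)
static void produce_proteins(const Kinetics& k, const GroupPars& gp, Pop& p,
                             double glc, double ace, double dt) {
  for (size_t i = 0; i < p.n(); ++i) {
    double* cnt = &p.counts[i * NGENE];
    int g = p.group[i];
    Rates r = reaction_rates(k, p.pep[i], p.fbp[i], p.B[i], cnt, glc, ace);
    double dil = r.mu * p.B[i] / k.B0;
    for (int gene = 0; gene < NGENE; ++gene) {
      double alpha;
      if (gene == AI) {
        double craA = cra_activity(cnt[CRA], p.fbp[i], gp.K_cra[g], k.n_Cra);
        double pb = promoter_occupancy(k, craA, p.B[i]);
        alpha = k.alpha_Ai_off * (1.0 - pb) + k.alpha_Ai_on * pb;
      } else {
        alpha = gp.a(g, gene);
      }
      double gam = gp.gp(g, gene);
      double k1 = alpha * (dil + gam);
      cnt[gene] += sample_production(k1, gp.b(g, gene), dt);
      if (gam > 0.0 && cnt[gene] > 0.0)
        cnt[gene] = R::rbinom(cnt[gene], std::exp(-gam * dt));
    }
  }
}

// (iii) random washout: survival probability exp(-D dt)
static void washout(Pop& p, double D, double dt, StepCounters& sc) {
  if (D <= 0.0 || p.n() == 0) return;
  double psurv = std::exp(-D * dt);
  size_t keep = 0;
  for (size_t i = 0; i < p.n(); ++i) {
    if (unif_rand() < psurv) {
      if (keep != i) {
        p.B[keep] = p.B[i]; p.pep[keep] = p.pep[i]; p.fbp[keep] = p.fbp[i];
        p.group[keep] = p.group[i]; p.lineage[keep] = p.lineage[i];
        for (int g = 0; g < NGENE; ++g)
          p.counts[keep * NGENE + g] = p.counts[i * NGENE + g];
      }
      ++keep;
    } else {
      sc.n_wash++;
    }
  }
  p.B.resize(keep); p.pep.resize(keep); p.fbp.resize(keep);
  p.group.resize(keep); p.lineage.resize(keep); p.counts.resize(keep * NGENE);
}

// (iv) division at doubled mass; binomial partition of each protein;
// metabolite concentrations (per mass) inherited unchanged
static void divide(const Kinetics& k, Pop& p, double& lineage_counter,
                   StepCounters& sc, bool lineage_mode) {
  size_t n0 = p.n();
  for (size_t i = 0; i < n0; ++i) {
    if (p.B[i] >= 2.0 * k.B0) {
      sc.n_div++;
      double newc[NGENE];
      for (int g = 0; g < NGENE; ++g) {
        double tot = p.counts[i * NGENE + g];
        double d1 = tot > 0 ? R::rbinom(tot, 0.5) : 0.0;
        newc[g] = tot - d1;
        p.counts[i * NGENE + g] = d1;
      }
      double Bd = p.B[i] / 2.0;
      p.B[i] = Bd;
      if (lineage_mode) {
        // follow one daughter chosen uniformly at random
        if (unif_rand() < 0.5)
          for (int g = 0; g < NGENE; ++g) p.counts[i * NGENE + g] = newc[g];
      } else {
        p.B.push_back(Bd);
        p.pep.push_back(p.pep[i]);
        p.fbp.push_back(p.fbp[i]);
        p.group.push_back(p.group[i]);
        p.lineage.push_back(++lineage_counter);
        for (int g = 0; g < NGENE; ++g) p.counts.push_back(newc[g]);
      }
    }
  }
}

// ---- exported kernels ----------------------------------------------------

// [[Rcpp::export]]
List cpp_reaction_rates(double pep, double fbp, double B, NumericVector counts,
                        double glc, double ace, List kin) {
  Kinetics k = kin_from_list(kin);
  Rates r = reaction_rates(k, pep, fbp, B, REAL(counts), glc, ace);
  return List::create(_["J_Gi"] = r.J_Gi, _["J_Ai"] = r.J_Ai,
                      _["J_Lg"] = r.J_Lg, _["J_An"] = r.J_An, _["mu"] = r.mu);
}

// [[Rcpp::export]]
List cpp_integrate_cell(double pep, double fbp, double B, NumericVector counts,
                        double glc, double ace, double dt, List kin) {
  Kinetics k = kin_from_list(kin);
  CellODE ode{&k, REAL(counts), glc, ace};
  double y[5] = {pep, fbp, B, 0.0, 0.0};
  if (!integrate_cell_ode(ode, y, dt, k.B0))
    stop("cell ODE integration failed (B=%g, pep=%g, fbp=%g)", B, pep, fbp);
  return List::create(_["pep"] = y[0], _["fbp"] = y[1], _["B"] = y[2],
                      _["uptake_glucose"] = y[3], _["uptake_acetate"] = y[4]);
}

// one full scheduler step on an R-side population (used by step_population)
// [[Rcpp::export]]
List cpp_step(List pop, List kin, List groups, double glc, double ace,
              double S_in_glc, double S_in_ace, double D, double kappa,
              double dt, double lineage_counter) {
  Kinetics k = kin_from_list(kin);
  GroupPars gp = groups_from_list(groups);
  Pop p = pop_from_list(pop);
  StepCounters sc;
  double upG, upA;
  integrate_all(k, p, glc, ace, dt, upG, upA);
  substrate_update(glc, S_in_glc, D, kappa, upG, dt, sc);
  substrate_update(ace, S_in_ace, D, kappa, upA, dt, sc);
  produce_proteins(k, gp, p, glc, ace, dt);
  washout(p, D, dt, sc);
  divide(k, p, lineage_counter, sc, false);
  return List::create(_["pop"] = pop_to_list(p), _["glucose"] = glc,
                      _["acetate"] = ace, _["n_washed"] = sc.n_wash,
                      _["n_divided"] = sc.n_div, _["n_clipped"] = sc.n_clip,
                      _["lineage_counter"] = lineage_counter,
                      _["uptake_glucose"] = upG, _["uptake_acetate"] = upA);
}

// full simulation loop
// substrate_in: integer per step, 0 = glucose inflow, 1 = acetate inflow
// [[Rcpp::export]]
List cpp_run(List pop, List kin, List groups, IntegerVector substrate_in,
             double glc0, double ace0, double S_in_glc, double S_in_ace,
             double D, double kappa, double dt, int log_every,
             NumericVector snapshot_steps, bool stop_on_fixation,
             double bottleneck_from, double bottleneck_to) {
  Kinetics k = kin_from_list(kin);
  GroupPars gp = groups_from_list(groups);
  Pop p = pop_from_list(pop);
  int n_steps = substrate_in.size();
  int ng = gp.n_groups;
  double glc = glc0, ace = ace0;
  double lineage_counter = 0.0;
  for (size_t i = 0; i < p.n(); ++i)
    if (p.lineage[i] > lineage_counter) lineage_counter = p.lineage[i];

  std::vector<double> log_t, log_glc, log_ace;
  std::vector<int> log_wash, log_div;
  std::vector<std::vector<int>> log_n(ng);
  List snapshots;
  std::vector<double> snap_at(snapshot_steps.begin(), snapshot_steps.end());
  std::vector<double> min_bneck(ng, R_PosInf), min_all(ng, R_PosInf);
  std::string stop_reason = "horizon";
  double t_stop = n_steps * dt, t_fix = NA_REAL;
  int winner = NA_INTEGER;

  std::vector<int> gcount(ng);
  auto count_groups = [&]() {
    std::fill(gcount.begin(), gcount.end(), 0);
    for (size_t i = 0; i < p.n(); ++i) gcount[p.group[i]]++;
  };
  auto log_state = [&](double t, int nw, int nd) {
    count_groups();
    log_t.push_back(t);
    for (int g = 0; g < ng; ++g) log_n[g].push_back(gcount[g]);
    log_glc.push_back(glc); log_ace.push_back(ace);
    log_wash.push_back(nw); log_div.push_back(nd);
  };
  auto take_snapshot = [&](double t) {
    size_t n = p.n();
    NumericVector B(n), pep(n), fbp(n), mu(n);
    IntegerVector grp(n);
    NumericMatrix cnt(n, NGENE);
    for (size_t i = 0; i < n; ++i) {
      B[i] = p.B[i]; pep[i] = p.pep[i]; fbp[i] = p.fbp[i];
      grp[i] = p.group[i] + 1;
      Rates r = reaction_rates(k, p.pep[i], p.fbp[i], p.B[i],
                               &p.counts[i * NGENE], glc, ace);
      mu[i] = r.mu;
      for (int g = 0; g < NGENE; ++g) cnt(i, g) = p.counts[i * NGENE + g];
    }
    colnames(cnt) = CharacterVector::create("Gi", "Ai", "Lg", "An", "Cra");
    snapshots.push_back(List::create(_["time"] = t, _["B"] = B, _["pep"] = pep,
                                     _["fbp"] = fbp, _["mu"] = mu,
                                     _["group"] = grp, _["counts"] = cnt));
  };

  log_state(0.0, 0, 0);
  double t_logged = 0.0, t_now = 0.0;
  StepCounters sc_last;
  size_t next_snap = 0;
  while (next_snap < snap_at.size() && snap_at[next_snap] <= 0) {
    take_snapshot(0.0);
    ++next_snap;
  }

  for (int s = 0; s < n_steps; ++s) {
    double t = (s + 1) * dt;
    t_now = t;
    double S_in_g = substrate_in[s] == 0 ? S_in_glc : 0.0;
    double S_in_a = substrate_in[s] == 1 ? S_in_ace : 0.0;
    StepCounters sc;
    double upG, upA;
    integrate_all(k, p, glc, ace, dt, upG, upA);
    substrate_update(glc, S_in_g, D, kappa, upG, dt, sc);
    substrate_update(ace, S_in_a, D, kappa, upA, dt, sc);
    produce_proteins(k, gp, p, glc, ace, dt);
    washout(p, D, dt, sc);
    divide(k, p, lineage_counter, sc, false);

    count_groups();
    for (int g = 0; g < ng; ++g) {
      if (gcount[g] < min_all[g]) min_all[g] = gcount[g];
      if (t > bottleneck_from && t <= bottleneck_to &&
          gcount[g] < min_bneck[g]) min_bneck[g] = gcount[g];
    }
    sc_last = sc;
    if ((s + 1) % log_every == 0 || s == n_steps - 1) {
      log_state(t, sc.n_wash, sc.n_div);
      t_logged = t;
    }
    while (next_snap < snap_at.size() && snap_at[next_snap] <= t + 1e-9) {
      take_snapshot(t);
      ++next_snap;
    }
    if (p.n() == 0) {
      stop_reason = "extinction"; t_stop = t;
      break;
    }
    if (stop_on_fixation && ng > 1) {
      int alive = 0, wg = -1;
      for (int g = 0; g < ng; ++g) if (gcount[g] > 0) { alive++; wg = g; }
      if (alive == 1) {
        stop_reason = "fixation"; t_fix = t; t_stop = t; winner = wg + 1;
        break;
      }
    }
    if (s % 600 == 0) Rcpp::checkUserInterrupt();
  }

  // terminal state is always logged, even when a stop condition fired
  // between logging points
  if (t_now > t_logged + 1e-12)
    log_state(t_now, sc_last.n_wash, sc_last.n_div);

  int nl = log_t.size();
  List logdf = List::create(_["time"] = NumericVector(log_t.begin(), log_t.end()),
                            _["glucose"] = NumericVector(log_glc.begin(), log_glc.end()),
                            _["acetate"] = NumericVector(log_ace.begin(), log_ace.end()),
                            _["n_washed"] = IntegerVector(log_wash.begin(), log_wash.end()),
                            _["n_divided"] = IntegerVector(log_div.begin(), log_div.end()));
  IntegerMatrix nmat(nl, ng);
  for (int g = 0; g < ng; ++g)
    for (int i = 0; i < nl; ++i) nmat(i, g) = log_n[g][i];
  NumericVector mb(ng), ma(ng);
  for (int g = 0; g < ng; ++g) {
    mb[g] = R_finite(min_bneck[g]) ? min_bneck[g] : NA_REAL;
    ma[g] = R_finite(min_all[g]) ? min_all[g] : NA_REAL;
  }
  return List::create(_["log"] = logdf, _["n_by_group"] = nmat,
                      _["snapshots"] = snapshots,
                      _["final_pop"] = pop_to_list(p),
                      _["stop_reason"] = stop_reason, _["t_stop"] = t_stop,
                      _["t_fix"] = t_fix, _["winner_group"] = winner,
                      _["min_bottleneck"] = mb, _["min_overall"] = ma);
}

// single-lineage engine: fixed cohort, constant substrate, no washout,
// one daughter kept at random at each division
// [[Rcpp::export]]
List cpp_run_lineages(List pop, List kin, List groups, double glc, double ace,
                      double dt, int n_steps, int log_every) {
  Kinetics k = kin_from_list(kin);
  GroupPars gp = groups_from_list(groups);
  Pop p = pop_from_list(pop);
  size_t n = p.n();
  int nl = n_steps / log_every + 1;
  NumericMatrix mu_log(nl, n);
  NumericVector t_log(nl);
  double lc = 0.0;
  int row = 0;
  auto log_mu = [&](double t) {
    for (size_t i = 0; i < n; ++i) {
      Rates r = reaction_rates(k, p.pep[i], p.fbp[i], p.B[i],
                               &p.counts[i * NGENE], glc, ace);
      mu_log(row, i) = r.mu;
    }
    t_log[row] = t;
    ++row;
  };
  log_mu(0.0);
  for (int s = 0; s < n_steps; ++s) {
    StepCounters sc;
    double upG, upA;
    integrate_all(k, p, glc, ace, dt, upG, upA);
    produce_proteins(k, gp, p, glc, ace, dt);
    divide(k, p, lc, sc, true);
    if ((s + 1) % log_every == 0 && row < nl) log_mu((s + 1) * dt);
    if (s % 600 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = t_log, _["mu"] = mu_log,
                      _["final_pop"] = pop_to_list(p));
}
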