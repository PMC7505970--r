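// Hybrid stochastic-deterministic (piecewise deterministic Markov process)
// simulator of microbial decomposition on a lattice of microsites.
//
// Between events, SOC (c), DOC (d) and enzymes (z) of every microsite follow
// deterministic mass-balance flows integrated with an adaptive explicit
// Euler scheme, and each cell accrues storage at rate
// (1 - phi) gamma_M V_max d/(K_m + d) omega_M. Cells divide deterministically
// when storage reaches omega_M; cell death is the only stochastic jump, with
// one exponential clock at rate d_M * (total cells). Microsites are coupled
// by an explicit-Euler DOC diffusion stencil (Neumann boundaries), newborn
// dispersal and micro-disturbances.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Par {
  int L;
  double V, k;
  double I_C, I_D, l_C, l_D, theta, V_max, K_m, d_M, d_Z;
  double gamma_M, gamma_Z, omega_M, l, p;
  double p_disp, p_open, p_mut, sigma_mut, sigma_diff, tau_diff;
};

struct Site {
  double c, d, z;
  std::vector<double> S;      // per-cell stored reserve (mg)
  std::vector<double> phi;    // per-cell trait
  std::vector<int> strain;    // per-cell strain id (> 0)
  double sumphi;              // running sum of phi over cells
};

struct Newborn { int site; double S; double phi; int strain; };

inline double truncated_normal(double mean, double sd) {
  // rejection sampling keeps the trait in [0, 1] without boundary atoms
  for (int it = 0; it < 10000; ++it) {
    double v = mean + sd * norm_rand();
    if (v >= 0.0 && v <= 1.0) return v;
  }
  return mean; // sd == 0 or pathological; never reached with sane sigma_mut
}

} // namespace

// [[Rcpp::export(name = ".sim_hybrid_cpp")]]
List sim_hybrid_cpp(List par_, NumericVector c0, NumericVector d0,
                    NumericVector z0, List cells0, double t0, double t_max,
                    double record_every, int n_track, int next_strain_id,
                    bool fixed_tau, bool zero_reset_division,
                    bool route_death_p_to_doc, int stop_strain,
                    bool stop_on_extinction) {
  Par P;
  P.L = as<int>(par_["L"]);
  P.V = as<double>(par_["V"]);       P.k = as<double>(par_["k"]);
  P.I_C = as<double>(par_["I_C"]);   P.I_D = as<double>(par_["I_D"]);
  P.l_C = as<double>(par_["l_C"]);   P.l_D = as<double>(par_["l_D"]);
  P.theta = as<double>(par_["theta"]); P.V_max = as<double>(par_["V_max"]);
  P.K_m = as<double>(par_["K_m"]);   P.d_M = as<double>(par_["d_M"]);
  P.d_Z = as<double>(par_["d_Z"]);   P.gamma_M = as<double>(par_["gamma_M"]);
  P.gamma_Z = as<double>(par_["gamma_Z"]); P.omega_M = as<double>(par_["omega_M"]);
  P.l = as<double>(par_["l"]);       P.p = as<double>(par_["p"]);
  P.p_disp = as<double>(par_["p_disp"]); P.p_open = as<double>(par_["p_open"]);
  P.p_mut = as<double>(par_["p_mut"]); P.sigma_mut = as<double>(par_["sigma_mut"]);
  P.sigma_diff = as<double>(par_["sigma_diff"]);
  P.tau_diff = as<double>(par_["tau_diff"]);

  const int L = P.L, n_sites = L * L;
  const double site_area = std::pow(P.V * P.k, 2.0 / 3.0);

  // stability cap on the diffusion step (4 f < 1, with safety factor 1/2)
  double tau_eff = P.tau_diff;
  if (P.sigma_diff > 0.0 && L > 1) {
    double tau_stab = site_area / (4.0 * P.sigma_diff);
    tau_eff = std::min(tau_eff, 0.5 * tau_stab);
  }

  // state
  std::vector<Site> sites(n_sites);
  long M_tot = 0;
  for (int s = 0; s < n_sites; ++s) {
    sites[s].c = c0[s]; sites[s].d = d0[s]; sites[s].z = z0[s];
    List cl = cells0[s];
    NumericVector S = cl["S"], phi = cl["phi"];
    IntegerVector st = cl["strain"];
    int m = S.size();
    sites[s].S.assign(S.begin(), S.end());
    sites[s].phi.assign(phi.begin(), phi.end());
    sites[s].strain.assign(st.begin(), st.end());
    sites[s].sumphi = 0.0;
    for (int j = 0; j < m; ++j) sites[s].sumphi += phi[j];
    M_tot += m;
  }

  // tracked strain counts
  std::vector<long> cnt(n_track + 1, 0);
  long cnt_other = 0;
  for (int s = 0; s < n_sites; ++s)
    for (size_t j = 0; j < sites[s].strain.size(); ++j) {
      int id = sites[s].strain[j];
      if (id >= 1 && id <= n_track) cnt[id]++; else cnt_other++;
    }

  // neighbours (Neumann boundaries: only existing neighbours)
  std::vector<std::vector<int>> nb(n_sites);
  for (int r = 0; r < L; ++r)
    for (int cc = 0; cc < L; ++cc) {
      int s = r * L + cc;
      if (r > 0)     nb[s].push_back(s - L);
      if (r < L - 1) nb[s].push_back(s + L);
      if (cc > 0)     nb[s].push_back(s - 1);
      if (cc < L - 1) nb[s].push_back(s + 1);
    }

  // carbon ledger and event counters
  double cum_input = 0.0, cum_leach = 0.0, cum_resp = 0.0, cum_discard = 0.0;
  long births = 0, deaths = 0, disturbances = 0, disturbance_deaths = 0,
       dispersals = 0, mutations = 0, clips = 0, n_steps = 0;

  // strain registry of mutants founded during the run
  std::vector<int> reg_id, reg_parent;
  std::vector<double> reg_phi, reg_t;

  // records
  std::vector<double> rec_t, rec_c, rec_d, rec_z, rec_res, rec_mean, rec_min,
      rec_max, rec_in, rec_le, rec_rs;
  std::vector<long> rec_M;
  std::vector<std::vector<long>> rec_cnt(n_track);

  auto record = [&](double t) {
    double ct = 0, dt_ = 0, zt = 0, rs = 0, sp = 0;
    double mn = R_PosInf, mx = R_NegInf;
    for (int s = 0; s < n_sites; ++s) {
      ct += sites[s].c; dt_ += sites[s].d; zt += sites[s].z;
      for (size_t j = 0; j < sites[s].S.size(); ++j) {
        rs += sites[s].S[j]; sp += sites[s].phi[j];
        if (sites[s].phi[j] < mn) mn = sites[s].phi[j];
        if (sites[s].phi[j] > mx) mx = sites[s].phi[j];
      }
    }
    rec_t.push_back(t); rec_c.push_back(ct); rec_d.push_back(dt_);
    rec_z.push_back(zt); rec_M.push_back(M_tot); rec_res.push_back(rs);
    rec_mean.push_back(M_tot > 0 ? sp / M_tot : NA_REAL);
    rec_min.push_back(M_tot > 0 ? mn : NA_REAL);
    rec_max.push_back(M_tot > 0 ? mx : NA_REAL);
    rec_in.push_back(cum_input); rec_le.push_back(cum_leach);
    rec_rs.push_back(cum_resp);
    for (int i = 0; i < n_track; ++i) rec_cnt[i].push_back(cnt[i + 1]);
  };

  // deterministic flows over one interval h_tot for one site; accumulates
  // the per-cell uptake integral A (mg of DOC taken up per cell)
  std::vector<double> A(n_sites, 0.0);
  auto integrate_site = [&](Site &st, double h_tot) {
    double rem = h_tot;
    const double h_min = h_tot / 256.0;
    int m = (int)st.S.size();
    while (rem > 0.0) {
      double upt_f = P.V_max * st.d / (P.K_m + st.d);   // 1/h per unit biomass
      double upt = upt_f * P.omega_M * m;               // mg/h out of DOC
      double dec = P.theta * st.z * st.c;               // mg/h SOC -> DOC
      double deact = P.d_Z * st.z;                      // mg/h enzyme decay
      double prodz = P.gamma_Z * upt_f * P.omega_M * st.sumphi;
      double dc = P.I_C - P.l_C * st.c - dec;
      double dd = P.I_D - P.l_D * st.d + dec + (1.0 - P.l) * deact - upt;
      double dz = prodz - deact;
      double h = rem;
      if (dd < 0.0 && st.d > 0.0) h = std::min(h, 0.01 * st.d / (-dd));
      if (dc < 0.0 && st.c > 0.0) h = std::min(h, 0.5 * st.c / (-dc));
      if (dz < 0.0 && st.z > 0.0) h = std::min(h, 0.5 * st.z / (-dz));
      if (h < h_min) h = h_min;
      if (h > rem) h = rem;
      double res_gain = P.gamma_M * upt_f * P.omega_M * (m - st.sumphi) * h;
      st.c += h * dc; st.d += h * dd; st.z += h * dz;
      cum_input += h * (P.I_C + P.I_D);
      cum_leach += h * (P.l_C * (st.c - h * dc) + P.l_D * (st.d - h * dd) +
                        P.l * deact);
      cum_resp += h * upt - h * prodz - res_gain;
      if (m > 0) A[(int)(&st - &sites[0])] += h * upt_f * P.omega_M;
      if (st.c < 0.0) { cum_discard += st.c; st.c = 0.0; clips++; }
      if (st.d < 0.0) { cum_discard += st.d; st.d = 0.0; clips++; }
      if (st.z < 0.0) { cum_discard += st.z; st.z = 0.0; clips++; }
      rem -= h;
    }
  };

  auto recycle_mass = [&](Site &st, double mass) {
    // dead-cell (or disturbed) carbon: fraction l leached, of the remainder
    // p to SOC and 1 - p to DOC (optionally the literal algorithmic routing
    // with p to DOC instead)
    double keep = (1.0 - P.l) * mass;
    cum_leach += P.l * mass;
    if (route_death_p_to_doc) {
      st.d += P.p * keep; st.c += (1.0 - P.p) * keep;
    } else {
      st.c += P.p * keep; st.d += (1.0 - P.p) * keep;
    }
  };

  auto remove_cell = [&](Site &st, int j) {
    int id = st.strain[j];
    if (id >= 1 && id <= n_track) cnt[id]--; else cnt_other--;
    st.sumphi -= st.phi[j];
    st.S[j] = st.S.back(); st.S.pop_back();
    st.phi[j] = st.phi.back(); st.phi.pop_back();
    st.strain[j] = st.strain.back(); st.strain.pop_back();
    M_tot--;
  };

  auto add_cell = [&](int s, double S, double phi, int strain) {
    sites[s].S.push_back(S); sites[s].phi.push_back(phi);
    sites[s].strain.push_back(strain); sites[s].sumphi += phi;
    if (strain >= 1 && strain <= n_track) cnt[strain]++; else cnt_other++;
    M_tot++;
  };

  auto disturb = [&](int s) {
    Site &st = sites[s];
    int m = (int)st.S.size();
    double mass = P.omega_M * m;
    for (int j = 0; j < m; ++j) mass += st.S[j];
    for (int j = m - 1; j >= 0; --j) remove_cell(st, j);
    recycle_mass(st, mass);
    disturbances++; disturbance_deaths += m;
  };

  double t = t0;
  std::vector<double> buf(n_sites);
  double next_rec = (record_every > 0.0) ? t0 + record_every : R_PosInf;
  record(t);
  bool extinct_stop = false, strain_stop = false;
  std::vector<Newborn> newborns;

  while (t < t_max) {
    n_steps++;
    // 1. global death clock
    double T = R_PosInf;
    if (M_tot > 0) T = exp_rand() / (P.d_M * (double)M_tot);
    double dt = std::min(T, tau_eff);
    if (t + dt > t_max) { // truncate final interval; a death past t_max is dropped
      dt = t_max - t;
      if (T <= dt) { /* keep death */ } else T = R_PosInf;
    }
    bool death_now = (T <= dt * (1.0 + 1e-12)) && M_tot > 0 && T <= tau_eff;

    // 2. deterministic flows with cell numbers frozen
    for (int s = 0; s < n_sites; ++s) {
      A[s] = 0.0;
      integrate_site(sites[s], dt);
    }

    // 3. storage update and deterministic divisions
    newborns.clear();
    for (int s = 0; s < n_sites; ++s) {
      Site &st = sites[s];
      double gA = P.gamma_M * A[s];
      for (size_t j = 0; j < st.S.size(); ++j) {
        st.S[j] += (1.0 - st.phi[j]) * gA;
        if (st.S[j] >= P.omega_M) {
          double excess = st.S[j] - P.omega_M;
          double S_each;
          if (zero_reset_division) { S_each = 0.0; cum_discard += excess; }
          else S_each = 0.5 * excess;
          st.S[j] = S_each;
          double phi_c = st.phi[j];
          int strain_c = st.strain[j];
          if (P.p_mut > 0.0 && unif_rand() < P.p_mut) {
            phi_c = truncated_normal(phi_c, P.sigma_mut);
            strain_c = next_strain_id++;
            reg_id.push_back(strain_c); reg_parent.push_back(st.strain[j]);
            reg_phi.push_back(phi_c); reg_t.push_back(t + dt);
            mutations++;
          }
          newborns.push_back(Newborn{s, S_each, phi_c, strain_c});
        }
      }
    }

    // relocate newborns one after another in uniformly random order
    int nb_n = (int)newborns.size();
    for (int i = nb_n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(newborns[i], newborns[j]);
    }
    for (int i = 0; i < nb_n; ++i) {
      Newborn &b = newborns[i];
      int dest = b.site;
      const std::vector<int> &ngh = nb[b.site];
      if (!ngh.empty() && unif_rand() >= 1.0 - P.p_disp) {
        std::vector<int> empty;
        for (size_t q = 0; q < ngh.size(); ++q)
          if (sites[ngh[q]].S.empty()) empty.push_back(ngh[q]);
        if (!empty.empty()) {
          dest = empty[(int)std::floor(unif_rand() * empty.size()) % empty.size()];
          dispersals++;
        } else if (unif_rand() >= 1.0 - P.p_open) {
          dest = ngh[(int)std::floor(unif_rand() * ngh.size()) % ngh.size()];
          disturb(dest);
          dispersals++;
        }
      }
      add_cell(dest, b.S, b.phi, b.strain);
      births++;
    }

    // 4. DOC diffusion (explicit Euler, Neumann boundaries, conservative)
    if (P.sigma_diff > 0.0 && L > 1) {
      double tau_use = fixed_tau ? tau_eff : dt;
      double f = P.sigma_diff * tau_use / site_area;
      for (int s = 0; s < n_sites; ++s) {
        double acc = 0.0;
        const std::vector<int> &ngh = nb[s];
        for (size_t q = 0; q < ngh.size(); ++q) acc += sites[ngh[q]].d;
        buf[s] = sites[s].d + f * (acc - (double)ngh.size() * sites[s].d);
      }
      for (int s = 0; s < n_sites; ++s) sites[s].d = buf[s];
    }

    // 5. death event
    if (death_now) {
      double r = unif_rand() * (double)M_tot;
      long acc = 0; int s_hit = -1, j_hit = -1;
      for (int s = 0; s < n_sites && s_hit < 0; ++s) {
        long m = (long)sites[s].S.size();
        if (r < (double)(acc + m)) {
          s_hit = s; j_hit = (int)(r - (double)acc);
          if (j_hit >= m) j_hit = (int)m - 1;
        }
        acc += m;
      }
      if (s_hit >= 0) {
        Site &st = sites[s_hit];
        double mass = P.omega_M + st.S[j_hit];
        remove_cell(st, j_hit);
        recycle_mass(st, mass);
        deaths++;
      }
    }

    t += dt;
    if (t >= next_rec) {
      record(t);
      while (next_rec <= t) next_rec += record_every;
    }
    if (stop_strain >= 1 && stop_strain <= n_track && cnt[stop_strain] == 0) {
      strain_stop = true; break;
    }
    if (M_tot == 0 && stop_on_extinction) { extinct_stop = true; break; }
    if ((n_steps & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (rec_t.empty() || rec_t.back() != t) record(t);

  // assemble outputs
  int nr = (int)rec_t.size();
  List traj = List::create(
      _["time"] = wrap(rec_t), _["c"] = wrap(rec_c), _["d"] = wrap(rec_d),
      _["z"] = wrap(rec_z), _["M"] = wrap(rec_M), _["reserve"] = wrap(rec_res),
      _["mean_phi"] = wrap(rec_mean), _["min_phi"] = wrap(rec_min),
      _["max_phi"] = wrap(rec_max), _["cum_input"] = wrap(rec_in),
      _["cum_leach"] = wrap(rec_le), _["cum_resp"] = wrap(rec_rs));
  List strain_counts(n_track);
  for (int i = 0; i < n_track; ++i) strain_counts[i] = wrap(rec_cnt[i]);

  NumericVector fc(n_sites), fd(n_sites), fz(n_sites);
  List fcells(n_sites);
  for (int s = 0; s < n_sites; ++s) {
    fc[s] = sites[s].c; fd[s] = sites[s].d; fz[s] = sites[s].z;
    fcells[s] = List::create(_["S"] = wrap(sites[s].S),
                             _["phi"] = wrap(sites[s].phi),
                             _["strain"] = wrap(sites[s].strain));
  }
  std::vector<long> final_cnt(cnt.begin() + 1, cnt.end());

  return List::create(
      _["trajectory"] = traj, _["strain_counts"] = strain_counts,
      _["n_records"] = nr, _["t_end"] = t,
      _["final"] = List::create(_["c"] = fc, _["d"] = fd, _["z"] = fz,
                                _["cells"] = fcells),
      _["final_strain_counts"] = wrap(final_cnt),
      _["M_final"] = (double)M_tot,
      _["counters"] = List::create(
          _["births"] = (double)births, _["deaths"] = (double)deaths,
          _["disturbances"] = (double)disturbances,
          _["disturbance_deaths"] = (double)disturbance_deaths,
          _["dispersals"] = (double)dispersals,
          _["mutations"] = (double)mutations, _["clips"] = (double)clips,
          _["steps"] = (double)n_steps),
      _["ledger"] = List::create(
          _["input"] = cum_input, _["leach"] = cum_leach,
          _["respiration"] = cum_resp, _["discard"] = cum_discard),
      _["registry"] = List::create(
          _["id"] = wrap(reg_id), _["parent"] = wrap(reg_parent),
          _["phi"] = wrap(reg_phi), _["t_founded"] = wrap(reg_t)),
      _["next_strain_id"] = next_strain_id, _["tau_eff"] = tau_eff,
      _["stopped_strain_extinct"] = strain_stop,
      _["stopped_all_extinct"] = extinct_stop);
}
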