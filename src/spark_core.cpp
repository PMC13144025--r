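// Compiled core of the spark engine: fixed-dt coupled update of channel
// gating (two-state RyR2, six-state IP3R2) and the explicit-Euler
// reaction-diffusion fields. Semantics mirror the R-level step_ryr /
// step_ip3r / step_fields reference implementations, which the test suite
// cross-checks against this path.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Portable uniform(0,1) from mt19937_64: top 53 bits -> double. Keeps
// trials bit-reproducible across platforms and compilers.
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(double seed) : gen(static_cast<uint64_t>(seed)) {}
  double next() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
};

struct ModalPars {
  double a24_max, k_a24, v24, a42_max, k_a42;
  double k_m24, k_h24, k_m42, k_h42, k_g;
};

inline double sq(double x) { return x * x; }

inline void intermodal(double c, double ip3, const ModalPars& mp, double v42,
                       double& q24, double& q42) {
  const double c2 = c * c, i2 = ip3 * ip3, i4 = i2 * i2;
  // g and a42 are quartic in IP3 (drive mode inaccessible at trace IP3)
  const double g = i4 / (i4 + sq(sq(mp.k_g)));
  const double m24 = c2 / (c2 + sq(mp.k_m24));
  const double h24 = sq(mp.k_h24) / (c2 + sq(mp.k_h24));
  const double m42 = g * c2 / (c2 + sq(mp.k_m42));
  const double h42 = sq(mp.k_h42) / (c2 + sq(mp.k_h42));
  const double a24 = mp.a24_max * sq(mp.k_a24) / (sq(mp.k_a24) + i2);
  const double a42 = mp.a42_max * i4 / (i4 + sq(sq(mp.k_a42)));
  q24 = a24 + mp.v24 * (1.0 - m24 * h24);
  q42 = a42 + v42 * m42 * h42;
}

inline double powh(double x, int hill, bool h4) {
  if (h4) { const double x2 = x * x; return x2 * x2; }
  return std::pow(x, static_cast<double>(hill));
}

}  // namespace

// Intermodal rates evaluated by the compiled path; exposed so the test
// suite can verify exact agreement with the R implementation.
// [[Rcpp::export]]
NumericVector ip3r_rates_cpp(double c_ds, double ip3, List ip3r_par) {
  ModalPars mp{as<double>(ip3r_par["a24_max"]), as<double>(ip3r_par["k_a24"]),
               as<double>(ip3r_par["v24"]),     as<double>(ip3r_par["a42_max"]),
               as<double>(ip3r_par["k_a42"]),   as<double>(ip3r_par["k_m24"]),
               as<double>(ip3r_par["k_h24"]),   as<double>(ip3r_par["k_m42"]),
               as<double>(ip3r_par["k_h42"]),   as<double>(ip3r_par["k_g"])};
  double q24, q42;
  intermodal(c_ds, ip3, mp, as<double>(ip3r_par["v42"]), q24, q42);
  return NumericVector::create(_["q24"] = q24, _["q42"] = q42);
}

// Single free IP3R2 at clamped fields: fraction of time in an open state
// ({5, 6}) over `duration` ms.
// [[Rcpp::export]]
double ip3r_po_sim_cpp(double c_ds, double ip3, double duration, double dt,
                       double seed, List ip3r_par) {
  ModalPars mp{as<double>(ip3r_par["a24_max"]), as<double>(ip3r_par["k_a24"]),
               as<double>(ip3r_par["v24"]),     as<double>(ip3r_par["a42_max"]),
               as<double>(ip3r_par["k_a42"]),   as<double>(ip3r_par["k_m24"]),
               as<double>(ip3r_par["k_h24"]),   as<double>(ip3r_par["k_m42"]),
               as<double>(ip3r_par["k_h42"]),   as<double>(ip3r_par["k_g"])};
  const double q12 = ip3r_par["q12"], q21 = ip3r_par["q21"],
               q23 = ip3r_par["q23"], q32 = ip3r_par["q32"],
               q26 = ip3r_par["q26"], q62 = ip3r_par["q62"],
               q45 = ip3r_par["q45"], q54 = ip3r_par["q54"],
               v42 = ip3r_par["v42"];
  double q24, q42;
  intermodal(c_ds, ip3, mp, v42, q24, q42);
  Rng rng(seed);
  int state = 4;  // park-closed start; negligible for long runs
  const long nsteps = static_cast<long>(std::ceil(duration / dt));
  long open_steps = 0;
  for (long s = 0; s < nsteps; ++s) {
    const double u = rng.next();
    switch (state) {
      case 1: if (u < dt * q12) state = 2; break;
      case 2: {
        double p1 = dt * q21, p2 = p1 + dt * q23, p3 = p2 + dt * q26,
               p4 = p3 + dt * q24;
        if (u < p1) state = 1;
        else if (u < p2) state = 3;
        else if (u < p3) state = 6;
        else if (u < p4) state = 4;
        break;
      }
      case 3: if (u < dt * q32) state = 2; break;
      case 4: {
        double p1 = dt * q42, p2 = p1 + dt * q45;
        if (u < p1) state = 2;
        else if (u < p2) state = 5;
        break;
      }
      case 5: if (u < dt * q54) state = 4; break;
      case 6: if (u < dt * q62) state = 2; break;
    }
    if (state == 5 || state == 6) ++open_steps;
  }
  return static_cast<double>(open_steps) / static_cast<double>(nsteps);
}

// One full stochastic trial: channels + fields on the same dt.
// Cells are 0-based column-major indices (ix-1) + (iy-1)*nx.
// [[Rcpp::export]]
List run_trial_cpp(int nx, int ny,
                   IntegerVector ryr_cell, List ryr_nbrs,
                   IntegerVector ip3r_cell,
                   int forced,
                   double duration, double dt, int stride,
                   double seed_ryr, double seed_ip3r,
                   List ryr_par, List ip3r_par, List tp, List buf_par,
                   double ip3,
                   bool dirichlet_ds, bool refill, double beta,
                   NumericVector init_cds, NumericVector init_cjsr,
                   List init_b, NumericVector pi0) {
  const int ncell = nx * ny;
  const int n_ryr = ryr_cell.size();
  const int n_ip3r = ip3r_cell.size();

  // --- parameters ---
  const double krmax = ryr_par["k_r_max"], alpha = ryr_par["alpha_r"],
               kpmax = ryr_par["kplus_max"], kminus = ryr_par["kminus"],
               ej = ryr_par["ej"], krfloor = ryr_par["k_r_floor"];
  const int hill = as<int>(ryr_par["hill"]);
  const bool h4 = (hill == 4);

  ModalPars mp{as<double>(ip3r_par["a24_max"]), as<double>(ip3r_par["k_a24"]),
               as<double>(ip3r_par["v24"]),     as<double>(ip3r_par["a42_max"]),
               as<double>(ip3r_par["k_a42"]),   as<double>(ip3r_par["k_m24"]),
               as<double>(ip3r_par["k_h24"]),   as<double>(ip3r_par["k_m42"]),
               as<double>(ip3r_par["k_h42"]),   as<double>(ip3r_par["k_g"])};
  const double q12 = ip3r_par["q12"], q21 = ip3r_par["q21"],
               q23 = ip3r_par["q23"], q32 = ip3r_par["q32"],
               q26 = ip3r_par["q26"], q62 = ip3r_par["q62"],
               q45 = ip3r_par["q45"], q54 = ip3r_par["q54"],
               v42 = ip3r_par["v42"];

  const double d_myo = tp["d_myo"], d_jsr = tp["d_jsr"],
               v_ds = tp["v_ds_L"], ca_nsr = tp["ca_nsr"],
               tau_refill = tp["tau_refill"], c_rest = tp["c_rest"],
               p_ryr = tp["p_ryr"], p_ip3r = tp["p_ip3r"];
  const double dx_um = as<double>(tp["pitch_nm"]) / 1000.0;
  const double rmyo = d_myo / (dx_um * dx_um);
  const double rjsr = d_jsr / (dx_um * dx_um);
  // pA per (uM gradient) through one channel: i = 2 F P dC (SI inside)
  const double FARADAY = 96485.33212;
  const double i_coef_ryr = 2.0 * FARADAY * p_ryr * 1000.0 * 1e-6 * 1e12;
  const double i_coef_ip3r = 2.0 * FARADAY * p_ip3r * 1000.0 * 1e-6 * 1e12;

  const int nbuf = buf_par.size();
  std::vector<double> kon(nbuf), koff(nbuf), btot(nbuf);
  for (int b = 0; b < nbuf; ++b) {
    List bp = buf_par[b];
    kon[b] = bp["k_on"]; koff[b] = bp["k_off"]; btot[b] = bp["b_total"];
  }

  // coupling factor lookup for num_net in [-4, 4]
  double kc_pow[9];
  for (int k = 0; k < 9; ++k) kc_pow[k] = std::exp(ej * (k - 4));

  // --- state ---
  std::vector<double> cds(init_cds.begin(), init_cds.end());
  std::vector<double> cjsr(init_cjsr.begin(), init_cjsr.end());
  std::vector<double> cds_new(ncell), cjsr_new(ncell);
  std::vector<std::vector<double> > bfree(nbuf);
  for (int b = 0; b < nbuf; ++b) {
    NumericVector v = init_b[b];
    bfree[b].assign(v.begin(), v.end());
  }
  std::vector<int> ryr_open(n_ryr, 0), ryr_new(n_ryr, 0);
  std::vector<std::vector<int> > nbrs(n_ryr);
  for (int i = 0; i < n_ryr; ++i) {
    IntegerVector v = ryr_nbrs[i];
    nbrs[i].assign(v.begin(), v.end());
  }
  std::vector<int> ip3r_state(n_ip3r, 4);
  std::vector<int> ip3r_open_pre(n_ip3r, 0);

  Rng rng_ryr(seed_ryr), rng_ip3r(seed_ip3r);
  const bool ip3_active = (ip3 > 0.0) && (n_ip3r > 0);
  if (ip3_active) {
    double cum[6];
    cum[0] = pi0[0];
    for (int k = 1; k < 6; ++k) cum[k] = cum[k - 1] + pi0[k];
    for (int i = 0; i < n_ip3r; ++i) {
      const double u = rng_ip3r.next() * cum[5];
      int s = 0;
      while (s < 5 && u >= cum[s]) ++s;
      ip3r_state[i] = s + 1;
    }
  }
  if (forced >= 0) ryr_open[forced] = 1;

  const long nsteps = static_cast<long>(std::ceil(duration / dt));
  const int nsamp = static_cast<int>(nsteps / stride) + 1 +
                    ((nsteps % stride) ? 1 : 0);
  NumericVector t_out(nsamp), i_out(nsamp), cds_mean(nsamp), cds_max(nsamp),
      cjsr_min(nsamp), ca_total(nsamp);
  IntegerVector nro(nsamp), nio(nsamp);
  int isamp = 0;

  auto record = [&](long s) {
    double itot = 0.0;
    int no_r = 0, no_i = 0;
    for (int i = 0; i < n_ryr; ++i)
      if (ryr_open[i]) {
        ++no_r;
        const int c = ryr_cell[i];
        itot += i_coef_ryr * (cjsr[c] - cds[c]);
      }
    for (int i = 0; i < n_ip3r; ++i)
      if (ip3r_state[i] == 5 || ip3r_state[i] == 6) {
        ++no_i;
        const int c = ip3r_cell[i];
        itot += i_coef_ip3r * (cjsr[c] - cds[c]);
      }
    double sds = 0.0, mx = 0.0, sj = 0.0, mnj = cjsr[0], bound = 0.0;
    for (int c = 0; c < ncell; ++c) {
      sds += cds[c];
      if (cds[c] > mx) mx = cds[c];
      sj += cjsr[c];
      if (cjsr[c] < mnj) mnj = cjsr[c];
    }
    for (int b = 0; b < nbuf; ++b)
      for (int c = 0; c < ncell; ++c) bound += btot[b] - bfree[b][c];
    t_out[isamp] = s * dt;
    nro[isamp] = no_r; nio[isamp] = no_i;
    i_out[isamp] = itot;
    cds_mean[isamp] = sds / ncell;
    cds_max[isamp] = mx;
    cjsr_min[isamp] = mnj;
    ca_total[isamp] = sds + sj + bound;
    ++isamp;
  };

  for (long s = 0; s < nsteps; ++s) {
    if (s % stride == 0) record(s);

    // --- gating decisions from the pre-step state ---
    for (int i = 0; i < n_ryr; ++i) {
      const double u = rng_ryr.next();
      const int c = ryr_cell[i];
      int net = 0;
      for (size_t k = 0; k < nbrs[i].size(); ++k)
        net += ryr_open[nbrs[i][k]] ? 1 : -1;
      double p;
      if (ryr_open[i]) {
        p = dt * kminus * kc_pow[(-net) + 4];
      } else {
        double kr = krmax - alpha * cjsr[c];
        if (kr < krfloor) kr = krfloor;
        const double ch = powh(cds[c], hill, h4);
        const double kp = kpmax * ch / (ch + powh(kr, hill, h4));
        p = dt * kp * kc_pow[net + 4];
      }
      ryr_new[i] = (u < p) ? !ryr_open[i] : ryr_open[i];
    }
    if (ip3_active) {
      for (int i = 0; i < n_ip3r; ++i)
        ip3r_open_pre[i] = (ip3r_state[i] == 5 || ip3r_state[i] == 6);
      for (int i = 0; i < n_ip3r; ++i) {
        const double u = rng_ip3r.next();
        const int c = ip3r_cell[i];
        int& st = ip3r_state[i];
        double q24, q42;
        switch (st) {
          case 1: if (u < dt * q12) st = 2; break;
          case 2: {
            intermodal(cds[c], ip3, mp, v42, q24, q42);
            double p1 = dt * q21, p2 = p1 + dt * q23, p3 = p2 + dt * q26,
                   p4 = p3 + dt * q24;
            if (u < p1) st = 1;
            else if (u < p2) st = 3;
            else if (u < p3) st = 6;
            else if (u < p4) st = 4;
            break;
          }
          case 3: if (u < dt * q32) st = 2; break;
          case 4: {
            intermodal(cds[c], ip3, mp, v42, q24, q42);
            double p1 = dt * q42, p2 = p1 + dt * q45;
            if (u < p1) st = 2;
            else if (u < p2) st = 5;
            break;
          }
          case 5: if (u < dt * q54) st = 4; break;
          case 6: if (u < dt * q62) st = 2; break;
        }
      }
    }

    // --- field update from the pre-step channel states ---
    for (int y = 0; y < ny; ++y) {
      const int row = y * nx;
      for (int x = 0; x < nx; ++x) {
        const int c = row + x;
        const double cc = cds[c];
        const double gL = (x > 0) ? cds[c - 1]
                                  : (dirichlet_ds ? c_rest : cc);
        const double gR = (x < nx - 1) ? cds[c + 1]
                                       : (dirichlet_ds ? c_rest : cc);
        const double gD = (y > 0) ? cds[c - nx]
                                  : (dirichlet_ds ? c_rest : cc);
        const double gU = (y < ny - 1) ? cds[c + nx]
                                       : (dirichlet_ds ? c_rest : cc);
        double jbuf = 0.0;
        for (int b = 0; b < nbuf; ++b) {
          const double bf = bfree[b][c];
          const double j = koff[b] * (btot[b] - bf) - kon[b] * bf * cc;
          double bn = bf + dt * j;
          if (bn < 0.0) bn = 0.0;
          else if (bn > btot[b]) bn = btot[b];
          bfree[b][c] = bn;
          jbuf += j;
        }
        cds_new[c] = cc + dt * (rmyo * (gL + gR + gD + gU - 4.0 * cc) + jbuf);

        const double jj = cjsr[c];
        const double jL = (x > 0) ? cjsr[c - 1] : jj;
        const double jR = (x < nx - 1) ? cjsr[c + 1] : jj;
        const double jD = (y > 0) ? cjsr[c - nx] : jj;
        const double jU = (y < ny - 1) ? cjsr[c + nx] : jj;
        double dj = rjsr * (jL + jR + jD + jU - 4.0 * jj);
        if (refill) dj += (ca_nsr - jj) / tau_refill;
        cjsr_new[c] = jj + dt * beta * dj;
      }
    }
    // channel fluxes (sparse): + into dyad, - out of JSR, same step
    for (int i = 0; i < n_ryr; ++i)
      if (ryr_open[i]) {
        const int c = ryr_cell[i];
        const double f = p_ryr * (cjsr[c] - cds[c]) / v_ds;
        cds_new[c] += dt * f;
        cjsr_new[c] -= dt * beta * f;
      }
    if (ip3_active)
      for (int i = 0; i < n_ip3r; ++i)
        if (ip3r_open_pre[i]) {
          const int c = ip3r_cell[i];
          const double f = p_ip3r * (cjsr[c] - cds[c]) / v_ds;
          cds_new[c] += dt * f;
          cjsr_new[c] -= dt * beta * f;
        }

    for (int c = 0; c < ncell; ++c) {
      if (cds_new[c] < 0.0) cds_new[c] = 0.0;
      if (cjsr_new[c] < 0.0) cjsr_new[c] = 0.0;
    }
    cds.swap(cds_new);
    cjsr.swap(cjsr_new);
    for (int i = 0; i < n_ryr; ++i) ryr_open[i] = ryr_new[i];
  }
  record(nsteps);

  List final_b(nbuf);
  for (int b = 0; b < nbuf; ++b) final_b[b] = NumericVector(bfree[b].begin(),
                                                            bfree[b].end());
  return List::create(
      _["t"] = t_out, _["n_open_ryr"] = nro, _["n_open_ip3r"] = nio,
      _["i_total_pA"] = i_out, _["cds_mean"] = cds_mean,
      _["cds_max"] = cds_max, _["cjsr_min"] = cjsr_min,
      _["ca_total"] = ca_total,
      _["final_cds"] = NumericVector(cds.begin(), cds.end()),
      _["final_cjsr"] = NumericVector(cjsr.begin(), cjsr.end()),
      _["final_b"] = final_b);
}
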