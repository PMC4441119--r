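// Analytic potential-energy surfaces and a compact L-BFGS minimiser.
// Families: 1 = double_well_1d, 2 = muller_brown, 3 = lj_cluster, 4 = bead_peptide.
// All bead-peptide forces are analytic; correctness is pinned by the
// finite-difference gradient tests on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Terms {
  double bonded = 0, angular = 0, torsional = 0, vdw = 0, elec = 0, analytic = 0;
  double total() const { return bonded + angular + torsional + vdw + elec + analytic; }
};

// ---------------------------------------------------------------- double well
// V(x) = x^4 - x^2
double dw_energy(const arma::vec& x, Terms* t) {
  double v = std::pow(x[0], 4) - x[0] * x[0];
  if (t) t->analytic = v;
  return v;
}
void dw_gradient(const arma::vec& x, arma::vec& g) {
  g[0] = 4.0 * std::pow(x[0], 3) - 2.0 * x[0];
}

// -------------------------------------------------------------- Muller-Brown
static const double MB_A[4]  = {-200.0, -100.0, -170.0, 15.0};
static const double MB_a[4]  = {-1.0, -1.0, -6.5, 0.7};
static const double MB_b[4]  = {0.0, 0.0, 11.0, 0.6};
static const double MB_c[4]  = {-10.0, -10.0, -6.5, 0.7};
static const double MB_x0[4] = {1.0, 0.0, -0.5, -1.0};
static const double MB_y0[4] = {0.0, 0.5, 1.5, 1.0};

double mb_energy(const arma::vec& x, Terms* t) {
  double v = 0.0;
  for (int k = 0; k < 4; ++k) {
    double dx = x[0] - MB_x0[k], dy = x[1] - MB_y0[k];
    v += MB_A[k] * std::exp(MB_a[k] * dx * dx + MB_b[k] * dx * dy + MB_c[k] * dy * dy);
  }
  if (t) t->analytic = v;
  return v;
}
void mb_gradient(const arma::vec& x, arma::vec& g) {
  g.zeros();
  for (int k = 0; k < 4; ++k) {
    double dx = x[0] - MB_x0[k], dy = x[1] - MB_y0[k];
    double e = MB_A[k] * std::exp(MB_a[k] * dx * dx + MB_b[k] * dx * dy + MB_c[k] * dy * dy);
    g[0] += e * (2.0 * MB_a[k] * dx + MB_b[k] * dy);
    g[1] += e * (MB_b[k] * dx + 2.0 * MB_c[k] * dy);
  }
}

// ----------------------------------------------------------------- LJ cluster
struct LJParams { int n; double eps, sigma; };

double lj_energy(const LJParams& p, const arma::vec& x, Terms* t) {
  double v = 0.0, s2 = p.sigma * p.sigma;
  for (int i = 0; i < p.n - 1; ++i)
    for (int j = i + 1; j < p.n; ++j) {
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      double ir6 = std::pow(s2 / r2, 3);
      v += 4.0 * p.eps * (ir6 * ir6 - ir6);
    }
  if (t) t->vdw = v;
  return v;
}
void lj_gradient(const LJParams& p, const arma::vec& x, arma::vec& g) {
  g.zeros();
  double s2 = p.sigma * p.sigma;
  for (int i = 0; i < p.n - 1; ++i)
    for (int j = i + 1; j < p.n; ++j) {
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      double sr2 = s2 / r2, ir6 = sr2 * sr2 * sr2;
      // dV/dr2 = 4 eps (-6 s^12 r^-14 + 3 s^6 r^-8) = (4 eps / r2) (-6 ir6^2 + 3 ir6)
      double c = (4.0 * p.eps / r2) * (-12.0 * ir6 * ir6 + 6.0 * ir6) * 0.5 * 2.0;
      // c = dV/d(r2) * 2 ; gradient wrt x_i is c * dx etc.
      c = (4.0 * p.eps / r2) * (-12.0 * ir6 * ir6 + 6.0 * ir6);
      g[3*i]   += c * dx; g[3*i+1] += c * dy; g[3*i+2] += c * dz;
      g[3*j]   -= c * dx; g[3*j+1] -= c * dy; g[3*j+2] -= c * dz;
    }
}

// --------------------------------------------------------------- bead peptide
struct BPParams {
  int n;
  arma::vec q;              // per-bead charge (e)
  arma::ivec hydrophobic;   // 1 if bead type H
  double k_bond, r0, k_angle, theta0, k_tor, phi0;
  double eps_hh, eps_bb, sigma;    // nonbonded LJ
  double coulomb, debye;           // kcal*A/mol per e^2 (already / dielectric), A
};

BPParams parse_bp(const List& params) {
  BPParams p;
  p.q = as<arma::vec>(params["charges"]);
  p.hydrophobic = as<arma::ivec>(params["hydrophobic"]);
  p.n = p.q.n_elem;
  p.k_bond = params["k_bond"];   p.r0 = params["r0"];
  p.k_angle = params["k_angle"]; p.theta0 = params["theta0"];
  p.k_tor = params["k_tor"];     p.phi0 = params["phi0"];
  p.eps_hh = params["eps_hh"];   p.eps_bb = params["eps_bb"];
  p.sigma = params["sigma"];
  p.coulomb = params["coulomb"]; p.debye = params["debye"];
  return p;
}

inline arma::vec3 bead(const arma::vec& x, int i) {
  return arma::vec3{x[3*i], x[3*i+1], x[3*i+2]};
}

double bp_energy(const BPParams& p, const arma::vec& x, Terms* t) {
  Terms loc;
  // bonds
  for (int i = 0; i + 1 < p.n; ++i) {
    double r = arma::norm(bead(x, i + 1) - bead(x, i));
    loc.bonded += p.k_bond * (r - p.r0) * (r - p.r0);
  }
  // angles
  for (int j = 1; j + 1 < p.n; ++j) {
    arma::vec3 u = bead(x, j - 1) - bead(x, j), v = bead(x, j + 1) - bead(x, j);
    double ct = arma::dot(u, v) / (arma::norm(u) * arma::norm(v));
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    loc.angular += p.k_angle * (th - p.theta0) * (th - p.theta0);
  }
  // torsions
  for (int i = 0; i + 3 < p.n; ++i) {
    arma::vec3 b1 = bead(x, i+1) - bead(x, i);
    arma::vec3 b2 = bead(x, i+2) - bead(x, i+1);
    arma::vec3 b3 = bead(x, i+3) - bead(x, i+2);
    arma::vec3 n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
    double phi = std::atan2(arma::dot(arma::cross(n1, n2), b2) / arma::norm(b2),
                            arma::dot(n1, n2));
    loc.torsional += p.k_tor * (1.0 - std::cos(phi - p.phi0));
  }
  // nonbonded |i-j| >= 3
  for (int i = 0; i < p.n - 3; ++i)
    for (int j = i + 3; j < p.n; ++j) {
      double r = arma::norm(bead(x, j) - bead(x, i));
      double eps = (p.hydrophobic[i] && p.hydrophobic[j]) ? p.eps_hh : p.eps_bb;
      double sr6 = std::pow(p.sigma / r, 6);
      loc.vdw += 4.0 * eps * (sr6 * sr6 - sr6);
      if (p.q[i] != 0.0 && p.q[j] != 0.0)
        loc.elec += p.coulomb * p.q[i] * p.q[j] * std::exp(-r / p.debye) / r;
    }
  if (t) *t = loc;
  return loc.total();
}

void bp_gradient(const BPParams& p, const arma::vec& x, arma::vec& g) {
  g.zeros();
  auto add = [&](int i, const arma::vec3& v) {
    g[3*i] += v[0]; g[3*i+1] += v[1]; g[3*i+2] += v[2];
  };
  // bonds
  for (int i = 0; i + 1 < p.n; ++i) {
    arma::vec3 d = bead(x, i + 1) - bead(x, i);
    double r = arma::norm(d);
    double c = 2.0 * p.k_bond * (r - p.r0) / r;
    add(i + 1, c * d); add(i, -c * d);
  }
  // angles
  for (int j = 1; j + 1 < p.n; ++j) {
    arma::vec3 u = bead(x, j - 1) - bead(x, j), v = bead(x, j + 1) - bead(x, j);
    double nu = arma::norm(u), nv = arma::norm(v);
    arma::vec3 hu = u / nu, hv = v / nv;
    double ct = std::max(-1.0, std::min(1.0, arma::dot(hu, hv)));
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-16));
    double th = std::acos(ct);
    double dV = 2.0 * p.k_angle * (th - p.theta0);
    arma::vec3 dthi = -(hv - ct * hu) / (nu * st);   // d theta / d r_{j-1}
    arma::vec3 dthk = -(hu - ct * hv) / (nv * st);   // d theta / d r_{j+1}
    add(j - 1, dV * dthi);
    add(j + 1, dV * dthk);
    add(j, -dV * (dthi + dthk));
  }
  // torsions
  for (int i = 0; i + 3 < p.n; ++i) {
    arma::vec3 b1 = bead(x, i+1) - bead(x, i);
    arma::vec3 b2 = bead(x, i+2) - bead(x, i+1);
    arma::vec3 b3 = bead(x, i+3) - bead(x, i+2);
    arma::vec3 n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
    double nb2 = arma::norm(b2), n1sq = arma::dot(n1, n1), n2sq = arma::dot(n2, n2);
    if (n1sq < 1e-18 || n2sq < 1e-18) continue;     // collinear: torsion undefined
    double phi = std::atan2(arma::dot(arma::cross(n1, n2), b2) / nb2, arma::dot(n1, n2));
    double dV = p.k_tor * std::sin(phi - p.phi0);
    arma::vec3 d1 = -(nb2 / n1sq) * n1;             // d phi / d r_i
    arma::vec3 d4 =  (nb2 / n2sq) * n2;             // d phi / d r_{i+3}
    double c12 = arma::dot(b1, b2) / (nb2 * nb2);
    double c32 = arma::dot(b3, b2) / (nb2 * nb2);
    arma::vec3 d2 = -(1.0 + c12) * d1 + c32 * d4;   // d phi / d r_{i+1}
    arma::vec3 d3 = c12 * d1 - (1.0 + c32) * d4;    // d phi / d r_{i+2}
    add(i, dV * d1); add(i + 1, dV * d2); add(i + 2, dV * d3); add(i + 3, dV * d4);
  }
  // nonbonded
  for (int i = 0; i < p.n - 3; ++i)
    for (int j = i + 3; j < p.n; ++j) {
      arma::vec3 d = bead(x, j) - bead(x, i);
      double r = arma::norm(d);
      double eps = (p.hydrophobic[i] && p.hydrophobic[j]) ? p.eps_hh : p.eps_bb;
      double sr6 = std::pow(p.sigma / r, 6);
      double dVdr = 4.0 * eps * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
      if (p.q[i] != 0.0 && p.q[j] != 0.0) {
        double pre = p.coulomb * p.q[i] * p.q[j] * std::exp(-r / p.debye);
        dVdr += pre * (-1.0 / (r * r) - 1.0 / (p.debye * r));
      }
      arma::vec3 f = (dVdr / r) * d;
      add(j, f); add(i, -f);
    }
}

// ------------------------------------------------------------------ dispatch
struct Surface {
  int family;
  LJParams lj;
  BPParams bp;
  double energy(const arma::vec& x, Terms* t = nullptr) const {
    switch (family) {
      case 1: return dw_energy(x, t);
      case 2: return mb_energy(x, t);
      case 3: return lj_energy(lj, x, t);
      default: return bp_energy(bp, x, t);
    }
  }
  void gradient(const arma::vec& x, arma::vec& g) const {
    switch (family) {
      case 1: dw_gradient(x, g); break;
      case 2: mb_gradient(x, g); break;
      case 3: lj_gradient(lj, x, g); break;
      default: bp_gradient(bp, x, g); break;
    }
  }
};

Surface make_surface(int family, const List& params) {
  Surface s; s.family = family;
  if (family == 3) {
    s.lj.n = params["n_atoms"]; s.lj.eps = params["eps"]; s.lj.sigma = params["sigma"];
  } else if (family == 4) {
    s.bp = parse_bp(params);
  }
  return s;
}

} // namespace

// [[Rcpp::export]]
double cpp_energy(int family, List params, NumericVector x) {
  Surface s = make_surface(family, params);
  return s.energy(as<arma::vec>(x));
}

// [[Rcpp::export]]
NumericVector cpp_energy_terms(int family, List params, NumericVector x) {
  Surface s = make_surface(family, params);
  Terms t;
  s.energy(as<arma::vec>(x), &t);
  return NumericVector::create(
    _["bonded"] = t.bonded, _["angular"] = t.angular, _["torsional"] = t.torsional,
    _["van_der_waals"] = t.vdw, _["electrostatic"] = t.elec, _["analytic"] = t.analytic);
}

// [[Rcpp::export]]
NumericVector cpp_gradient(int family, List params, NumericVector x) {
  Surface s = make_surface(family, params);
  arma::vec g(x.size());
  s.gradient(as<arma::vec>(x), g);
  return wrap(g);
}

// L-BFGS with backtracking Armijo line search; convergence on RMS gradient.
// [[Rcpp::export]]
List cpp_lbfgs(int family, List params, NumericVector x0, double rms_tol,
               int max_iter, double max_step = 0.5) {
  Surface s = make_surface(family, params);
  const int n = x0.size(), m = 8;
  arma::vec x = as<arma::vec>(x0), g(n), gnew(n);
  double f = s.energy(x);
  if (!std::isfinite(f)) return List::create(_["x"] = wrap(x), _["energy"] = f,
    _["rms_grad"] = NA_REAL, _["n_iter"] = 0, _["converged"] = false);
  s.gradient(x, g);
  arma::mat S(n, m, arma::fill::zeros), Y(n, m, arma::fill::zeros);
  arma::vec rho(m, arma::fill::zeros);
  int k = 0, stored = 0, last_improve = 0;
  bool just_reset = false;
  double rms = arma::norm(g) / std::sqrt((double)n);
  double best_rms = rms;
  for (k = 0; k < max_iter && rms > rms_tol; ++k) {
    if (k - last_improve > 200) {
      // stalled: drop the (possibly poisoned) curvature memory once, then
      // give up if that does not restore progress
      if (just_reset) break;
      stored = 0;
      last_improve = k;
      just_reset = true;
    }
    // two-loop recursion over the most recent min(stored, m) pairs
    arma::vec q = g, alpha(m);
    int navail = std::min(stored, m);
    for (int i = stored - 1; i >= stored - navail; --i) {
      int ci = i % m;
      alpha[ci] = rho[ci] * arma::dot(S.col(ci), q);
      q -= alpha[ci] * Y.col(ci);
    }
    if (stored > 0) {
      int last = (stored - 1) % m;
      double gamma = arma::dot(S.col(last), Y.col(last)) / arma::dot(Y.col(last), Y.col(last));
      q *= gamma;
    } else {
      q *= 1.0 / std::max(1.0, arma::norm(g));
    }
    for (int i = stored - navail; i < stored; ++i) {
      int ci = i % m;
      double beta = rho[ci] * arma::dot(Y.col(ci), q);
      q += (alpha[ci] - beta) * S.col(ci);
    }
    arma::vec d = -q;
    double dg = arma::dot(d, g);
    if (dg > 0) { d = -g; dg = -arma::dot(g, g); stored = 0; }
    double dnorm = arma::norm(d);
    double step = std::min(1.0, max_step * std::sqrt((double)n) / dnorm);
    double fnew = 0.0; bool ok = false;
    for (int ls = 0; ls < 30; ++ls) {
      arma::vec xt = x + step * d;
      fnew = s.energy(xt);
      bool armijo = std::isfinite(fnew) && fnew <= f + 1e-4 * step * dg;
      // near float precision the energy cannot resolve the decrease: accept
      // any step that lowers the gradient norm instead of stalling
      bool grad_ok = false;
      if (!armijo && std::isfinite(fnew) &&
          fnew <= f + 1e-12 * std::max(1.0, std::abs(f))) {
        s.gradient(xt, gnew);
        grad_ok = arma::norm(gnew) < arma::norm(g);
      }
      if (armijo || grad_ok) {
        s.gradient(xt, gnew);
        arma::vec sv = xt - x, yv = gnew - g;
        double sy = arma::dot(sv, yv);
        if (sy > 1e-12) {
          int ci = stored % m;
          S.col(ci) = sv; Y.col(ci) = yv; rho[ci] = 1.0 / sy;
          ++stored;
        }
        x = xt; f = fnew; g = gnew; ok = true;
        break;
      }
      step *= 0.5;
    }
    if (!ok) break;
    rms = arma::norm(g) / std::sqrt((double)n);
    if (rms < 0.99 * best_rms) {
      best_rms = rms; last_improve = k; just_reset = false;
    }
  }
  return List::create(_["x"] = wrap(x), _["energy"] = f, _["rms_grad"] = rms,
                      _["n_iter"] = k, _["converged"] = rms <= rms_tol);
}
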