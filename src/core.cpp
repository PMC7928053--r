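// Numerical core: serial-chain rigid-body dynamics (RNEA / unit-acceleration
// mass matrix), polyline muscle geometry with via points, rigid-tendon Hill
// force generation, smooth first-order activation dynamics, RK4 shooting,
// a condensed bounded Gauss-Newton (Levenberg-Marquardt) solver for the
// per-window tracking NLP, the moving-horizon loop, per-interval reference
// tracking, static muscle redundancy resolution and marker-based inverse
// kinematics.
//
// Models arrive as a flat list produced by compile_model() on the R side;
// all quantities are SI (m, kg, s, rad, N).

#include <RcppArmadillo.h>
#include <chrono>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Model {
  int nq = 0, nb = 0, nmus = 0, nmark = 0;
  ivec joint_parent;        // -1 = world
  mat joint_trans;          // 3 x nq, in parent joint frame
  mat joint_axis;           // 3 x nq, unit, local
  vec qmin, qmax;
  ivec body_joint;
  vec body_mass;
  mat body_com;             // 3 x nb, in joint frame
  cube body_inertia;        // 3 x 3 x nb, about com, in joint frame
  ivec marker_joint;        // -1 = world
  mat marker_loc;           // 3 x nmark
  ivec mus_npts;
  ivec mus_pt_joint;        // concatenated
  mat mus_pt_loc;           // 3 x total
  vec fmax, lopt, lts, vmax, tact, tdeact;
  vec3 gravity;
  double passive_scale = 1.0;
  double act_switch_k = 100.0;
  imat anc;                 // anc(i, j) = 1 if joint i is ancestor-or-self of j
};

vec clampv(const vec& x, const vec& lo, const vec& hi) {
  vec out = x;
  for (uword i = 0; i < x.n_elem; ++i)
    out(i) = std::min(std::max(x(i), lo(i)), hi(i));
  return out;
}

Model parse_model(const Rcpp::List& L) {
  Model m;
  m.nq = Rcpp::as<int>(L["nq"]);
  m.nmus = Rcpp::as<int>(L["nmus"]);
  m.nmark = Rcpp::as<int>(L["nmark"]);
  m.joint_parent = Rcpp::as<ivec>(L["joint_parent"]);
  m.joint_trans = Rcpp::as<mat>(L["joint_trans"]);
  m.joint_axis = Rcpp::as<mat>(L["joint_axis"]);
  m.qmin = Rcpp::as<vec>(L["qmin"]);
  m.qmax = Rcpp::as<vec>(L["qmax"]);
  m.body_joint = Rcpp::as<ivec>(L["body_joint"]);
  m.body_mass = Rcpp::as<vec>(L["body_mass"]);
  m.body_com = Rcpp::as<mat>(L["body_com"]);
  mat bi = Rcpp::as<mat>(L["body_inertia"]);   // 9 x nb, column-major 3x3
  m.nb = (int)m.body_mass.n_elem;
  m.body_inertia.set_size(3, 3, m.nb);
  for (int b = 0; b < m.nb; ++b) m.body_inertia.slice(b) = reshape(bi.col(b), 3, 3);
  m.marker_joint = Rcpp::as<ivec>(L["marker_joint"]);
  m.marker_loc = Rcpp::as<mat>(L["marker_loc"]);
  m.mus_npts = Rcpp::as<ivec>(L["mus_npts"]);
  m.mus_pt_joint = Rcpp::as<ivec>(L["mus_pt_joint"]);
  m.mus_pt_loc = Rcpp::as<mat>(L["mus_pt_loc"]);
  m.fmax = Rcpp::as<vec>(L["fmax"]);
  m.lopt = Rcpp::as<vec>(L["lopt"]);
  m.lts = Rcpp::as<vec>(L["lts"]);
  m.vmax = Rcpp::as<vec>(L["vmax"]);
  m.tact = Rcpp::as<vec>(L["tact"]);
  m.tdeact = Rcpp::as<vec>(L["tdeact"]);
  m.gravity = Rcpp::as<vec>(L["gravity"]);
  m.passive_scale = Rcpp::as<double>(L["passive_scale"]);
  m.act_switch_k = Rcpp::as<double>(L["act_switch_k"]);
  m.anc.zeros(m.nq, m.nq);
  for (int j = 0; j < m.nq; ++j) {
    int i = j;
    while (i >= 0) { m.anc(i, j) = 1; i = m.joint_parent(i); }
  }
  return m;
}

mat33 axis_rot(const vec3& a, double th) {
  // Rodrigues
  double c = std::cos(th), s = std::sin(th);
  mat33 K = {{0, -a(2), a(1)}, {a(2), 0, -a(0)}, {-a(1), a(0), 0}};
  return eye(3, 3) + s * K + (1.0 - c) * (K * K);
}

struct Frames {
  std::vector<mat33> R;   // world rotation of each joint frame
  std::vector<vec3> o;    // world origin of each joint frame
  std::vector<vec3> s;    // world joint axis
};

void fk_frames(const Model& m, const vec& q, Frames& F) {
  F.R.resize(m.nq); F.o.resize(m.nq); F.s.resize(m.nq);
  for (int i = 0; i < m.nq; ++i) {
    int p = m.joint_parent(i);
    mat33 Rp = (p >= 0) ? F.R[p] : eye(3, 3);
    vec3 op = (p >= 0) ? F.o[p] : zeros<vec>(3);
    F.o[i] = op + Rp * m.joint_trans.col(i);
    vec3 ax = m.joint_axis.col(i);
    F.s[i] = Rp * ax;
    F.R[i] = Rp * axis_rot(ax, q(i));
  }
}

inline vec3 point_world(const Model& m, const Frames& F, int j, const vec3& loc) {
  if (j < 0) return loc;
  return F.o[j] + F.R[j] * loc;
}

// 3 x nq Jacobian of a point attached to joint frame j
void point_jac(const Model& m, const Frames& F, int j, const vec3& p, mat& J) {
  J.zeros(3, m.nq);
  if (j < 0) return;
  for (int i = 0; i < m.nq; ++i)
    if (m.anc(i, j)) J.col(i) = cross(F.s[i], p - F.o[i]);
}

void markers_world(const Model& m, const Frames& F, mat& M) {
  M.set_size(3, m.nmark);
  for (int k = 0; k < m.nmark; ++k)
    M.col(k) = point_world(m, F, m.marker_joint(k), m.marker_loc.col(k));
}

// Polyline musculotendon geometry: lengths, d l / d q, velocities.
void muscle_geometry(const Model& m, const Frames& F, const vec& qd,
                     vec& lmt, mat& dldq, vec& vmt) {
  lmt.zeros(m.nmus); dldq.zeros(m.nmus, m.nq); vmt.zeros(m.nmus);
  int off = 0;
  mat Ja(3, m.nq), Jb(3, m.nq);
  for (int mu = 0; mu < m.nmus; ++mu) {
    int np = m.mus_npts(mu);
    vec3 pa = point_world(m, F, m.mus_pt_joint(off), m.mus_pt_loc.col(off));
    point_jac(m, F, m.mus_pt_joint(off), pa, Ja);
    for (int k = 1; k < np; ++k) {
      vec3 pb = point_world(m, F, m.mus_pt_joint(off + k), m.mus_pt_loc.col(off + k));
      point_jac(m, F, m.mus_pt_joint(off + k), pb, Jb);
      vec3 d = pb - pa;
      double len = norm(d);
      if (len < 1e-9) Rcpp::stop("degenerate muscle path segment (coincident points)");
      vec3 u = d / len;
      lmt(mu) += len;
      dldq.row(mu) += u.t() * (Jb - Ja);
      pa = pb; Ja = Jb;
    }
    off += np;
  }
  vmt = dldq * qd;
}

// Hill curves (rigid tendon). Normalised fiber length / velocity.
inline double f_l(double l) { double d = l - 1.0; return std::exp(-d * d / 0.45); }
inline double f_v(double v) {
  if (v >= 0.0) return 1.5 - 0.5 * std::exp(-10.0 * v);
  if (v <= -1.0) return 0.0;
  return (1.0 + v) / (1.0 - 4.0 * v);
}
inline double f_p(double l) {
  double x = l - 1.0;
  if (x <= 0.0) return 0.0;
  return 3.24 * x * x * x / (x + 0.1);   // C2 at l = 1, f_p(1.6) ~ 1
}

void hill_forces(const Model& m, const vec& a, const vec& lmt, const vec& vmt, vec& F) {
  F.set_size(m.nmus);
  for (int mu = 0; mu < m.nmus; ++mu) {
    double lf = lmt(mu) - m.lts(mu);
    double lt = lf / m.lopt(mu);
    if (lt < 0.01) lt = 0.01;            // guard for off-path solver iterates
    double vt = vmt(mu) / (m.lopt(mu) * m.vmax(mu));
    double f = m.fmax(mu) * (a(mu) * f_l(lt) * f_v(vt) + m.passive_scale * f_p(lt));
    F(mu) = f > 0.0 ? f : 0.0;
  }
}

inline double act_rate(double a, double e, double tact, double tdeact, double k) {
  double d = e - a;
  double s = 0.5 * (1.0 + std::tanh(k * d));
  return d * (s / tact + (1.0 - s) / tdeact);
}

// Recursive Newton-Euler in world frame. Gravity handled as base acceleration.
void rnea(const Model& m, const Frames& F, const vec& qd, const vec& qdd,
          bool with_gravity, vec& tau) {
  int nq = m.nq;
  std::vector<vec3> w(nq), al(nq), ao(nq);
  vec3 abase = with_gravity ? vec3(-m.gravity) : vec3(zeros<vec>(3));
  for (int i = 0; i < nq; ++i) {
    int p = m.joint_parent(i);
    vec3 wp = (p >= 0) ? w[p] : zeros<vec>(3);
    vec3 alp = (p >= 0) ? al[p] : zeros<vec>(3);
    vec3 aop = (p >= 0) ? ao[p] : abase;
    vec3 op = (p >= 0) ? F.o[p] : zeros<vec>(3);
    vec3 r = F.o[i] - op;
    w[i] = wp + F.s[i] * qd(i);
    al[i] = alp + F.s[i] * qdd(i) + cross(wp, F.s[i]) * qd(i);
    ao[i] = aop + cross(alp, r) + cross(wp, cross(wp, r));
  }
  std::vector<vec3> f(nq, zeros<vec>(3)), n(nq, zeros<vec>(3));
  for (int b = 0; b < m.nb; ++b) {
    int j = m.body_joint(b);
    vec3 c = F.o[j] + F.R[j] * m.body_com.col(b);
    vec3 rc = c - F.o[j];
    vec3 ac = ao[j] + cross(al[j], rc) + cross(w[j], cross(w[j], rc));
    mat33 Iw = F.R[j] * m.body_inertia.slice(b) * F.R[j].t();
    vec3 Fb = m.body_mass(b) * ac;
    vec3 Nb = Iw * al[j] + cross(w[j], Iw * w[j]);
    f[j] += Fb;
    n[j] += Nb + cross(rc, Fb);
  }
  tau.set_size(nq);
  for (int i = nq - 1; i >= 0; --i) {
    int p = m.joint_parent(i);
    if (p >= 0) {
      f[p] += f[i];
      n[p] += n[i] + cross(F.o[i] - F.o[p], f[i]);
    }
    tau(i) = dot(F.s[i], n[i]);
  }
}

// xdot. Formulation 0: excitation-driven, x = (q, qd, a), u = excitations.
// Formulation 1: activation-driven, x = (q, qd), u = activations.
void dynamics(const Model& m, const vec& x, const vec& u, int formulation, vec& xdot) {
  int nq = m.nq;
  vec q = x.subvec(0, nq - 1), qd = x.subvec(nq, 2 * nq - 1);
  vec a = (formulation == 0) ? x.subvec(2 * nq, 2 * nq + m.nmus - 1) : u;
  Frames F;
  fk_frames(m, q, F);
  vec lmt, vmt, Fm;
  mat dldq;
  muscle_geometry(m, F, qd, lmt, dldq, vmt);
  hill_forces(m, a, lmt, vmt, Fm);
  vec tau_mus = -dldq.t() * Fm;
  vec nle;
  rnea(m, F, qd, zeros<vec>(nq), true, nle);
  mat M(nq, nq);
  vec col;
  vec e(nq, fill::zeros);
  for (int j = 0; j < nq; ++j) {
    e(j) = 1.0;
    rnea(m, F, zeros<vec>(nq), e, false, col);
    M.col(j) = col;
    e(j) = 0.0;
  }
  vec qdd = solve(M, tau_mus - nle, solve_opts::fast);
  int nx = (formulation == 0) ? 2 * nq + m.nmus : 2 * nq;
  xdot.set_size(nx);
  xdot.subvec(0, nq - 1) = qd;
  xdot.subvec(nq, 2 * nq - 1) = qdd;
  if (formulation == 0)
    for (int mu = 0; mu < m.nmus; ++mu)
      xdot(2 * nq + mu) = act_rate(a(mu), u(mu), m.tact(mu), m.tdeact(mu), m.act_switch_k);
}

void rk4_step(const Model& m, vec& x, const vec& u, double h, int formulation) {
  vec k1, k2, k3, k4;
  dynamics(m, x, u, formulation, k1);
  dynamics(m, x + 0.5 * h * k1, u, formulation, k2);
  dynamics(m, x + 0.5 * h * k2, u, formulation, k3);
  dynamics(m, x + h * k3, u, formulation, k4);
  x += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  if (!x.is_finite()) Rcpp::stop("integration blow-up: non-finite state");
}

void integrate(const Model& m, vec& x, const vec& u, double dt, int nsub, int formulation) {
  double h = dt / nsub;
  for (int i = 0; i < nsub; ++i) rk4_step(m, x, u, h, formulation);
}

// ------------------------------------------------------------------
// Condensed window NLP
// ------------------------------------------------------------------

struct WinSpec {
  int N = 0;                 // frames; N - 1 shooting intervals
  double dt = 0.0;
  int nsub = 1;
  int formulation = 0;
  int variant = 0;           // 0 = EMG tracking, 1 = least-squared excitations
  double wm, we, wrx, wru, wlim;
  mat mark;                  // (3*nmark) x N, NaN = occluded
  mat emg;                   // nmus x N
  bool x0_free = false;
  vec x0;                    // fixed initial state when !x0_free
  int maxit = 50;
  double lam0 = 1e-3;
};

struct WinWork {
  int nx, nu, nz, nres;
  int node_len;              // residual entries per node block
  int ctrl_len;              // residual entries per control block
};

void win_dims(const Model& m, const WinSpec& w, WinWork& wk) {
  wk.nx = (w.formulation == 0) ? 2 * m.nq + m.nmus : 2 * m.nq;
  wk.nu = m.nmus;
  wk.nz = (w.x0_free ? wk.nx : 0) + wk.nu * (w.N - 1);
  wk.node_len = 3 * m.nmark + m.nq + m.nq;        // markers, qdot reg, limit pen
  wk.ctrl_len = 2 * m.nmus;                       // emg/minex term, u reg
  wk.nres = w.N * wk.node_len + (w.N - 1) * wk.ctrl_len;
}

void unpack_z(const WinSpec& w, const WinWork& wk, const vec& z, vec& x0, mat& U) {
  if (w.x0_free) x0 = z.subvec(0, wk.nx - 1);
  else x0 = w.x0;
  U = reshape(z.subvec(w.x0_free ? wk.nx : 0, wk.nz - 1), wk.nu, w.N - 1);
}

// States at all N nodes from (x0, U); from_node lets partial FD restart.
void win_rollout(const Model& m, const WinSpec& w, const vec& x0, const mat& U,
                 mat& X, int from_node = 0) {
  if (from_node == 0) X.col(0) = x0;
  for (int k = std::max(from_node - 1, 0); k < w.N - 1; ++k) {
    vec x = X.col(k);
    integrate(m, x, U.col(k), w.dt, w.nsub, w.formulation);
    X.col(k + 1) = x;
  }
}

// Residual blocks for node k (markers, qdot regularisation, limit penalty)
void node_resid(const Model& m, const WinSpec& w, const WinWork& wk,
                const mat& X, int k, vec& r) {
  int base = k * wk.node_len;
  vec q = X.col(k).subvec(0, m.nq - 1);
  vec qd = X.col(k).subvec(m.nq, 2 * m.nq - 1);
  Frames F;
  fk_frames(m, q, F);
  mat Mk;
  markers_world(m, F, Mk);
  double sm = std::sqrt(w.wm), srx = std::sqrt(w.wrx), sl = std::sqrt(w.wlim);
  for (int j = 0; j < 3 * m.nmark; ++j) {
    double meas = w.mark(j, k);
    r(base + j) = std::isnan(meas) ? 0.0 : sm * (Mk(j % 3, j / 3) - meas);
  }
  for (int j = 0; j < m.nq; ++j) r(base + 3 * m.nmark + j) = srx * qd(j);
  for (int j = 0; j < m.nq; ++j) {
    double v = 0.0;
    if (q(j) > m.qmax(j)) v = q(j) - m.qmax(j);
    else if (q(j) < m.qmin(j)) v = q(j) - m.qmin(j);
    r(base + 3 * m.nmark + m.nq + j) = sl * v;
  }
}

void ctrl_resid(const Model& m, const WinSpec& w, const WinWork& wk,
                const mat& U, int k, vec& r) {
  int base = w.N * wk.node_len + k * wk.ctrl_len;
  double se = std::sqrt(w.we), sru = std::sqrt(w.wru);
  for (int j = 0; j < m.nmus; ++j) {
    double target = (w.variant == 1) ? 0.0 : w.emg(j, k);
    r(base + j) = se * (U(j, k) - target);
    r(base + m.nmus + j) = sru * U(j, k);
  }
}

void full_resid(const Model& m, const WinSpec& w, const WinWork& wk,
                const mat& X, const mat& U, vec& r) {
  for (int k = 0; k < w.N; ++k) node_resid(m, w, wk, X, k, r);
  for (int k = 0; k < w.N - 1; ++k) ctrl_resid(m, w, wk, U, k, r);
}

double max_limit_violation(const Model& m, const WinSpec& w, const mat& X) {
  double v = 0.0;
  for (int k = 0; k < w.N; ++k)
    for (int j = 0; j < m.nq; ++j) {
      double q = X(j, k);
      v = std::max(v, std::max(q - m.qmax(j), m.qmin(j) - q));
    }
  return std::max(v, 0.0);
}

struct WinResult {
  mat X, U;
  bool converged = false;
  int iters = 0;
  double cost = 0.0, limviol = 0.0;
};

void win_bounds(const Model& m, const WinSpec& w, const WinWork& wk, vec& lb, vec& ub) {
  lb.set_size(wk.nz); ub.set_size(wk.nz);
  int off = 0;
  if (w.x0_free) {
    for (int j = 0; j < m.nq; ++j) { lb(j) = m.qmin(j); ub(j) = m.qmax(j); }
    for (int j = 0; j < m.nq; ++j) { lb(m.nq + j) = -50.0; ub(m.nq + j) = 50.0; }
    if (w.formulation == 0)
      for (int j = 0; j < m.nmus; ++j) { lb(2 * m.nq + j) = 0.0; ub(2 * m.nq + j) = 1.0; }
    off = wk.nx;
  }
  for (int j = off; j < wk.nz; ++j) { lb(j) = 0.0; ub(j) = 1.0; }
}

// FD Jacobian exploiting causality: control u_k only affects nodes > k.
void win_jacobian(const Model& m, const WinSpec& w, const WinWork& wk,
                  const vec& z, const mat& X, const vec& r, mat& J) {
  J.zeros(wk.nres, wk.nz);
  vec x0; mat U;
  unpack_z(w, wk, z, x0, U);
  mat Xp = X;
  vec rp = r;
  double h;
  if (w.x0_free) {
    for (int j = 0; j < wk.nx; ++j) {
      vec x0p = x0;
      h = 1e-6 * (1.0 + std::abs(x0(j)));
      x0p(j) += h;
      win_rollout(m, w, x0p, U, Xp, 0);
      full_resid(m, w, wk, Xp, U, rp);
      J.col(j) = (rp - r) / h;
    }
    Xp = X;
  }
  int off = w.x0_free ? wk.nx : 0;
  for (int k = 0; k < w.N - 1; ++k) {
    for (int j = 0; j < wk.nu; ++j) {
      mat Up = U;
      h = 1e-6;
      Up(j, k) += h;
      // recompute only downstream states and affected residual blocks
      Xp.cols(0, k) = X.cols(0, k);
      win_rollout(m, w, x0, Up, Xp, k + 1);
      for (int kk = k + 1; kk < w.N; ++kk) node_resid(m, w, wk, Xp, kk, rp);
      ctrl_resid(m, w, wk, Up, k, rp);
      int col = off + k * wk.nu + j;
      for (int kk = k + 1; kk < w.N; ++kk) {
        int b = kk * wk.node_len;
        for (int t = 0; t < wk.node_len; ++t)
          J(b + t, col) = (rp(b + t) - r(b + t)) / h;
      }
      int b = w.N * wk.node_len + k * wk.ctrl_len;
      for (int t = 0; t < wk.ctrl_len; ++t)
        J(b + t, col) = (rp(b + t) - r(b + t)) / h;
      // restore touched residual entries
      for (int kk = k + 1; kk < w.N; ++kk) {
        int bb = kk * wk.node_len;
        rp.subvec(bb, bb + wk.node_len - 1) = r.subvec(bb, bb + wk.node_len - 1);
      }
      rp.subvec(b, b + wk.ctrl_len - 1) = r.subvec(b, b + wk.ctrl_len - 1);
    }
  }
}

WinResult solve_window(const Model& m, const WinSpec& w, const vec& z_init) {
  WinWork wk;
  win_dims(m, w, wk);
  vec lb, ub;
  win_bounds(m, w, wk, lb, ub);
  vec z = clampv(z_init, lb, ub);
  vec x0; mat U;
  unpack_z(w, wk, z, x0, U);
  mat X(wk.nx, w.N);
  win_rollout(m, w, x0, U, X);
  vec r(wk.nres);
  full_resid(m, w, wk, X, U, r);
  double cost = 0.5 * dot(r, r);
  double lambda = w.lam0;
  mat J;
  bool converged = false;
  int it = 0;
  const double eps_b = 1e-12;
  double gp_inf = datum::inf, gscale = 1.0;
  int j_age = 0;            // stale-Jacobian LM: refresh on poor gain ratio
  for (it = 0; it < w.maxit; ++it) {
    if (it == 0 || j_age >= 4) { win_jacobian(m, w, wk, z, X, r, J); j_age = 0; }
    vec g = J.t() * r;
    // projected gradient (bound-blocked coordinates removed)
    vec gp = g;
    for (int j = 0; j < wk.nz; ++j) {
      if (z(j) <= lb(j) + eps_b && g(j) > 0) gp(j) = 0;
      if (z(j) >= ub(j) - eps_b && g(j) < 0) gp(j) = 0;
    }
    vec coln = sum(square(J), 0).t();
    gscale = std::max(1.0, norm(r) * std::sqrt(coln.max()));
    gp_inf = norm(gp, "inf");
    if (getenv("MHE_TRACE"))
      Rprintf("it %d cost %.10e gp %.3e gscale %.3e lam %.1e age %d\n", it, cost, gp_inf, gscale, lambda, j_age);
    if (j_age == 0 && (gp_inf <= 1e-9 * gscale || norm(r) < 1e-12)) { converged = true; break; }
    std::vector<uword> freev;
    for (int j = 0; j < wk.nz; ++j) {
      bool lo_block = (z(j) <= lb(j) + eps_b) && (g(j) >= 0);
      bool hi_block = (z(j) >= ub(j) - eps_b) && (g(j) <= 0);
      if (!lo_block && !hi_block) freev.push_back(j);
    }
    uvec freeix(freev);
    if (freeix.n_elem == 0) { converged = true; break; }
    mat Jf = J.cols(freeix);
    mat A0 = Jf.t() * Jf;
    vec gf = g(freeix);
    vec dscale = diagvec(A0);
    dscale.transform([](double v) { return std::max(v, 1e-10); });
    bool accepted = false;
    double cost_new = cost, pred = 0.0;
    vec z_new, r_new(wk.nres), d_acc;
    mat X_new = X;
    for (int inner = 0; inner < 25; ++inner) {
      mat A = A0;
      A.diag() += lambda * dscale;
      vec d;
      bool ok = solve(d, A, -gf, solve_opts::no_approx);
      if (ok) {
        z_new = z;
        for (uword t = 0; t < freeix.n_elem; ++t) z_new(freeix(t)) += d(t);
        z_new = clampv(z_new, lb, ub);
        vec x0n; mat Un;
        unpack_z(w, wk, z_new, x0n, Un);
        win_rollout(m, w, x0n, Un, X_new, 0);
        full_resid(m, w, wk, X_new, Un, r_new);
        cost_new = 0.5 * dot(r_new, r_new);
        if (std::isfinite(cost_new) && cost_new < cost) {
          accepted = true;
          d_acc = d;
          pred = -(dot(gf, d) + 0.5 * dot(d, A0 * d));
          lambda = std::max(lambda / 3.0, 1e-12);
          break;
        }
      }
      lambda *= 4.0;
      if (lambda > 1e14) break;
    }
    if (!accepted) {
      if (j_age > 0) { win_jacobian(m, w, wk, z, X, r, J); j_age = 0; --it; continue; }
      // stalled with a fresh Jacobian (typically at FD-precision floor)
      converged = gp_inf <= 1e-4 * gscale;
      break;
    }
    double dz = norm(z_new - z, "inf");
    double dcost = cost - cost_new;
    z = z_new; r = r_new; cost = cost_new;
    unpack_z(w, wk, z, x0, U);
    win_rollout(m, w, x0, U, X);
    if (getenv("MHE_TRACE")) Rprintf("   dz %.3e dcost %.3e pred %.3e\n", dz, dcost, pred);
    if (dz < 1e-6 * (1.0 + norm(z, "inf")) || dcost < 1e-6 * std::max(cost, 1e-10)) {
      converged = true; ++it; break;
    }
    j_age = (pred > 0 && dcost < 0.25 * pred) ? 4 : j_age + 1;
  }
  WinResult res;
  res.X = X; res.U = U;
  res.iters = it;
  res.cost = cost;
  res.limviol = max_limit_violation(m, w, X);
  res.converged = converged && res.limviol <= 1e-6;
  return res;
}

WinSpec make_winspec(const Model& m, const Rcpp::List& opts) {
  WinSpec w;
  w.dt = Rcpp::as<double>(opts["dt"]);
  w.nsub = Rcpp::as<int>(opts["nsub"]);
  w.formulation = Rcpp::as<int>(opts["formulation"]);
  w.variant = Rcpp::as<int>(opts["variant"]);
  w.wm = Rcpp::as<double>(opts["wm"]);
  w.we = Rcpp::as<double>(opts["we"]);
  w.wrx = Rcpp::as<double>(opts["wrx"]);
  w.wru = Rcpp::as<double>(opts["wru"]);
  w.wlim = Rcpp::as<double>(opts["wlim"]);
  w.maxit = Rcpp::as<int>(opts["maxit"]);
  return w;
}

}  // namespace

// ------------------------------------------------------------------
// Exported primitives
// ------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_forward_kinematics(Rcpp::List model, arma::vec q) {
  Model m = parse_model(model);
  Frames F;
  fk_frames(m, q, F);
  mat M;
  markers_world(m, F, M);
  Rcpp::List frames(m.nq);
  for (int i = 0; i < m.nq; ++i) {
    mat T = eye(4, 4);
    T.submat(0, 0, 2, 2) = F.R[i];
    T.submat(0, 3, 2, 3) = F.o[i];
    frames[i] = T;
  }
  return Rcpp::List::create(Rcpp::Named("markers") = mat(M.t()),
                            Rcpp::Named("frames") = frames);
}

// [[Rcpp::export]]
Rcpp::List cpp_muscle_geometry(Rcpp::List model, arma::vec q, arma::vec qdot) {
  Model m = parse_model(model);
  Frames F;
  fk_frames(m, q, F);
  vec lmt, vmt;
  mat dldq;
  muscle_geometry(m, F, qdot, lmt, dldq, vmt);
  return Rcpp::List::create(Rcpp::Named("lmt") = lmt,
                            Rcpp::Named("vmt") = vmt,
                            Rcpp::Named("moment_arms") = mat(-dldq));
}

// [[Rcpp::export]]
arma::vec cpp_hill_forces(Rcpp::List model, arma::vec a, arma::vec lmt, arma::vec vmt) {
  Model m = parse_model(model);
  vec F;
  hill_forces(m, a, lmt, vmt, F);
  return F;
}

// [[Rcpp::export]]
arma::vec cpp_activation_rate(Rcpp::List model, arma::vec a, arma::vec e) {
  Model m = parse_model(model);
  vec r(m.nmus);
  for (int mu = 0; mu < m.nmus; ++mu)
    r(mu) = act_rate(a(mu), e(mu), m.tact(mu), m.tdeact(mu), m.act_switch_k);
  return r;
}

// [[Rcpp::export]]
arma::vec cpp_forward_dynamics(Rcpp::List model, arma::vec x, arma::vec u, int formulation) {
  Model m = parse_model(model);
  vec xdot;
  dynamics(m, x, u, formulation, xdot);
  return xdot;
}

// [[Rcpp::export]]
arma::vec cpp_inverse_dynamics(Rcpp::List model, arma::vec q, arma::vec qd, arma::vec qdd,
                               bool with_gravity) {
  Model m = parse_model(model);
  Frames F;
  fk_frames(m, q, F);
  vec tau;
  rnea(m, F, qd, qdd, with_gravity, tau);
  return tau;
}

// [[Rcpp::export]]
arma::vec cpp_integrate_interval(Rcpp::List model, arma::vec x0, arma::vec u,
                                 double dt, int nsteps, int formulation) {
  Model m = parse_model(model);
  vec x = x0;
  integrate(m, x, u, dt, nsteps, formulation);
  return x;
}

// [[Rcpp::export]]
arma::mat cpp_rollout(Rcpp::List model, arma::vec x0, arma::mat U,
                      double dt, int nsub, int formulation) {
  Model m = parse_model(model);
  int T = U.n_cols + 1;
  mat X(x0.n_elem, T);
  X.col(0) = x0;
  vec x = x0;
  for (int k = 0; k < T - 1; ++k) {
    integrate(m, x, U.col(k), dt, nsub, formulation);
    X.col(k + 1) = x;
  }
  return X;
}

// ------------------------------------------------------------------
// Window solve / MHE loop
// ------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_solve_window(Rcpp::List model, Rcpp::List opts,
                            arma::mat mark, arma::mat emg,
                            Rcpp::Nullable<Rcpp::NumericVector> x0_fixed,
                            arma::vec x0_init, arma::mat U_init) {
  Model m = parse_model(model);
  WinSpec w = make_winspec(m, opts);
  w.N = mark.n_cols;
  w.mark = mark;
  w.emg = emg;
  if (x0_fixed.isNotNull()) {
    w.x0_free = false;
    w.x0 = Rcpp::as<vec>(x0_fixed);
  } else {
    w.x0_free = true;
  }
  WinWork wk;
  win_dims(m, w, wk);
  vec z(wk.nz);
  int off = 0;
  if (w.x0_free) { z.subvec(0, wk.nx - 1) = x0_init; off = wk.nx; }
  z.subvec(off, wk.nz - 1) = vectorise(U_init);
  WinResult res = solve_window(m, w, z);
  return Rcpp::List::create(
      Rcpp::Named("X") = res.X, Rcpp::Named("U") = res.U,
      Rcpp::Named("converged") = res.converged, Rcpp::Named("iterations") = res.iters,
      Rcpp::Named("cost") = res.cost, Rcpp::Named("limit_violation") = res.limviol);
}

// [[Rcpp::export]]
Rcpp::List cpp_run_mhe(Rcpp::List model, Rcpp::List opts,
                       arma::mat mark, arma::mat emg, int N,
                       arma::vec x0_init, arma::mat U_init) {
  Model m = parse_model(model);
  WinSpec w = make_winspec(m, opts);
  w.N = N;
  int T = mark.n_cols;
  if (T < N + 1) Rcpp::stop("stream shorter than window");
  w.x0_free = true;
  WinWork wk;
  win_dims(m, w, wk);
  int nstep = T - N + 1;
  mat Xs(wk.nx, nstep), Us(wk.nu, nstep);
  Rcpp::LogicalVector conv(nstep);
  Rcpp::IntegerVector iters(nstep);
  Rcpp::NumericVector ms(nstep), costs(nstep);

  // first window: free initial state
  w.mark = mark.cols(0, N - 1);
  w.emg = emg.cols(0, N - 1);
  w.x0_free = true;
  vec z(wk.nz);
  z.subvec(0, wk.nx - 1) = x0_init;
  z.subvec(wk.nx, wk.nz - 1) = vectorise(U_init);
  auto t0 = std::chrono::steady_clock::now();
  WinResult prev = solve_window(m, w, z);
  auto t1 = std::chrono::steady_clock::now();
  ms[0] = std::chrono::duration<double, std::milli>(t1 - t0).count();
  Xs.col(0) = prev.X.col(0); Us.col(0) = prev.U.col(0);
  conv[0] = prev.converged; iters[0] = prev.iters; costs[0] = prev.cost;

  w.x0_free = false;
  WinWork wk2;
  win_dims(m, w, wk2);
  for (int s = 1; s < nstep; ++s) {
    w.mark = mark.cols(s, s + N - 1);
    w.emg = emg.cols(s, s + N - 1);
    w.x0 = prev.X.col(1);                         // initial-state chaining
    mat Uw(wk2.nu, N - 1);
    if (N >= 3) {
      Uw.cols(0, N - 3) = prev.U.cols(1, N - 2);  // shift warm start
      Uw.col(N - 2) = prev.U.col(N - 2);          // hold last control
    } else {
      Uw = prev.U;
    }
    vec z2 = vectorise(Uw);
    t0 = std::chrono::steady_clock::now();
    WinResult cur = solve_window(m, w, z2);
    t1 = std::chrono::steady_clock::now();
    ms[s] = std::chrono::duration<double, std::milli>(t1 - t0).count();
    if (!cur.converged && !std::isfinite(cur.cost)) {
      // catastrophic failure: fall back to the shifted previous solution,
      // which keeps the stored sequence dynamically consistent
      mat Xf = cur.X;
      Xf.cols(0, N - 2) = prev.X.cols(1, N - 1);
      Xf.col(N - 1) = prev.X.col(N - 1);
      cur.X = Xf; cur.U = Uw;
      cur.cost = datum::inf;
    }
    Xs.col(s) = cur.X.col(0); Us.col(s) = cur.U.col(0);
    conv[s] = cur.converged; iters[s] = cur.iters; costs[s] = cur.cost;
    prev = cur;
  }
  return Rcpp::List::create(
      Rcpp::Named("X") = Xs, Rcpp::Named("U") = Us,
      Rcpp::Named("converged") = conv, Rcpp::Named("iterations") = iters,
      Rcpp::Named("cost") = costs, Rcpp::Named("ms") = ms,
      Rcpp::Named("X_last") = prev.X, Rcpp::Named("U_last") = prev.U);
}

// ------------------------------------------------------------------
// Reference generation helpers
// ------------------------------------------------------------------

// Per-interval optimal tracking: land the RK4 rollout on the planned nodes.
// The correction is parametrized as u = e_plan + Bc v with a fixed pattern
// matrix Bc (nmus x nv, typically a damped pseudo-inverse of the torque
// gains), so the per-node problem is square and has no redundant null space
// -- the closed loop then converges to a periodic orbit instead of letting
// synergist activations wander. Returns states (nx x (T+1)), controls
// (nmus x T).
// [[Rcpp::export]]
Rcpp::List cpp_track_reference(Rcpp::List model, arma::vec x0,
                               arma::mat qref, arma::mat qdref,
                               arma::mat eplan, arma::mat Bc,
                               double dt, int nsub,
                               double wq, double wqd, double wv) {
  Model m = parse_model(model);
  int T = eplan.n_cols;
  int nv = Bc.n_cols;
  int nx = 2 * m.nq + m.nmus;
  mat X(nx, T + 1), U(m.nmus, T);
  X.col(0) = x0;
  int nres = 2 * m.nq + nv;
  vec r(nres), rp(nres);
  double sq = std::sqrt(wq), sqd = std::sqrt(wqd), sv = std::sqrt(wv);
  vec carry(nv, fill::zeros);       // previous node's correction, warm start
  for (int k = 0; k < T; ++k) {
    vec v = carry;
    vec xk = X.col(k);
    auto resid = [&](const vec& vv, vec& out) {
      vec uu = clamp(eplan.col(k) + Bc * vv, 0.0, 1.0);
      vec x = xk;
      integrate(m, x, uu, dt, nsub, 0);
      for (int j = 0; j < m.nq; ++j) {
        out(j) = sq * (x(j) - qref(j, k + 1));
        out(m.nq + j) = sqd * (x(m.nq + j) - qdref(j, k + 1));
      }
      for (int j = 0; j < nv; ++j) out(2 * m.nq + j) = sv * vv(j);
    };
    resid(v, r);
    double cost = 0.5 * dot(r, r), lambda = 1e-4;
    mat J(nres, nv);
    for (int it = 0; it < 50; ++it) {
      for (int j = 0; j < nv; ++j) {
        vec vp = v;
        double h = 1e-6;
        vp(j) += h;
        resid(vp, rp);
        J.col(j) = (rp - r) / h;
      }
      vec g = J.t() * r;
      if (norm(g, "inf") < 1e-11 * std::max(1.0, norm(r) * norm(J, "inf"))) break;
      mat A0 = J.t() * J;
      vec ds = diagvec(A0);
      ds.transform([](double x) { return std::max(x, 1e-12); });
      bool accepted = false;
      for (int inner = 0; inner < 25; ++inner) {
        mat A = A0;
        A.diag() += lambda * ds;
        vec d = solve(A, -g);
        vec vn = v + d;
        resid(vn, rp);
        double cn = 0.5 * dot(rp, rp);
        if (std::isfinite(cn) && cn < cost) {
          v = vn; r = rp;
          double dcost = cost - cn;
          cost = cn;
          lambda = std::max(lambda / 3.0, 1e-12);
          accepted = true;
          if (dcost < 1e-15 * std::max(cost, 1e-12)) it = 1000;
          break;
        }
        lambda *= 5.0;
        if (lambda > 1e14) break;
      }
      if (!accepted) break;
    }
    vec u = clamp(eplan.col(k) + Bc * v, 0.0, 1.0);
    U.col(k) = u;
    carry = v;
    vec x = xk;
    integrate(m, x, u, dt, nsub, 0);
    X.col(k + 1) = x;
  }
  return Rcpp::List::create(Rcpp::Named("X") = X, Rcpp::Named("U") = U);
}

// Static redundancy: activations reproducing required torques at one node.
// Torque is affine in the activations, so this is a bounded linear LSQ.
// [[Rcpp::export]]
arma::vec cpp_static_activation(Rcpp::List model, arma::vec q, arma::vec qd, arma::vec qdd,
                                arma::vec a_pref, arma::vec w_pref, double wtau) {
  Model m = parse_model(model);
  Frames F;
  fk_frames(m, q, F);
  vec lmt, vmt, tau_req;
  mat dldq;
  muscle_geometry(m, F, qd, lmt, dldq, vmt);
  rnea(m, F, qd, qdd, true, tau_req);
  // torque(a) = B a + c
  mat B(m.nq, m.nmus);
  vec Fa0, Fa1, zero_a(m.nmus, fill::zeros), one_a(m.nmus);
  hill_forces(m, zero_a, lmt, vmt, Fa0);
  vec c = -dldq.t() * Fa0;
  for (int mu = 0; mu < m.nmus; ++mu) {
    one_a.zeros(); one_a(mu) = 1.0;
    hill_forces(m, one_a, lmt, vmt, Fa1);
    B.col(mu) = -dldq.t() * (Fa1 - Fa0);
  }
  double st = std::sqrt(wtau);
  mat A(m.nq + m.nmus, m.nmus, fill::zeros);
  vec b(m.nq + m.nmus);
  A.rows(0, m.nq - 1) = st * B;
  b.subvec(0, m.nq - 1) = st * (tau_req - c);
  for (int mu = 0; mu < m.nmus; ++mu) {
    A(m.nq + mu, mu) = std::sqrt(w_pref(mu));
    b(m.nq + mu) = std::sqrt(w_pref(mu)) * a_pref(mu);
  }
  // box-constrained convex QP by monotone projected Newton
  mat H = A.t() * A;
  vec Atb = A.t() * b;
  vec hd = diagvec(H);
  vec a = clamp(solve(H + 1e-10 * eye(m.nmus, m.nmus), Atb), 0.0, 1.0);
  vec ra = A * a - b;
  double cost = dot(ra, ra);
  for (int pass = 0; pass < 100; ++pass) {
    vec g = H * a - Atb;
    std::vector<uword> freev;
    double gp = 0.0;
    for (int mu = 0; mu < m.nmus; ++mu) {
      bool lo_block = (a(mu) <= 1e-12) && (g(mu) >= 0);
      bool hi_block = (a(mu) >= 1.0 - 1e-12) && (g(mu) <= 0);
      if (!lo_block && !hi_block) {
        freev.push_back(mu);
        gp = std::max(gp, std::abs(g(mu)));
      }
    }
    if (freev.empty() || gp <= 1e-10 * (1.0 + norm(Atb, "inf"))) break;
    uvec freeix(freev);
    vec d(m.nmus, fill::zeros);
    mat Hf = H.submat(freeix, freeix);
    vec df = solve(Hf + 1e-12 * eye(freeix.n_elem, freeix.n_elem), -g(freeix));
    d(freeix) = df;
    double t = 1.0;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      vec an = clamp(a + t * d, 0.0, 1.0);
      vec rn = A * an - b;
      double cn = dot(rn, rn);
      if (cn < cost * (1.0 - 1e-14)) { a = an; cost = cn; ok = true; break; }
      t *= 0.5;
    }
    if (!ok) break;
  }
  return a;
}

// Marker-fit inverse kinematics (Gauss-Newton with mild regularisation).
// [[Rcpp::export]]
arma::vec cpp_inverse_kinematics(Rcpp::List model, arma::vec mark_target, arma::vec q0) {
  Model m = parse_model(model);
  vec q = clampv(q0, m.qmin, m.qmax);
  int nres = 3 * m.nmark + m.nq;
  vec r(nres), rp(nres);
  auto resid = [&](const vec& qq, vec& out) {
    Frames F;
    fk_frames(m, qq, F);
    mat M;
    markers_world(m, F, M);
    for (int j = 0; j < 3 * m.nmark; ++j) {
      double t = mark_target(j);
      out(j) = std::isnan(t) ? 0.0 : (M(j % 3, j / 3) - t);
    }
    for (int j = 0; j < m.nq; ++j) out(3 * m.nmark + j) = 1e-4 * (qq(j) - q0(j));
  };
  resid(q, r);
  double cost = 0.5 * dot(r, r), lambda = 1e-3;
  mat J(nres, m.nq);
  for (int it = 0; it < 100; ++it) {
    for (int j = 0; j < m.nq; ++j) {
      vec qp = q;
      double h = 1e-7;
      qp(j) += h;
      resid(qp, rp);
      J.col(j) = (rp - r) / h;
    }
    vec g = J.t() * r;
    if (norm(g, "inf") < 1e-12) break;
    mat A0 = J.t() * J;
    bool accepted = false;
    for (int inner = 0; inner < 20; ++inner) {
      mat A = A0;
      A.diag() += lambda * clamp(diagvec(A0), 1e-12, datum::inf);
      vec d = solve(A, -g);
      vec qn = clampv(q + d, m.qmin, m.qmax);
      resid(qn, rp);
      double cn = 0.5 * dot(rp, rp);
      if (std::isfinite(cn) && cn < cost) {
        q = qn; r = rp;
        double dc = cost - cn;
        cost = cn;
        lambda = std::max(lambda / 3.0, 1e-12);
        accepted = true;
        if (dc < 1e-18) it = 1000;
        break;
      }
      lambda *= 5.0;
    }
    if (!accepted) break;
  }
  return q;
}
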