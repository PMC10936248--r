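// Serial-chain kinematics core: forward kinematics under the standard
// (distal) Denavit-Hartenberg convention and damped least-squares inverse
// kinematics with joint-limit projection. Compiled because trajectory IK
// (thousands of poses per trial) and the exhaustive design search dominate
// runtime.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Elementary DH transform: Rot_z(theta) * Trans_z(d) * Trans_x(a) * Rot_x(alpha)
static mat44 dh_transform(double a, double alpha, double d, double theta) {
  double ct = std::cos(theta), st = std::sin(theta);
  double ca = std::cos(alpha), sa = std::sin(alpha);
  mat44 T;
  T(0,0) = ct; T(0,1) = -st*ca; T(0,2) =  st*sa; T(0,3) = a*ct;
  T(1,0) = st; T(1,1) =  ct*ca; T(1,2) = -ct*sa; T(1,3) = a*st;
  T(2,0) = 0;  T(2,1) =  sa;    T(2,2) =  ca;    T(2,3) = d;
  T(3,0) = 0;  T(3,1) = 0;      T(3,2) = 0;      T(3,3) = 1;
  return T;
}

// Accumulate frames 0..n. origins: 3 x (n+1), axes (frame z): 3 x (n+1).
// Joint i (1-based) rotates about axes.col(i-1) through origins.col(i-1).
static void fk_frames(const mat& par, const vec& q,
                      mat& origins, mat& axes, mat44& Tend) {
  const uword n = par.n_rows;
  mat44 T; T.eye();
  origins.set_size(3, n + 1);
  axes.set_size(3, n + 1);
  origins.col(0) = T.submat(0,3,2,3);
  axes.col(0) = T.submat(0,2,2,2);
  for (uword i = 0; i < n; ++i) {
    T = T * dh_transform(par(i,0), par(i,1), par(i,2), par(i,3) + q(i));
    origins.col(i+1) = T.submat(0,3,2,3);
    axes.col(i+1) = T.submat(0,2,2,2);
  }
  Tend = T;
}

// [[Rcpp::export(name = ".fk_cpp")]]
Rcpp::List fk_cpp(const arma::mat& par, const arma::vec& q) {
  mat origins, axes; mat44 Tend;
  fk_frames(par, q, origins, axes, Tend);
  return Rcpp::List::create(
    Rcpp::Named("transform") = mat(Tend),
    Rcpp::Named("origins") = origins,
    Rcpp::Named("axes") = axes);
}

// 6-vector pose error target-vs-current: position (mm) stacked with
// axis-angle orientation error scaled by char_len (mm per radian).
static vec pose_error(const mat44& Tcur, const mat33& Rt, const vec3& pt,
                      double char_len, bool position_only,
                      double& pos_err, double& ori_err) {
  vec3 p = Tcur.submat(0,3,2,3);
  mat33 Rc = Tcur.submat(0,0,2,2);
  vec3 ep = pt - p;
  pos_err = norm(ep);
  vec e(6, fill::zeros);
  e.subvec(0,2) = ep;
  if (position_only) { ori_err = 0.0; return e; }
  mat33 Rerr = Rt * Rc.t();
  double c = (trace(Rerr) - 1.0) / 2.0;
  c = std::max(-1.0, std::min(1.0, c));
  double ang = std::acos(c);
  vec3 w;
  w(0) = Rerr(2,1) - Rerr(1,2);
  w(1) = Rerr(0,2) - Rerr(2,0);
  w(2) = Rerr(1,0) - Rerr(0,1);
  double s = norm(w);          // = 2 sin(angle)
  if (c > 0.0 && s < 1e-3) {
    // small rotation: acos loses precision, use asin of the skew part
    ang = std::asin(std::min(1.0, s / 2.0));
    w *= 0.5;
  } else if (s > 1e-12) {
    w *= ang / s;
  } else if (ang > 1.0) {
    // angle near pi: recover axis from the symmetric part
    vec3 ax;
    ax(0) = std::sqrt(std::max(0.0, (Rerr(0,0)+1.0)/2.0));
    ax(1) = std::sqrt(std::max(0.0, (Rerr(1,1)+1.0)/2.0));
    ax(2) = std::sqrt(std::max(0.0, (Rerr(2,2)+1.0)/2.0));
    if (ax(0) > ax(1) && ax(0) > ax(2)) {
      ax(1) = (Rerr(0,1)+Rerr(1,0))/(4*ax(0)); ax(2) = (Rerr(0,2)+Rerr(2,0))/(4*ax(0));
    } else if (ax(1) > ax(2)) {
      ax(0) = (Rerr(0,1)+Rerr(1,0))/(4*ax(1)); ax(2) = (Rerr(1,2)+Rerr(2,1))/(4*ax(1));
    } else if (ax(2) > 0) {
      ax(0) = (Rerr(0,2)+Rerr(2,0))/(4*ax(2)); ax(1) = (Rerr(1,2)+Rerr(2,1))/(4*ax(2));
    }
    w = ang * normalise(ax);
  } else {
    w *= 0.5; // small-angle fallback
  }
  ori_err = ang;
  e.subvec(3,5) = char_len * w;
  return e;
}

struct IKResult { vec q; double pos_err; double ori_err; bool converged; int iters; };

// element-wise joint-limit projection
static vec clampv(const vec& q, const vec& lo, const vec& hi) {
  return arma::min(arma::max(q, lo), hi);
}

static IKResult ik_dls(const mat& par, const mat33& Rt, const vec3& pt,
                       vec q, const vec& qmin, const vec& qmax,
                       int max_iter, double lambda0, double char_len,
                       double tol_pos, double tol_ori_rad,
                       bool position_only, double stop_tol) {
  const uword n = par.n_rows;
  mat origins, axes; mat44 Tcur;
  double lambda = lambda0;
  q = clampv(q, qmin, qmax);
  fk_frames(par, q, origins, axes, Tcur);
  double pos_err, ori_err;
  vec e = pose_error(Tcur, Rt, pt, char_len, position_only, pos_err, ori_err);
  double err = norm(e);
  int it = 0;
  for (; it < max_iter; ++it) {
    if (err < stop_tol) break;
    vec3 p_e = Tcur.submat(0,3,2,3);
    mat J(6, n, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      vec3 z = axes.col(i);
      vec3 o = origins.col(i);
      J.submat(0, i, 2, i) = cross(z, p_e - o);
      J.submat(3, i, 5, i) = char_len * z;
    }
    if (position_only) J.rows(3,5).zeros();
    bool accepted = false;
    for (int tries = 0; tries < 8 && !accepted; ++tries) {
      mat H = J.t() * J;
      H.diag() += lambda * lambda;
      vec dq;
      bool ok = solve(dq, H, J.t() * e, solve_opts::fast + solve_opts::no_approx);
      if (ok) {
        vec q_new = clampv(q + dq, qmin, qmax);
        mat o2, a2; mat44 T2;
        fk_frames(par, q_new, o2, a2, T2);
        double pe2, oe2;
        vec e2 = pose_error(T2, Rt, pt, char_len, position_only, pe2, oe2);
        double err2 = norm(e2);
        if (err2 < err) {
          q = q_new; Tcur = T2; origins = o2; axes = a2;
          e = e2; err = err2; pos_err = pe2; ori_err = oe2;
          lambda = std::max(lambda / 10.0, 1e-12);
          accepted = true;
        }
      }
      if (!accepted) lambda *= 10.0;
    }
    if (!accepted) break; // stalled
  }
  IKResult res;
  res.q = q; res.pos_err = pos_err; res.ori_err = ori_err; res.iters = it;
  res.converged = (pos_err <= tol_pos) &&
                  (position_only || ori_err <= tol_ori_rad);
  return res;
}

// deterministic restarts: damped least squares is occasionally trapped in a
// local minimum when seeded far from the solution; retry from perturbed and
// canonical seeds, keeping the best result.
static IKResult ik_robust(const mat& par, const mat33& Rt, const vec3& pt,
                          const vec& q0, const vec& qmin, const vec& qmax,
                          int max_iter, double lambda0, double char_len,
                          double tol_pos, double tol_ori_rad,
                          bool position_only, double stop_tol, int restarts) {
  IKResult best = ik_dls(par, Rt, pt, q0, qmin, qmax, max_iter, lambda0,
                         char_len, tol_pos, tol_ori_rad, position_only,
                         stop_tol);
  if (best.converged || restarts <= 0) return best;
  const uword n = par.n_rows;
  std::vector<vec> seeds;
  seeds.push_back((qmin + qmax) / 2.0);
  double signs[4][2] = {{1,1},{-1,-1},{1,-1},{-1,1}};
  for (int k = 0; k < 4; ++k) {
    vec d(n);
    for (uword i = 0; i < n; ++i) d(i) = 0.5 * signs[k][i % 2];
    seeds.push_back(clampv(q0 + d, qmin, qmax));
  }
  int tried = 0;
  for (const vec& s : seeds) {
    if (tried++ >= restarts) break;
    IKResult r = ik_dls(par, Rt, pt, s, qmin, qmax, max_iter, lambda0,
                        char_len, tol_pos, tol_ori_rad, position_only,
                        stop_tol);
    double rscore = r.pos_err + char_len * r.ori_err;
    double bscore = best.pos_err + char_len * best.ori_err;
    if (r.converged || rscore < bscore) best = r;
    if (best.converged) break;
  }
  return best;
}

// [[Rcpp::export(name = ".ik_cpp")]]
Rcpp::List ik_cpp(const arma::mat& par, const arma::mat& target,
                  const arma::vec& q_init,
                  const arma::vec& qmin, const arma::vec& qmax,
                  int max_iter, double lambda0, double char_len,
                  double tol_pos, double tol_ori_rad,
                  bool position_only, double stop_tol) {
  mat33 Rt = target.submat(0,0,2,2);
  vec3 pt = target.submat(0,3,2,3);
  IKResult r = ik_robust(par, Rt, pt, q_init, qmin, qmax, max_iter, lambda0,
                         char_len, tol_pos, tol_ori_rad, position_only,
                         stop_tol, 5);
  return Rcpp::List::create(
    Rcpp::Named("q") = r.q,
    Rcpp::Named("pos_err") = r.pos_err,
    Rcpp::Named("ori_err") = r.ori_err,
    Rcpp::Named("converged") = r.converged,
    Rcpp::Named("iters") = r.iters);
}

// Trajectory IK with warm starts: targets is 4 x (4*m) horizontally stacked
// homogeneous transforms. Returns joint matrix m x n plus residuals.
// [[Rcpp::export(name = ".ik_traj_cpp")]]
Rcpp::List ik_traj_cpp(const arma::mat& par, const arma::mat& targets,
                       const arma::vec& q_init,
                       const arma::vec& qmin, const arma::vec& qmax,
                       int max_iter, double lambda0, double char_len,
                       double tol_pos, double tol_ori_rad,
                       bool position_only, double stop_tol) {
  const uword m = targets.n_cols / 4;
  const uword n = par.n_rows;
  mat Q(m, n);
  vec pos_err(m), ori_err(m);
  Rcpp::LogicalVector conv(m);
  vec q = q_init;
  for (uword k = 0; k < m; ++k) {
    mat44 T = targets.submat(0, 4*k, 3, 4*k + 3);
    mat33 Rt = T.submat(0,0,2,2);
    vec3 pt = T.submat(0,3,2,3);
    IKResult r = ik_robust(par, Rt, pt, q, qmin, qmax, max_iter, lambda0,
                           char_len, tol_pos, tol_ori_rad, position_only,
                           stop_tol, 3);
    Q.row(k) = r.q.t();
    pos_err(k) = r.pos_err; ori_err(k) = r.ori_err; conv(k) = r.converged;
    q = r.q; // warm start for the next sample
  }
  return Rcpp::List::create(
    Rcpp::Named("q") = Q,
    Rcpp::Named("pos_err") = pos_err,
    Rcpp::Named("ori_err") = ori_err,
    Rcpp::Named("converged") = conv);
}

// Reachability screen for the design search: position-only IK over a point
// cloud with warm starts; early exit on first unreachable point when
// early_exit is true. Returns reached count and the joint solutions.
// [[Rcpp::export(name = ".reach_cpp")]]
Rcpp::List reach_cpp(const arma::mat& par, const arma::mat& points,
                     const arma::vec& q_init,
                     const arma::vec& qmin, const arma::vec& qmax,
                     int max_iter, double lambda0, double tol_reach,
                     bool early_exit) {
  const uword m = points.n_cols;
  const uword n = par.n_rows;
  mat33 Reye; Reye.eye();
  mat Q(m, n, fill::value(datum::nan));
  vec pos_err(m, fill::value(datum::nan));
  uword reached = 0, evaluated = 0;
  vec q = q_init;
  for (uword k = 0; k < m; ++k) {
    vec3 pt = points.col(k);
    IKResult r = ik_robust(par, Reye, pt, q, qmin, qmax, max_iter, lambda0,
                           100.0, tol_reach, 1e9, true, tol_reach * 1e-3, 5);
    Q.row(k) = r.q.t();
    pos_err(k) = r.pos_err;
    ++evaluated;
    if (r.converged) { ++reached; q = r.q; }
    else if (early_exit) break;
  }
  return Rcpp::List::create(
    Rcpp::Named("reached") = (int)reached,
    Rcpp::Named("evaluated") = (int)evaluated,
    Rcpp::Named("q") = Q,
    Rcpp::Named("pos_err") = pos_err);
}
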