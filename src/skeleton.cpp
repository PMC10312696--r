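// Rigid-body kernels for articulated skeletons: forward kinematics,
// marker placement, analytic Jacobians, composite mass matrix and
// Newton-Euler inverse dynamics.  All quantities are SI (m, kg, s, rad).
//
// The "model" argument is the compiled list produced by skel_compile() on
// the R side: plain arrays ordered so that every parent precedes its child.
// Joint types: 0 = free6 (3 translations then XYZ-intrinsic Euler),
// 1 = ball3 (XYZ Euler), 2 = universal2 (two axes), 3 = revolute1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

namespace {

struct Model {
  int ns, nq, nm;
  arma::ivec parent;   // parent segment index, -1 at root
  arma::ivec jtype;    // joint type code of the joint above each segment
  arma::ivec dof0;     // first q index of that joint (0-based)
  arma::ivec ndof;
  mat poff, coff;      // 3 x ns joint offsets (unscaled, local frames)
  cube porient, corient; // 3x3xns constant joint-frame rotations
  cube axes;           // 3x3xns joint axes (columns; used by rev/universal)
  mat com;             // 3 x ns local COM (unscaled)
  vec mass0;
  cube inertia0;       // 3x3xns at COM, unscaled, for mass0
  vec gravity;
  arma::ivec marker_seg; // 0-based segment per marker
};

Model unpack(const List& m) {
  Model M;
  M.ns = as<int>(m["ns"]);
  M.nq = as<int>(m["nq"]);
  M.parent = as<arma::ivec>(m["parent"]);
  M.jtype = as<arma::ivec>(m["jtype"]);
  M.dof0 = as<arma::ivec>(m["dof0"]);
  M.ndof = as<arma::ivec>(m["ndof"]);
  M.poff = as<mat>(m["poff"]);
  M.coff = as<mat>(m["coff"]);
  M.porient = as<cube>(m["porient"]);
  M.corient = as<cube>(m["corient"]);
  M.axes = as<cube>(m["axes"]);
  M.com = as<mat>(m["com"]);
  M.mass0 = as<vec>(m["mass0"]);
  M.inertia0 = as<cube>(m["inertia0"]);
  M.gravity = as<vec>(m["gravity"]);
  M.marker_seg = as<arma::ivec>(m["marker_seg"]);
  M.nm = M.marker_seg.n_elem;
  return M;
}

mat rot_x(double a) {
  mat R(3,3,arma::fill::eye);
  double c = std::cos(a), s = std::sin(a);
  R(1,1)=c; R(1,2)=-s; R(2,1)=s; R(2,2)=c;
  return R;
}
mat rot_y(double a) {
  mat R(3,3,arma::fill::eye);
  double c = std::cos(a), s = std::sin(a);
  R(0,0)=c; R(0,2)=s; R(2,0)=-s; R(2,2)=c;
  return R;
}
mat rot_z(double a) {
  mat R(3,3,arma::fill::eye);
  double c = std::cos(a), s = std::sin(a);
  R(0,0)=c; R(0,1)=-s; R(1,0)=s; R(1,1)=c;
  return R;
}
mat rot_axis(const vec& u, double a) {
  // Rodrigues formula, |u| = 1
  mat K(3,3,arma::fill::zeros);
  K(0,1)=-u(2); K(0,2)=u(1); K(1,0)=u(2); K(1,2)=-u(0); K(2,0)=-u(1); K(2,1)=u(0);
  return arma::eye(3,3) + std::sin(a)*K + (1.0-std::cos(a))*(K*K);
}
vec cross3(const vec& a, const vec& b) { return arma::cross(a, b); }

// Per-configuration kinematic state shared by all downstream routines.
struct KinState {
  mat o;            // 3 x ns segment origins (world)
  cube R;           // 3x3xns segment rotations (world)
  // per-dof records for Jacobians
  mat dof_axis;     // 3 x nq world axis
  mat dof_anchor;   // 3 x nq world rotation/translation anchor
  arma::ivec dof_rot;   // 1 rotational, 0 translational
  arma::ivec dof_seg;   // segment whose joint owns the dof
  // scale sensitivities of segment origins: ns entries of 3 x (3*ns)
  cube dO;          // 3 x 3ns x ns
};

// Forward kinematics with per-axis segment scaling s (length 3*ns).
KinState fk(const Model& M, const vec& s, const vec& q, bool want_ds) {
  KinState K;
  K.o.set_size(3, M.ns);
  K.R.set_size(3, 3, M.ns);
  K.dof_axis.set_size(3, M.nq);
  K.dof_anchor.set_size(3, M.nq);
  K.dof_rot.set_size(M.nq);
  K.dof_seg.set_size(M.nq);
  if (want_ds) K.dO.zeros(3, 3*M.ns, M.ns);

  for (int i = 0; i < M.ns; ++i) {
    int p = M.parent(i);
    mat Rp = (p >= 0) ? mat(K.R.slice(p)) : arma::eye(3,3);
    vec op = (p >= 0) ? vec(K.o.col(p)) : vec(3, arma::fill::zeros);
    vec sp = (p >= 0) ? vec(s.subvec(3*p, 3*p+2)) : vec(3, arma::fill::ones);
    vec si = s.subvec(3*i, 3*i+2);

    vec anchor = op + Rp * (sp % M.poff.col(i));
    mat Rj0 = Rp * M.porient.slice(i);
    int d0 = M.dof0(i), nd = M.ndof(i), t = M.jtype(i);

    mat Rq(3,3,arma::fill::eye);
    if (t == 0) { // free6: translation in joint frame, then XYZ Euler
      vec u = q.subvec(d0, d0+2);
      anchor += Rj0 * u;
      for (int k = 0; k < 3; ++k) {
        K.dof_axis.col(d0+k) = Rj0.col(k);
        K.dof_anchor.col(d0+k) = anchor;
        K.dof_rot(d0+k) = 0; K.dof_seg(d0+k) = i;
      }
      double a1=q(d0+3), a2=q(d0+4), a3=q(d0+5);
      mat R1 = rot_x(a1), R2 = rot_y(a2), R3 = rot_z(a3);
      Rq = R1*R2*R3;
      K.dof_axis.col(d0+3) = Rj0.col(0);
      K.dof_axis.col(d0+4) = Rj0 * R1.col(1);
      K.dof_axis.col(d0+5) = Rj0 * mat(R1*R2).col(2);
      for (int k = 3; k < 6; ++k) {
        K.dof_anchor.col(d0+k) = anchor;
        K.dof_rot(d0+k) = 1; K.dof_seg(d0+k) = i;
      }
    } else if (t == 1) { // ball3, XYZ Euler
      double a1=q(d0), a2=q(d0+1), a3=q(d0+2);
      mat R1 = rot_x(a1), R2 = rot_y(a2), R3 = rot_z(a3);
      Rq = R1*R2*R3;
      K.dof_axis.col(d0)   = Rj0.col(0);
      K.dof_axis.col(d0+1) = Rj0 * R1.col(1);
      K.dof_axis.col(d0+2) = Rj0 * mat(R1*R2).col(2);
      for (int k = 0; k < 3; ++k) {
        K.dof_anchor.col(d0+k) = anchor;
        K.dof_rot(d0+k) = 1; K.dof_seg(d0+k) = i;
      }
    } else if (t == 2) { // universal2
      vec a1 = M.axes.slice(i).col(0), a2 = M.axes.slice(i).col(1);
      mat R1 = rot_axis(a1, q(d0));
      mat R2 = rot_axis(a2, q(d0+1));
      Rq = R1*R2;
      K.dof_axis.col(d0)   = Rj0 * a1;
      K.dof_axis.col(d0+1) = Rj0 * (R1 * a2);
      for (int k = 0; k < 2; ++k) {
        K.dof_anchor.col(d0+k) = anchor;
        K.dof_rot(d0+k) = 1; K.dof_seg(d0+k) = i;
      }
    } else { // revolute1
      vec a1 = M.axes.slice(i).col(0);
      Rq = rot_axis(a1, q(d0));
      K.dof_axis.col(d0) = Rj0 * a1;
      K.dof_anchor.col(d0) = anchor;
      K.dof_rot(d0) = 1; K.dof_seg(d0) = i;
    }
    (void)nd;

    mat Ri = Rj0 * Rq * M.corient.slice(i).t();
    vec oi = anchor - Ri * (si % M.coff.col(i));
    K.R.slice(i) = Ri;
    K.o.col(i) = oi;

    if (want_ds) {
      mat dOi(3, 3*M.ns, arma::fill::zeros);
      if (p >= 0) {
        dOi = K.dO.slice(p);
        for (int ax = 0; ax < 3; ++ax)
          dOi.col(3*p+ax) += Rp.col(ax) * M.poff(ax, i);
      }
      for (int ax = 0; ax < 3; ++ax)
        dOi.col(3*i+ax) -= Ri.col(ax) * M.coff(ax, i);
      K.dO.slice(i) = dOi;
    }
  }
  return K;
}

// Ancestor-dof loop: apply f(dof index) for every dof affecting segment b.
template <typename F>
void for_ancestor_dofs(const Model& M, int b, F f) {
  for (int g = b; g >= 0; g = M.parent(g)) {
    int d0 = M.dof0(g);
    for (int k = 0; k < M.ndof(g); ++k) f(d0 + k);
  }
}

// 6 x nq spatial Jacobian of a world point fixed to segment b:
// rows 1-3 linear velocity of the point, rows 4-6 angular velocity.
void point_jacobian(const Model& M, const KinState& K, int b, const vec& x,
                    mat& J) {
  J.zeros(6, M.nq);
  for_ancestor_dofs(M, b, [&](int d) {
    if (K.dof_rot(d)) {
      vec w = K.dof_axis.col(d);
      J.submat(0, d, 2, d) = cross3(w, x - K.dof_anchor.col(d));
      J.submat(3, d, 5, d) = w;
    } else {
      J.submat(0, d, 2, d) = K.dof_axis.col(d);
    }
  });
}

// Inertia tensor of segment i in world frame for given scale/mass.
mat world_inertia(const Model& M, const KinState& K, int i, const vec& s,
                  double mass) {
  const mat& I0 = M.inertia0.slice(i);
  vec si = s.subvec(3*i, 3*i+2);
  // per-axis second moments implied by I0
  double px = 0.5 * (-I0(0,0) + I0(1,1) + I0(2,2));
  double py = 0.5 * ( I0(0,0) - I0(1,1) + I0(2,2));
  double pz = 0.5 * ( I0(0,0) + I0(1,1) - I0(2,2));
  mat I(3,3);
  I(0,0) = si(1)*si(1)*py + si(2)*si(2)*pz;
  I(1,1) = si(0)*si(0)*px + si(2)*si(2)*pz;
  I(2,2) = si(0)*si(0)*px + si(1)*si(1)*py;
  I(0,1) = I(1,0) = si(0)*si(1)*I0(0,1);
  I(0,2) = I(2,0) = si(0)*si(2)*I0(0,2);
  I(1,2) = I(2,1) = si(1)*si(2)*I0(1,2);
  I *= mass / M.mass0(i);
  const mat& Rw = K.R.slice(i);
  return Rw * I * Rw.t();
}

vec com_point(const Model& M, const KinState& K, int i, const vec& s) {
  vec si = s.subvec(3*i, 3*i+2);
  return K.o.col(i) + K.R.slice(i) * (si % M.com.col(i));
}

// Body velocity/acceleration propagation.  Outputs per segment:
// omega, alpha (world), acom (world linear acceleration of the COM).
void propagate(const Model& M, const KinState& K, const vec& s,
               const vec& q, const vec& qd, const vec& qdd,
               mat& omega, mat& alpha, mat& acom, mat& vcom) {
  omega.zeros(3, M.ns); alpha.zeros(3, M.ns);
  acom.zeros(3, M.ns);  vcom.zeros(3, M.ns);
  mat vo(3, M.ns), ao(3, M.ns); // segment-origin kinematics
  for (int i = 0; i < M.ns; ++i) {
    int p = M.parent(i);
    vec wp(3, arma::fill::zeros), alp(3, arma::fill::zeros);
    vec vp(3, arma::fill::zeros), ap(3, arma::fill::zeros);
    vec op(3, arma::fill::zeros);
    if (p >= 0) {
      wp = omega.col(p); alp = alpha.col(p);
      vp = vo.col(p); ap = ao.col(p); op = K.o.col(p);
    }
    int d0 = M.dof0(i), t = M.jtype(i);
    // anchor before any free-joint translation
    vec sp = (p >= 0) ? vec(s.subvec(3*p, 3*p+2)) : vec(3, arma::fill::ones);
    mat Rp = (p >= 0) ? mat(K.R.slice(p)) : arma::eye(3,3);
    vec anchor0 = op + Rp * (sp % M.poff.col(i));
    vec r0 = anchor0 - op;
    vec va = vp + cross3(wp, r0);
    vec aa = ap + cross3(alp, r0) + cross3(wp, cross3(wp, r0));
    vec w = wp, al = alp;
    int rot0 = d0;
    if (t == 0) {
      mat Rj0 = Rp * M.porient.slice(i);
      vec u = q.subvec(d0, d0+2), ud = qd.subvec(d0, d0+2),
          udd = qdd.subvec(d0, d0+2);
      vec ru = Rj0 * u, rud = Rj0 * ud;
      va += cross3(wp, ru) + rud;
      aa += cross3(alp, ru) + cross3(wp, cross3(wp, ru)) +
            2.0 * cross3(wp, rud) + Rj0 * udd;
      rot0 = d0 + 3;
    }
    int nrot = M.ndof(i) - (t == 0 ? 3 : 0);
    for (int k = 0; k < nrot; ++k) {
      int d = rot0 + k;
      vec wk = K.dof_axis.col(d);
      al += cross3(w, wk) * qd(d) + wk * qdd(d);
      w  += wk * qd(d);
    }
    // child origin relative to (translated) anchor, fixed in child frame
    vec anchor = K.dof_anchor.col(d0); // includes free-joint translation
    vec r = K.o.col(i) - anchor;
    vec voi = va + cross3(w, r);
    vec aoi = aa + cross3(al, r) + cross3(w, cross3(w, r));
    omega.col(i) = w; alpha.col(i) = al;
    vo.col(i) = voi; ao.col(i) = aoi;
    vec rc = com_point(M, K, i, s) - K.o.col(i);
    vcom.col(i) = voi + cross3(w, rc);
    acom.col(i) = aoi + cross3(al, rc) + cross3(w, cross3(w, rc));
  }
}

// Generalized forces from external wrenches (ext: 6 x ns, world force then
// world moment about the WORLD ORIGIN).
vec ext_gen_forces_state(const Model& M, const KinState& K, const mat& ext) {
  vec Q(M.nq, arma::fill::zeros);
  for (int b = 0; b < M.ns; ++b) {
    vec F = ext.submat(0, b, 2, b);
    vec M0 = ext.submat(3, b, 5, b);
    if (arma::norm(F) == 0 && arma::norm(M0) == 0) continue;
    vec ob = K.o.col(b);
    for_ancestor_dofs(M, b, [&](int d) {
      if (K.dof_rot(d)) {
        vec w = K.dof_axis.col(d);
        vec vk = cross3(w, ob - K.dof_anchor.col(d));
        Q(d) += arma::dot(F, vk) + arma::dot(w, M0 - cross3(ob, F));
      } else {
        Q(d) += arma::dot(F, K.dof_axis.col(d));
      }
    });
  }
  return Q;
}

vec inverse_dynamics_state(const Model& M, const KinState& K, const vec& s,
                           const vec& masses, const vec& q, const vec& qd,
                           const vec& qdd, const mat& ext) {
  mat omega, alpha, acom, vcom;
  propagate(M, K, s, q, qd, qdd, omega, alpha, acom, vcom);
  vec tau(M.nq, arma::fill::zeros);
  mat J(6, M.nq);
  for (int b = 0; b < M.ns; ++b) {
    vec cb = com_point(M, K, b, s);
    point_jacobian(M, K, b, cb, J);
    vec F = masses(b) * (acom.col(b) - M.gravity);
    mat Iw = world_inertia(M, K, b, s, masses(b));
    vec N = Iw * alpha.col(b) + cross3(omega.col(b), Iw * omega.col(b));
    tau += J.rows(0,2).t() * F + J.rows(3,5).t() * N;
  }
  tau -= ext_gen_forces_state(M, K, ext);
  return tau;
}

} // namespace

// [[Rcpp::export]]
List cpp_fk(List model, arma::vec s, arma::vec q) {
  Model M = unpack(model);
  KinState K = fk(M, s, q, false);
  return List::create(_["o"] = K.o.t(), _["R"] = K.R,
                      _["dof_axis"] = K.dof_axis,
                      _["dof_anchor"] = K.dof_anchor,
                      _["dof_rot"] = K.dof_rot,
                      _["dof_seg"] = K.dof_seg);
}

// [[Rcpp::export]]
arma::mat cpp_markers(List model, arma::vec s, arma::vec q, arma::mat p) {
  Model M = unpack(model);
  KinState K = fk(M, s, q, false);
  mat X(M.nm, 3);
  for (int i = 0; i < M.nm; ++i) {
    int b = M.marker_seg(i);
    vec sb = s.subvec(3*b, 3*b+2);
    vec x = K.o.col(b) + K.R.slice(b) * (sb % p.col(i));
    X.row(i) = x.t();
  }
  return X;
}

// [[Rcpp::export]]
List cpp_marker_jac(List model, arma::vec s, arma::vec q, arma::mat p) {
  Model M = unpack(model);
  KinState K = fk(M, s, q, true);
  mat X(M.nm, 3);
  mat Jq(3*M.nm, M.nq, arma::fill::zeros);
  mat Js(3*M.nm, 3*M.ns, arma::fill::zeros);
  cube Rm(3, 3, M.nm);
  mat J(6, M.nq);
  for (int i = 0; i < M.nm; ++i) {
    int b = M.marker_seg(i);
    vec sb = s.subvec(3*b, 3*b+2);
    vec x = K.o.col(b) + K.R.slice(b) * (sb % p.col(i));
    X.row(i) = x.t();
    point_jacobian(M, K, b, x, J);
    Jq.rows(3*i, 3*i+2) = J.rows(0, 2);
    mat Jsb = K.dO.slice(b);
    Js.rows(3*i, 3*i+2) = Jsb;
    for (int ax = 0; ax < 3; ++ax)
      Js.submat(3*i, 3*b+ax, 3*i+2, 3*b+ax) += K.R.slice(b).col(ax) * p(ax, i);
    Rm.slice(i) = K.R.slice(b);
  }
  return List::create(_["x"] = X, _["Jq"] = Jq, _["Js"] = Js, _["R"] = Rm);
}

// [[Rcpp::export]]
arma::mat cpp_mass_matrix(List model, arma::vec s, arma::vec masses,
                          arma::vec q) {
  Model M = unpack(model);
  KinState K = fk(M, s, q, false);
  mat Mm(M.nq, M.nq, arma::fill::zeros);
  mat J(6, M.nq);
  for (int b = 0; b < M.ns; ++b) {
    vec cb = com_point(M, K, b, s);
    point_jacobian(M, K, b, cb, J);
    mat Jv = J.rows(0, 2), Jw = J.rows(3, 5);
    mat Iw = world_inertia(M, K, b, s, masses(b));
    Mm += masses(b) * (Jv.t() * Jv) + Jw.t() * Iw * Jw;
  }
  return 0.5 * (Mm + Mm.t());
}

// [[Rcpp::export]]
arma::vec cpp_inverse_dynamics(List model, arma::vec s, arma::vec masses,
                               arma::vec q, arma::vec qd, arma::vec qdd,
                               arma::mat ext) {
  Model M = unpack(model);
  KinState K = fk(M, s, q, false);
  return inverse_dynamics_state(M, K, s, masses, q, qd, qdd, ext);
}

// [[Rcpp::export]]
arma::vec cpp_ext_gen_forces(List model, arma::vec s, arma::vec q,
                             arma::mat ext) {
  Model M = unpack(model);
  KinState K = fk(M, s, q, false);
  return ext_gen_forces_state(M, K, ext);
}

// [[Rcpp::export]]
arma::vec cpp_com(List model, arma::vec s, arma::vec masses, arma::vec q) {
  Model M = unpack(model);
  KinState K = fk(M, s, q, false);
  vec c(3, arma::fill::zeros);
  double mt = 0;
  for (int b = 0; b < M.ns; ++b) {
    c += masses(b) * com_point(M, K, b, s);
    mt += masses(b);
  }
  return c / mt;
}

// [[Rcpp::export]]
arma::mat cpp_com_traj(List model, arma::vec s, arma::vec masses,
                       arma::mat Q) {
  Model M = unpack(model);
  int T = Q.n_rows;
  mat Z(T, 3);
  for (int t = 0; t < T; ++t) {
    KinState K = fk(M, s, Q.row(t).t(), false);
    vec c(3, arma::fill::zeros); double mt = 0;
    for (int b = 0; b < M.ns; ++b) {
      c += masses(b) * com_point(M, K, b, s); mt += masses(b);
    }
    Z.row(t) = (c / mt).t();
  }
  return Z;
}

// [[Rcpp::export]]
arma::mat cpp_id_traj(List model, arma::vec s, arma::vec masses,
                      arma::mat Q, arma::mat Qd, arma::mat Qdd,
                      arma::cube ext) {
  // ext: 6 x ns x T
  Model M = unpack(model);
  int T = Q.n_rows;
  mat Tau(T, M.nq);
  for (int t = 0; t < T; ++t) {
    vec q = Q.row(t).t();
    KinState K = fk(M, s, q, false);
    Tau.row(t) = inverse_dynamics_state(M, K, s, masses, q, Qd.row(t).t(),
                                        Qdd.row(t).t(), ext.slice(t)).t();
  }
  return Tau;
}

// [[Rcpp::export]]
arma::mat cpp_markers_traj(List model, arma::vec s, arma::mat Q,
                           arma::mat p) {
  // returns T x (3*M) matrix, markers stacked x1 y1 z1 x2 ...
  Model Mo = unpack(model);
  int T = Q.n_rows;
  mat X(T, 3*Mo.nm);
  for (int t = 0; t < T; ++t) {
    KinState K = fk(Mo, s, Q.row(t).t(), false);
    for (int i = 0; i < Mo.nm; ++i) {
      int b = Mo.marker_seg(i);
      vec sb = s.subvec(3*b, 3*b+2);
      vec x = K.o.col(b) + K.R.slice(b) * (sb % p.col(i));
      X(t, 3*i) = x(0); X(t, 3*i+1) = x(1); X(t, 3*i+2) = x(2);
    }
  }
  return X;
}

// [[Rcpp::export]]
List cpp_body_jacobians(List model, arma::vec s, arma::vec q) {
  // 6 x nq Jacobian (linear at segment origin; angular) per segment
  Model M = unpack(model);
  KinState K = fk(M, s, q, false);
  List out(M.ns);
  mat J(6, M.nq);
  for (int b = 0; b < M.ns; ++b) {
    point_jacobian(M, K, b, K.o.col(b), J);
    out[b] = J;
  }
  return out;
}
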