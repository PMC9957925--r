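// Finite-strain FE core: Neo-Hookean hex8 assembly and penalty contact with
// the adhesive-frictional interface law. Dof ordering is node-major
// (dof = 3*node + comp, 0-based internally, 1-based ids from R).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// ---------------------------------------------------------------------------
// Contact law (mirrors the exported R functions; cross-checked in the tests)
// ---------------------------------------------------------------------------
struct LawPar {
  double a_s, b_s, mu_ub, mu_b, t0, g0, gb, eps_n, eps_t;
  int law; // 0 coulomb, 1 mc, 2 emc
};

static inline double law_state(double gd, double phi0, const LawPar& P) {
  double c1 = gd / P.a_s;
  if (c1 < 1.0) return phi0;
  if (c1 > 1.0 + 2.0 * P.b_s) return 0.0;
  return phi0 * (0.5 - 0.5 * std::sin(M_PI / (2.0 * P.b_s) * (c1 - P.b_s - 1.0)));
}

static inline double law_mu(double phi, const LawPar& P) {
  if (P.law == 0) return P.mu_b;
  return phi * P.mu_ub + (1.0 - phi) * P.mu_b;
}

// signed normal traction (tension > 0) and its slope d t_n / d g_n
static inline void law_tn(double gn, double phi, double phi0, const LawPar& P,
                          double& tn, double& ktn) {
  if (gn < 0.0) { tn = P.eps_n * gn; ktn = P.eps_n; return; }
  if (P.law == 2 && gn < P.gb && phi > 0.0) {
    double x = gn / P.g0, ex = std::exp(1.0 - x);
    tn = phi0 * P.t0 * x * ex;
    ktn = phi0 * P.t0 / P.g0 * (1.0 - x) * ex;
    return;
  }
  tn = 0.0; ktn = 0.0;
}

static inline double law_slide_limit(double tn, double phi, const LawPar& P) {
  double mu = law_mu(phi, P);
  if (P.law == 2) return std::max(0.0, mu * (P.t0 - tn));
  return mu * std::max(0.0, -tn);
}

static LawPar par_from_list(const Rcpp::List& par) {
  LawPar P;
  P.a_s = par["a_s"]; P.b_s = par["b_s"];
  P.mu_ub = par["mu_ub"]; P.mu_b = par["mu_b"];
  P.t0 = par["t0"]; P.g0 = par["g0"]; P.gb = par["g_b"];
  P.eps_n = par["eps_n"]; P.eps_t = par["eps_t"];
  std::string law = Rcpp::as<std::string>(par["law"]);
  P.law = (law == "coulomb") ? 0 : (law == "mc" ? 1 : 2);
  return P;
}

// ---------------------------------------------------------------------------
// hex8 Neo-Hookean assembly
// ---------------------------------------------------------------------------
static const double GP = 0.5773502691896257645091488; // 1/sqrt(3)

static void hex_shape_deriv(double xi, double eta, double ze, mat& dN) {
  // node order: (-,-,-)(+,-,-)(+,+,-)(-,+,-)(-,-,+)(+,-,+)(+,+,+)(-,+,+)
  static const double sg[8][3] = {
    {-1,-1,-1},{1,-1,-1},{1,1,-1},{-1,1,-1},
    {-1,-1, 1},{1,-1, 1},{1,1, 1},{-1,1, 1}};
  dN.set_size(8, 3);
  for (int a = 0; a < 8; ++a) {
    double sx = sg[a][0], sy = sg[a][1], sz = sg[a][2];
    dN(a,0) = 0.125 * sx * (1 + sy*eta) * (1 + sz*ze);
    dN(a,1) = 0.125 * sy * (1 + sx*xi)  * (1 + sz*ze);
    dN(a,2) = 0.125 * sz * (1 + sx*xi)  * (1 + sy*eta);
  }
}

// [[Rcpp::export(name = ".hex8_assemble_cpp")]]
Rcpp::List hex8_assemble_cpp(const arma::mat& X, const arma::mat& U,
                             const arma::imat& conn, const arma::vec& Gv,
                             const arma::vec& Lv, bool want_K) {
  const uword nn = X.n_rows, ne = conn.n_rows, ndof = 3 * nn;
  vec fint(ndof, fill::zeros);
  double minJ = datum::inf;

  // precompute shape derivatives at the 2x2x2 points
  std::vector<mat> dNs(8);
  int q = 0;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k, ++q)
        hex_shape_deriv((i ? GP : -GP), (j ? GP : -GP), (k ? GP : -GP), dNs[q]);

  umat loc;
  vec vals;
  uword cap = want_K ? ne * 8 * 576 / 8 : 0; // triplets appended in blocks
  std::vector<uword> ti, tj;
  std::vector<double> tv;
  if (want_K) { ti.reserve(ne * 576); tj.reserve(ne * 576); tv.reserve(ne * 576); }
  (void)cap; (void)loc; (void)vals;

  mat Xe(8,3), Ue(8,3), Ke(24,24);
  for (uword e = 0; e < ne; ++e) {
    uvec nd(8);
    for (int a = 0; a < 8; ++a) {
      nd(a) = (uword)(conn(e,a) - 1);
      Xe.row(a) = X.row(nd(a));
      Ue.row(a) = U.row(nd(a));
    }
    double G = Gv(e), L = Lv(e);
    vec fe(24, fill::zeros);
    if (want_K) Ke.zeros();

    for (int g = 0; g < 8; ++g) {
      const mat& dN = dNs[g];
      mat J0 = Xe.t() * dN;            // dX/dxi
      double dJ0 = det(J0);
      if (dJ0 <= 0) Rcpp::stop("negative reference Jacobian in element %d", (int)e + 1);
      mat dNdX = dN * inv(J0);         // 8x3
      mat F = eye(3,3) + Ue.t() * dNdX;
      double J = det(F);
      if (J < minJ) minJ = J;
      if (J <= 0) continue;            // flagged via minJ; caller bisects
      mat b = F * F.t();
      double lnJ = std::log(J);
      mat sig = (L * lnJ / J) * eye(3,3) + (G / J) * (b - eye(3,3));
      mat dNdx = dNdX * inv(F);        // 8x3 spatial derivatives
      double w = dJ0 * J;              // unit gauss weights, current volume

      // internal force
      mat fblock = dNdx * sig.t() * w; // 8x3: f_{a,i} = sig_{ij} dNdx_{a,j} w
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          fe(3*a+i) += fblock(a,i);

      if (want_K) {
        double lamp = L / J;
        double mup  = (G - L * lnJ) / J;
        mat dd = dNdx * dNdx.t();          // 8x8: dNa.dNb
        mat gs = dNdx * sig * dNdx.t();    // 8x8: dNa.sig.dNb
        for (int a = 0; a < 8; ++a)
          for (int bb = 0; bb < 8; ++bb) {
            double geo = gs(a,bb) * w;
            for (int i = 0; i < 3; ++i) {
              for (int k = 0; k < 3; ++k) {
                double v = lamp * dNdx(a,i) * dNdx(bb,k)
                         + mup * dNdx(a,k) * dNdx(bb,i);
                if (i == k) v += mup * dd(a,bb);
                v *= w;
                if (i == k) v += geo;
                Ke(3*a+i, 3*bb+k) += v;
              }
            }
          }
      }
    }

    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        fint(3*nd(a)+i) += fe(3*a+i);
    if (want_K) {
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          uword gi = 3*nd(a)+i;
          for (int bb = 0; bb < 8; ++bb)
            for (int k = 0; k < 3; ++k) {
              ti.push_back(gi);
              tj.push_back(3*nd(bb)+k);
              tv.push_back(Ke(3*a+i, 3*bb+k));
            }
        }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("fint") = fint,
    Rcpp::Named("minJ") = minJ);
  if (want_K) {
    Rcpp::IntegerVector Ti(ti.size()), Tj(tj.size());
    Rcpp::NumericVector Tv(tv.size());
    for (size_t s = 0; s < ti.size(); ++s) {
      Ti[s] = (int)ti[s] + 1; Tj[s] = (int)tj[s] + 1; Tv[s] = tv[s];
    }
    out["Ki"] = Ti; out["Kj"] = Tj; out["Kx"] = Tv;
  }
  return out;
}

// ---------------------------------------------------------------------------
// bilinear facet geometry
// ---------------------------------------------------------------------------
static inline void facet_eval(const mat& C, const irowvec& fnodes,
                              double xi, double eta,
                              vec& x, vec& dxi, vec& deta) {
  double N[4] = {0.25*(1-xi)*(1-eta), 0.25*(1+xi)*(1-eta),
                 0.25*(1+xi)*(1+eta), 0.25*(1-xi)*(1+eta)};
  double Dxi[4]  = {-0.25*(1-eta), 0.25*(1-eta), 0.25*(1+eta), -0.25*(1+eta)};
  double Deta[4] = {-0.25*(1-xi), -0.25*(1+xi), 0.25*(1+xi),  0.25*(1-xi)};
  x.zeros(3); dxi.zeros(3); deta.zeros(3);
  for (int a = 0; a < 4; ++a) {
    rowvec xa = C.row(fnodes(a) - 1);
    for (int i = 0; i < 3; ++i) {
      x(i)   += N[a]   * xa(i);
      dxi(i) += Dxi[a] * xa(i);
      deta(i)+= Deta[a]* xa(i);
    }
  }
}

// projected-Newton closest point on one facet; returns squared distance
static double project_facet(const mat& C, const irowvec& fnodes, const vec& p,
                            double& xi, double& eta) {
  xi = 0.0; eta = 0.0;
  vec x(3), dxi(3), deta(3);
  // bilinear twist vector (constant)
  vec xeta(3, fill::zeros);
  {
    rowvec x1 = C.row(fnodes(0)-1), x2 = C.row(fnodes(1)-1),
           x3 = C.row(fnodes(2)-1), x4 = C.row(fnodes(3)-1);
    for (int i = 0; i < 3; ++i)
      xeta(i) = 0.25 * (x1(i) - x2(i) + x3(i) - x4(i));
  }
  for (int it = 0; it < 20; ++it) {
    facet_eval(C, fnodes, xi, eta, x, dxi, deta);
    vec r = p - x;
    double g1 = dot(dxi, r), g2 = dot(deta, r);
    double h11 = dot(dxi, dxi), h22 = dot(deta, deta);
    double h12 = dot(dxi, deta) - dot(r, xeta);
    double dtm = h11*h22 - h12*h12;
    if (std::abs(dtm) < 1e-30) break;
    double dxi_ = ( h22*g1 - h12*g2) / dtm;
    double deta_= (-h12*g1 + h11*g2) / dtm;
    double nxi = std::min(1.0, std::max(-1.0, xi + dxi_));
    double neta= std::min(1.0, std::max(-1.0, eta + deta_));
    if (std::abs(nxi - xi) + std::abs(neta - eta) < 1e-12) { xi = nxi; eta = neta; break; }
    xi = nxi; eta = neta;
  }
  facet_eval(C, fnodes, xi, eta, x, dxi, deta);
  return dot(p - x, p - x);
}

struct Projection {
  int facet = -1;        // 0-based best facet, -1 none
  double xi = 0, eta = 0, gn = 0;
  vec x_l, n;
  bool valid = false;
};

static Projection project_surface(const mat& C, const imat& fac,
                                  const umat& bnd, const mat& lo,
                                  const mat& hi, const vec& p,
                                  double margin, double edge_tol) {
  Projection best;
  double dbest = datum::inf;
  for (uword f = 0; f < fac.n_rows; ++f) {
    bool out = false;
    for (int i = 0; i < 3; ++i)
      if (p(i) < lo(f,i) - margin || p(i) > hi(f,i) + margin) { out = true; break; }
    if (out) continue;
    double xi, eta;
    double d2 = project_facet(C, fac.row(f), p, xi, eta);
    if (d2 < dbest) {
      dbest = d2;
      best.facet = (int)f; best.xi = xi; best.eta = eta;
    }
  }
  if (best.facet < 0) return best;
  vec x(3), dxi(3), deta(3);
  irowvec fn = fac.row(best.facet);
  facet_eval(C, fn, best.xi, best.eta, x, dxi, deta);
  vec n = cross(dxi, deta);
  double nn_ = norm(n);
  if (nn_ < 1e-30) return best;
  n /= nn_;
  vec g = p - x;
  best.x_l = x; best.n = n; best.gn = dot(g, n);
  best.valid = true;

  // reject projections clamped onto a free boundary edge of the surface
  double h = std::sqrt(norm(dxi) * norm(deta)) * 2.0; // facet size scale
  vec gt = g - best.gn * n;
  if (norm(gt) > edge_tol * h) {
    // which clamped edge? local edges: 0:(xi=-1)? use parametric position
    bool onb = false;
    const double one = 1.0 - 1e-9;
    if (best.eta <= -one && bnd(best.facet, 0)) onb = true; // edge 1-2
    if (best.xi  >=  one && bnd(best.facet, 1)) onb = true; // edge 2-3
    if (best.eta >=  one && bnd(best.facet, 2)) onb = true; // edge 3-4
    if (best.xi  <= -one && bnd(best.facet, 3)) onb = true; // edge 4-1
    if (onb) best.valid = false;
  }
  return best;
}

static void facet_boxes(const mat& C, const imat& fac, mat& lo, mat& hi) {
  lo.set_size(fac.n_rows, 3); hi.set_size(fac.n_rows, 3);
  for (uword f = 0; f < fac.n_rows; ++f)
    for (int i = 0; i < 3; ++i) {
      double a = datum::inf, b = -datum::inf;
      for (int k = 0; k < 4; ++k) {
        double v = C(fac(f,k)-1, i);
        a = std::min(a, v); b = std::max(b, v);
      }
      lo(f,i) = a; hi(f,i) = b;
    }
}

// exported for unit tests of the projection alone
// [[Rcpp::export(name = ".project_points_cpp")]]
Rcpp::List project_points_cpp(const arma::mat& pts, const arma::mat& C,
                              const arma::imat& fac, const arma::umat& bnd,
                              double margin, double edge_tol) {
  mat lo, hi;
  facet_boxes(C, fac, lo, hi);
  uword np = pts.n_rows;
  vec gn(np); ivec fct(np); vec xi(np), eta(np);
  mat xl(np,3), nrm(np,3);
  ivec valid(np);
  for (uword k = 0; k < np; ++k) {
    Projection pr = project_surface(C, fac, bnd, lo, hi, pts.row(k).t(),
                                    margin, edge_tol);
    valid(k) = pr.valid ? 1 : 0;
    fct(k) = pr.facet + 1;
    xi(k) = pr.xi; eta(k) = pr.eta;
    if (pr.valid) {
      gn(k) = pr.gn;
      xl.row(k) = pr.x_l.t(); nrm.row(k) = pr.n.t();
    } else { gn(k) = datum::nan; xl.row(k).fill(datum::nan); nrm.row(k).fill(datum::nan); }
  }
  return Rcpp::List::create(
    Rcpp::Named("valid") = valid, Rcpp::Named("facet") = fct,
    Rcpp::Named("xi") = xi, Rcpp::Named("eta") = eta,
    Rcpp::Named("g_n") = gn, Rcpp::Named("x_l") = xl, Rcpp::Named("n") = nrm);
}

// ---------------------------------------------------------------------------
// contact residual / stiffness / trial state
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".contact_assemble_cpp")]]
Rcpp::List contact_assemble_cpp(const arma::mat& C,        // current coords n x 3
                                const arma::imat& sfac,    // slave facets (1-based)
                                const arma::imat& mfac,    // master facets
                                const arma::umat& mbnd,    // master boundary edges
                                const arma::mat& Ns,       // gp shape fns (ngp x 4)
                                const arma::vec& wA,       // ref area weights (nsf*ngp)
                                const Rcpp::List& state,
                                const Rcpp::List& par,
                                bool want_K) {
  LawPar P = par_from_list(par);
  const uword nsf = sfac.n_rows, ngp = Ns.n_rows, npt = nsf * ngp;
  const uword ndof = 3 * C.n_rows;

  vec phi0 = state["phi0"];
  vec phi  = state["phi"];
  ivec anc_f  = state["anchor_facet"];   // 1-based, 0 = none
  vec anc_xi  = state["anchor_xi"];
  vec anc_eta = state["anchor_eta"];

  mat lo, hi;
  facet_boxes(C, mfac, lo, hi);
  double margin = 3.0 * P.gb + 1e-4;

  vec fc(ndof, fill::zeros);
  std::vector<uword> ti, tj;
  std::vector<double> tv;
  if (want_K) { ti.reserve(npt * 64); tj.reserve(npt * 64); tv.reserve(npt * 64); }

  // trial-state outputs (history is committed later, in R, on convergence)
  ivec o_status(npt, fill::zeros);     // 0 open, 1 stick, 2 slip
  vec o_gn(npt, fill::zeros), o_tn(npt, fill::zeros), o_lim(npt, fill::zeros);
  mat o_tt(npt, 3, fill::zeros);
  ivec o_pf(npt); o_pf.fill(0);
  vec o_pxi(npt, fill::zeros), o_peta(npt, fill::zeros);
  ivec o_af(npt); vec o_axi(npt), o_aeta(npt);
  vec o_slip(npt, fill::zeros);        // slip increment (anchor travel)
  vec o_p(npt, fill::zeros);           // pressure (= -tn when compressive)

  vec xk(3), x(3), dxi(3), deta(3);
  std::vector<int> acc_m;     // master facets touched by the current slave facet
  std::vector<mat> acc_K;     // accumulated 24x24 pair blocks
  for (uword sf = 0; sf < nsf; ++sf) {
    irowvec sn = sfac.row(sf);
    for (uword g = 0; g < ngp; ++g) {
      uword k = sf * ngp + g;
      // defaults: keep old anchor
      o_af(k) = anc_f(k); o_axi(k) = anc_xi(k); o_aeta(k) = anc_eta(k);

      // slave point position
      xk.zeros();
      for (int a = 0; a < 4; ++a)
        xk += Ns(g,a) * C.row(sn(a)-1).t();

      Projection pr = project_surface(C, mfac, mbnd, lo, hi, xk, margin, 0.01);
      if (!pr.valid) { o_status(k) = 0; o_af(k) = 0; continue; }
      o_pf(k) = pr.facet + 1; o_pxi(k) = pr.xi; o_peta(k) = pr.eta;
      o_gn(k) = pr.gn;

      bool open;
      if (P.law == 2)
        open = (pr.gn >= P.gb) || (pr.gn >= 0.0 && phi(k) <= 0.0);
      else
        open = (pr.gn >= 0.0);
      if (open) { o_status(k) = 0; o_af(k) = 0; continue; }

      double tn, ktn;
      law_tn(pr.gn, phi(k), phi0(k), P, tn, ktn);
      o_tn(k) = tn; o_p(k) = std::max(0.0, -tn);

      // tangential trial from the stick anchor (interacting point)
      vec apos;
      int af = anc_f(k);
      if (af > 0) {
        vec adxi(3), adeta(3);
        apos.set_size(3);
        facet_eval(C, mfac.row(af-1), anc_xi(k), anc_eta(k), apos, adxi, adeta);
      } else {
        apos = pr.x_l; // fresh contact: anchor at current projection
      }
      vec gvec = xk - apos;
      vec gt = gvec - dot(gvec, pr.n) * pr.n;
      vec trial = -P.eps_t * gt;
      double lim = law_slide_limit(tn, phi(k), P);
      o_lim(k) = lim;
      double tnrm = norm(trial);
      vec tt(3, fill::zeros);
      bool slip = (tnrm >= lim);
      double keff_t = P.eps_t;
      if (slip) {
        if (tnrm > 0) tt = trial * (lim / tnrm);
        keff_t = 0.0;
        o_status(k) = 2;
      } else {
        tt = trial;
        o_status(k) = 1;
      }
      o_tt.row(k) = tt.t();

      // anchor update candidate + slip increment (used only at commit)
      if (slip && tnrm > 0) {
        vec q = xk + tt / P.eps_t; // trailing anchor target
        // reproject q onto master surface
        Projection qa = project_surface(C, mfac, mbnd, lo, hi, q, margin, 0.25);
        if (qa.facet >= 0) {
          o_af(k) = qa.facet + 1; o_axi(k) = qa.xi; o_aeta(k) = qa.eta;
          vec qpos(3), d1(3), d2(3);
          facet_eval(C, mfac.row(qa.facet), qa.xi, qa.eta, qpos, d1, d2);
          o_slip(k) = norm(qpos - apos);
        } else {
          o_af(k) = pr.facet + 1; o_axi(k) = pr.xi; o_aeta(k) = pr.eta;
          o_slip(k) = norm(pr.x_l - apos);
        }
      } else if (af == 0) {
        o_af(k) = pr.facet + 1; o_axi(k) = pr.xi; o_aeta(k) = pr.eta;
      }

      // traction on the slave surface
      vec tvec = -tn * pr.n + tt;
      double w = wA(k);

      irowvec mn = mfac.row(pr.facet);
      double Nm[4];
      {
        double q1 = pr.xi, q2 = pr.eta;
        Nm[0] = 0.25*(1-q1)*(1-q2); Nm[1] = 0.25*(1+q1)*(1-q2);
        Nm[2] = 0.25*(1+q1)*(1+q2); Nm[3] = 0.25*(1-q1)*(1+q2);
      }
      // f_int contribution: -(applied force). slave gets +tvec*w applied.
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          fc(3*(sn(a)-1)+i) -= Ns(g,a) * w * tvec(i);
      for (int b = 0; b < 4; ++b)
        for (int i = 0; i < 3; ++i)
          fc(3*(mn(b)-1)+i) += Nm[b] * w * tvec(i);

      if (want_K) {
        // Kp = ktn n n' + keff_t (I - n n')
        mat nn_ = pr.n * pr.n.t();
        mat Kp = ktn * nn_ + keff_t * (eye(3,3) - nn_);
        // accumulate into the per-(slave facet, master facet) 24x24 block;
        // all gauss points of a facet pair share one triplet emission
        int slot = -1;
        for (size_t q2 = 0; q2 < acc_m.size(); ++q2)
          if (acc_m[q2] == pr.facet) { slot = (int)q2; break; }
        if (slot < 0) {
          acc_m.push_back(pr.facet);
          acc_K.push_back(mat(24, 24, fill::zeros));
          slot = (int)acc_m.size() - 1;
        }
        mat& Kb = acc_K[slot];
        double sgn[8];
        for (int a = 0; a < 4; ++a) sgn[a] = Ns(g,a);
        for (int b = 0; b < 4; ++b) sgn[4+b] = -Nm[b];
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double c = sgn[a] * sgn[b] * w;
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                Kb(3*a+i, 3*b+j) += c * Kp(i,j);
          }
      }
    }
    if (want_K && !acc_m.empty()) {
      for (size_t q2 = 0; q2 < acc_m.size(); ++q2) {
        irowvec mn2 = mfac.row(acc_m[q2]);
        uword gid[8];
        for (int a = 0; a < 4; ++a) gid[a] = sn(a) - 1;
        for (int b = 0; b < 4; ++b) gid[4+b] = mn2(b) - 1;
        const mat& Kb = acc_K[q2];
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b)
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j) {
                double v = Kb(3*a+i, 3*b+j);
                if (v != 0.0) {
                  ti.push_back(3*gid[a]+i);
                  tj.push_back(3*gid[b]+j);
                  tv.push_back(v);
                }
              }
      }
      acc_m.clear(); acc_K.clear();
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("fc") = fc,
    Rcpp::Named("status") = o_status,
    Rcpp::Named("g_n") = o_gn,
    Rcpp::Named("t_n") = o_tn,
    Rcpp::Named("p") = o_p,
    Rcpp::Named("limit") = o_lim,
    Rcpp::Named("t_t") = o_tt,
    Rcpp::Named("proj_facet") = o_pf,
    Rcpp::Named("anchor_facet") = o_af,
    Rcpp::Named("anchor_xi") = o_axi,
    Rcpp::Named("anchor_eta") = o_aeta,
    Rcpp::Named("slip_inc") = o_slip);
  if (want_K) {
    Rcpp::IntegerVector Ti(ti.size()), Tj(tj.size());
    Rcpp::NumericVector Tv(tv.size());
    for (size_t s = 0; s < ti.size(); ++s) {
      Ti[s] = (int)ti[s] + 1; Tj[s] = (int)tj[s] + 1; Tv[s] = tv[s];
    }
    out["Ki"] = Ti; out["Kj"] = Tj; out["Kx"] = Tv;
  }
  return out;
}
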