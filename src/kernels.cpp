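// Boundary-element kernels for the Helmholtz transmission solver:
//  - Galerkin assembly of the single-layer, double-layer, adjoint
//    double-layer and hypersingular operators on P1 triangle meshes
//    (hypersingular via the Maue integration-by-parts identity),
//  - representation-formula field evaluation,
//  - signed solid angles for point-in-mesh tests and the near-surface
//    exclusion rule.
//
// Conventions: time factor e^{-i w t}, Green's function
// G(x,y) = e^{ikR}/(4 pi R) with Im k >= 0 (decay in lossy media).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef std::complex<double> cdbl;

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm3(const Vec3& a) { return std::sqrt(dot(a, a)); }

// Dunavant symmetric triangle rules in barycentric coordinates,
// weights sum to 1 (multiply by triangle area).
struct TriRule {
  std::vector<double> l1, l2, l3, w;
};

static TriRule tri_rule(int degree) {
  TriRule r;
  auto push = [&](double a, double b, double c, double w) {
    r.l1.push_back(a); r.l2.push_back(b); r.l3.push_back(c);
    r.w.push_back(w);
  };
  auto push3 = [&](double a, double b, double w) {
    push(a, b, b, w); push(b, a, b, w); push(b, b, a, w);
  };
  if (degree <= 1) {
    push(1.0 / 3, 1.0 / 3, 1.0 / 3, 1.0);
  } else if (degree == 2) {
    push3(2.0 / 3, 1.0 / 6, 1.0 / 3);
  } else if (degree <= 4) {
    push3(0.108103018168070, 0.445948490915965, 0.223381589678011);
    push3(0.816847572980459, 0.091576213509771, 0.109951743655322);
  } else {
    // degree 6, 12 points
    push3(0.873821971016996, 0.063089014491502, 0.050844906370207);
    push3(0.501426509658179, 0.249286745170910, 0.116786275726379);
    double a = 0.636502499121399, b = 0.310352451033785,
           c = 0.053145049844816, w = 0.082851075618374;
    push(a, b, c, w); push(a, c, b, w); push(b, a, c, w);
    push(b, c, a, w); push(c, a, b, w); push(c, b, a, w);
  }
  return r;
}

// Gauss-Legendre on [0,1]
static void gauss01(int n, std::vector<double>& x, std::vector<double>& w) {
  std::vector<double> xr, wr;
  switch (n) {
  case 2:
    xr = {-0.5773502691896257, 0.5773502691896257};
    wr = {1.0, 1.0};
    break;
  case 3:
    xr = {-0.7745966692414834, 0.0, 0.7745966692414834};
    wr = {5.0 / 9, 8.0 / 9, 5.0 / 9};
    break;
  case 4:
    xr = {-0.8611363115940526, -0.3399810435848563,
          0.3399810435848563, 0.8611363115940526};
    wr = {0.3478548451374538, 0.6521451548625461,
          0.6521451548625461, 0.3478548451374538};
    break;
  default:
    xr = {-0.9061798459386640, -0.5384693101056831, 0.0,
          0.5384693101056831, 0.9061798459386640};
    wr = {0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
          0.4786286704993665, 0.2369268850561891};
  }
  x.resize(xr.size()); w.resize(xr.size());
  for (size_t i = 0; i < xr.size(); ++i) {
    x[i] = 0.5 * (xr[i] + 1.0);
    w[i] = 0.5 * wr[i];
  }
}

struct TriGeom {
  Vec3 v0, v1, v2;   // corners
  Vec3 n;            // unit normal
  double area;
  Vec3 g0, g1, g2;   // surface gradients of the three hat functions
  Vec3 c0, c1, c2;   // surface curls n x grad
  Vec3 centroid;
  double radius;     // circumscribed (max corner-centroid distance)
};

static TriGeom tri_geom(const arma::mat& V, int i0, int i1, int i2) {
  TriGeom g;
  g.v0 = Vec3(V(i0, 0), V(i0, 1), V(i0, 2));
  g.v1 = Vec3(V(i1, 0), V(i1, 1), V(i1, 2));
  g.v2 = Vec3(V(i2, 0), V(i2, 1), V(i2, 2));
  Vec3 e01 = g.v1 - g.v0, e02 = g.v2 - g.v0;
  Vec3 cr = cross(e01, e02);
  double a2 = norm3(cr);
  g.area = 0.5 * a2;
  g.n = cr * (1.0 / a2);
  // grad of hat_i is (n x e_opp) / (2A) with e_opp the opposite edge,
  // oriented so that grad points toward vertex i
  Vec3 e12 = g.v2 - g.v1;
  g.g0 = cross(g.n, e12) * (1.0 / a2);
  g.g1 = cross(g.n, g.v0 - g.v2) * (1.0 / a2);
  g.g2 = cross(g.n, g.v1 - g.v0) * (1.0 / a2);
  g.c0 = cross(g.n, g.g0);
  g.c1 = cross(g.n, g.g1);
  g.c2 = cross(g.n, g.g2);
  g.centroid = (g.v0 + g.v1 + g.v2) * (1.0 / 3.0);
  g.radius = std::max(norm3(g.v0 - g.centroid),
                      std::max(norm3(g.v1 - g.centroid),
                               norm3(g.v2 - g.centroid)));
  return g;
}

// barycentric coordinates of point y (assumed in the triangle plane)
static inline void barycentric(const TriGeom& t, const Vec3& y,
                               double& l0, double& l1, double& l2) {
  Vec3 d = y - t.v0;
  // hat function value = 1 + grad . (y - v_i); use gradients directly
  l0 = 1.0 + dot(t.g0, y - t.v0);
  l1 = dot(t.g1, y - t.v0);
  l2 = dot(t.g2, y - t.v0);
  (void)d; (void)l2;
  l2 = 1.0 - l0 - l1;
}

// closest point on triangle to p (Ericson, Real-Time Collision Detection)
static Vec3 closest_point(const TriGeom& t, const Vec3& p) {
  Vec3 ab = t.v1 - t.v0, ac = t.v2 - t.v0, ap = p - t.v0;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return t.v0;
  Vec3 bp = p - t.v1;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return t.v1;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return t.v0 + ab * v;
  }
  Vec3 cp = p - t.v2;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return t.v2;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return t.v0 + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return t.v1 + (t.v2 - t.v1) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return t.v0 + ab * v + ac * w;
}

struct KernelVals { cdbl G, dGdny, dGdnx; };

static inline KernelVals kernel(const Vec3& x, const Vec3& y,
                                const Vec3& nx, const Vec3& ny, cdbl k) {
  Vec3 d = x - y;
  double R = norm3(d);
  cdbl ikR = cdbl(0, 1) * k * R;
  cdbl G = std::exp(ikR) / (4.0 * M_PI * R);
  cdbl dGdR = G * (ikR - 1.0) / R;
  KernelVals kv;
  kv.G = G;
  kv.dGdny = dGdR * (dot(ny, y - x) / R);
  kv.dGdnx = dGdR * (dot(nx, d) / R);
  return kv;
}

// Assemble the Galerkin matrices <Op phi_j, phi_i> for i in the test mesh
// (V1,F1) and j in the trial mesh (V2,F2), for wavenumber k.
// Returns S, D (double layer), Dp (adjoint), N (= d/dn_x of the double
// layer potential, via the Maue identity).
// [[Rcpp::export]]
List assemble_block_cpp(const arma::mat& V1, const arma::imat& F1,
                        const arma::mat& V2, const arma::imat& F2,
                        const arma::cx_double k, const bool same_surface,
                        const int quad_degree = 4, const int duffy_points = 5,
                        const double near_factor = 1.0) {
  const int nv1 = V1.n_rows, nv2 = V2.n_rows;
  const int nt1 = F1.n_rows, nt2 = F2.n_rows;
  arma::cx_mat S(nv1, nv2, arma::fill::zeros), D(nv1, nv2, arma::fill::zeros),
      Dp(nv1, nv2, arma::fill::zeros), N(nv1, nv2, arma::fill::zeros);

  TriRule rule = tri_rule(quad_degree);
  TriRule rule_far = tri_rule(quad_degree >= 4 ? 2 : quad_degree);
  const double far_factor = 4.0;   // distance (in summed panel radii) past
                                   // which the low-order rule suffices
  const int nq = rule.w.size();
  std::vector<double> gx, gw;
  gauss01(duffy_points, gx, gw);
  const int ng = gx.size();

  std::vector<TriGeom> G1(nt1), G2(nt2);
  for (int t = 0; t < nt1; ++t) G1[t] = tri_geom(V1, F1(t, 0), F1(t, 1), F1(t, 2));
  for (int t = 0; t < nt2; ++t) G2[t] = tri_geom(V2, F2(t, 0), F2(t, 1), F2(t, 2));

  const cdbl k2 = k * k;

  for (int t1 = 0; t1 < nt1; ++t1) {
    const TriGeom& T1 = G1[t1];
    const int i1[3] = {(int)F1(t1, 0), (int)F1(t1, 1), (int)F1(t1, 2)};
    const Vec3 curl1[3] = {T1.c0, T1.c1, T1.c2};

    // test quadrature points for both rules
    std::vector<Vec3> xq(nq), xq_far(rule_far.w.size());
    for (int q = 0; q < nq; ++q)
      xq[q] = T1.v0 * rule.l1[q] + T1.v1 * rule.l2[q] + T1.v2 * rule.l3[q];
    for (size_t q = 0; q < rule_far.w.size(); ++q)
      xq_far[q] = T1.v0 * rule_far.l1[q] + T1.v1 * rule_far.l2[q] +
                  T1.v2 * rule_far.l3[q];

    for (int t2 = 0; t2 < nt2; ++t2) {
      const TriGeom& T2 = G2[t2];
      const int i2[3] = {(int)F2(t2, 0), (int)F2(t2, 1), (int)F2(t2, 2)};
      const Vec3 curl2[3] = {T2.c0, T2.c1, T2.c2};
      const double nn = dot(T1.n, T2.n);
      double cc[3][3];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) cc[a][b] = dot(curl1[a], curl2[b]);

      bool touching = false;
      if (same_surface) {
        if (t1 == t2) touching = true;
        else
          for (int a = 0; a < 3 && !touching; ++a)
            for (int b = 0; b < 3; ++b)
              if (i1[a] == i2[b]) { touching = true; break; }
      }
      const double dist = norm3(T1.centroid - T2.centroid);
      bool nearby = touching || dist < near_factor * (T1.radius + T2.radius);
      const bool far = !nearby && dist > far_factor * (T1.radius + T2.radius);
      const TriRule& R1 = far ? rule_far : rule;
      const std::vector<Vec3>& xr = far ? xq_far : xq;
      const int nq1 = R1.w.size();

      cdbl s_acc[3][3] = {}, d_acc[3][3] = {}, dp_acc[3][3] = {},
           g_acc = 0.0, gl_acc[3][3] = {};
      // g_acc: plain G integral (for curl term); gl_acc: G * li * lj

      if (!nearby) {
        for (int q = 0; q < nq1; ++q) {
          const double wq = R1.w[q] * T1.area;
          const double lt[3] = {R1.l1[q], R1.l2[q], R1.l3[q]};
          for (int p = 0; p < nq1; ++p) {
            Vec3 y = T2.v0 * R1.l1[p] + T2.v1 * R1.l2[p] +
                     T2.v2 * R1.l3[p];
            const double w = wq * R1.w[p] * T2.area;
            KernelVals kv = kernel(xr[q], y, T1.n, T2.n, k);
            const double ls[3] = {R1.l1[p], R1.l2[p], R1.l3[p]};
            g_acc += w * kv.G;
            for (int a = 0; a < 3; ++a) {
              const double wa = w * lt[a];
              for (int b = 0; b < 3; ++b) {
                s_acc[a][b] += wa * ls[b] * kv.G;
                d_acc[a][b] += wa * ls[b] * kv.dGdny;
                dp_acc[a][b] += wa * ls[b] * kv.dGdnx;
                gl_acc[a][b] += wa * ls[b] * kv.G;
              }
            }
          }
        }
      } else {
        // singular / near pair: regular rule on the test triangle, Duffy
        // subdivision of the trial triangle around the closest point
        for (int q = 0; q < nq; ++q) {
          const Vec3& x = xq[q];
          const double wq = rule.w[q] * T1.area;
          const double lt[3] = {rule.l1[q], rule.l2[q], rule.l3[q]};
          Vec3 xi = closest_point(T2, x);
          const Vec3 corners[3] = {T2.v0, T2.v1, T2.v2};
          for (int e = 0; e < 3; ++e) {
            const Vec3& P = corners[e];
            const Vec3& Q = corners[(e + 1) % 3];
            double a2 = norm3(cross(P - xi, Q - xi));
            if (a2 < 1e-12 * 2.0 * T2.area) continue;  // degenerate wedge
            for (int gu = 0; gu < ng; ++gu) {
              const double u = gx[gu];
              for (int gv = 0; gv < ng; ++gv) {
                const double v = gx[gv];
                Vec3 y = xi + ((P - xi) * (1.0 - v) + (Q - xi) * v) * u;
                const double w = wq * gw[gu] * gw[gv] * u * a2;
                KernelVals kv = kernel(x, y, T1.n, T2.n, k);
                double l0, l1, l2;
                barycentric(T2, y, l0, l1, l2);
                const double ls[3] = {l0, l1, l2};
                g_acc += w * kv.G;
                for (int a = 0; a < 3; ++a) {
                  const double wa = w * lt[a];
                  for (int b = 0; b < 3; ++b) {
                    s_acc[a][b] += wa * ls[b] * kv.G;
                    d_acc[a][b] += wa * ls[b] * kv.dGdny;
                    dp_acc[a][b] += wa * ls[b] * kv.dGdnx;
                    gl_acc[a][b] += wa * ls[b] * kv.G;
                  }
                }
              }
            }
          }
        }
      }

      // scatter; hypersingular N = -(curl . curl) G + k^2 (n.n) G l l,
      // where the curl term needs the *unweighted-by-hat* G integral.
      // The curl-curl piece integrates G(x,y) c_a . c_b over both panels:
      // hats drop out (curls are constants), so reuse g_acc.
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          S(i1[a], i2[b]) += s_acc[a][b];
          D(i1[a], i2[b]) += d_acc[a][b];
          Dp(i1[a], i2[b]) += dp_acc[a][b];
          N(i1[a], i2[b]) += -cc[a][b] * g_acc + k2 * nn * gl_acc[a][b];
        }
    }
  }
  return List::create(_["S"] = S, _["D"] = D, _["Dp"] = Dp, _["N"] = N);
}

// Evaluate single- and double-layer potentials of P1 densities at points.
// dl[i] = int dG/dn_y(x_i, y) phi(y) ds ; sl[i] = int G(x_i, y) psi(y) ds.
// [[Rcpp::export]]
List eval_potentials_cpp(const arma::mat& pts, const arma::mat& V,
                         const arma::imat& F, const arma::cx_vec& phi,
                         const arma::cx_vec& psi, const arma::cx_double k,
                         const int quad_degree = 4) {
  const int np = pts.n_rows, nt = F.n_rows;
  arma::cx_vec dl(np, arma::fill::zeros), sl(np, arma::fill::zeros);
  TriRule rule = tri_rule(quad_degree);
  const int nq = rule.w.size();
  std::vector<TriGeom> G(nt);
  for (int t = 0; t < nt; ++t) G[t] = tri_geom(V, F(t, 0), F(t, 1), F(t, 2));

  for (int t = 0; t < nt; ++t) {
    const TriGeom& T = G[t];
    const cdbl ph[3] = {phi(F(t, 0)), phi(F(t, 1)), phi(F(t, 2))};
    const cdbl ps[3] = {psi(F(t, 0)), psi(F(t, 1)), psi(F(t, 2))};
    for (int q = 0; q < nq; ++q) {
      Vec3 y = T.v0 * rule.l1[q] + T.v1 * rule.l2[q] + T.v2 * rule.l3[q];
      const double w = rule.w[q] * T.area;
      const cdbl phq = ph[0] * rule.l1[q] + ph[1] * rule.l2[q] +
                       ph[2] * rule.l3[q];
      const cdbl psq = ps[0] * rule.l1[q] + ps[1] * rule.l2[q] +
                       ps[2] * rule.l3[q];
      for (int i = 0; i < np; ++i) {
        Vec3 x(pts(i, 0), pts(i, 1), pts(i, 2));
        Vec3 d = x - y;
        double R = norm3(d);
        cdbl ikR = cdbl(0, 1) * k * R;
        cdbl Gv = std::exp(ikR) / (4.0 * M_PI * R);
        cdbl dGdny = Gv * (ikR - 1.0) / R * (dot(T.n, y - x) / R);
        dl(i) += w * dGdny * phq;
        sl(i) += w * Gv * psq;
      }
    }
  }
  return List::create(_["dl"] = dl, _["sl"] = sl);
}

// Signed solid angles subtended by mesh triangles at each point:
// total winding (~ 4 pi inside, ~ 0 outside) and the maximum absolute
// per-triangle solid angle (near-surface exclusion rule).
// [[Rcpp::export]]
List solid_angles_cpp(const arma::mat& pts, const arma::mat& V,
                      const arma::imat& F) {
  const int np = pts.n_rows, nt = F.n_rows;
  NumericVector total(np), maxtri(np);
  for (int i = 0; i < np; ++i) {
    Vec3 p(pts(i, 0), pts(i, 1), pts(i, 2));
    double tot = 0.0, mx = 0.0;
    for (int t = 0; t < nt; ++t) {
      Vec3 a = Vec3(V(F(t, 0), 0), V(F(t, 0), 1), V(F(t, 0), 2)) - p;
      Vec3 b = Vec3(V(F(t, 1), 0), V(F(t, 1), 1), V(F(t, 1), 2)) - p;
      Vec3 c = Vec3(V(F(t, 2), 0), V(F(t, 2), 1), V(F(t, 2), 2)) - p;
      double la = norm3(a), lb = norm3(b), lc = norm3(c);
      double num = dot(a, cross(b, c));
      double den = la * lb * lc + dot(a, b) * lc + dot(a, c) * lb +
                   dot(b, c) * la;
      double om = 2.0 * std::atan2(num, den);
      tot += om;
      double aom = std::fabs(om);
      if (aom > mx) mx = aom;
    }
    total[i] = tot;
    maxtri[i] = mx;
  }
  return List::create(_["total"] = total, _["max_triangle"] = maxtri);
}
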