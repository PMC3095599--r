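// Hot numerical kernels: batched ligand placement with backbone clash
// checking (classic matching), batched six-parameter geometry screening
// (secondary matching), and pairwise nonbonded energies for the simplified
// energy model. Plain Rcpp; all angles in degrees.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// positive remainder without libm fmod
static inline double pmod(double x, double p) {
  return x - p * std::floor(x / p);
}

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 sub(const V3 &a, const V3 &b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 add(const V3 &a, const V3 &b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 scl(const V3 &a, double s) { return V3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3 &a) { double n = norm(a); return V3(a.x / n, a.y / n, a.z / n); }

// NeRF placement: q bonded to p3, angle(p2,p3,q)=theta, dihedral(p1,p2,p3,q)=phi
static V3 nerf(const V3 &p1, const V3 &p2, const V3 &p3,
               double d, double theta, double phi) {
  V3 bc = unit(sub(p3, p2));
  V3 n = unit(cross(sub(p2, p1), bc));
  V3 m = cross(n, bc);
  double th = theta * DEG, ph = phi * DEG;
  V3 d2(-d * std::cos(th), d * std::sin(th) * std::cos(ph), -d * std::sin(th) * std::sin(ph));
  return add(p3, add(scl(bc, d2.x), add(scl(m, d2.y), scl(n, d2.z))));
}

static double angle_deg(const V3 &a, const V3 &b, const V3 &c) {
  V3 u = unit(sub(a, b)), v = unit(sub(c, b));
  double cc = dot(u, v);
  if (cc > 1) cc = 1; if (cc < -1) cc = -1;
  return std::acos(cc) / DEG;
}

static double dihedral_deg(const V3 &p1, const V3 &p2, const V3 &p3, const V3 &p4) {
  V3 b1 = sub(p2, p1), b2 = sub(p3, p2), b3 = sub(p4, p3);
  V3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  V3 m1 = cross(n1, unit(b2));
  return std::atan2(dot(m1, n2), dot(n1, n2)) / DEG;
}

// orthonormal frame columns from a triple (origin a1, x toward a2)
static void frame3(const V3 &a1, const V3 &a2, const V3 &a3, V3 F[3]) {
  F[0] = unit(sub(a2, a1));
  F[2] = unit(cross(F[0], sub(a3, a1)));
  F[1] = cross(F[2], F[0]);
}

static inline V3 rowv(const NumericMatrix &m, int i, int off = 0) {
  return V3(m(i, off), m(i, off + 1), m(i, off + 2));
}

// Classic matching inner loop. anchors: n x 9 side-chain anchor triples
// (atom1, atom2, atom3 of the residue-side map); tuples: m x 6 parameter
// samples ordered (distanceAB, angle_A, angle_B, torsion_A, torsion_AB,
// torsion_B) with Res1 = the side chain; lig_local: ligand conformer;
// aidx: 0-based rows of the three ligand anchor atoms; wall: backbone
// atoms used for the clash test. Returns the surviving placements.
// [[Rcpp::export]]
List cpp_classic_place(NumericMatrix anchors, NumericMatrix tuples,
                       NumericMatrix lig_local, IntegerVector aidx,
                       NumericMatrix wall, NumericVector wall_rad,
                       NumericVector lig_rad, LogicalVector lig_heavy,
                       double clash_factor) {
  const int n = anchors.nrow(), m = tuples.nrow(), L = lig_local.nrow();
  const int W = wall.nrow();
  V3 c1 = rowv(lig_local, aidx[0]), c2 = rowv(lig_local, aidx[1]),
     c3 = rowv(lig_local, aidx[2]);
  double d12 = norm(sub(c2, c1)), d23 = norm(sub(c3, c2));
  double ang123 = angle_deg(c1, c2, c3);
  V3 FL[3];
  frame3(c1, c2, c3, FL);
  // ligand atoms in the local anchor frame
  std::vector<V3> rel(L);
  for (int i = 0; i < L; ++i) {
    V3 v = sub(rowv(lig_local, i), c1);
    rel[i] = V3(dot(v, FL[0]), dot(v, FL[1]), dot(v, FL[2]));
  }
  std::vector<int> hit_rot, hit_tup;
  std::vector<double> hit_xyz;
  long rejected = 0;
  for (int i = 0; i < n; ++i) {
    V3 a1 = rowv(anchors, i, 0), a2 = rowv(anchors, i, 3), a3 = rowv(anchors, i, 6);
    for (int j = 0; j < m; ++j) {
      V3 q1 = nerf(a3, a2, a1, tuples(j, 0), tuples(j, 1), tuples(j, 3));
      V3 q2 = nerf(a2, a1, q1, d12, tuples(j, 2), tuples(j, 4));
      V3 q3 = nerf(a1, q1, q2, d23, ang123, tuples(j, 5));
      V3 FT[3];
      frame3(q1, q2, q3, FT);
      std::vector<V3> world(L);
      bool clash = false;
      for (int k = 0; k < L && !clash; ++k) {
        V3 w = add(q1, add(scl(FT[0], rel[k].x),
                           add(scl(FT[1], rel[k].y), scl(FT[2], rel[k].z))));
        world[k] = w;
        if (!lig_heavy[k]) continue;
        for (int b = 0; b < W; ++b) {
          double dx = w.x - wall(b, 0), dy = w.y - wall(b, 1), dz = w.z - wall(b, 2);
          double lim = clash_factor * (lig_rad[k] + wall_rad[b]);
          if (dx * dx + dy * dy + dz * dz < lim * lim) { clash = true; break; }
        }
      }
      if (clash) { ++rejected; continue; }
      hit_rot.push_back(i + 1);
      hit_tup.push_back(j + 1);
      for (int k = 0; k < L; ++k) {
        hit_xyz.push_back(world[k].x);
        hit_xyz.push_back(world[k].y);
        hit_xyz.push_back(world[k].z);
      }
    }
  }
  const int H = hit_rot.size();
  NumericMatrix coords(H, 3 * L);
  for (int h = 0; h < H; ++h)
    for (int c = 0; c < 3 * L; ++c) coords(h, c) = hit_xyz[(size_t)h * 3 * L + c];
  return List::create(_["rot"] = wrap(hit_rot), _["tuple"] = wrap(hit_tup),
                      _["coords"] = coords, _["rejected"] = (double)rejected);
}

// Secondary matching screen: for every Res1 triple (rows of t1) against
// every Res2 triple (rows of t2), check that each defined parameter lies
// within [x0 - xtol, x0 + xtol] of some periodic copy. Parameter order:
// distanceAB, angle_A, angle_B, torsion_A, torsion_AB, torsion_B.
// [[Rcpp::export]]
LogicalMatrix cpp_secondary_screen(NumericMatrix t1, NumericMatrix t2,
                                   LogicalVector defined, NumericVector x0,
                                   NumericVector xtol, NumericVector per) {
  const int n1 = t1.nrow(), n2 = t2.nrow();
  LogicalMatrix ok(n1, n2);
  for (int i = 0; i < n1; ++i) {
    V3 a1 = rowv(t1, i, 0), a2 = rowv(t1, i, 3), a3 = rowv(t1, i, 6);
    for (int j = 0; j < n2; ++j) {
      V3 b1 = rowv(t2, j, 0), b2 = rowv(t2, j, 3), b3 = rowv(t2, j, 6);
      double v[6];
      v[0] = norm(sub(a1, b1));
      bool pass = true;
      if (defined[0] && std::fabs(v[0] - x0[0]) > xtol[0]) pass = false;
      if (pass && defined[1]) {
        v[1] = angle_deg(a2, a1, b1);
        double d = pmod(std::fabs(v[1] - x0[1]), per[1]);
        if (std::min(d, per[1] - d) > xtol[1]) pass = false;
      }
      if (pass && defined[2]) {
        v[2] = angle_deg(a1, b1, b2);
        double d = pmod(std::fabs(v[2] - x0[2]), per[2]);
        if (std::min(d, per[2] - d) > xtol[2]) pass = false;
      }
      if (pass && defined[3]) {
        v[3] = dihedral_deg(a3, a2, a1, b1);
        double d = pmod(std::fabs(v[3] - x0[3]), per[3]);
        if (std::min(d, per[3] - d) > xtol[3]) pass = false;
      }
      if (pass && defined[4]) {
        v[4] = dihedral_deg(a2, a1, b1, b2);
        double d = pmod(std::fabs(v[4] - x0[4]), per[4]);
        if (std::min(d, per[4] - d) > xtol[4]) pass = false;
      }
      if (pass && defined[5]) {
        v[5] = dihedral_deg(a1, b1, b2, b3);
        double d = pmod(std::fabs(v[5] - x0[5]), per[5]);
        if (std::min(d, per[5] - d) > xtol[5]) pass = false;
      }
      ok(i, j) = pass;
    }
  }
  return ok;
}

// Pairwise nonbonded energy between two atom sets: capped Lennard-Jones
// split into repulsive/attractive parts plus a geometric hydrogen-bond
// term evaluated at donor and acceptor heavy atoms (angle at the donor
// measured through its base atom). skip: 0-based (i,j) pairs exempt from
// the LJ terms (covalent constraint exclusions).
// [[Rcpp::export]]
List cpp_pair_energy(NumericMatrix ax, NumericVector arad, LogicalVector adon,
                     LogicalVector aacc, NumericMatrix abase,
                     NumericMatrix bx, NumericVector brad, LogicalVector bdon,
                     LogicalVector bacc, NumericMatrix bbase,
                     double sigma_scale, IntegerMatrix skip) {
  const int na = ax.nrow(), nb = bx.nrow();
  const double eps = 0.15, rep_cap = 10.0, cutoff = 6.0;
  double rep = 0, atr = 0, hb = 0;
  for (int i = 0; i < na; ++i) {
    V3 a = rowv(ax, i);
    for (int j = 0; j < nb; ++j) {
      double dx = a.x - bx(j, 0), dy = a.y - bx(j, 1), dz = a.z - bx(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cutoff * cutoff) continue;
      bool excl = false;
      for (int k = 0; k < skip.nrow(); ++k)
        if (skip(k, 0) == i && skip(k, 1) == j) { excl = true; break; }
      double r = std::sqrt(r2);
      if (!excl) {
        double s = sigma_scale * (arad[i] + brad[j]);
        double q = s / std::max(r, 0.3);
        double q6 = q * q * q; q6 *= q6;
        double lj = eps * (q6 * q6 - 2.0 * q6);
        if (lj > 0) rep += std::min(lj, rep_cap); else atr += lj;
      }
      // hydrogen bond: try both donor/acceptor assignments
      if (r >= 2.4 && r <= 3.4) {
        double fr = (r - 2.9) / 0.5;
          double f = 1.0 - fr * fr;
        if (f > 0) {
          if (adon[i] && bacc[j]) {
            double ang = angle_deg(rowv(abase, i), a, V3(bx(j, 0), bx(j, 1), bx(j, 2)));
            double g = (ang - 100.0) / 80.0;
            if (g > 1) g = 1;
            if (g > 0) hb -= f * g;
          }
          if (bdon[j] && aacc[i]) {
            double ang = angle_deg(rowv(bbase, j), V3(bx(j, 0), bx(j, 1), bx(j, 2)), a);
            double g = (ang - 100.0) / 80.0;
            if (g > 1) g = 1;
            if (g > 0) hb -= f * g;
          }
        }
      }
    }
  }
  return List::create(_["rep"] = rep, _["atr"] = atr, _["hb"] = hb);
}

// minimum-distance clash test between two atom sets with per-atom radii
// [[Rcpp::export]]
bool cpp_has_clash(NumericMatrix ax, NumericVector arad,
                   NumericMatrix bx, NumericVector brad, double factor) {
  for (int i = 0; i < ax.nrow(); ++i)
    for (int j = 0; j < bx.nrow(); ++j) {
      double dx = ax(i, 0) - bx(j, 0), dy = ax(i, 1) - bx(j, 1), dz = ax(i, 2) - bx(j, 2);
      double lim = factor * (arad[i] + brad[j]);
      if (dx * dx + dy * dy + dz * dz < lim * lim) return true;
    }
  return false;
}
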