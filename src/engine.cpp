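#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Quartic repulsive intermolecular energy between two posed atom sets.
// E = k * sum_pairs max(0, (s*rmin_ij)^2 - r_ij^2)^2 over active pairs with
// r_ij <= nb_cutoff; rmin_ij = rmin_i + rmin_j.
static double quartic_energy(const std::vector<double> &ax,
                             const std::vector<double> &ay,
                             const std::vector<double> &az,
                             const std::vector<double> &ar,
                             const std::vector<int> &aact,
                             const std::vector<double> &bx,
                             const std::vector<double> &by,
                             const std::vector<double> &bz,
                             const std::vector<double> &br,
                             const std::vector<int> &bact,
                             double tx, double ty, double tz,
                             double s, double kvdw, double nb_cutoff) {
  const double nb2 = nb_cutoff * nb_cutoff;
  double e = 0.0;
  const size_t na = ax.size(), nb = bx.size();
  for (size_t j = 0; j < nb; ++j) {
    if (!bact[j]) continue;
    const double pjx = bx[j] + tx, pjy = by[j] + ty, pjz = bz[j] + tz;
    const double srb = br[j];
    for (size_t i = 0; i < na; ++i) {
      if (!aact[i]) continue;
      const double dx = pjx - ax[i], dy = pjy - ay[i], dz = pjz - az[i];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > nb2) continue;
      const double q = s * (srb + ar[i]);
      const double diff = q * q - r2;
      if (diff > 0.0) e += diff * diff;
    }
  }
  return kvdw * e;
}

struct ContactResult {
  bool found;
  double disp;
  double energy;
};

// Per-pair coefficients of r_ij^2(t) = t^2 + 2 b t + c2 along the line,
// for pairs whose quartic interval can overlap the contact boundary.
struct PairCoef {
  double b;
  double c2;
  double q2;
};

// Translate the mobile set along unit vector e until the quartic energy sits
// in (0, ecut].  The exact onset displacement (largest displacement with any
// pair inside its quartic onset) is found analytically per pair, then the
// zero/positive boundary is refined by inward 'step' stepping and bisection
// to 'tol', exactly as the translate-to-contact procedure prescribes.  The
// analytic bracket only seeds the stepping start so the search is fast; the
// returned displacement is always the bisection result.
static ContactResult contact_line(const std::vector<double> &ax,
                                  const std::vector<double> &ay,
                                  const std::vector<double> &az,
                                  const std::vector<double> &ar,
                                  const std::vector<int> &aact,
                                  const std::vector<double> &bx,
                                  const std::vector<double> &by,
                                  const std::vector<double> &bz,
                                  const std::vector<double> &br,
                                  const std::vector<int> &bact,
                                  double ex, double ey, double ez,
                                  double s, double kvdw, double nb_cutoff,
                                  double ecut, double step, double tol,
                                  bool require_positive,
                                  std::vector<PairCoef> &scratch) {
  ContactResult res;
  res.found = false;
  res.disp = NA_REAL;
  res.energy = NA_REAL;

  // Pass 1: largest root t* of |c + t e|^2 = q^2 over all active pairs, and
  // the line coefficients of every pair whose interval could matter near the
  // boundary.  All stepping/bisection probes below lie in
  // [t* - margin, t* + step], so pairs whose positive interval ends before
  // t* - margin can never contribute to a probed energy.
  const double margin = 4.0 * step;
  double tstar = -std::numeric_limits<double>::infinity();
  const size_t na = ax.size(), nb = bx.size();
  scratch.clear();
  const double nb2 = nb_cutoff * nb_cutoff;
  for (size_t j = 0; j < nb; ++j) {
    if (!bact[j]) continue;
    for (size_t i = 0; i < na; ++i) {
      if (!aact[i]) continue;
      const double cx = bx[j] - ax[i], cy = by[j] - ay[i], cz = bz[j] - az[i];
      const double q = s * (br[j] + ar[i]);
      const double ce = cx * ex + cy * ey + cz * ez;
      const double c2 = cx * cx + cy * cy + cz * cz;
      const double disc = ce * ce - c2 + q * q;
      if (disc >= 0.0) {
        const double root = std::sqrt(disc);
        const double t_pair = -ce + root;
        if (t_pair > tstar) {
          tstar = t_pair;
          // drop candidates that ended before the new boundary window
          size_t keep = 0;
          for (size_t m = 0; m < scratch.size(); ++m) {
            const double bm = scratch[m].b;
            const double dm = bm * bm - scratch[m].c2 + scratch[m].q2;
            if (-bm + std::sqrt(dm) >= tstar - margin) scratch[keep++] = scratch[m];
          }
          scratch.resize(keep);
        }
        if (t_pair >= tstar - margin) {
          PairCoef pc;
          pc.b = ce;
          pc.c2 = c2;
          pc.q2 = q * q;
          scratch.push_back(pc);
        }
      }
    }
  }
  if (tstar == -std::numeric_limits<double>::infinity()) return res;
  if (require_positive && tstar <= 0.0) return res;

  // Energy restricted to the boundary window (exact there: every pair whose
  // quartic term is positive at a probed t is in the candidate list).
  auto window_energy = [&](double t) {
    double e = 0.0;
    for (size_t m = 0; m < scratch.size(); ++m) {
      const double r2 = t * t + 2.0 * scratch[m].b * t + scratch[m].c2;
      if (r2 > nb2) continue;
      const double diff = scratch[m].q2 - r2;
      if (diff > 0.0) e += diff * diff;
    }
    return kvdw * e;
  };

  // Inward stepping from a guaranteed zero-energy start (t* + step), kept
  // inside the candidate window.
  double t_hi = tstar + step;  // E == 0 here by construction
  double t_lo = NA_REAL, e_lo = 0.0;
  bool pos = false;
  for (int it = 0; it < 3; ++it) {
    const double t = t_hi - step * (it + 1);
    const double e = window_energy(t);
    if (e > 0.0) {
      t_lo = t;
      e_lo = e;
      t_hi = t + step;
      pos = true;
      break;
    }
  }
  if (!pos) return res;  // tangential graze: no resolvable positive energy

  // Bisection on the zero/positive boundary; keep the outermost positive
  // probe whose energy does not exceed the cut-off.
  for (int it = 0; it < 80; ++it) {
    if ((t_hi - t_lo) <= tol && e_lo > 0.0 && e_lo <= ecut) break;
    const double mid = 0.5 * (t_lo + t_hi);
    const double e = window_energy(mid);
    if (e > 0.0) {
      t_lo = mid;
      e_lo = e;
    } else {
      t_hi = mid;
    }
  }
  if (!(e_lo > 0.0 && e_lo <= ecut)) return res;
  res.found = true;
  res.disp = t_lo;
  res.energy = e_lo;
  return res;
}

static void unpack_coords(const NumericMatrix &m, std::vector<double> &x,
                          std::vector<double> &y, std::vector<double> &z) {
  const int n = m.nrow();
  x.resize(n);
  y.resize(n);
  z.resize(n);
  for (int i = 0; i < n; ++i) {
    x[i] = m(i, 0);
    y[i] = m(i, 1);
    z[i] = m(i, 2);
  }
}

static std::vector<int> unpack_flags(const LogicalVector &v) {
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] ? 1 : 0;
  return out;
}

static std::vector<double> unpack_num(const NumericVector &v) {
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export]]
double cpp_vdw_energy(NumericMatrix a_xyz, NumericVector a_rmin,
                      LogicalVector a_active, NumericMatrix b_xyz,
                      NumericVector b_rmin, LogicalVector b_active, double s,
                      double kvdw, double nb_cutoff) {
  std::vector<double> ax, ay, az, bx, by, bz;
  unpack_coords(a_xyz, ax, ay, az);
  unpack_coords(b_xyz, bx, by, bz);
  std::vector<double> ar = unpack_num(a_rmin), br = unpack_num(b_rmin);
  std::vector<int> aact = unpack_flags(a_active), bact = unpack_flags(b_active);
  return quartic_energy(ax, ay, az, ar, aact, bx, by, bz, br, bact, 0.0, 0.0,
                        0.0, s, kvdw, nb_cutoff);
}

// [[Rcpp::export]]
double cpp_min_pair_dist(NumericMatrix a_xyz, NumericMatrix b_xyz) {
  double best = std::numeric_limits<double>::infinity();
  for (int j = 0; j < b_xyz.nrow(); ++j) {
    for (int i = 0; i < a_xyz.nrow(); ++i) {
      const double dx = b_xyz(j, 0) - a_xyz(i, 0);
      const double dy = b_xyz(j, 1) - a_xyz(i, 1);
      const double dz = b_xyz(j, 2) - a_xyz(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
List cpp_contact_line(NumericMatrix a_xyz, NumericVector a_rmin,
                      LogicalVector a_active, NumericMatrix b_xyz,
                      NumericVector b_rmin, LogicalVector b_active,
                      NumericVector e_dir, double s, double kvdw,
                      double nb_cutoff, double ecut, double step, double tol,
                      bool require_positive) {
  std::vector<double> ax, ay, az, bx, by, bz;
  unpack_coords(a_xyz, ax, ay, az);
  unpack_coords(b_xyz, bx, by, bz);
  std::vector<double> ar = unpack_num(a_rmin), br = unpack_num(b_rmin);
  std::vector<int> aact = unpack_flags(a_active), bact = unpack_flags(b_active);
  std::vector<PairCoef> scratch;
  ContactResult r = contact_line(ax, ay, az, ar, aact, bx, by, bz, br, bact,
                                 e_dir[0], e_dir[1], e_dir[2], s, kvdw,
                                 nb_cutoff, ecut, step, tol, require_positive,
                                 scratch);
  return List::create(Named("found") = r.found, Named("disp") = r.disp,
                      Named("energy") = r.energy);
}

// Minimal distance between two posed cofactor subsets.
static double cof_min_dist(const std::vector<double> &ax,
                           const std::vector<double> &ay,
                           const std::vector<double> &az,
                           const std::vector<int> &ia,
                           const std::vector<double> &bx,
                           const std::vector<double> &by,
                           const std::vector<double> &bz,
                           const std::vector<int> &ib, double tx, double ty,
                           double tz) {
  double best = std::numeric_limits<double>::infinity();
  for (size_t jj = 0; jj < ib.size(); ++jj) {
    const int j = ib[jj];
    const double pjx = bx[j] + tx, pjy = by[j] + ty, pjz = bz[j] + tz;
    for (size_t ii = 0; ii < ia.size(); ++ii) {
      const int i = ia[ii];
      const double dx = pjx - ax[i], dy = pjy - ay[i], dz = pjz - az[i];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Main placement x rotamer docking loop.
//
// a_xyz: fixed body in the world frame (CM at origin).
// b_xyz: mobile body centred on its CM, frontal alignment already applied.
// r_place: P x 9 row-major placement rotations; p0: P x 3 initial CM positions
// (p0 = R_place %*% p_ref).  r_body: K x 9 row-major body rotations about the
// mobile CM, enumerated in rotamer order.  All work happens in the placement
// frame: fixed atoms are rotated by R_place^T once per placement so the
// translation line is the placement-frame CM direction.
// [[Rcpp::export]]
List cpp_sample(NumericMatrix a_xyz, NumericVector a_rmin,
                LogicalVector a_active, NumericMatrix b_xyz,
                NumericVector b_rmin, LogicalVector b_active,
                IntegerVector cof_a, IntegerVector cof_b,
                NumericMatrix r_place, NumericMatrix p0, NumericMatrix r_body,
                double s, double kvdw, double nb_cutoff, double ecut,
                double step, double tol) {
  const int P = r_place.nrow();
  const int K = r_body.nrow();
  const int na = a_xyz.nrow(), nb = b_xyz.nrow();

  std::vector<double> ax0, ay0, az0, bx0, by0, bz0;
  unpack_coords(a_xyz, ax0, ay0, az0);
  unpack_coords(b_xyz, bx0, by0, bz0);
  std::vector<double> ar = unpack_num(a_rmin), br = unpack_num(b_rmin);
  std::vector<int> aact = unpack_flags(a_active), bact = unpack_flags(b_active);
  std::vector<int> ia(cof_a.begin(), cof_a.end());
  std::vector<int> ib(cof_b.begin(), cof_b.end());

  LogicalVector found(P);
  IntegerVector best_k(P);
  NumericVector r_contact(P), dmin(P), fvdw(P);

  std::vector<double> ax(na), ay(na), az(na), bx(nb), by(nb), bz(nb);
  std::vector<PairCoef> scratch;
  scratch.reserve(64);

  for (int p = 0; p < P; ++p) {
    Rcpp::checkUserInterrupt();
    const double R0 = r_place(p, 0), R1 = r_place(p, 1), R2 = r_place(p, 2);
    const double R3 = r_place(p, 3), R4 = r_place(p, 4), R5 = r_place(p, 5);
    const double R6 = r_place(p, 6), R7 = r_place(p, 7), R8 = r_place(p, 8);
    // fixed into placement frame: a' = R^T a
    for (int i = 0; i < na; ++i) {
      ax[i] = R0 * ax0[i] + R3 * ay0[i] + R6 * az0[i];
      ay[i] = R1 * ax0[i] + R4 * ay0[i] + R7 * az0[i];
      az[i] = R2 * ax0[i] + R5 * ay0[i] + R8 * az0[i];
    }
    // placement-frame CM direction
    double ux = R0 * p0(p, 0) + R3 * p0(p, 1) + R6 * p0(p, 2);
    double uy = R1 * p0(p, 0) + R4 * p0(p, 1) + R7 * p0(p, 2);
    double uz = R2 * p0(p, 0) + R5 * p0(p, 1) + R8 * p0(p, 2);
    const double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un;
    uy /= un;
    uz /= un;

    bool got = false;
    double bd = std::numeric_limits<double>::infinity();
    int bk = -1;
    double bt = NA_REAL, be = NA_REAL;

    for (int k = 0; k < K; ++k) {
      const double B0 = r_body(k, 0), B1 = r_body(k, 1), B2 = r_body(k, 2);
      const double B3 = r_body(k, 3), B4 = r_body(k, 4), B5 = r_body(k, 5);
      const double B6 = r_body(k, 6), B7 = r_body(k, 7), B8 = r_body(k, 8);
      for (int j = 0; j < nb; ++j) {
        bx[j] = B0 * bx0[j] + B1 * by0[j] + B2 * bz0[j];
        by[j] = B3 * bx0[j] + B4 * by0[j] + B5 * bz0[j];
        bz[j] = B6 * bx0[j] + B7 * by0[j] + B8 * bz0[j];
      }
      ContactResult cr =
          contact_line(ax, ay, az, ar, aact, bx, by, bz, br, bact, ux, uy, uz,
                       s, kvdw, nb_cutoff, ecut, step, tol, true, scratch);
      if (!cr.found) continue;
      const double d = cof_min_dist(ax, ay, az, ia, bx, by, bz, ib,
                                    cr.disp * ux, cr.disp * uy, cr.disp * uz);
      if (d < bd) {  // strict: ties keep the earlier (lexicographic) rotamer
        bd = d;
        bk = k;
        bt = cr.disp;
        be = cr.energy;
        got = true;
      }
    }
    found[p] = got;
    best_k[p] = got ? bk + 1 : NA_INTEGER;
    r_contact[p] = got ? bt : NA_REAL;
    dmin[p] = got ? bd : NA_REAL;
    fvdw[p] = got ? be : NA_REAL;
  }
  return List::create(Named("found") = found, Named("best_rotamer") = best_k,
                      Named("r_contact") = r_contact, Named("d_min") = dmin,
                      Named("f_vdw") = fvdw);
}

// Scan body rotations for the one minimising the cofactor-cofactor minimal
// distance with the mobile CM held at 'offset' (frontal alignment search).
// [[Rcpp::export]]
List cpp_frontal_scan(NumericMatrix cof_fixed, NumericMatrix cof_mobile_cent,
                      NumericMatrix r_body, NumericVector offset) {
  const int K = r_body.nrow();
  const int n = cof_fixed.nrow(), m = cof_mobile_cent.nrow();
  double best = std::numeric_limits<double>::infinity();
  int best_k = -1;
  for (int k = 0; k < K; ++k) {
    const double B0 = r_body(k, 0), B1 = r_body(k, 1), B2 = r_body(k, 2);
    const double B3 = r_body(k, 3), B4 = r_body(k, 4), B5 = r_body(k, 5);
    const double B6 = r_body(k, 6), B7 = r_body(k, 7), B8 = r_body(k, 8);
    double dk = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      const double x = cof_mobile_cent(j, 0), y = cof_mobile_cent(j, 1),
                   z = cof_mobile_cent(j, 2);
      const double px = B0 * x + B1 * y + B2 * z + offset[0];
      const double py = B3 * x + B4 * y + B5 * z + offset[1];
      const double pz = B6 * x + B7 * y + B8 * z + offset[2];
      for (int i = 0; i < n; ++i) {
        const double dx = px - cof_fixed(i, 0), dy = py - cof_fixed(i, 1),
                     dz = pz - cof_fixed(i, 2);
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < dk) dk = d2;
      }
    }
    if (dk < best) {
      best = dk;
      best_k = k;
    }
  }
  return List::create(Named("best") = best_k + 1,
                      Named("d_min") = std::sqrt(best));
}
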