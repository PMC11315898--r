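// Hot numerical kernels for cross-link-restrained docking: steric clash
// counting, vectorised rotation-grid scans, and greedy rigid-body pose
// refinement. All loops are deterministic.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// number of point pairs closer than cd (strict, with a tiny tolerance so a
// pair exactly at the cutoff does not count)
// [[Rcpp::export(name = ".clash_count_cpp")]]
int clash_count_cpp(NumericMatrix pa, NumericMatrix pb, double cd) {
  const int m = pa.nrow(), n = pb.nrow();
  const double cd2 = cd * cd - 1e-12;
  int count = 0;
  for (int j = 0; j < n; ++j) {
    const double xj = pb(j, 0), yj = pb(j, 1), zj = pb(j, 2);
    for (int i = 0; i < m; ++i) {
      const double dx = pa(i, 0) - xj, dy = pa(i, 1) - yj, dz = pa(i, 2) - zj;
      if (dx * dx + dy * dy + dz * dz < cd2) ++count;
    }
  }
  return count;
}

static inline void apply_rot(const double *R, const double *p, double *out) {
  // R is 3x3 column-major, acts on column vectors
  out[0] = R[0] * p[0] + R[3] * p[1] + R[6] * p[2];
  out[1] = R[1] * p[0] + R[4] * p[1] + R[7] * p[2];
  out[2] = R[2] * p[0] + R[5] * p[1] + R[8] * p[2];
}

// per-link minimum restraint distances for a pose (R, t): anchors a fixed,
// anchors b mobile; gid maps combo rows to 0-based link ids
static void link_dmin(const NumericMatrix &a, const NumericMatrix &b,
                      const IntegerVector &gid, int ngroups,
                      const double *R, const double *t,
                      std::vector<double> &dmin) {
  std::fill(dmin.begin(), dmin.end(), R_PosInf);
  const int m = a.nrow();
  for (int i = 0; i < m; ++i) {
    double p[3] = { b(i, 0), b(i, 1), b(i, 2) }, q[3];
    apply_rot(R, p, q);
    const double dx = a(i, 0) - (q[0] + t[0]);
    const double dy = a(i, 1) - (q[1] + t[1]);
    const double dz = a(i, 2) - (q[2] + t[2]);
    const double d2 = dx * dx + dy * dy + dz * dz;
    const int g = gid[i];
    if (d2 < dmin[g]) dmin[g] = d2;
  }
  for (int g = 0; g < ngroups; ++g) dmin[g] = std::sqrt(dmin[g]);
}

static double restraint_score_c(const std::vector<double> &dmin,
                                double threshold, const NumericVector &hb,
                                double *frac_out) {
  const int n = dmin.size();
  int sat = 0;
  double hinge = 0.0;
  for (int g = 0; g < n; ++g) {
    if (dmin[g] < threshold) ++sat;
    const double h = dmin[g] - hb[g];
    if (h > 0) hinge += h;
  }
  const double frac = (double)sat / n;
  if (frac_out) *frac_out = frac;
  return frac - 1e-3 * hinge / n;
}

// scan a rotation grid: for each rotation the closed-form restraint-optimal
// translation (mean offset over first-combo anchors), satisfied fraction
// and restraint score
// [[Rcpp::export(name = ".scan_rotations_cpp")]]
List scan_rotations_cpp(NumericMatrix a, NumericMatrix b, IntegerVector gid,
                        int ngroups, IntegerVector first,
                        NumericMatrix grid_flat, double threshold,
                        NumericVector hb) {
  const int ngrid = grid_flat.ncol();
  const int nfirst = first.size();
  NumericVector frac(ngrid), score(ngrid);
  NumericMatrix tmat(ngrid, 3);
  std::vector<double> dmin(ngroups);
  for (int k = 0; k < ngrid; ++k) {
    double R[9];
    for (int z = 0; z < 9; ++z) R[z] = grid_flat(z, k);
    double t[3] = { 0.0, 0.0, 0.0 };
    for (int ii = 0; ii < nfirst; ++ii) {
      const int i = first[ii];
      double p[3] = { b(i, 0), b(i, 1), b(i, 2) }, q[3];
      apply_rot(R, p, q);
      t[0] += a(i, 0) - q[0];
      t[1] += a(i, 1) - q[1];
      t[2] += a(i, 2) - q[2];
    }
    t[0] /= nfirst; t[1] /= nfirst; t[2] /= nfirst;
    link_dmin(a, b, gid, ngroups, R, t, dmin);
    double fr;
    score[k] = restraint_score_c(dmin, threshold, hb, &fr);
    frac[k] = fr;
    tmat(k, 0) = t[0]; tmat(k, 1) = t[1]; tmat(k, 2) = t[2];
  }
  return List::create(_["frac"] = frac, _["score"] = score,
                      _["translations"] = tmat);
}

static void axis_rot(int axis, double ang_deg, double *R) {
  const double th = ang_deg * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  // column-major 3x3
  if (axis == 0) {
    R[0] = 1; R[1] = 0; R[2] = 0;
    R[3] = 0; R[4] = c; R[5] = s;
    R[6] = 0; R[7] = -s; R[8] = c;
  } else if (axis == 1) {
    R[0] = c; R[1] = 0; R[2] = -s;
    R[3] = 0; R[4] = 1; R[5] = 0;
    R[6] = s; R[7] = 0; R[8] = c;
  } else {
    R[0] = c; R[1] = s; R[2] = 0;
    R[3] = -s; R[4] = c; R[5] = 0;
    R[6] = 0; R[7] = 0; R[8] = 1;
  }
}

static void mat_mult(const double *A, const double *B, double *C) {
  // C = A %*% B, all column-major 3x3
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      C[i + 3 * j] = A[i] * B[3 * j] + A[i + 3] * B[1 + 3 * j] +
                     A[i + 6] * B[2 + 3 * j];
}

// greedy deterministic coordinate descent over body-centred rotation tweaks
// and axis translations; objective = restraint score - clash_penalty *
// clashes + a small capped contact reward (shape-complementarity stand-in),
// with the steric pass evaluated lazily
// [[Rcpp::export(name = ".refine_pose_cpp")]]
List refine_pose_cpp(NumericMatrix a, NumericMatrix b, IntegerVector gid,
                     int ngroups, NumericMatrix R0, NumericVector t0,
                     double step, double threshold, NumericVector hb,
                     double clash_penalty, double clash_distance,
                     double contact_weight, double contact_distance,
                     int contact_cap,
                     NumericMatrix aca, NumericMatrix bca, int max_sweeps) {
  double bestR[9], tmpR[9];
  for (int z = 0; z < 9; ++z) bestR[z] = R0[z];
  double bestT[3] = { t0[0], t0[1], t0[2] };
  const int nb = bca.nrow(), na = aca.nrow();
  double bcen[3] = { 0, 0, 0 };
  for (int i = 0; i < nb; ++i)
    for (int z = 0; z < 3; ++z) bcen[z] += bca(i, z);
  for (int z = 0; z < 3; ++z) bcen[z] /= nb;
  std::vector<double> dmin(ngroups);
  std::vector<double> bp(3 * nb);

  // one pass counts both clashes (< clash_distance) and contacts
  // (< contact_distance)
  auto steric = [&](const double *R, const double *t, int *contacts) {
    const double cd2 = clash_distance * clash_distance - 1e-12;
    const double kd2 = contact_distance * contact_distance;
    int count = 0, touch = 0;
    for (int i = 0; i < nb; ++i) {
      double p[3] = { bca(i, 0), bca(i, 1), bca(i, 2) }, q[3];
      apply_rot(R, p, q);
      bp[3 * i] = q[0] + t[0]; bp[3 * i + 1] = q[1] + t[1];
      bp[3 * i + 2] = q[2] + t[2];
    }
    for (int j = 0; j < na; ++j) {
      const double xj = aca(j, 0), yj = aca(j, 1), zj = aca(j, 2);
      for (int i = 0; i < nb; ++i) {
        const double dx = bp[3 * i] - xj, dy = bp[3 * i + 1] - yj,
                     dz = bp[3 * i + 2] - zj;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < cd2) ++count;
        if (d2 < kd2) ++touch;
      }
    }
    *contacts = touch;
    return count;
  };
  const double max_bonus = contact_weight * contact_cap;
  auto objective = [&](const double *R, const double *t, double floor_sc) {
    link_dmin(a, b, gid, ngroups, R, t, dmin);
    double sc = restraint_score_c(dmin, threshold, hb, nullptr);
    if (na == 0 || sc + max_bonus <= floor_sc) return sc;
    int touch = 0;
    const int count = steric(R, t, &touch);
    if (touch > contact_cap) touch = contact_cap;
    return sc - clash_penalty * count + contact_weight * touch;
  };

  double best = objective(bestR, bestT, R_NegInf);
  const double angles[6] = { step / 2, -step / 2, step / 4, -step / 4,
                             step / 8, -step / 8 };
  const double shifts[6] = { 2, -2, 1, -1, 0.5, -0.5 };
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool improved = false;
    for (int ax = 0; ax < 3; ++ax)
      for (int ai = 0; ai < 6; ++ai) {
        double dR[9];
        axis_rot(ax, angles[ai], dR);
        // pivot about the current body centroid
        double cen[3], q[3];
        apply_rot(bestR, bcen, q);
        for (int z = 0; z < 3; ++z) cen[z] = q[z] + bestT[z];
        mat_mult(dR, bestR, tmpR);
        double d0[3] = { bestT[0] - cen[0], bestT[1] - cen[1],
                         bestT[2] - cen[2] }, d1[3];
        apply_rot(dR, d0, d1);
        double tc[3] = { d1[0] + cen[0], d1[1] + cen[1], d1[2] + cen[2] };
        const double sc = objective(tmpR, tc, best);
        if (sc > best + 1e-12) {
          best = sc; improved = true;
          for (int z = 0; z < 9; ++z) bestR[z] = tmpR[z];
          for (int z = 0; z < 3; ++z) bestT[z] = tc[z];
        }
      }
    for (int k = 0; k < 3; ++k)
      for (int si = 0; si < 6; ++si) {
        double tc[3] = { bestT[0], bestT[1], bestT[2] };
        tc[k] += shifts[si];
        const double sc = objective(bestR, tc, best);
        if (sc > best + 1e-12) {
          best = sc; improved = true;
          for (int z = 0; z < 3; ++z) bestT[z] = tc[z];
        }
      }
    if (!improved) break;
  }
  NumericMatrix Rout(3, 3);
  for (int z = 0; z < 9; ++z) Rout[z] = bestR[z];
  return List::create(_["R"] = Rout,
                      _["t"] = NumericVector::create(bestT[0], bestT[1],
                                                     bestT[2]),
                      _["score"] = best);
}
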