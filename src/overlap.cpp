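// Disk-cone overlap integrals and sequential network wiring.
//
// The mitral-cell lateral-dendrite density rho_m(r) integrates in closed
// form along rays: with F(r) = (alpha/2pi) * atan(k*r - tan(m)),
//   int_{r1}^{r2} rho_m(r) r dr = F(r2) - F(r1),
// so every lens integral reduces to a one-dimensional quadrature over the
// polar angle. Quadrature is adaptive Simpson with an absolute tolerance
// of 1e-3 um on the overlap length.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TWOPI = 2.0 * M_PI;

struct McProfile {
  double alpha, k, tanm;
  // radial primitive of rho_m(r) * r
  double F(double r) const { return alpha / TWOPI * std::atan(k * r - tanm); }
};

// Chord bounds of a circle of radius rg centred a distance s from the
// origin, along the ray at angle theta from the centre line.
static inline double chord_lo(double s, double rg, double th) {
  double d = rg * rg - s * s * std::sin(th) * std::sin(th);
  if (d < 0) d = 0;
  return s * std::cos(th) - std::sqrt(d);
}
static inline double chord_hi(double s, double rg, double th) {
  double d = rg * rg - s * s * std::sin(th) * std::sin(th);
  if (d < 0) d = 0;
  return s * std::cos(th) + std::sqrt(d);
}

// integrand selector: 0: F(rm)-F(g), 1: F(g')-F(g), 2: F(g')-F(0), 3: F(rm)-F(0)
struct Seg {
  int kind;
  double a, b; // theta range
};

static double seg_f(const Seg& sg, const McProfile& p, double s, double rm,
                    double rg, double th) {
  switch (sg.kind) {
    case 0: return p.F(rm) - p.F(chord_lo(s, rg, th));
    case 1: return p.F(chord_hi(s, rg, th)) - p.F(chord_lo(s, rg, th));
    case 2: return p.F(chord_hi(s, rg, th)) - p.F(0.0);
    default: return p.F(rm) - p.F(0.0);
  }
}

static double simpson(const Seg& sg, const McProfile& p, double s, double rm,
                      double rg, double a, double b, double fa, double fm,
                      double fb, double tol, int depth) {
  double m = 0.5 * (a + b);
  double lm = 0.5 * (a + m), rm_ = 0.5 * (m + b);
  double flm = seg_f(sg, p, s, rm, rg, lm);
  double frm = seg_f(sg, p, s, rm, rg, rm_);
  double whole = (b - a) / 6.0 * (fa + 4.0 * fm + fb);
  double left = (m - a) / 6.0 * (fa + 4.0 * flm + fm);
  double right = (b - m) / 6.0 * (fm + 4.0 * frm + fb);
  double d = left + right - whole;
  if (depth <= 0 || std::fabs(d) < 15.0 * tol)
    return left + right + d / 15.0;
  return simpson(sg, p, s, rm, rg, a, m, fa, flm, fm, tol * 0.5, depth - 1) +
         simpson(sg, p, s, rm, rg, m, b, fm, frm, fb, tol * 0.5, depth - 1);
}

static double integrate_seg(const Seg& sg, const McProfile& p, double s,
                            double rm, double rg, double tol) {
  if (sg.b <= sg.a) return 0.0;
  double fa = seg_f(sg, p, s, rm, rg, sg.a);
  double fm = seg_f(sg, p, s, rm, rg, 0.5 * (sg.a + sg.b));
  double fb = seg_f(sg, p, s, rm, rg, sg.b);
  return simpson(sg, p, s, rm, rg, sg.a, sg.b, fa, fm, fb, tol, 40);
}

// Case ids: 0 no overlap; 1 far lens (s >= sqrt(rg^2+rm^2));
// 11/12/13 large-disk cases (rm > 2 rg) by decreasing s;
// 21/22/23 comparable (2 rg > rm > rg); 31/32/33 large-cone (rg > rm).
static int overlap_case_id(double s, double rm, double rg) {
  if (rg <= 0 || rm <= 0 || s >= rg + rm) return 0;
  double scrit = std::sqrt(rg * rg + rm * rm);
  if (s >= scrit) return 1;
  if (rm > 2.0 * rg) {
    if (s >= rm - rg) return 11;
    if (s >= rg) return 12;
    return 13;
  } else if (rm > rg) {
    if (s >= rg) return 21;
    if (s >= rm - rg) return 22;
    return 23;
  } else {
    if (s >= rg) return 31;
    if (s >= rg - rm) return 32;
    return 33;
  }
}

static double overlap_length_core(double s, double rm, double rg,
                                  const McProfile& p, double tol) {
  int cid = overlap_case_id(s, rm, rg);
  if (cid == 0) return 0.0;
  double L = 0.0;
  double mu = 0.0, ga = 0.0;
  if (s > 0) {
    double cmu = (rm * rm + s * s - rg * rg) / (2.0 * rm * s);
    if (cmu > 1) cmu = 1; if (cmu < -1) cmu = -1;
    mu = std::acos(cmu);
    double sga = rg / s;
    ga = (sga >= 1) ? M_PI_2 : std::asin(sga);
  }
  Seg sg;
  switch (cid) {
    case 1: // far lens, doubled half-integral
      sg = {0, 0.0, mu};
      L = 2.0 * integrate_seg(sg, p, s, rm, rg, tol / 2.0);
      break;
    case 11: case 21: case 31: // near lens: disk rim then far chord
      sg = {0, 0.0, mu};
      L = 2.0 * integrate_seg(sg, p, s, rm, rg, tol / 4.0);
      sg = {1, mu, ga};
      L += 2.0 * integrate_seg(sg, p, s, rm, rg, tol / 4.0);
      break;
    case 12: // cone circle strictly inside annulus sector
      sg = {1, 0.0, ga};
      L = 2.0 * integrate_seg(sg, p, s, rm, rg, tol / 2.0);
      break;
    case 22: case 32: // cone circle covers disk centre, rim visible
      sg = {2, mu, M_PI};
      L = 2.0 * integrate_seg(sg, p, s, rm, rg, tol / 4.0);
      sg = {3, 0.0, mu};
      L += 2.0 * integrate_seg(sg, p, s, rm, rg, tol / 4.0);
      break;
    case 13: case 23: // cone circle inside disk, covering centre
      sg = {2, 0.0, TWOPI};
      L = integrate_seg(sg, p, s, rm, rg, tol);
      break;
    case 33: // disk contained in cone circle
      L = TWOPI * (p.F(rm) - p.F(0.0));
      break;
  }
  return L < 0 ? 0.0 : L;
}

// [[Rcpp::export]]
int cpp_overlap_case(double s, double rm, double rg) {
  return overlap_case_id(s, rm, rg);
}

// [[Rcpp::export]]
double cpp_overlap_length(double s, double rm, double rg, double alpha,
                          double k, double m, double tol = 1e-3) {
  if (rm < 0 || rg < 0 || s < 0) stop("invalid geometry: negative radius or distance");
  McProfile p{alpha, k, std::tan(m)};
  return overlap_length_core(s, rm, rg, p, tol);
}

// Granule-cell volumetric spine density at height z (clamped eps above the
// cone vertex), using an effective spine count seff.
static inline double rho_g_at(double z, double z0, double zmax, double rmax,
                              double seff, double eps) {
  if (z > zmax || z <= z0) return 0.0;
  double zz = z;
  if (zz < z0 + eps) zz = z0 + eps;
  return 6.0 * seff * (zmax - zz) /
         (M_PI * rmax * rmax * (zmax - z0) * (zz - z0));
}

// [[Rcpp::export]]
double cpp_rho_g(double z, double z0, double zmax, double rmax, double seff,
                 double eps = 1.0) {
  return rho_g_at(z, z0, zmax, rmax, seff, eps);
}

// Sample a synapse point inside the lens with planar density proportional
// to rho_m(r): draw r from the full-disk radial marginal by inverse CDF,
// accept with probability (angular extent inside the lens)/(2 pi), then
// draw the angle uniformly within that extent. Returns (r, theta) with
// theta relative to the MC->GC centre line. Falls back to the lens
// midpoint direction if rejection stalls.
static bool sample_lens_point(const McProfile& p, double s, double rm,
                              double rg, double& r_out, double& th_out) {
  double u0 = std::atan(-p.tanm); // angle primitive at r = 0
  double u1 = std::atan(p.k * rm - p.tanm);
  for (int it = 0; it < 20000; ++it) {
    double u = u0 + (u1 - u0) * unif_rand();
    double r = (std::tan(u) + p.tanm) / p.k;
    if (r <= 0 || r > rm) continue;
    // angular half-extent where the annulus at r lies inside the cone circle
    double thmax;
    if (s <= 1e-12) {
      if (r > rg) continue;
      thmax = M_PI;
    } else {
      double c = (r * r + s * s - rg * rg) / (2.0 * r * s);
      if (c >= 1) continue;          // annulus entirely outside
      thmax = (c <= -1) ? M_PI : std::acos(c);
    }
    if (unif_rand() < thmax / M_PI) {
      r_out = r;
      th_out = (2.0 * unif_rand() - 1.0) * thmax;
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_sample_lens(double s, double rm, double rg, double alpha, double k,
                     double m, int n) {
  McProfile p{alpha, k, std::tan(m)};
  NumericVector r(n), th(n);
  for (int i = 0; i < n; ++i) {
    double ri, ti;
    if (!sample_lens_point(p, s, rm, rg, ri, ti)) stop("lens sampling failed");
    r[i] = ri;
    th[i] = ti;
  }
  return List::create(_["r"] = r, _["theta"] = th);
}

// Sequential wiring of a batch of candidate granule cells onto placed
// mitral cells. Uses R's RNG stream (set.seed reproducible). MCs are
// visited in a freshly shuffled order for every GC; the per-pair synapse
// expectation is corrected for the MC's current occupancy; accepted
// connections beyond the GC spine budget are dropped at random with
// occupancy rollback; GCs left with no connection are discarded.
// [[Rcpp::export]]
List cpp_wire_batch(NumericVector mc_x, NumericVector mc_y, NumericVector mc_z,
                    NumericVector mc_rm, NumericVector mc_alpha,
                    NumericVector mc_k, NumericVector mc_m,
                    NumericVector mc_len, IntegerVector n_ps,
                    NumericVector gc_vx, NumericVector gc_vy,
                    NumericVector gc_fx, NumericVector gc_fy,
                    NumericVector gc_rmax, NumericVector gc_z0,
                    NumericVector gc_zmax, NumericVector gc_savail,
                    IntegerVector gc_budget,
                    double q, double v_spine, double eps,
                    int mode, double p_const, int target_keep,
                    double box = 0.0, double tol = 1e-3,
                    bool uniform_loc = false) {
  int nmc = mc_x.size(), ngc = gc_vx.size();
  IntegerVector nps = clone(n_ps); // never mutate the caller's vector
  std::vector<McProfile> prof(nmc);
  for (int i = 0; i < nmc; ++i)
    prof[i] = McProfile{mc_alpha[i], mc_k[i], std::tan(mc_m[i])};

  std::vector<int> syn_mc, syn_gc;
  std::vector<double> syn_x, syn_y, syn_z, syn_d;
  LogicalVector keep(ngc, false);
  std::vector<int> order(nmc);
  std::vector<int> acc;
  int kept = 0, processed = 0;

  for (int g = 0; g < ngc; ++g) {
    if (kept >= target_keep) break;
    processed = g + 1;
    // shuffled MC order (Fisher-Yates on R's RNG)
    for (int i = 0; i < nmc; ++i) order[i] = i;
    for (int i = nmc - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    acc.clear();
    double zspan = gc_zmax[g] - gc_z0[g];
    for (int oi = 0; oi < nmc; ++oi) {
      int i = order[oi];
      double zm = mc_z[i];
      double lam = 0.0;
      double s = 0.0, rg = 0.0;
      if (mode == 1) { // distance-independent control
        if (unif_rand() >= p_const) continue;
        acc.push_back(i);
        nps[i] += 1;
        continue;
      }
      if (zm <= gc_z0[g] || zm > gc_zmax[g]) continue;
      double frac = (zm - gc_z0[g]) / zspan;
      rg = gc_rmax[g] * frac;
      double cx = gc_vx[g] + (gc_fx[g] - gc_vx[g]) * frac;
      double cy = gc_vy[g] + (gc_fy[g] - gc_vy[g]) * frac;
      double dx = mc_x[i] - cx, dy = mc_y[i] - cy;
      if (box > 0) { // periodic wrap on a square of side box
        dx -= box * std::round(dx / box);
        dy -= box * std::round(dy / box);
      }
      s = std::sqrt(dx * dx + dy * dy);
      if (s >= rg + mc_rm[i]) continue;
      double L = overlap_length_core(s, mc_rm[i], rg, prof[i], tol);
      if (L <= 0) continue;
      double veff = q * M_PI * L *
                    (1.0 - (double)nps[i] * v_spine / (q * M_PI * mc_len[i]));
      if (veff < 0) veff = 0;
      lam = rho_g_at(zm, gc_z0[g], gc_zmax[g], gc_rmax[g], gc_savail[g], eps) *
            veff;
      if (lam <= 0) continue;
      if (unif_rand() < 1.0 - std::exp(-lam)) {
        acc.push_back(i);
        nps[i] += 1;
      }
    }
    int nacc = (int)acc.size();
    if (nacc == 0) continue; // disconnected GC: discard, not counted
    int budget = gc_budget[g];
    if (budget < 1) budget = 0;
    if (nacc > budget) {
      // keep a uniformly random subset of size budget, roll back the rest
      for (int i = nacc - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(acc[i], acc[j]);
      }
      for (int i = budget; i < nacc; ++i) nps[acc[i]] -= 1;
      acc.resize(budget);
      nacc = budget;
      if (nacc == 0) continue;
    }
    keep[g] = true;
    ++kept;
    for (int a = 0; a < nacc; ++a) {
      int i = acc[a];
      double zm = mc_z[i];
      double r = 0.0, th = 0.0, phi0 = 0.0;
      if (mode == 1) {
        // no geometry: radial draw over the full disk, uniform angle
        double u0 = std::atan(-prof[i].tanm);
        double u1 = std::atan(prof[i].k * mc_rm[i] - prof[i].tanm);
        double u = u0 + (u1 - u0) * unif_rand();
        r = (std::tan(u) + prof[i].tanm) / prof[i].k;
        if (r < 0) r = 0; if (r > mc_rm[i]) r = mc_rm[i];
        th = TWOPI * unif_rand();
      } else {
        double frac = (zm - gc_z0[g]) / zspan;
        double rg = gc_rmax[g] * frac;
        double cx = gc_vx[g] + (gc_fx[g] - gc_vx[g]) * frac;
        double cy = gc_vy[g] + (gc_fy[g] - gc_vy[g]) * frac;
        double dx = cx - mc_x[i], dy = cy - mc_y[i];
        if (box > 0) {
          dx -= box * std::round(dx / box);
          dy -= box * std::round(dy / box);
        }
        double s = std::sqrt(dx * dx + dy * dy);
        phi0 = std::atan2(dy, dx);
        if (uniform_loc) {
          // uniform over the lens by rejection in the bounding box
          bool ok = false;
          for (int it = 0; it < 20000 && !ok; ++it) {
            double rr = mc_rm[i] * std::sqrt(unif_rand());
            double tt = TWOPI * unif_rand();
            double px = rr * std::cos(tt), py = rr * std::sin(tt);
            double ddx = px - s; // GC centre at (s, 0) in lens frame
            if (ddx * ddx + py * py <= rg * rg) {
              r = rr; th = tt; ok = true;
            }
          }
          if (!ok) { r = 0.5 * s; th = 0; }
        } else if (!sample_lens_point(prof[i], s, mc_rm[i], rg, r, th)) {
          r = std::max(0.0, s - rg * 0.5);
          th = 0.0;
        }
      }
      double ang = phi0 + th;
      syn_mc.push_back(i + 1);
      syn_gc.push_back(g + 1);
      syn_x.push_back(mc_x[i] + r * std::cos(ang));
      syn_y.push_back(mc_y[i] + r * std::sin(ang));
      syn_z.push_back(zm);
      syn_d.push_back(r);
    }
  }
  return List::create(
      _["keep"] = keep, _["processed"] = processed, _["kept"] = kept,
      _["syn_mc"] = wrap(syn_mc), _["syn_gc"] = wrap(syn_gc),
      _["syn_x"] = wrap(syn_x), _["syn_y"] = wrap(syn_y),
      _["syn_z"] = wrap(syn_z), _["syn_dist"] = wrap(syn_d),
      _["n_ps"] = nps);
}
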