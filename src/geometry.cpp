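#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Label codes shared with R/constants.R: 0 background, 1 guidewire, 2 lumen,
// 3 intima, 4 media, 5 lipid, 6 calcium, 7 side branch, 8 plaque rupture,
// 9 thrombus.

static const int LBL_BG = 0, LBL_GW = 1, LBL_LUMEN = 2, LBL_INTIMA = 3,
                 LBL_MEDIA = 4, LBL_LIPID = 5;

// Rasterise one synthetic cross-section from precomputed polar fields
// (dx, dy, r, theta of every pixel about the image centre; theta in degrees
// CCW from +x in [0, 360)).  All radii in pixels.  A lipid pool subtending
// [arc_start, arc_start + arc_extent) sits behind an intima band of radial
// width cap_px; outside the pool the intima band has width intima_px.
// arc_extent == 0 means no lipid anywhere.
// [[Rcpp::export]]
IntegerMatrix cpp_frame_labels(NumericMatrix dx, NumericMatrix dy,
                               NumericMatrix r, NumericMatrix theta,
                               double lumen_r, double cap_px,
                               double arc_start_deg, double arc_extent_deg,
                               double lipid_depth_px, double intima_px,
                               double media_px, bool guidewire) {
  int nr = r.nrow(), nc = r.ncol();
  IntegerMatrix lab(nr, nc);
  double gw_cx = 0.45 * lumen_r, gw_r2 = 0.12 * lumen_r * 0.12 * lumen_r;
  double lip_in = lumen_r + cap_px;
  double lip_out = lip_in + lipid_depth_px;
  double arc_med_out = lip_out + media_px;
  double int_out = lumen_r + intima_px;
  double med_out = int_out + media_px;
  int n = nr * nc;
  for (int i = 0; i < n; ++i) {
    double ri = r[i];
    int v;
    if (ri < lumen_r) {
      v = LBL_LUMEN;
      if (guidewire) {
        double gx = dx[i] - gw_cx, gy = dy[i];
        if (gx * gx + gy * gy < gw_r2) v = LBL_GW;
      }
    } else {
      double rel = theta[i] - arc_start_deg;  // in (-360, 360)
      if (rel < 0) rel += 360.0;
      bool in_arc = arc_extent_deg >= 360.0 ||
                    (arc_extent_deg > 0 && rel < arc_extent_deg);
      if (in_arc) {
        if (ri < lip_in) v = LBL_INTIMA;
        else if (ri < lip_out) v = LBL_LIPID;
        else if (ri < arc_med_out) v = LBL_MEDIA;
        else v = LBL_BG;
      } else {
        if (ri < int_out) v = LBL_INTIMA;
        else if (ri < med_out) v = LBL_MEDIA;
        else v = LBL_BG;
      }
    }
    lab[i] = v;
  }
  return lab;
}

// Mean pixel coordinate of the lumen class (0-based x = column, y = row).
// Returns (x, y, count); count 0 when the frame has no lumen.
// [[Rcpp::export]]
NumericVector cpp_lumen_centroid(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  double sx = 0, sy = 0;
  long cnt = 0;
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      if (lab(y, x) == LBL_LUMEN) { sx += x; sy += y; ++cnt; }
  if (cnt == 0) return NumericVector::create(NA_REAL, NA_REAL, 0);
  return NumericVector::create(sx / cnt, sy / cnt, (double)cnt);
}

// Cast n_bins rays from (cx, cy) with nearest-pixel lookup at radial steps
// of `step` pixels.  Per bin: the lumen boundary radius (last lumen-labelled
// sample of the initial contiguous lumen/guidewire run), the first lipid
// radius anywhere along the ray, the pixel coordinates backing both, and the
// guidewire fraction of all on-grid samples.  When bg_break > 0 a ray is
// terminated after that many consecutive background samples beyond the lumen
// run (the vessel wall is radially contiguous, so nothing can follow).
// Returns n_bins x 7: lumen_r, lipid_r, lum_x, lum_y, lip_x, lip_y, gw_frac.
// [[Rcpp::export]]
NumericMatrix cpp_cast_rays(IntegerMatrix lab, double cx, double cy,
                            int n_bins, double step, int bg_break) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericMatrix out(n_bins, 7);
  double two_pi = 2.0 * M_PI;
  double rmax = std::sqrt((double)nr * nr + (double)nc * nc);
  for (int k = 0; k < n_bins; ++k) {
    double th = (k + 0.5) * two_pi / n_bins;
    double ux = std::cos(th), uy = std::sin(th);
    double lum_r = NA_REAL, lip_r = NA_REAL;
    double lum_x = NA_REAL, lum_y = NA_REAL, lip_x = NA_REAL, lip_y = NA_REAL;
    bool in_run = true;  // still inside initial lumen/guidewire run
    int n_gw = 0, n_tot = 0, bg_streak = 0;
    for (double t = 0.0; t <= rmax; t += step) {
      int px = (int)std::llround(cx + t * ux);
      int py = (int)std::llround(cy + t * uy);
      if (px < 0 || px >= nc || py < 0 || py >= nr) break;
      int v = lab(py, px);
      ++n_tot;
      if (v == LBL_GW) ++n_gw;
      if (in_run) {
        if (v == LBL_LUMEN) {
          lum_r = t; lum_x = px; lum_y = py;
        } else if (v != LBL_GW) {
          in_run = false;
        }
      }
      if (v == LBL_LIPID && ISNA(lip_r)) {
        lip_r = t; lip_x = px; lip_y = py;
      }
      if (bg_break > 0 && !in_run) {
        bg_streak = (v == LBL_BG) ? bg_streak + 1 : 0;
        if (bg_streak >= bg_break) break;
      }
    }
    out(k, 0) = lum_r;
    out(k, 1) = lip_r;
    out(k, 2) = lum_x;
    out(k, 3) = lum_y;
    out(k, 4) = lip_x;
    out(k, 5) = lip_y;
    out(k, 6) = n_tot > 0 ? (double)n_gw / n_tot : 0.0;
  }
  return out;
}
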