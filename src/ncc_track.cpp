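// Reference point tracker inner loop: exhaustive zero-normalized
// cross-correlation search around each point's previous position with
// parabolic sub-pixel refinement. Coordinates are 0-based, x = column,
// y = row, matching the package convention; matrices are H x W.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export(name = ".ncc_step")]]
List ncc_step(NumericMatrix prev, NumericMatrix cur,
              NumericVector px, NumericVector py, LogicalVector vis,
              int patch, int radius, double min_corr) {
  const int H = prev.nrow(), W = prev.ncol();
  const int half = patch / 2;
  const int K = px.size();
  const int side = 2 * radius + 1;
  const int n = patch * patch;

  NumericVector nx(K), ny(K), ncorr(K);
  LogicalVector nvis(K);
  std::vector<double> tpl(n);
  std::vector<double> cgrid(side * side);

  for (int k = 0; k < K; ++k) {
    nx[k] = px[k]; ny[k] = py[k];
    nvis[k] = false; ncorr[k] = NA_REAL;
    if (!vis[k]) continue;

    const int cx = (int) std::lround(px[k]);
    const int cy = (int) std::lround(py[k]);
    if (cx - half < 0 || cx + half >= W || cy - half < 0 || cy + half >= H)
      continue;  // template not fully inside the previous frame

    // zero-mean template from the previous frame
    double tmean = 0.0;
    int idx = 0;
    for (int dy = -half; dy <= half; ++dy)
      for (int dx = -half; dx <= half; ++dx) {
        const double v = prev(cy + dy, cx + dx);
        tpl[idx++] = v; tmean += v;
      }
    tmean /= n;
    double tss = 0.0;
    for (int i = 0; i < n; ++i) { tpl[i] -= tmean; tss += tpl[i] * tpl[i]; }

    double best = -2.0;
    int bdx = 0, bdy = 0;
    long bestd2 = std::numeric_limits<long>::max();
    std::fill(cgrid.begin(), cgrid.end(), NA_REAL);

    for (int dy = -radius; dy <= radius; ++dy) {
      const int ccy = cy + dy;
      if (ccy - half < 0 || ccy + half >= H) continue;
      for (int dx = -radius; dx <= radius; ++dx) {
        const int ccx = cx + dx;
        if (ccx - half < 0 || ccx + half >= W) continue;
        double s = 0.0, ss = 0.0, cross = 0.0;
        int i = 0;
        for (int yy = -half; yy <= half; ++yy)
          for (int xx = -half; xx <= half; ++xx) {
            const double v = cur(ccy + yy, ccx + xx);
            s += v; ss += v * v;
            cross += v * tpl[i++];  // == sum (cur - cmean)(tpl - tmean)
          }
        const double cmean = s / n;
        const double css = ss - n * cmean * cmean;
        double corr;
        if (tss < 1e-12 && css < 1e-12)
          corr = (std::fabs(cmean - tmean) < 1e-6) ? 1.0 : 0.0;
        else if (tss < 1e-12 || css < 1e-12)
          corr = 0.0;
        else
          corr = cross / std::sqrt(tss * css);
        cgrid[(dy + radius) * side + (dx + radius)] = corr;
        // tie-break: smallest displacement, then first in row-major order
        const long d2 = (long) dx * dx + (long) dy * dy;
        if (corr > best + 1e-12 ||
            (std::fabs(corr - best) <= 1e-12 && d2 < bestd2)) {
          best = corr; bdx = dx; bdy = dy; bestd2 = d2;
        }
      }
    }

    if (best < -1.5 || best < min_corr) continue;  // lost

    // 1-D parabolic fits around the integer argmax
    double offx = 0.0, offy = 0.0;
    const int gi = (bdy + radius) * side + (bdx + radius);
    if (bdx > -radius && bdx < radius) {
      const double cm = cgrid[gi - 1], c0 = cgrid[gi], cp = cgrid[gi + 1];
      if (!ISNA(cm) && !ISNA(cp)) {
        const double den = cm - 2.0 * c0 + cp;
        if (den < -1e-12) {
          offx = 0.5 * (cm - cp) / den;
          if (offx > 0.5) offx = 0.5; else if (offx < -0.5) offx = -0.5;
        }
      }
    }
    if (bdy > -radius && bdy < radius) {
      const double cm = cgrid[gi - side], c0 = cgrid[gi], cp = cgrid[gi + side];
      if (!ISNA(cm) && !ISNA(cp)) {
        const double den = cm - 2.0 * c0 + cp;
        if (den < -1e-12) {
          offy = 0.5 * (cm - cp) / den;
          if (offy > 0.5) offy = 0.5; else if (offy < -0.5) offy = -0.5;
        }
      }
    }

    nx[k] = cx + bdx + offx;
    ny[k] = cy + bdy + offy;
    ncorr[k] = best;
    nvis[k] = true;
  }

  return List::create(_["x"] = nx, _["y"] = ny,
                      _["visible"] = nvis, _["corr"] = ncorr);
}
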