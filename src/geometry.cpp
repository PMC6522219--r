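#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Polygon conventions used throughout the package:
//  - vertices in order (either orientation), implicitly closed;
//  - containment by the even-odd rule;
//  - points exactly on an edge count as inside (documented tie-break).

static const double EDGE_EPS = 1e-12;
// squared-cross-product tolerance for "on the edge": a point within
// ~1e-10 length units of an edge counts as on it
static const double ON_EDGE_EPS2 = 1e-20;

static bool on_segment(double px, double py, double ax, double ay,
                       double bx, double by) {
  double cross = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
  double l2 = (bx - ax) * (bx - ax) + (by - ay) * (by - ay);
  if (cross * cross > ON_EDGE_EPS2 * (l2 > 1.0 ? l2 : 1.0)) return false;
  double dot = (px - ax) * (bx - ax) + (py - ay) * (by - ay);
  return dot >= -EDGE_EPS && dot <= l2 + EDGE_EPS;
}

static bool pip_one(double px, double py,
                    const NumericVector& vx, const NumericVector& vy) {
  int n = vx.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (on_segment(px, py, vx[j], vy[j], vx[i], vy[i])) return true;
    bool cond = ((vy[i] > py) != (vy[j] > py));
    if (cond) {
      double xint = (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i];
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export(name = ".pip_cpp")]]
LogicalVector pip_cpp(NumericVector px, NumericVector py,
                      NumericVector vx, NumericVector vy) {
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = pip_one(px[i], py[i], vx, vy);
  return out;
}

// [[Rcpp::export(name = ".polygon_area_cpp")]]
double polygon_area_cpp(NumericVector vx, NumericVector vy) {
  int n = vx.size();
  double s = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    s += vx[j] * vy[i] - vx[i] * vy[j];
  return std::fabs(s) / 2.0;
}

// Do two segments properly intersect (or touch)?
static bool seg_intersect(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy) {
  auto orient = [](double ox, double oy, double px, double py,
                   double qx, double qy) {
    double v = (px - ox) * (qy - oy) - (py - oy) * (qx - ox);
    if (v > EDGE_EPS) return 1;
    if (v < -EDGE_EPS) return -1;
    return 0;
  };
  int o1 = orient(ax, ay, bx, by, cx, cy);
  int o2 = orient(ax, ay, bx, by, dx, dy);
  int o3 = orient(cx, cy, dx, dy, ax, ay);
  int o4 = orient(cx, cy, dx, dy, bx, by);
  if (o1 != o2 && o3 != o4) return true;
  if (o1 == 0 && on_segment(cx, cy, ax, ay, bx, by)) return true;
  if (o2 == 0 && on_segment(dx, dy, ax, ay, bx, by)) return true;
  if (o3 == 0 && on_segment(ax, ay, cx, cy, dx, dy)) return true;
  if (o4 == 0 && on_segment(bx, by, cx, cy, dx, dy)) return true;
  return false;
}

// [[Rcpp::export(name = ".polygons_overlap_cpp")]]
bool polygons_overlap_cpp(NumericVector ax, NumericVector ay,
                          NumericVector bx, NumericVector by) {
  int na = ax.size(), nb = bx.size();
  for (int i = 0; i < na; i++)
    if (pip_one(ax[i], ay[i], bx, by)) return true;
  for (int i = 0; i < nb; i++)
    if (pip_one(bx[i], by[i], ax, ay)) return true;
  for (int i = 0, j = na - 1; i < na; j = i++)
    for (int k = 0, l = nb - 1; k < nb; l = k++)
      if (seg_intersect(ax[j], ay[j], ax[i], ay[i],
                        bx[l], by[l], bx[k], by[k])) return true;
  return false;
}

// Does any edge of polygon A intersect any edge of polygon B?
// [[Rcpp::export(name = ".edges_cross_cpp")]]
bool edges_cross_cpp(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by) {
  int na = ax.size(), nb = bx.size();
  for (int i = 0, j = na - 1; i < na; j = i++)
    for (int k = 0, l = nb - 1; k < nb; l = k++)
      if (seg_intersect(ax[j], ay[j], ax[i], ay[i],
                        bx[l], by[l], bx[k], by[k])) return true;
  return false;
}

// [[Rcpp::export(name = ".polygon_self_intersects_cpp")]]
bool polygon_self_intersects_cpp(NumericVector vx, NumericVector vy) {
  int n = vx.size();
  for (int i = 0; i < n; i++) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; j++) {
      int j2 = (j + 1) % n;
      // skip edges sharing a vertex
      if (j == i || j2 == i || j == i2) continue;
      if (seg_intersect(vx[i], vy[i], vx[i2], vy[i2],
                        vx[j], vy[j], vx[j2], vy[j2])) return true;
    }
  }
  return false;
}

// Fraction of the circle of radius r centred at (cx, cy) whose arc lies
// inside the polygon.  Angles of all circle/edge intersections are
// collected; each resulting arc is classified by its midpoint.
// [[Rcpp::export(name = ".arc_fraction_cpp")]]
double arc_fraction_cpp(double cx, double cy, double r,
                        NumericVector vx, NumericVector vy) {
  int n = vx.size();
  std::vector<double> ang;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double ax = vx[j] - cx, ay = vy[j] - cy;
    double dx = vx[i] - vx[j], dy = vy[i] - vy[j];
    double A = dx * dx + dy * dy;
    double B = 2.0 * (ax * dx + ay * dy);
    double C = ax * ax + ay * ay - r * r;
    if (A <= 0) continue;
    double disc = B * B - 4.0 * A * C;
    if (disc < 0) continue;
    double sq = std::sqrt(disc);
    for (int s = -1; s <= 1; s += 2) {
      double t = (-B + s * sq) / (2.0 * A);
      if (t < 0.0 || t > 1.0) continue;
      double ix = ax + t * dx, iy = ay + t * dy;
      ang.push_back(std::atan2(iy, ix));
    }
  }
  const double TWO_PI = 2.0 * M_PI;
  if (ang.empty()) {
    // circle entirely on one side: classify by a single sample point
    return pip_one(cx + r, cy, vx, vy) ? 1.0 : 0.0;
  }
  std::sort(ang.begin(), ang.end());
  double inside_len = 0.0;
  int m = ang.size();
  for (int i = 0; i < m; i++) {
    double a0 = ang[i];
    double a1 = (i + 1 < m) ? ang[i + 1] : ang[0] + TWO_PI;
    double mid = 0.5 * (a0 + a1);
    double len = a1 - a0;
    if (len <= 0) continue;
    if (pip_one(cx + r * std::cos(mid), cy + r * std::sin(mid), vx, vy))
      inside_len += len;
  }
  return inside_len / TWO_PI;
}

// Edge-corrected neighbourhood density N(r) on a radius grid.
// N(r) = (1/Np) * sum_i sum_{j != i, d <= r} 2*pi*d / C_in(i, d),
// where C_in is the arclength of the circle of radius d centred on i
// inside the region.  Pairs whose circle lies fully outside (C_in = 0)
// are excluded and counted.
// [[Rcpp::export(name = ".ripley_nr_cpp")]]
List ripley_nr_cpp(NumericVector x, NumericVector y,
                   NumericVector vx, NumericVector vy,
                   NumericVector radii) {
  int n = x.size(), nr = radii.size();
  double rmax = radii[nr - 1];
  NumericVector bin(nr);
  int excluded = 0;
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax || d <= 0) continue;
      double frac = arc_fraction_cpp(x[i], y[i], d, vx, vy);
      if (frac <= 0) { excluded++; continue; }
      double w = 1.0 / frac;  // = 2*pi*d / C_in
      int k = std::lower_bound(radii.begin(), radii.end(), d) -
              radii.begin();
      if (k < nr) bin[k] += w;
    }
  }
  NumericVector N(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; k++) { acc += bin[k]; N[k] = acc / n; }
  return List::create(_["N"] = N, _["excluded"] = excluded);
}

// Greedy frame-to-frame linker used by link_localizations(); operates on
// one cell.  Localizations are given sorted by frame.  For each active
// trajectory end we search the next frames (up to 1 + gap_frames ahead)
// for the nearest unclaimed localization within r_max(k); links are
// assigned globally shortest-first per target frame; ends with more than
// max_competitors candidates terminate (ambiguity rule).
// [[Rcpp::export(name = ".link_cpp")]]
IntegerVector link_cpp(NumericVector x, NumericVector y,
                       IntegerVector frame, double d_max, double dt,
                       int gap_frames, int max_competitors) {
  int n = x.size();
  IntegerVector traj(n, NA_INTEGER);
  if (n == 0) return traj;
  int fmax = frame[n - 1];
  // index ranges per frame (frame sorted ascending)
  std::vector<int> start(fmax + 2, -1), cnt(fmax + 2, 0);
  for (int i = 0; i < n; i++) {
    if (start[frame[i]] < 0) start[frame[i]] = i;
    cnt[frame[i]]++;
  }
  int next_id = 1;
  std::vector<int> active;  // localization index of each open end
  for (int f = 0; f <= fmax; f++) {
    // drop ends whose last localization is too old to bridge to frame f
    std::vector<int> kept;
    for (size_t a = 0; a < active.size(); a++)
      if (f - frame[active[a]] <= 1 + gap_frames) kept.push_back(active[a]);
    active = kept;
    if (start[f] < 0) continue;
    int b = start[f], e = start[f] + cnt[f];
    std::vector<bool> claimed(e - b, false);
    // candidate links: (dist, (end index in `active`, loc index))
    std::vector<std::pair<double, std::pair<int, int> > > cand;
    std::vector<int> ncand(active.size(), 0);
    for (size_t a = 0; a < active.size(); a++) {
      int p = active[a];
      int k = f - frame[p];  // lag in frames for this link
      double rmax = std::sqrt(4.0 * d_max * k * dt);
      for (int i = b; i < e; i++) {
        double dx = x[i] - x[p], dy = y[i] - y[p];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= rmax) {
          ncand[a]++;
          cand.push_back(std::make_pair(d, std::make_pair((int)a, i)));
        }
      }
    }
    // shortest links first; an end with more than max_competitors
    // candidates is terminated rather than linked (ambiguity rule)
    std::sort(cand.begin(), cand.end());
    std::vector<bool> end_used(active.size(), false);
    for (size_t c = 0; c < cand.size(); c++) {
      int a = cand[c].second.first, i = cand[c].second.second;
      if (end_used[a] || claimed[i - b]) continue;
      if (ncand[a] > max_competitors) continue;
      traj[i] = traj[active[a]];
      end_used[a] = true;
      claimed[i - b] = true;
      active[a] = i;
    }
    // unclaimed localizations start new trajectories and become ends
    for (int i = b; i < e; i++) {
      if (!claimed[i - b]) {
        traj[i] = next_id++;
        active.push_back(i);
      }
    }
  }
  return traj;
}
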