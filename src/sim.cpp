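// Geometry kernels for the planar fish tank: equal-angle ray casting against
// capsule-shaped fish bodies and arena walls, and sequential collision
// resolution between stadium colliders.
#include <Rcpp.h>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;
static const double INF = R_PosInf;

// smallest positive t with |O + t d| crossing segment [P,Q]; -1 if none
static double ray_segment(double ox, double oy, double dx, double dy,
                          double px, double py, double qx, double qy) {
  double ex = qx - px, ey = qy - py;
  double den = dx * (-ey) - dy * (-ex); // det [d, -(Q-P)]
  if (std::fabs(den) < 1e-14) return -1.0;
  double rx = px - ox, ry = py - oy;
  double t = (rx * (-ey) - ry * (-ex)) / den;
  double s = (dx * ry - dy * rx) / den;
  if (t > 1e-9 && s >= 0.0 && s <= 1.0) return t;
  return -1.0;
}

// smallest positive t with |O + t d - C| = r; -1 if none
static double ray_circle(double ox, double oy, double dx, double dy,
                         double cx, double cy, double r) {
  double fx = ox - cx, fy = oy - cy;
  double b = fx * dx + fy * dy;
  double c = fx * fx + fy * fy - r * r;
  double disc = b * b - c;
  if (disc < 0.0) return -1.0;
  double sq = std::sqrt(disc);
  double t1 = -b - sq, t2 = -b + sq;
  if (t1 > 1e-9) return t1;
  if (t2 > 1e-9) return t2;
  return -1.0;
}

// nearest hit of ray with a capsule (segment AB inflated by r); -1 if none
static double ray_capsule(double ox, double oy, double dx, double dy,
                          double ax, double ay, double bx, double by, double r) {
  double best = INF;
  double t = ray_circle(ox, oy, dx, dy, ax, ay, r);
  if (t > 0 && t < best) best = t;
  t = ray_circle(ox, oy, dx, dy, bx, by, r);
  if (t > 0 && t < best) best = t;
  double ex = bx - ax, ey = by - ay;
  double len = std::sqrt(ex * ex + ey * ey);
  if (len > 1e-12) {
    double nx = -ey / len, ny = ex / len;
    t = ray_segment(ox, oy, dx, dy, ax + r * nx, ay + r * ny, bx + r * nx, by + r * ny);
    if (t > 0 && t < best) best = t;
    t = ray_segment(ox, oy, dx, dy, ax - r * nx, ay - r * ny, bx - r * nx, by - r * ny);
    if (t > 0 && t < best) best = t;
  }
  return (best < INF) ? best : -1.0;
}

// [[Rcpp::export]]
NumericMatrix render_rays_cpp(NumericVector origin, double heading_deg,
                              NumericVector offsets_deg, NumericMatrix caps,
                              int arena_type, double arena_par,
                              NumericVector wall_rgb, int textured,
                              double shade) {
  // caps columns: x, y, heading_deg, half_len, radius, r, g, b
  int nray = offsets_deg.size();
  int ncap = caps.nrow();
  NumericMatrix out(nray, 3);
  double ox = origin[0], oy = origin[1];
  for (int i = 0; i < nray; ++i) {
    double ang = (heading_deg + offsets_deg[i]) * DEG;
    double dx = std::cos(ang), dy = std::sin(ang);
    double best = INF;
    int hit = -1; // capsule index, -2 wall
    for (int j = 0; j < ncap; ++j) {
      double h = caps(j, 2) * DEG, hl = caps(j, 3);
      double ux = std::cos(h), uy = std::sin(h);
      double t = ray_capsule(ox, oy, dx, dy,
                             caps(j, 0) - hl * ux, caps(j, 1) - hl * uy,
                             caps(j, 0) + hl * ux, caps(j, 1) + hl * uy,
                             caps(j, 4));
      if (t > 0 && t < best) { best = t; hit = j; }
    }
    double tw = -1.0;
    if (arena_type == 0) { // square [0,L]^2
      double L = arena_par;
      double tt;
      tt = ray_segment(ox, oy, dx, dy, 0, 0, L, 0); if (tt > 0 && (tw < 0 || tt < tw)) tw = tt;
      tt = ray_segment(ox, oy, dx, dy, L, 0, L, L); if (tt > 0 && (tw < 0 || tt < tw)) tw = tt;
      tt = ray_segment(ox, oy, dx, dy, L, L, 0, L); if (tt > 0 && (tw < 0 || tt < tw)) tw = tt;
      tt = ray_segment(ox, oy, dx, dy, 0, L, 0, 0); if (tt > 0 && (tw < 0 || tt < tw)) tw = tt;
    } else { // circle radius R centered at origin
      tw = ray_circle(ox, oy, dx, dy, 0, 0, arena_par);
    }
    if (tw > 0 && tw < best) { best = tw; hit = -2; }
    double r = 0, g = 0, b = 0;
    if (hit >= 0) {
      r = caps(hit, 5); g = caps(hit, 6); b = caps(hit, 7);
    } else if (hit == -2) {
      r = wall_rgb[0]; g = wall_rgb[1]; b = wall_rgb[2];
      if (textured) {
        double hx = ox + best * dx, hy = oy + best * dy;
        double tex = 0.6 + 0.4 * (0.5 + 0.5 * std::sin(1.7 * hx) * std::sin(2.3 * hy + 0.9));
        r *= tex; g *= tex; b *= tex;
      }
    }
    double att = (best < INF) ? 1.0 / (1.0 + shade * best) : 1.0;
    out(i, 0) = r * att; out(i, 1) = g * att; out(i, 2) = b * att;
  }
  return out;
}

// shortest distance between segments [a1,a2] and [b1,b2]
static double seg_seg_dist(double a1x, double a1y, double a2x, double a2y,
                           double b1x, double b1y, double b2x, double b2y) {
  double ux = a2x - a1x, uy = a2y - a1y;
  double vx = b2x - b1x, vy = b2y - b1y;
  double wx = a1x - b1x, wy = a1y - b1y;
  double a = ux * ux + uy * uy;
  double bb = ux * vx + uy * vy;
  double c = vx * vx + vy * vy;
  double d = ux * wx + uy * wy;
  double e = vx * wx + vy * wy;
  double D = a * c - bb * bb;
  double sc, tc;
  if (D < 1e-12) { sc = 0.0; tc = (c > 1e-12) ? e / c : 0.0; }
  else { sc = (bb * e - c * d) / D; tc = (a * e - bb * d) / D; }
  sc = std::min(1.0, std::max(0.0, sc));
  // recompute tc for clamped sc, then clamp and recompute sc once more
  tc = (c > 1e-12) ? (e + bb * sc) / c : 0.0;
  tc = std::min(1.0, std::max(0.0, tc));
  sc = (a > 1e-12) ? (bb * tc - d) / a : 0.0;
  sc = std::min(1.0, std::max(0.0, sc));
  double px = a1x + sc * ux - (b1x + tc * vx);
  double py = a1y + sc * uy - (b1y + tc * vy);
  return std::sqrt(px * px + py * py);
}

// [[Rcpp::export]]
NumericMatrix capsule_pair_dists_cpp(NumericMatrix pos, NumericVector heading_deg,
                                     double half_len) {
  int n = pos.nrow();
  NumericMatrix out(n, n);
  std::vector<double> ax(n), ay(n), bx(n), by(n);
  for (int i = 0; i < n; ++i) {
    double h = heading_deg[i] * DEG;
    ax[i] = pos(i, 0) - half_len * std::cos(h);
    ay[i] = pos(i, 1) - half_len * std::sin(h);
    bx[i] = pos(i, 0) + half_len * std::cos(h);
    by[i] = pos(i, 1) + half_len * std::sin(h);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dd = seg_seg_dist(ax[i], ay[i], bx[i], by[i], ax[j], ay[j], bx[j], by[j]);
      out(i, j) = dd; out(j, i) = dd;
    }
  return out;
}

static bool capsule_in_arena(double cx, double cy, double h_deg, double half_len,
                             double radius, int arena_type, double arena_par) {
  double h = h_deg * DEG;
  double ex[2] = { cx - half_len * std::cos(h), cx + half_len * std::cos(h) };
  double ey[2] = { cy - half_len * std::sin(h), cy + half_len * std::sin(h) };
  for (int k = 0; k < 2; ++k) {
    if (arena_type == 0) {
      if (ex[k] < radius || ex[k] > arena_par - radius ||
          ey[k] < radius || ey[k] > arena_par - radius) return false;
    } else {
      if (std::sqrt(ex[k] * ex[k] + ey[k] * ey[k]) > arena_par - radius) return false;
    }
  }
  return true;
}

// Sequentially resolve proposed moves: each fish keeps the largest fraction
// of its displacement (found by bisection) that leaves its collider inside
// the arena and at distance >= 2*radius from every other collider. Headings
// are not altered.
// [[Rcpp::export]]
NumericMatrix resolve_collisions_cpp(NumericMatrix old_pos, NumericMatrix new_pos,
                                     NumericVector heading_deg, double half_len,
                                     double radius, int arena_type, double arena_par,
                                     NumericMatrix static_caps) {
  // static_caps columns: x, y, heading_deg, half_len, radius (scenery bodies)
  int n = old_pos.nrow();
  int ns = static_caps.nrow();
  NumericMatrix res(n, 2);
  for (int i = 0; i < n; ++i) { res(i, 0) = old_pos(i, 0); res(i, 1) = old_pos(i, 1); }
  double mind = 2.0 * radius;
  for (int i = 0; i < n; ++i) {
    double x0 = old_pos(i, 0), y0 = old_pos(i, 1);
    double x1 = new_pos(i, 0), y1 = new_pos(i, 1);
    auto feasible = [&](double al) -> bool {
      double cx = x0 + al * (x1 - x0), cy = y0 + al * (y1 - y0);
      if (!capsule_in_arena(cx, cy, heading_deg[i], half_len, radius, arena_type, arena_par))
        return false;
      double h = heading_deg[i] * DEG;
      double a1x = cx - half_len * std::cos(h), a1y = cy - half_len * std::sin(h);
      double a2x = cx + half_len * std::cos(h), a2y = cy + half_len * std::sin(h);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        // resolved position for j < i, old position for j > i
        double jx = (j < i) ? res(j, 0) : old_pos(j, 0);
        double jy = (j < i) ? res(j, 1) : old_pos(j, 1);
        double hj = heading_deg[j] * DEG;
        double b1x = jx - half_len * std::cos(hj), b1y = jy - half_len * std::sin(hj);
        double b2x = jx + half_len * std::cos(hj), b2y = jy + half_len * std::sin(hj);
        if (seg_seg_dist(a1x, a1y, a2x, a2y, b1x, b1y, b2x, b2y) < mind - 1e-9)
          return false;
      }
      for (int j = 0; j < ns; ++j) {
        double hj = static_caps(j, 2) * DEG, hlj = static_caps(j, 3);
        double b1x = static_caps(j, 0) - hlj * std::cos(hj);
        double b1y = static_caps(j, 1) - hlj * std::sin(hj);
        double b2x = static_caps(j, 0) + hlj * std::cos(hj);
        double b2y = static_caps(j, 1) + hlj * std::sin(hj);
        if (seg_seg_dist(a1x, a1y, a2x, a2y, b1x, b1y, b2x, b2y) <
            radius + static_caps(j, 4) - 1e-9)
          return false;
      }
      return true;
    };
    double alpha;
    if (feasible(1.0)) {
      alpha = 1.0;
    } else if (!feasible(0.0)) {
      alpha = 0.0; // previous state already tight; stay put
    } else {
      double lo = 0.0, hi = 1.0;
      for (int it = 0; it < 24; ++it) {
        double mid = 0.5 * (lo + hi);
        if (feasible(mid)) lo = mid; else hi = mid;
      }
      alpha = lo;
    }
    res(i, 0) = x0 + alpha * (x1 - x0);
    res(i, 1) = y0 + alpha * (y1 - y0);
  }
  // relaxation pass: separate any pre-existing overlaps (e.g. injected
  // states) by pushing centers apart along their connecting line
  for (int pass = 0; pass < 12; ++pass) {
    bool moved = false;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double hi = heading_deg[i] * DEG, hj = heading_deg[j] * DEG;
        double a1x = res(i, 0) - half_len * std::cos(hi);
        double a1y = res(i, 1) - half_len * std::sin(hi);
        double a2x = res(i, 0) + half_len * std::cos(hi);
        double a2y = res(i, 1) + half_len * std::sin(hi);
        double b1x = res(j, 0) - half_len * std::cos(hj);
        double b1y = res(j, 1) - half_len * std::sin(hj);
        double b2x = res(j, 0) + half_len * std::cos(hj);
        double b2y = res(j, 1) + half_len * std::sin(hj);
        double dd = seg_seg_dist(a1x, a1y, a2x, a2y, b1x, b1y, b2x, b2y);
        if (dd < mind - 1e-9) {
          double cx = res(j, 0) - res(i, 0), cy = res(j, 1) - res(i, 1);
          double cl = std::sqrt(cx * cx + cy * cy);
          if (cl < 1e-9) { cx = 1.0; cy = 0.0; cl = 1.0; }
          double push = 0.5 * (mind - dd) / cl + 1e-9;
          double nix = res(i, 0) - push * cx, niy = res(i, 1) - push * cy;
          double njx = res(j, 0) + push * cx, njy = res(j, 1) + push * cy;
          if (capsule_in_arena(nix, niy, heading_deg[i], half_len, radius,
                               arena_type, arena_par)) {
            res(i, 0) = nix; res(i, 1) = niy;
          }
          if (capsule_in_arena(njx, njy, heading_deg[j], half_len, radius,
                               arena_type, arena_par)) {
            res(j, 0) = njx; res(j, 1) = njy;
          }
          moved = true;
        }
      }
    if (!moved) break;
  }
  return res;
}
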