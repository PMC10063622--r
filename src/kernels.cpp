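#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// Raster convention used throughout: R matrices indexed (row, col) 1-based;
// the continuous pixel coordinate of cell (i, j) is (x, y) = (j - 0.5, i - 0.5),
// i.e. 0-based pixel centres at half-integers. Polygons and points passed from
// R use this continuous (x = column, y = row) system.

// Scanline even-odd fill of one or more closed polygons.
// polys: list of n x 2 matrices (x, y) in continuous pixel coordinates.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_polygons(int nrow, int ncol, List polys) {
  LogicalMatrix out(nrow, ncol);
  std::vector<double> xs;
  for (int r = 0; r < nrow; ++r) {
    double y = r + 0.5;
    xs.clear();
    for (int p = 0; p < polys.size(); ++p) {
      NumericMatrix pm = polys[p];
      int n = pm.nrow();
      for (int k = 0; k < n; ++k) {
        double x1 = pm(k, 0), y1 = pm(k, 1);
        double x2 = pm((k + 1) % n, 0), y2 = pm((k + 1) % n, 1);
        if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
          double t = (y - y1) / (y2 - y1);
          xs.push_back(x1 + t * (x2 - x1));
        }
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k] - 0.5);
      int c1 = (int)std::floor(xs[k + 1] - 0.5);
      if (c0 < 0) c0 = 0;
      if (c1 > ncol - 1) c1 = ncol - 1;
      for (int c = c0; c <= c1; ++c) out(r, c) = true;
    }
  }
  return out;
}

// 8-connected component labelling (two-pass BFS flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Moore-neighbour contour tracing; returns chain-code perimeter with
// unit steps for 4-neighbour moves and sqrt(2) for diagonal moves.
static double trace_perimeter(const IntegerMatrix &lab, int label,
                              int si, int sj) {
  const int di8[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dj8[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  int nr = lab.nrow(), nc = lab.ncol();
  // single pixel?
  bool alone = true;
  for (int k = 0; k < 8; ++k) {
    int ii = si + di8[k], jj = sj + dj8[k];
    if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && lab(ii, jj) == label)
      alone = false;
  }
  if (alone) return 4.0;  // crack perimeter of an isolated pixel
  double per = 0.0;
  int ci = si, cj = sj;
  int dir = 4;  // came from the left scan: backtrack direction west
  int firsti = -1, firstj = -1, firstdir = -1;
  int guard = 8 * nr * nc;
  while (guard-- > 0) {
    int k;
    bool moved = false;
    for (k = 0; k < 8; ++k) {
      int d = (dir + 1 + k) % 8;  // clockwise from backtrack
      int ii = ci + di8[d], jj = cj + dj8[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (lab(ii, jj) == label) {
        per += (d % 2 == 0) ? 1.0 : M_SQRT2;
        ci = ii;
        cj = jj;
        dir = (d + 4) % 8;  // new backtrack = opposite of move
        moved = true;
        break;
      }
    }
    if (!moved) break;
    if (firsti < 0) {
      firsti = ci;
      firstj = cj;
      firstdir = dir;
    } else if (ci == si && cj == sj) {
      // Jacob's stopping criterion: re-entered start; require next move
      // to repeat the first move.
      int d0 = -1;
      for (int k2 = 0; k2 < 8; ++k2) {
        int d = (dir + 1 + k2) % 8;
        int ii = ci + di8[d], jj = cj + dj8[d];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (lab(ii, jj) == label) {
          d0 = d;
          break;
        }
      }
      if (d0 >= 0) {
        int ii = ci + di8[d0], jj = cj + dj8[d0];
        if (ii == firsti && jj == firstj && firstdir >= 0) break;
      } else {
        break;
      }
    }
  }
  return per;
}

static double cross2(double ox, double oy, double ax, double ay, double bx,
                     double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static long long igcd(long long a, long long b) {
  a = a < 0 ? -a : a;
  b = b < 0 ? -b : b;
  while (b) {
    long long t = a % b;
    a = b;
    b = t;
  }
  return a;
}

// Per-component statistics: area (px), centroid (continuous px coords),
// chain-code perimeter, number of lattice pixels inside the convex hull
// (via Pick's theorem), and second central moments.
// Columns: area, cx, cy, perimeter, hull_px, mxx, myy, mxy
// [[Rcpp::export]]
NumericMatrix cpp_blob_stats(IntegerMatrix lab) {
  int n = as<int>(lab.attr("n"));
  int nr = lab.nrow(), nc = lab.ncol();
  NumericMatrix out(n, 8);
  if (n == 0) return out;
  std::vector<std::vector<std::pair<int, int> > > px(n);
  std::vector<int> firsti(n, -1), firstj(n, -1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l > 0) {
        px[l - 1].push_back(std::make_pair(i, j));
        if (firsti[l - 1] < 0) {
          firsti[l - 1] = i;
          firstj[l - 1] = j;
        }
      }
    }
  }
  // first pixel encountered scanning column-major is not guaranteed to be a
  // contour start for Moore tracing with west backtrack; rescan row-major.
  for (int l = 0; l < n; ++l) {
    int bi = -1, bj = -1;
    for (size_t k = 0; k < px[l].size(); ++k) {
      int i = px[l][k].first, j = px[l][k].second;
      if (bi < 0 || i < bi || (i == bi && j < bj)) {
        bi = i;
        bj = j;
      }
    }
    double area = (double)px[l].size();
    double sx = 0, sy = 0;
    for (size_t k = 0; k < px[l].size(); ++k) {
      sx += px[l][k].second + 0.5;
      sy += px[l][k].first + 0.5;
    }
    double cx = sx / area, cy = sy / area;
    double mxx = 0, myy = 0, mxy = 0;
    for (size_t k = 0; k < px[l].size(); ++k) {
      double dx = (px[l][k].second + 0.5) - cx;
      double dy = (px[l][k].first + 0.5) - cy;
      mxx += dx * dx;
      myy += dy * dy;
      mxy += dx * dy;
    }
    mxx = mxx / area + 1.0 / 12.0;  // pixel extent correction
    myy = myy / area + 1.0 / 12.0;
    mxy /= area;
    double per = trace_perimeter(lab, l + 1, bi, bj);
    // convex hull (monotone chain) on integer pixel coordinates
    std::vector<std::pair<int, int> > pts = px[l];
    std::sort(pts.begin(), pts.end());
    pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
    double hull_px = area;
    if (pts.size() >= 3) {
      size_t m = pts.size();
      std::vector<std::pair<int, int> > hull(2 * m);
      size_t k = 0;
      for (size_t ii = 0; ii < m; ++ii) {
        while (k >= 2 && cross2(hull[k - 2].first, hull[k - 2].second,
                                hull[k - 1].first, hull[k - 1].second,
                                pts[ii].first, pts[ii].second) <= 0)
          --k;
        hull[k++] = pts[ii];
      }
      size_t lower = k + 1;
      for (size_t ii = m - 1; ii-- > 0;) {
        while (k >= lower && cross2(hull[k - 2].first, hull[k - 2].second,
                                    hull[k - 1].first, hull[k - 1].second,
                                    pts[ii].first, pts[ii].second) <= 0)
          --k;
        hull[k++] = pts[ii];
      }
      hull.resize(k - 1);
      // lattice points in hull via Pick: I + B = A + B/2 + 1
      double A2 = 0;
      long long B = 0;
      size_t h = hull.size();
      for (size_t ii = 0; ii < h; ++ii) {
        size_t jj = (ii + 1) % h;
        A2 += (double)hull[ii].first * hull[jj].second -
              (double)hull[jj].first * hull[ii].second;
        B += igcd(hull[jj].first - hull[ii].first,
                  hull[jj].second - hull[ii].second);
      }
      double A = std::fabs(A2) / 2.0;
      hull_px = A + B / 2.0 + 1.0;
    }
    out(l, 0) = area;
    out(l, 1) = cx;
    out(l, 2) = cy;
    out(l, 3) = per;
    out(l, 4) = hull_px;
    out(l, 5) = mxx;
    out(l, 6) = myy;
    out(l, 7) = mxy;
  }
  colnames(out) = CharacterVector::create("area", "cx", "cy", "perimeter",
                                          "hull_px", "mxx", "myy", "mxy");
  return out;
}

// Per-pixel median across a list of equally sized matrices (blocked for
// cache locality).
// [[Rcpp::export]]
NumericMatrix cpp_stack_median(List frames) {
  int nf = frames.size();
  NumericMatrix f0 = frames[0];
  int nr = f0.nrow(), nc = f0.ncol();
  NumericMatrix out(nr, nc);
  std::vector<const double *> ptr(nf);
  for (int k = 0; k < nf; ++k) {
    NumericMatrix fk = frames[k];
    if (fk.nrow() != nr || fk.ncol() != nc)
      stop("frame dimensions differ within the stack");
    ptr[k] = REAL(fk);
  }
  const R_xlen_t B = 4096;
  R_xlen_t npx = (R_xlen_t)nr * nc;
  std::vector<double> block((size_t)nf * B);
  std::vector<double> buf(nf);
  double *o = REAL(out);
  int mid = nf / 2;
  for (R_xlen_t p0 = 0; p0 < npx; p0 += B) {
    R_xlen_t bn = std::min(B, npx - p0);
    for (int k = 0; k < nf; ++k) {
      const double *src = ptr[k] + p0;
      double *dst = &block[(size_t)k * bn];
      std::copy(src, src + bn, dst);
    }
    for (R_xlen_t q = 0; q < bn; ++q) {
      for (int k = 0; k < nf; ++k) buf[k] = block[(size_t)k * bn + q];
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (nf % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1,
                         buf.begin() + mid);
        m = (m + buf[mid - 1]) / 2.0;
      }
      o[p0 + q] = m;
    }
  }
  return out;
}

// Additive Gaussian noise (R RNG), rounding and clamping to 0..255.
// [[Rcpp::export]]
NumericMatrix cpp_finalize_frame(NumericMatrix img, double noise_sd) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  R_xlen_t n = (R_xlen_t)nr * nc;
  const double *src = REAL(img);
  double *dst = REAL(out);
  if (noise_sd > 0) {
    for (R_xlen_t p = 0; p < n; ++p) {
      double v = std::nearbyint(src[p] + norm_rand() * noise_sd);
      dst[p] = v < 0 ? 0 : (v > 255 ? 255 : v);
    }
  } else {
    for (R_xlen_t p = 0; p < n; ++p) {
      double v = std::nearbyint(src[p]);
      dst[p] = v < 0 ? 0 : (v > 255 ? 255 : v);
    }
  }
  return out;
}

static int nb_count(const LogicalMatrix &m, int i, int j) {
  int nr = m.nrow(), nc = m.ncol(), cnt = 0;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      int ii = i + di, jj = j + dj;
      if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && m(ii, jj)) ++cnt;
    }
  return cnt;
}

// number of 8-connected components among the foreground neighbours of (i, j):
// 1 = curve endpoint, 2 = curve interior, >= 3 = true junction
static int nb_components(const LogicalMatrix &m, int i, int j) {
  static const int ri[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
  static const int rj[8] = {-1, 0, 1, 1, 1, 0, -1, -1};
  int nr = m.nrow(), nc = m.ncol();
  bool fg[8];
  for (int k = 0; k < 8; ++k) {
    int ii = i + ri[k], jj = j + rj[k];
    fg[k] = ii >= 0 && ii < nr && jj >= 0 && jj < nc && m(ii, jj);
  }
  int comp[8];
  for (int k = 0; k < 8; ++k) comp[k] = k;
  for (int a = 0; a < 8; ++a) {
    if (!fg[a]) continue;
    for (int b = a + 1; b < 8; ++b) {
      if (!fg[b]) continue;
      if (std::abs(ri[a] - ri[b]) <= 1 && std::abs(rj[a] - rj[b]) <= 1) {
        int ca = comp[a], cb = comp[b];
        if (ca != cb)
          for (int k = 0; k < 8; ++k)
            if (comp[k] == cb) comp[k] = ca;
      }
    }
  }
  int labels[8], nl = 0;
  for (int k = 0; k < 8; ++k) {
    if (!fg[k]) continue;
    bool found = false;
    for (int u = 0; u < nl; ++u)
      if (labels[u] == comp[k]) found = true;
    if (!found) labels[nl++] = comp[k];
  }
  return nl;
}

// classification of every skeleton pixel: 0 background, otherwise the
// number of neighbour components (1 endpoint, 2 interior, 3+ junction)
// [[Rcpp::export]]
IntegerMatrix cpp_pixel_class(LogicalMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (skel(i, j)) out(i, j) = nb_components(skel, i, j);
  return out;
}

// Zhang-Suen thinning to a 1-px-wide 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (!img(i, j)) continue;
          int p2 = img(i - 1, j), p3 = img(i - 1, j + 1), p4 = img(i, j + 1),
              p5 = img(i + 1, j + 1), p6 = img(i + 1, j), p7 = img(i + 1, j - 1),
              p8 = img(i, j - 1), p9 = img(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < del.size(); ++k)
        img(del[k].first, del[k].second) = false;
      if (!del.empty()) changed = true;
    }
  }
  // staircase cleanup: iteratively remove redundant pixels, i.e. simple
  // points (single 8-connected foreground component among the neighbours,
  // at least one 4-connected background neighbour) with 3+ neighbours.
  // Endpoints (B=1), curve interiors (B=2) and true junctions (several
  // neighbour components) are untouched.
  const int ri[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
  const int rj[8] = {-1, 0, 1, 1, 1, 0, -1, -1};
  changed = true;
  while (changed) {
    changed = false;
    for (int j = 1; j < nc - 1; ++j) {
      for (int i = 1; i < nr - 1; ++i) {
        if (!img(i, j)) continue;
        bool fg[8];
        int B = 0;
        for (int k = 0; k < 8; ++k) {
          fg[k] = img(i + ri[k], j + rj[k]);
          B += fg[k];
        }
        if (B < 2) continue;
        if (img(i - 1, j) && img(i + 1, j) && img(i, j - 1) && img(i, j + 1))
          continue;  // removal would open a hole
        // count 8-connected components among the foreground neighbours
        int comp[8];
        for (int k = 0; k < 8; ++k) comp[k] = k;
        for (int a = 0; a < 8; ++a) {
          if (!fg[a]) continue;
          for (int b = a + 1; b < 8; ++b) {
            if (!fg[b]) continue;
            if (std::abs(ri[a] - ri[b]) <= 1 && std::abs(rj[a] - rj[b]) <= 1) {
              int ca = comp[a], cb = comp[b];
              for (int k = 0; k < 8; ++k)
                if (comp[k] == cb) comp[k] = ca;
            }
          }
        }
        int ncomp = 0;
        for (int k = 0; k < 8; ++k)
          if (fg[k] && comp[k] == k) ++ncomp;
        // (representative = smallest index in component; count roots)
        if (ncomp != 1) {
          // roots may not be minimal; recount distinct labels properly
          int labels[8], nl = 0;
          for (int k = 0; k < 8; ++k) {
            if (!fg[k]) continue;
            bool found = false;
            for (int u = 0; u < nl; ++u)
              if (labels[u] == comp[k]) found = true;
            if (!found) labels[nl++] = comp[k];
          }
          ncomp = nl;
        }
        if (ncomp == 1) {
          img(i, j) = false;
          changed = true;
        }
      }
    }
  }
  return img;
}

// Remove spur branches shorter than min_len pixels, iteratively, until the
// skeleton is a simple open curve (or no more short spurs exist).
// [[Rcpp::export]]
LogicalMatrix cpp_prune_spurs(LogicalMatrix skel, int min_len) {
  int nr = skel.nrow(), nc = skel.ncol();
  LogicalMatrix img = clone(skel);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!img(i, j) || nb_components(img, i, j) != 1 ||
            nb_count(img, i, j) == 0)
          continue;
        // walk from this endpoint
        std::vector<std::pair<int, int> > walk;
        int ci = i, cj = j, pi = -2, pj = -2;
        bool hit_junction = false;
        while ((int)walk.size() < min_len) {
          walk.push_back(std::make_pair(ci, cj));
          int deg = nb_components(img, ci, cj);
          if (deg > 2 && walk.size() > 1) {
            hit_junction = true;
            walk.pop_back();  // keep the junction pixel
            break;
          }
          int ni = -1, nj = -1;
          for (int di = -1; di <= 1 && ni < 0; ++di)
            for (int dj = -1; dj <= 1; ++dj) {
              if (di == 0 && dj == 0) continue;
              int ii = ci + di, jj = cj + dj;
              if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
              if (img(ii, jj) && !(ii == pi && jj == pj)) {
                bool seen = false;
                for (size_t w = 0; w < walk.size(); ++w)
                  if (walk[w].first == ii && walk[w].second == jj) seen = true;
                if (!seen) {
                  ni = ii;
                  nj = jj;
                  break;
                }
              }
            }
          if (ni < 0) break;  // other endpoint: whole curve shorter than min_len
          pi = ci;
          pj = cj;
          ci = ni;
          cj = nj;
        }
        if (hit_junction && (int)walk.size() < min_len) {
          for (size_t w = 0; w < walk.size(); ++w)
            img(walk[w].first, walk[w].second) = false;
          changed = true;
        }
      }
    }
  }
  return img;
}

// Walk a simple open 8-connected curve from one endpoint, returning the
// ordered 1-based (row, col) indices.
// [[Rcpp::export]]
IntegerMatrix cpp_walk_curve(LogicalMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  int si = -1, sj = -1, npix = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (skel(i, j)) {
        ++npix;
        if (si < 0 && nb_count(skel, i, j) >= 1 &&
            nb_components(skel, i, j) == 1) {
          si = i;
          sj = j;
        }
      }
  if (si < 0) stop("skeleton has no endpoint (empty or closed curve)");
  LogicalMatrix seen(nr, nc);
  IntegerMatrix out(npix, 2);
  int ci = si, cj = sj;
  int k = 0;
  while (true) {
    seen(ci, cj) = true;
    out(k, 0) = ci + 1;
    out(k, 1) = cj + 1;
    ++k;
    // prefer 4-neighbours so diagonal short-cuts do not skip pixels
    const int di8[8] = {0, 0, -1, 1, -1, -1, 1, 1};
    const int dj8[8] = {-1, 1, 0, 0, -1, 1, -1, 1};
    int ni = -1, nj = -1;
    for (int d = 0; d < 8; ++d) {
      int ii = ci + di8[d], jj = cj + dj8[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (skel(ii, jj) && !seen(ii, jj)) {
        ni = ii;
        nj = jj;
        break;
      }
    }
    if (ni < 0) break;
    ci = ni;
    cj = nj;
  }
  if (k < npix)
    warning("curve walk visited %d of %d skeleton pixels; skeleton may "
            "not be a simple curve", k, npix);
  return out(Range(0, k - 1), Range(0, 1));
}

// Nearest reference point for each query point (bucketed uniform grid).
// pts, ref: n x 2 (x, y). Returns n x 2 matrix: 1-based ref index, distance.
// [[Rcpp::export]]
NumericMatrix cpp_nearest_point(NumericMatrix pts, NumericMatrix ref,
                                double cell) {
  int n = pts.nrow(), m = ref.nrow();
  if (m == 0) stop("empty reference set");
  double xmin = ref(0, 0), ymin = ref(0, 1), xmax = xmin, ymax = ymin;
  for (int k = 1; k < m; ++k) {
    xmin = std::min(xmin, ref(k, 0));
    xmax = std::max(xmax, ref(k, 0));
    ymin = std::min(ymin, ref(k, 1));
    ymax = std::max(ymax, ref(k, 1));
  }
  int gx = std::max(1, (int)((xmax - xmin) / cell) + 1);
  int gy = std::max(1, (int)((ymax - ymin) / cell) + 1);
  std::vector<std::vector<int> > bucket((size_t)gx * gy);
  for (int k = 0; k < m; ++k) {
    int bx = std::min(gx - 1, std::max(0, (int)((ref(k, 0) - xmin) / cell)));
    int by = std::min(gy - 1, std::max(0, (int)((ref(k, 1) - ymin) / cell)));
    bucket[(size_t)by * gx + bx].push_back(k);
  }
  NumericMatrix out(n, 2);
  for (int q = 0; q < n; ++q) {
    double px = pts(q, 0), py = pts(q, 1);
    int bx = std::min(gx - 1, std::max(0, (int)((px - xmin) / cell)));
    int by = std::min(gy - 1, std::max(0, (int)((py - ymin) / cell)));
    int best = -1;
    double bestd2 = R_PosInf;
    for (int ring = 0; ring < std::max(gx, gy) + 1; ++ring) {
      bool any = false;
      for (int dy = -ring; dy <= ring; ++dy) {
        for (int dx = -ring; dx <= ring; ++dx) {
          if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
          int cx = bx + dx, cy = by + dy;
          if (cx < 0 || cx >= gx || cy < 0 || cy >= gy) continue;
          any = true;
          const std::vector<int> &b = bucket[(size_t)cy * gx + cx];
          for (size_t u = 0; u < b.size(); ++u) {
            double ddx = ref(b[u], 0) - px, ddy = ref(b[u], 1) - py;
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < bestd2) {
              bestd2 = d2;
              best = b[u];
            }
          }
        }
      }
      // safe stop: nearest possible point in a later ring is at least
      // (ring - 1) * cell away from the query
      if (best >= 0 && std::sqrt(bestd2) <= (ring)*cell) break;
      if (!any && ring > std::max(gx, gy)) break;
    }
    out(q, 0) = best + 1;
    out(q, 1) = std::sqrt(bestd2);
  }
  return out;
}

// Subtract dark elliptical blobs from a frame (in place on a copy).
// blobs: n x 3 (cx, cy, angle); half axes a (major), b (minor); depth in
// grey levels. Soft 30 % fall-off rim beyond the nominal ellipse edge.
// [[Rcpp::export]]
NumericMatrix cpp_paint_blobs(NumericMatrix frame, NumericMatrix blobs,
                              double a, double b, double depth) {
  NumericMatrix img = clone(frame);
  int nr = img.nrow(), nc = img.ncol();
  int n = blobs.nrow();
  double rmax = std::max(a, b) * 1.3 + 1.0;
  for (int k = 0; k < n; ++k) {
    double cx = blobs(k, 0), cy = blobs(k, 1), th = blobs(k, 2);
    double ct = std::cos(th), st = std::sin(th);
    int i0 = std::max(0, (int)std::floor(cy - rmax));
    int i1 = std::min(nr - 1, (int)std::ceil(cy + rmax));
    int j0 = std::max(0, (int)std::floor(cx - rmax));
    int j1 = std::min(nc - 1, (int)std::ceil(cx + rmax));
    for (int i = i0; i <= i1; ++i) {
      for (int j = j0; j <= j1; ++j) {
        double dx = (j + 0.5) - cx, dy = (i + 0.5) - cy;
        double u = dx * ct + dy * st, v = -dx * st + dy * ct;
        double d = std::sqrt((u * u) / (a * a) + (v * v) / (b * b));
        double w = d <= 1.0 ? 1.0 : (d >= 1.3 ? 0.0 : (1.3 - d) / 0.3);
        if (w > 0) img(i, j) = std::max(0.0, img(i, j) - depth * w);
      }
    }
  }
  return img;
}
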