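#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// --- union-find helpers for 8-connected labeling ---------------------------

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Label 8-connected foreground components of a 0/1 matrix.
// Returns an integer matrix of labels (0 = background, 1..K = components).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 1;
  // column-major scan; previously visited 8-neighbours:
  // (i-1,j), (i-1,j-1), (i,j-1), (i+1,j-1)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0) continue;
      int best = 0;
      int cand[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      for (int k = 0; k < 4; ++k) {
        int ci = cand[k][0], cj = cand[k][1];
        if (ci < 0 || cj < 0 || ci >= nr) continue;
        int l = lab(ci, cj);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
      }
    }
  }
  // flatten and compact labels
  std::vector<int> newlab(next, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = uf_find(parent, lab(i, j));
        if (newlab[r] == 0) newlab[r] = ++k;
        lab(i, j) = newlab[r];
      }
  return lab;
}

// Fill holes: background pixels (0) not 4-connected to the image border
// become foreground. Flood-fills zeros from the border.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> stack;
  stack.reserve(2 * (nr + nc));
  // seed with all border background pixels
  for (int i = 0; i < nr; ++i) {
    if (mask(i, 0) == 0) { outside[i] = 1; stack.push_back(i); }
    int idx = i + (nc - 1) * nr;
    if (mask(i, nc - 1) == 0 && !outside[idx]) { outside[idx] = 1; stack.push_back(idx); }
  }
  for (int j = 0; j < nc; ++j) {
    int idx = j * nr;
    if (mask(0, j) == 0 && !outside[idx]) { outside[idx] = 1; stack.push_back(idx); }
    idx = (nr - 1) + j * nr;
    if (mask(nr - 1, j) == 0 && !outside[idx]) { outside[idx] = 1; stack.push_back(idx); }
  }
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int i = idx % nr, j = idx / nr;
    int nbr[4][2] = {{i - 1, j}, {i + 1, j}, {i, j - 1}, {i, j + 1}};
    for (int k = 0; k < 4; ++k) {
      int ci = nbr[k][0], cj = nbr[k][1];
      if (ci < 0 || cj < 0 || ci >= nr || cj >= nc) continue;
      int cidx = ci + cj * nr;
      if (!outside[cidx] && mask(ci, cj) == 0) {
        outside[cidx] = 1;
        stack.push_back(cidx);
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = (mask(i, j) != 0 || !outside[i + j * nr]) ? 1 : 0;
  return out;
}

// Sliding-window Shannon entropy (bits, 256-bin histogram of 8-bit values),
// square window of the given size, reflect padding. With stride > 1 the
// entropy is computed exactly but only at every stride-th centre; the
// returned matrix is then decimated (callers upsample). Values are clamped
// to [0,255] and truncated to integers before binning.
// [[Rcpp::export]]
NumericMatrix cpp_entropy_filter(NumericMatrix img, int window, int stride = 1) {
  int nr = img.nrow(), nc = img.ncol(), w = window;
  int lo = w / 2, hi = w - 1 - lo;
  int pr = nr + lo + hi, pc = nc + lo + hi;
  // reflect-padded, quantized copy (symmetric reflection, edge included)
  std::vector<int> pad((size_t)pr * pc);
  for (int j = 0; j < pc; ++j) {
    int sj = j - lo;
    if (sj < 0) sj = -sj - 1;
    if (sj >= nc) sj = 2 * nc - 1 - sj;
    if (sj < 0) sj = 0; else if (sj >= nc) sj = nc - 1;
    for (int i = 0; i < pr; ++i) {
      int si = i - lo;
      if (si < 0) si = -si - 1;
      if (si >= nr) si = 2 * nr - 1 - si;
      if (si < 0) si = 0; else if (si >= nr) si = nr - 1;
      double v = img(si, sj);
      int q = (int)v;
      if (q < 0) q = 0; else if (q > 255) q = 255;
      pad[(size_t)i + (size_t)j * pr] = q;
    }
  }
  long N = (long)w * w;
  // lookup table for n*log2(n)
  std::vector<double> nlog(N + 1, 0.0);
  for (long n = 1; n <= N; ++n) nlog[n] = (double)n * std::log2((double)n);
  double log2N = std::log2((double)N);

  if (stride < 1) stride = 1;
  int onr = 1 + (nr - 1) / stride, onc = 1 + (nc - 1) / stride;
  NumericMatrix out(onr, onc);
  std::vector<int> hist0(256, 0), hist(256);
  double S0 = 0.0;

  for (int oi = 0; oi < onr; ++oi) {
    int i = oi * stride;
    if (oi == 0) {
      std::fill(hist0.begin(), hist0.end(), 0);
      for (int jj = 0; jj < w; ++jj)
        for (int ii = 0; ii < w; ++ii)
          hist0[pad[(size_t)ii + (size_t)jj * pr]]++;
      S0 = 0.0;
      for (int b = 0; b < 256; ++b) S0 += nlog[hist0[b]];
    } else {
      // shift window `stride` rows down at column 0
      for (int r = i - stride; r < i; ++r) {
        for (int jj = 0; jj < w; ++jj) {
          int rem = pad[(size_t)r + (size_t)jj * pr];
          int add = pad[(size_t)(r + w) + (size_t)jj * pr];
          if (rem != add) {
            S0 -= nlog[hist0[rem]] + nlog[hist0[add]];
            hist0[rem]--; hist0[add]++;
            S0 += nlog[hist0[rem]] + nlog[hist0[add]];
          }
        }
      }
    }
    std::copy(hist0.begin(), hist0.end(), hist.begin());
    double S = S0;
    out(oi, 0) = log2N - S / (double)N;
    for (int oj = 1; oj < onc; ++oj) {
      int j = oj * stride;
      for (int c = j - stride; c < j; ++c) {
        for (int ii = 0; ii < w; ++ii) {
          int rem = pad[(size_t)(i + ii) + (size_t)c * pr];
          int add = pad[(size_t)(i + ii) + (size_t)(c + w) * pr];
          if (rem != add) {
            S -= nlog[hist[rem]] + nlog[hist[add]];
            hist[rem]--; hist[add]++;
            S += nlog[hist[rem]] + nlog[hist[add]];
          }
        }
      }
      out(oi, oj) = log2N - S / (double)N;
    }
  }
  return out;
}

// Zhang–Suen morphological thinning of a 0/1 mask to 1-px-wide curves.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m = clone(mask);
  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (m(i, j) == 0) continue;
          // neighbours P2..P9 clockwise from north; outside = 0
          auto at = [&](int r, int c) -> int {
            return (r < 0 || c < 0 || r >= nr || c >= nc) ? 0 : m(r, c);
          };
          int p[8] = {at(i - 1, j),     at(i - 1, j + 1), at(i, j + 1),
                      at(i + 1, j + 1), at(i + 1, j),     at(i + 1, j - 1),
                      at(i, j - 1),     at(i - 1, j - 1)};
          int B = 0;
          for (int k = 0; k < 8; ++k) B += p[k];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) A++;
          if (A != 1) continue;
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(i + j * nr);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k)
          m(del[k] % nr, del[k] / nr) = 0;
      }
    }
  }
  return m;
}

// Stamp tapering strokes (sequences of discs) into a leaf-id image.
// Inputs are flattened per-step arrays: centre (x = column, y = row, both
// 1-based), disc radius, arc-length fraction t, and the 1-based leaf id.
// Later stamps overwrite earlier ones (painting order).
// [[Rcpp::export]]
List cpp_stamp_strokes(NumericVector x, NumericVector y, NumericVector r,
                       NumericVector t, IntegerVector leaf,
                       int nr, int nc) {
  IntegerMatrix id(nr, nc);
  NumericMatrix tf(nr, nc);
  int n = x.size();
  for (int s = 0; s < n; ++s) {
    double cx = x[s], cy = y[s], rad = r[s];
    int r0 = (int)std::ceil(cy - rad), r1 = (int)std::floor(cy + rad);
    int c0 = (int)std::ceil(cx - rad), c1 = (int)std::floor(cx + rad);
    if (r0 < 1) r0 = 1; if (r1 > nr) r1 = nr;
    if (c0 < 1) c0 = 1; if (c1 > nc) c1 = nc;
    double rad2 = rad * rad;
    for (int ci = c0; ci <= c1; ++ci) {
      double dx = ci - cx;
      for (int ri = r0; ri <= r1; ++ri) {
        double dy = ri - cy;
        if (dx * dx + dy * dy <= rad2) {
          id(ri - 1, ci - 1) = leaf[s];
          tf(ri - 1, ci - 1) = t[s];
        }
      }
    }
  }
  return List::create(_["id"] = id, _["tfrac"] = tf);
}
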