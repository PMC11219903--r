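#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Per-pixel iterative mean-shift filter. `bands` is nr x nc x nb. For each
// pixel, the window of pixels within Chebyshev distance <= spatialr of the
// current (floating) position whose spectral Euclidean distance to the
// current value is <= ranger is averaged; value and position move to the
// window means until the value moves less than conv_thresh or max_iter is
// reached. Masked-out pixels neither move nor contribute.
// [[Rcpp::export]]
NumericVector cpp_meanshift_filter(NumericVector bands, int nr, int nc, int nb,
                                   LogicalMatrix mask, double spatialr,
                                   double ranger, int max_iter,
                                   double conv_thresh) {
  NumericVector out(nr * nc * nb);
  const double r2 = ranger * ranger;
  const double conv2 = conv_thresh * conv_thresh;
  // pixel-major copy (band values of one pixel contiguous) for cache
  // locality in the window scan
  std::vector<double> px((size_t)nr * nc * nb);
  std::vector<char> ok((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      ok[(size_t)i + (size_t)nr * j] = mask(i, j) ? 1 : 0;
      for (int b = 0; b < nb; ++b)
        px[((size_t)i + (size_t)nr * j) * nb + b] =
          bands[i + nr * j + nr * nc * b];
    }
  std::vector<double> v(nb), acc(nb);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!ok[(size_t)i + (size_t)nr * j]) {
        for (int b = 0; b < nb; ++b) out[i + nr * j + nr * nc * b] = NA_REAL;
        continue;
      }
      double pr = i, pc = j;
      const double* p0 = &px[((size_t)i + (size_t)nr * j) * nb];
      for (int b = 0; b < nb; ++b) v[b] = p0[b];
      for (int it = 0; it < max_iter; ++it) {
        int r0 = (int)std::ceil(pr - spatialr); if (r0 < 0) r0 = 0;
        int r1 = (int)std::floor(pr + spatialr); if (r1 > nr - 1) r1 = nr - 1;
        int c0 = (int)std::ceil(pc - spatialr); if (c0 < 0) c0 = 0;
        int c1 = (int)std::floor(pc + spatialr); if (c1 > nc - 1) c1 = nc - 1;
        double sr_ = 0.0, sc_ = 0.0;
        int cnt = 0;
        for (int b = 0; b < nb; ++b) acc[b] = 0.0;
        for (int cc = c0; cc <= c1; ++cc) {
          const size_t colbase = (size_t)nr * cc;
          const double* col = &px[(colbase + r0) * nb];
          const char* okc = &ok[colbase + r0];
          for (int rr = r0; rr <= r1; ++rr, col += nb) {
            if (!okc[rr - r0]) continue;
            double d2 = 0.0;
            for (int b = 0; b < nb; ++b) {
              double diff = col[b] - v[b];
              d2 += diff * diff;
            }
            if (d2 <= r2) {
              for (int b = 0; b < nb; ++b) acc[b] += col[b];
              sr_ += rr; sc_ += cc; ++cnt;
            }
          }
        }
        if (cnt == 0) break;
        double move2 = 0.0;
        for (int b = 0; b < nb; ++b) {
          double nv = acc[b] / cnt;
          double diff = nv - v[b];
          move2 += diff * diff;
          v[b] = nv;
        }
        pr = sr_ / cnt; pc = sc_ / cnt;
        if (move2 < conv2) break;
      }
      for (int b = 0; b < nb; ++b) out[i + nr * j + nr * nc * b] = v[b];
    }
  }
  return out;
}

// 4-connected components of pixels whose mode vectors differ by <= ranger
// along the connection. Labels are assigned 1..K in row-major discovery
// order (row 1 left to right, then row 2, ...). Masked pixels get label 0.
// [[Rcpp::export]]
IntegerMatrix cpp_cluster_modes(NumericVector modes, int nr, int nc, int nb,
                                LogicalMatrix mask, double ranger) {
  IntegerMatrix labels(nr, nc);
  const double r2 = ranger * ranger;
  int next = 0;
  std::vector<int> stack;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || labels(i, j) != 0) continue;
      ++next;
      labels(i, j) = next;
      stack.clear();
      stack.push_back(i + nr * j);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 4; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (!mask(qi, qj) || labels(qi, qj) != 0) continue;
          double d2 = 0.0;
          for (int b = 0; b < nb; ++b) {
            double diff = modes[pi + nr * pj + nr * nc * b] -
                          modes[qi + nr * qj + nr * nc * b];
            d2 += diff * diff;
            if (d2 > r2) break;
          }
          if (d2 <= r2) {
            labels(qi, qj) = next;
            stack.push_back(qi + nr * qj);
          }
        }
      }
    }
  }
  return labels;
}

// Iteratively merge the smallest region below minsize into the 4-adjacent
// region whose mean spectral vector is nearest (Euclidean); ties go to the
// lower label id. Region means are updated after each merge. Stops when all
// regions have >= minsize pixels or only one region remains. Output labels
// are renumbered 1..K in row-major discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_merge_small(IntegerMatrix labels_in, NumericVector bands,
                              int nr, int nc, int nb, int minsize) {
  IntegerMatrix labels = clone(labels_in);
  int K = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (labels(i, j) > K) K = labels(i, j);
  if (K == 0) return labels;
  std::vector<std::vector<int>> pix(K + 1);
  std::vector<long long> size(K + 1, 0);
  std::vector<std::vector<double>> sum(K + 1, std::vector<double>(nb, 0.0));
  std::vector<bool> alive(K + 1, false);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int L = labels(i, j);
      if (L == 0) continue;
      pix[L].push_back(i + nr * j);
      ++size[L];
      alive[L] = true;
      for (int b = 0; b < nb; ++b) sum[L][b] += bands[i + nr * j + nr * nc * b];
    }
  }
  int n_alive = 0;
  for (int L = 1; L <= K; ++L) if (alive[L]) ++n_alive;
  typedef std::pair<long long, int> Entry;  // (size, label)
  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry>> pq;
  for (int L = 1; L <= K; ++L)
    if (alive[L] && size[L] < minsize) pq.push(Entry(size[L], L));
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty() && n_alive > 1) {
    Entry e = pq.top(); pq.pop();
    int L = e.second;
    if (!alive[L] || size[L] != e.first || size[L] >= minsize) continue;
    // adjacent regions of L
    double best_d2 = R_PosInf;
    int best = 0;
    for (size_t t = 0; t < pix[L].size(); ++t) {
      int p = pix[L][t];
      int pi = p % nr, pj = p / nr;
      for (int k = 0; k < 4; ++k) {
        int qi = pi + dr[k], qj = pj + dc[k];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        int M = labels(qi, qj);
        if (M == 0 || M == L) continue;
        double d2 = 0.0;
        for (int b = 0; b < nb; ++b) {
          double diff = sum[L][b] / size[L] - sum[M][b] / size[M];
          d2 += diff * diff;
        }
        bool better = (best == 0) || (d2 < best_d2) ||
                      (d2 == best_d2 && M < best);
        if (better) { best_d2 = d2; best = M; }
      }
    }
    if (best == 0) continue;  // isolated region (no neighbours): leave as is
    // merge L into best
    for (size_t t = 0; t < pix[L].size(); ++t) {
      int p = pix[L][t];
      labels(p % nr, p / nr) = best;
      pix[best].push_back(p);
    }
    pix[L].clear();
    for (int b = 0; b < nb; ++b) sum[best][b] += sum[L][b];
    size[best] += size[L];
    size[L] = 0;
    alive[L] = false;
    --n_alive;
    if (size[best] < minsize) pq.push(Entry(size[best], best));
  }
  // renumber surviving labels in row-major discovery order
  std::vector<int> newid(K + 1, 0);
  int next = 0;
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int L = labels(i, j);
      if (L == 0) { out(i, j) = 0; continue; }
      if (newid[L] == 0) newid[L] = ++next;
      out(i, j) = newid[L];
    }
  }
  return out;
}

// Zonal sums per label: returns (K x (2*nb + 1)) matrix with count, sum and
// sum of squares per band, used by zonal_stats().
// [[Rcpp::export]]
NumericMatrix cpp_zonal_sums(IntegerMatrix labels, NumericVector bands,
                             int nr, int nc, int nb, int K) {
  NumericMatrix out(K, 2 * nb + 1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int L = labels(i, j);
      if (L <= 0 || L > K) continue;
      out(L - 1, 0) += 1.0;
      for (int b = 0; b < nb; ++b) {
        double x = bands[i + nr * j + nr * nc * b];
        out(L - 1, 1 + b) += x;
        out(L - 1, 1 + nb + b) += x * x;
      }
    }
  }
  return out;
}
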