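#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of M at fractional (row, col), 0-based. NA outside the grid
// or when any of the four support pixels is NA.
static inline double bilin(const NumericMatrix &M, double r, double c) {
  const int nr = M.nrow(), nc = M.ncol();
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) return NA_REAL;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 > nr - 2) r0 = nr - 2;
  if (c0 > nc - 2) c0 = nc - 2;
  if (r0 < 0) r0 = 0;
  if (c0 < 0) c0 = 0;
  const double fr = r - r0, fc = c - c0;
  const double v00 = M(r0, c0), v10 = M(r0 + 1, c0);
  const double v01 = M(r0, c0 + 1), v11 = M(r0 + 1, c0 + 1);
  if (ISNAN(v00) || ISNAN(v10) || ISNAN(v01) || ISNAN(v11)) return NA_REAL;
  return v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
         v01 * (1 - fr) * fc + v11 * fr * fc;
}

// Sum of bilinear samples of `field` at per-pixel offsets (dr[k], dc[k]).
// Output(p) = sum_k field(p + (dr[k], dc[k])); NA if any sample falls outside.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_accum(NumericMatrix field, NumericVector dr,
                                 NumericVector dc) {
  const int nr = field.nrow(), nc = field.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), 0.0);
  for (int k = 0; k < K; ++k) {
    const double drk = dr[k], dck = dc[k];
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double cur = out(i, j);
        if (ISNAN(cur)) continue;
        const double v = bilin(field, i + drk, j + dck);
        out(i, j) = ISNAN(v) ? NA_REAL : cur + v;
      }
    }
  }
  return out;
}

// Bilinear sample of `field` on an arbitrary coordinate grid (row-major over
// rows `rs` x cols `cs`), used for image resampling.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_resample(NumericMatrix field, NumericVector rs,
                                    NumericVector cs) {
  const int nr = rs.size(), nc = cs.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = bilin(field, rs[i], cs[j]);
  return out;
}

// Local gray-level range (max - min) over an integer disk neighbourhood.
// Boundary pixels use the in-image portion of the disk.
// [[Rcpp::export]]
IntegerMatrix cpp_disk_range(IntegerMatrix q, IntegerVector di,
                             IntegerVector dj) {
  const int nr = q.nrow(), nc = q.ncol(), K = di.size();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int lo = INT_MAX, hi = INT_MIN;
      for (int k = 0; k < K; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        const int v = q(ii, jj);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      out(i, j) = hi - lo;
    }
  }
  return out;
}

// Shannon entropy (bits) of the empirical distribution of integer range
// observations inside a disk around each valid pixel. `valid` marks centers
// whose whole counting disk lies inside the mask; other pixels get NA.
// Range values must lie in 0..255.
// [[Rcpp::export]]
NumericMatrix cpp_entropy_map(IntegerMatrix v, LogicalMatrix valid,
                              IntegerVector di, IntegerVector dj) {
  const int nr = v.nrow(), nc = v.ncol(), K = di.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<int> counts(256, 0);
  std::vector<int> used;
  used.reserve(K);
  const double log2e = 1.0 / std::log(2.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!valid(i, j)) continue;
      used.clear();
      for (int k = 0; k < K; ++k) {
        const int val = v(i + di[k], j + dj[k]);
        if (counts[val] == 0) used.push_back(val);
        ++counts[val];
      }
      if (used.size() == 1) { // single observed value: exactly zero entropy
        counts[used[0]] = 0;
        out(i, j) = 0.0;
        continue;
      }
      double acc = 0.0;
      for (size_t u = 0; u < used.size(); ++u) {
        const double c = counts[used[u]];
        acc += c * std::log(c);
        counts[used[u]] = 0;
      }
      // H = log2(n) - (1/n) sum c log2 c
      out(i, j) = (std::log((double)K) - acc / K) * log2e;
    }
  }
  return out;
}
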