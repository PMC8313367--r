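#include <Rcpp.h>
using namespace Rcpp;

// Cross-distance between sample rows and centroid rows.
// metric: 1 = Manhattan (L1), 2 = Euclidean (L2).
// Hot loop of the k-means assignment step; dimensions here are
// n_windows x M(M-1)/2, too large for repeated R-level sweeps.
// [[Rcpp::export(name = ".cross_distance_cpp")]]
NumericMatrix cross_distance_cpp(NumericMatrix x, NumericMatrix centers,
                                 int metric) {
  const int n = x.nrow(), d = x.ncol(), k = centers.nrow();
  if (centers.ncol() != d)
    stop("dimension mismatch: samples have %d columns, centers %d", d,
         centers.ncol());
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      if (metric == 1) {
        for (int c = 0; c < d; ++c)
          acc += std::abs(x(i, c) - centers(j, c));
      } else {
        for (int c = 0; c < d; ++c) {
          const double diff = x(i, c) - centers(j, c);
          acc += diff * diff;
        }
        acc = std::sqrt(acc);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Column means of x restricted to each label group; rows ordered 1..k.
// Empty groups yield NaN rows (caller repairs them).
// [[Rcpp::export(name = ".group_colmeans_cpp")]]
NumericMatrix group_colmeans_cpp(NumericMatrix x, IntegerVector labels,
                                 int k) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix out(k, d);
  IntegerVector counts(k);
  for (int i = 0; i < n; ++i) {
    const int g = labels[i] - 1;
    if (g < 0 || g >= k) stop("label out of range at sample %d", i + 1);
    counts[g] += 1;
    for (int c = 0; c < d; ++c) out(g, c) += x(i, c);
  }
  for (int g = 0; g < k; ++g) {
    if (counts[g] == 0) {
      for (int c = 0; c < d; ++c) out(g, c) = NA_REAL;
    } else {
      for (int c = 0; c < d; ++c) out(g, c) /= counts[g];
    }
  }
  return out;
}

// Column medians of x restricted to each label group; rows ordered 1..k.
// Empty groups yield NaN rows (caller repairs them).
// [[Rcpp::export(name = ".group_colmedians_cpp")]]
NumericMatrix group_colmedians_cpp(NumericMatrix x, IntegerVector labels,
                                   int k) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix out(k, d);
  std::vector<std::vector<int>> members(k);
  for (int i = 0; i < n; ++i) {
    const int g = labels[i] - 1;
    if (g < 0 || g >= k) stop("label out of range at sample %d", i + 1);
    members[g].push_back(i);
  }
  std::vector<double> buf;
  for (int g = 0; g < k; ++g) {
    const int m = members[g].size();
    if (m == 0) {
      for (int c = 0; c < d; ++c) out(g, c) = NA_REAL;
      continue;
    }
    buf.resize(m);
    for (int c = 0; c < d; ++c) {
      for (int i = 0; i < m; ++i) buf[i] = x(members[g][i], c);
      const int mid = m / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1,
                         buf.begin() + mid);
        med = (med + buf[mid - 1]) / 2.0;
      }
      out(g, c) = med;
    }
  }
  return out;
}
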