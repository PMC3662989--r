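#include <Rcpp.h>
using namespace Rcpp;

// k-means under the mean-of-component-distances metric.
//
// Points are rows of `mat`; columns are grouped into features (a 2D center
// group and scalar groups), already divided by their normalization scales.
// The distance between a point and a centroid is the mean over groups of
// the Euclidean distance within each group -- the averaged per-parameter
// distance used to cluster Gaussian units.  The objective minimized is the
// sum of point-to-centroid distances; `W` additionally reports the sum of
// squared distances (the within-cluster dispersion used by the gap
// statistic).

static double group_dist(const NumericMatrix &mat, int i,
                         const std::vector<double> &centroid,
                         const IntegerVector &group_start,
                         const IntegerVector &group_len) {
  double total = 0.0;
  int G = group_start.size();
  for (int g = 0; g < G; ++g) {
    double ss = 0.0;
    for (int c = group_start[g]; c < group_start[g] + group_len[g]; ++c) {
      double d = mat(i, c) - centroid[c];
      ss += d * d;
    }
    total += std::sqrt(ss);
  }
  return total / G;
}

static void recompute_centroid(const NumericMatrix &mat,
                               const IntegerVector &assign, int j,
                               std::vector<double> &centroid) {
  int n = mat.nrow(), d = mat.ncol(), cnt = 0;
  std::fill(centroid.begin(), centroid.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    if (assign[i] == j) {
      ++cnt;
      for (int c = 0; c < d; ++c) centroid[c] += mat(i, c);
    }
  }
  if (cnt > 0)
    for (int c = 0; c < d; ++c) centroid[c] /= cnt;
}

static double cluster_cost(const NumericMatrix &mat,
                           const IntegerVector &assign, int j,
                           const std::vector<double> &centroid,
                           const IntegerVector &group_start,
                           const IntegerVector &group_len) {
  double total = 0.0;
  for (int i = 0; i < mat.nrow(); ++i)
    if (assign[i] == j)
      total += group_dist(mat, i, centroid, group_start, group_len);
  return total;
}

// [[Rcpp::export(name = ".kmeans_features_cpp")]]
List kmeans_features_cpp(NumericMatrix mat, IntegerVector init_rows,
                         IntegerVector group_start, IntegerVector group_len,
                         int max_batch = 100, int max_pass = 20) {
  int n = mat.nrow(), d = mat.ncol();
  int k = init_rows.size();
  std::vector<std::vector<double> > centroids(k, std::vector<double>(d));
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) centroids[j][c] = mat(init_rows[j] - 1, c);

  IntegerVector assign(n, 0);
  int reseeded = 0;

  // batch (Lloyd) phase
  for (int iter = 0; iter < max_batch; ++iter) {
    bool changed = false;
    NumericVector own_dist(n);
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        double dd = group_dist(mat, i, centroids[j], group_start, group_len);
        if (dd < best) { best = dd; bj = j; }
      }
      if (bj != assign[i]) { assign[i] = bj; changed = true; }
      own_dist[i] = best;
    }
    // re-seed emptied clusters at the farthest point
    for (int j = 0; j < k; ++j) {
      bool empty = true;
      for (int i = 0; i < n; ++i) if (assign[i] == j) { empty = false; break; }
      if (empty) {
        int far = 0;
        double fd = -1.0;
        for (int i = 0; i < n; ++i)
          if (own_dist[i] > fd) { fd = own_dist[i]; far = i; }
        assign[far] = j;
        own_dist[far] = 0.0;
        ++reseeded;
        changed = true;
      }
    }
    for (int j = 0; j < k; ++j) recompute_centroid(mat, assign, j, centroids[j]);
    if (!changed && iter > 0) break;
  }

  // online phase: accept single-point moves that lower the summed distance
  std::vector<double> cost(k), cnt(k, 0.0);
  for (int j = 0; j < k; ++j)
    cost[j] = cluster_cost(mat, assign, j, centroids[j], group_start, group_len);
  for (int i = 0; i < n; ++i) cnt[assign[i]] += 1.0;

  std::vector<double> cand_a(d), cand_b(d);
  for (int pass = 0; pass < max_pass; ++pass) {
    bool moved = false;
    for (int i = 0; i < n; ++i) {
      int a = assign[i];
      if (cnt[a] <= 1.0) continue; // keep clusters non-empty
      for (int b = 0; b < k; ++b) {
        if (b == a) continue;
        // candidate centroids after moving i from a to b
        for (int c = 0; c < d; ++c) {
          cand_a[c] = (centroids[a][c] * cnt[a] - mat(i, c)) / (cnt[a] - 1.0);
          cand_b[c] = (centroids[b][c] * cnt[b] + mat(i, c)) / (cnt[b] + 1.0);
        }
        assign[i] = b;
        double new_a = cluster_cost(mat, assign, a, cand_a, group_start, group_len);
        double new_b = cluster_cost(mat, assign, b, cand_b, group_start, group_len);
        if (new_a + new_b < cost[a] + cost[b] - 1e-12) {
          centroids[a] = cand_a;
          centroids[b] = cand_b;
          cost[a] = new_a;
          cost[b] = new_b;
          cnt[a] -= 1.0;
          cnt[b] += 1.0;
          moved = true;
          break;
        }
        assign[i] = a; // reject
      }
    }
    if (!moved) break;
  }

  double objective = 0.0, W = 0.0;
  NumericMatrix cent_out(k, d);
  for (int j = 0; j < k; ++j) {
    recompute_centroid(mat, assign, j, centroids[j]);
    for (int c = 0; c < d; ++c) cent_out(j, c) = centroids[j][c];
  }
  for (int i = 0; i < n; ++i) {
    double dd = group_dist(mat, i, centroids[assign[i]], group_start, group_len);
    objective += dd;
    W += dd * dd;
  }
  IntegerVector assign_out(n);
  for (int i = 0; i < n; ++i) assign_out[i] = assign[i] + 1;
  return List::create(_["assign"] = assign_out, _["centroids"] = cent_out,
                      _["objective"] = objective, _["W"] = W,
                      _["reseeded"] = reseeded);
}
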