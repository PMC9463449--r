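#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Brute-force Euclidean k-nearest neighbours of each query row among the
// reference rows. Dimensions here are small (a handful of morphological
// features or a few dozen MCA axes), so a blocked brute-force scan is both
// exact and fast enough for sketches of ~2e4 points.
//
// Returns a n_query x k matrix of 1-based reference row indices, nearest
// first; ties broken toward the lower reference index. If `self` is true the
// query set IS the reference set and each point's own row is excluded.

// [[Rcpp::export(name = ".knn_brute")]]
IntegerMatrix knn_brute(NumericMatrix query, NumericMatrix ref, int k,
                        bool self) {
  const int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("dimension mismatch");
  if (k <= 0 || k > (self ? nr - 1 : nr)) stop("invalid k");
  IntegerMatrix out(nq, k);
  std::vector<std::pair<double, int> > cand(nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = query(i, c) - ref(j, c);
        s += diff * diff;
      }
      if (self && j == i) s = R_PosInf;
      cand[j] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
  }
  return out;
}

// Jaccard edge weights over a k-nearest-neighbour graph: for every directed
// edge i -> j of `nn` (n x k, 1-based), weight = |N(i) ∩ N(j)| / |N(i) ∪ N(j)|
// where N(.) is the point's k-neighbour set. Returns an edge list
// (from, to, weight) with from < to and duplicate (i,j)/(j,i) edges merged
// (the Jaccard weight is symmetric in the two sets).

// [[Rcpp::export(name = ".jaccard_edges")]]
DataFrame jaccard_edges(IntegerMatrix nn) {
  const int n = nn.nrow(), k = nn.ncol();
  std::vector<std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i) {
    nbr[i].resize(k);
    for (int j = 0; j < k; ++j) nbr[i][j] = nn(i, j) - 1;
    std::sort(nbr[i].begin(), nbr[i].end());
  }
  std::vector<int> from, to;
  std::vector<double> w;
  std::vector<int> inter;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      const int t = nn(i, j) - 1;
      const int a = std::min(i, t), b = std::max(i, t);
      if (a == b) continue;
      // emit each undirected pair once, from the endpoint that owns it in
      // sorted order; the reverse edge (if present) would duplicate it
      if (i == b) {
        // only emit if the reverse edge does not exist (it would have been
        // emitted when processing a)
        if (std::binary_search(nbr[a].begin(), nbr[a].end(), b)) continue;
      }
      inter.clear();
      std::set_intersection(nbr[a].begin(), nbr[a].end(),
                            nbr[b].begin(), nbr[b].end(),
                            std::back_inserter(inter));
      const double ni = (double)inter.size();
      const double nu = 2.0 * k - ni;
      from.push_back(a + 1);
      to.push_back(b + 1);
      w.push_back(nu > 0 ? ni / nu : 0.0);
    }
  }
  return DataFrame::create(_["from"] = from, _["to"] = to, _["weight"] = w);
}
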