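// Core geometry for convex-hull density clustering.
//
// The vertex sets involved stay small (hulls of point clouds in 2-D/3-D), so
// extreme points are found by facet enumeration: a point is a hull vertex iff
// it lies on some supporting plane (3-D: a triple of points whose plane has
// all points on one side; 2-D: a supporting edge). Rank-deficient sets fall
// back to the hull in the affine subspace they span (2-D hull, then segment
// endpoints), per the degenerate-geometry policy documented in the package.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::uvec all_idx(arma::uword k) {
  return arma::regspace<arma::uvec>(0, k - 1);
}

// extreme points (0-based local indices) of a k x d point set, d in {2, 3}
static arma::uvec extreme_points(const arma::mat& P) {
  const arma::uword k = P.n_rows;
  const arma::uword d = P.n_cols;
  if (k == 0) return arma::uvec();
  if (k <= d + 1) return all_idx(k);

  arma::rowvec ctr = arma::mean(P, 0);
  arma::mat X = P.each_row() - ctr;
  const double scale = arma::abs(X).max();
  if (scale <= 0.0) {           // all points coincident
    arma::uvec v(1); v[0] = 0; return v;
  }
  const double tol = scale * 1e-9;

  arma::mat U, V;
  arma::vec s;
  if (!arma::svd_econ(U, s, V, X)) return all_idx(k);
  const arma::uword rank = arma::sum(s > s.max() * 1e-8);

  if (rank <= 1) {              // collinear: segment endpoints
    arma::vec t = X * V.col(0);
    arma::uword a = t.index_min(), b = t.index_max();
    if (a == b) { arma::uvec v(1); v[0] = a; return v; }
    arma::uvec v(2); v[0] = std::min(a, b); v[1] = std::max(a, b);
    return v;
  }

  std::vector<bool> mark(k, false);

  if (rank == 2 || d == 2) {    // planar: supporting edges
    arma::mat Y = (d == 2) ? X : arma::mat(X * V.cols(0, 1));
    for (arma::uword i = 0; i + 1 < k; ++i) {
      for (arma::uword j = i + 1; j < k; ++j) {
        if (mark[i] && mark[j]) continue;
        const double dx = Y(j, 0) - Y(i, 0), dy = Y(j, 1) - Y(i, 1);
        const double len = std::sqrt(dx * dx + dy * dy);
        if (len < tol) continue;
        const double nx = -dy / len, ny = dx / len;
        bool pos = true, neg = true;
        for (arma::uword l = 0; l < k && (pos || neg); ++l) {
          const double sv = nx * (Y(l, 0) - Y(i, 0)) + ny * (Y(l, 1) - Y(i, 1));
          if (sv > tol) neg = false;
          if (sv < -tol) pos = false;
        }
        if (pos || neg) { mark[i] = true; mark[j] = true; }
      }
    }
  } else {                      // full-rank 3-D: supporting facets
    for (arma::uword i = 0; i + 2 < k; ++i) {
      for (arma::uword j = i + 1; j + 1 < k; ++j) {
        const double ax = X(j, 0) - X(i, 0), ay = X(j, 1) - X(i, 1),
                     az = X(j, 2) - X(i, 2);
        for (arma::uword m = j + 1; m < k; ++m) {
          if (mark[i] && mark[j] && mark[m]) continue;
          const double bx = X(m, 0) - X(i, 0), by = X(m, 1) - X(i, 1),
                       bz = X(m, 2) - X(i, 2);
          const double nx = ay * bz - az * by;
          const double ny = az * bx - ax * bz;
          const double nz = ax * by - ay * bx;
          const double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
          if (nn < scale * tol) continue;   // degenerate triple
          bool pos = true, neg = true;
          for (arma::uword l = 0; l < k && (pos || neg); ++l) {
            const double sv = (nx * (X(l, 0) - X(i, 0)) +
                               ny * (X(l, 1) - X(i, 1)) +
                               nz * (X(l, 2) - X(i, 2))) / nn;
            if (sv > tol) neg = false;
            if (sv < -tol) pos = false;
          }
          if (pos || neg) { mark[i] = true; mark[j] = true; mark[m] = true; }
        }
      }
    }
  }

  arma::uvec out(k);
  arma::uword n = 0;
  for (arma::uword i = 0; i < k; ++i) if (mark[i]) out[n++] = i;
  if (n == 0) return all_idx(k);
  out.resize(n);
  return out;
}

static double pt_dist(const arma::mat& pts, int i, int j) {
  double s = 0.0;
  for (arma::uword c = 0; c < pts.n_cols; ++c) {
    const double d = pts(i, c) - pts(j, c);
    s += d * d;
  }
  return std::sqrt(s);
}

static double mean_pairwise(const arma::mat& pts, const std::vector<int>& v) {
  const size_t n = v.size();
  if (n < 2) return 0.0;
  double s = 0.0;
  size_t c = 0;
  for (size_t i = 0; i + 1 < n; ++i)
    for (size_t j = i + 1; j < n; ++j) { s += pt_dist(pts, v[i], v[j]); ++c; }
  return s / static_cast<double>(c);
}

// [[Rcpp::export]]
IntegerVector cpp_hull_vertices(const arma::mat& pts) {
  arma::uvec v = extreme_points(pts);
  IntegerVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = static_cast<int>(v[i]);
  return out;                   // 0-based; R wrapper shifts
}

// [[Rcpp::export]]
IntegerVector cpp_neighbor_counts(const arma::mat& pts, const double radius) {
  const int n = pts.n_rows;
  IntegerVector counts(n, 0);
  for (int i = 0; i + 1 < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (pt_dist(pts, i, j) <= radius) { ++counts[i]; ++counts[j]; }
    }
  }
  return counts;
}

struct Group {
  int peak;
  std::vector<int> members;
  std::vector<int> verts;       // global point indices of hull vertices
  double rbar;                  // mean pairwise distance among hull vertices
};

// Density-ordered walk: seed the first group at the top-ranked cell from the
// first bin of its distance histogram, then absorb each next-ranked cell into
// the group whose hull it is near (distance to the nearest hull vertex below
// that hull's mean vertex-vertex distance), expanding the hull; otherwise the
// cell is a new local maximum and seeds a new group, until the unassigned
// remainder is too small to form a hull.
// [[Rcpp::export]]
List cpp_density_walk(const arma::mat& pts, const IntegerVector& order0,
                      const int bg) {
  const int N = pts.n_rows;
  const int d = pts.n_cols;
  std::vector<int> assign(N, -1);
  std::vector<Group> groups;
  int n_unassigned = N;

  // The histogram of distances to a peak is binned over the full observed
  // distance scale (distances from the peak to every cell), but only
  // unassigned cells in the first bin seed the group. Ranging over the
  // unassigned remainder alone would collapse the bin width once only a
  // tight remnant is left, shattering small clusters.
  auto seed_group = [&](int peak) {
    std::vector<double> dd(N);
    double maxd = 0.0;
    for (int i = 0; i < N; ++i) {
      dd[i] = pt_dist(pts, i, peak);
      if (dd[i] > maxd) maxd = dd[i];
    }
    const double width = maxd / bg;
    Group g;
    g.peak = peak;
    const int gid = static_cast<int>(groups.size());
    for (int i = 0; i < N; ++i) {
      if (assign[i] >= 0) continue;
      if (maxd <= 0.0 || dd[i] <= width * (1.0 + 1e-12)) {
        g.members.push_back(i);
        assign[i] = gid;
        --n_unassigned;
      }
    }
    arma::mat M(g.members.size(), d);
    for (size_t i = 0; i < g.members.size(); ++i)
      M.row(i) = pts.row(g.members[i]);
    arma::uvec ep = extreme_points(M);
    g.verts.reserve(ep.n_elem);
    for (arma::uword i = 0; i < ep.n_elem; ++i)
      g.verts.push_back(g.members[ep[i]]);
    g.rbar = mean_pairwise(pts, g.verts);
    groups.push_back(g);
  };

  for (int t = 0; t < N; ++t) {
    const int idx = order0[t];
    if (assign[idx] >= 0) continue;
    if (groups.empty()) { seed_group(idx); continue; }

    int best = -1;
    double bestr = 0.0;
    for (size_t g = 0; g < groups.size(); ++g) {
      if (groups[g].rbar <= 0.0) continue;
      double rmin = std::numeric_limits<double>::infinity();
      for (size_t v = 0; v < groups[g].verts.size(); ++v) {
        const double dv = pt_dist(pts, idx, groups[g].verts[v]);
        if (dv < rmin) rmin = dv;
      }
      if (rmin < groups[g].rbar && (best < 0 || rmin < bestr)) {
        best = static_cast<int>(g);
        bestr = rmin;
      }
    }

    if (best >= 0) {            // absorb and expand that hull
      Group& g = groups[best];
      assign[idx] = best;
      g.members.push_back(idx);
      --n_unassigned;
      std::vector<int> cand = g.verts;
      cand.push_back(idx);
      arma::mat M(cand.size(), d);
      for (size_t i = 0; i < cand.size(); ++i) M.row(i) = pts.row(cand[i]);
      arma::uvec ep = extreme_points(M);
      std::vector<int> nv;
      nv.reserve(ep.n_elem);
      for (arma::uword i = 0; i < ep.n_elem; ++i) nv.push_back(cand[ep[i]]);
      if (nv != g.verts) {
        g.verts = nv;
        g.rbar = mean_pairwise(pts, g.verts);
      }
    } else {                    // new local maximum
      if (n_unassigned < d + 1) break;
      seed_group(idx);
    }
  }

  const int K = static_cast<int>(groups.size());
  IntegerVector assignR(N);
  for (int i = 0; i < N; ++i) assignR[i] = assign[i];
  List gl(K);
  for (int g = 0; g < K; ++g) {
    gl[g] = List::create(
      _["peak"] = groups[g].peak,
      _["members"] = IntegerVector(groups[g].members.begin(),
                                   groups[g].members.end()),
      _["verts"] = IntegerVector(groups[g].verts.begin(),
                                 groups[g].verts.end()));
  }
  return List::create(_["assign"] = assignR, _["groups"] = gl);
}
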