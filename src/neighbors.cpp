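// Exact neighbor queries on a uniform hash grid, plus the two point-cloud
// kernels that dominate runtime: k-nearest-neighbor lists (deterministically
// tie-broken) and rolling-ball boundary-edge extraction in 2D.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct HashGrid {
  const arma::mat& P;      // N x d, d in {2,3}
  int d;
  double h;
  arma::rowvec lo;
  std::unordered_map<long long, std::vector<int>> cells;

  HashGrid(const arma::mat& pts, double cell) : P(pts), d((int)pts.n_cols), h(cell) {
    lo = arma::min(P, 0);
    // keep cell coordinates well inside the injective packing range
    double span = (arma::max(P, 0) - lo).max();
    if (span > 0 && h < span / 1e6) h = span / 1e6;
    cells.reserve(P.n_rows * 2 + 16);
    for (arma::uword i = 0; i < P.n_rows; ++i)
      cells[key_of(P.row(i))].push_back((int)i);
  }

  long long cell_coord(double x, int j) const {
    return (long long)std::floor((x - lo(j)) / h);
  }
  long long pack(long long cx, long long cy, long long cz) const {
    // base-K positional packing, injective for |coords| < K/2
    const long long K = 2097152LL; // 2^21
    return (cx * K + cy) * K + cz;
  }
  long long key_of(const arma::rowvec& p) const {
    long long cx = cell_coord(p(0), 0), cy = cell_coord(p(1), 1);
    long long cz = d > 2 ? cell_coord(p(2), 2) : 0;
    return pack(cx, cy, cz);
  }

  // all points within Chebyshev cell distance m of the query's cell
  void gather(const arma::rowvec& q, long long m, std::vector<int>& out) const {
    out.clear();
    long long cx = cell_coord(q(0), 0), cy = cell_coord(q(1), 1);
    long long cz = d > 2 ? cell_coord(q(2), 2) : 0;
    long long zlo = d > 2 ? cz - m : 0, zhi = d > 2 ? cz + m : 0;
    for (long long x = cx - m; x <= cx + m; ++x)
      for (long long y = cy - m; y <= cy + m; ++y)
        for (long long z = zlo; z <= zhi; ++z) {
          auto it = cells.find(pack(x, y, z));
          if (it != cells.end())
            out.insert(out.end(), it->second.begin(), it->second.end());
        }
  }

  void within_radius(const arma::rowvec& q, double r, std::vector<int>& out) const {
    long long m = (long long)std::ceil(r / h);
    gather(q, m, out);
    double r2 = r * r;
    size_t w = 0;
    for (size_t s = 0; s < out.size(); ++s) {
      double d2 = 0;
      for (int j = 0; j < d; ++j) { double dx = P(out[s], j) - q(j); d2 += dx * dx; }
      if (d2 <= r2) out[w++] = out[s];
    }
    out.resize(w);
  }
};

inline double dist2_row(const arma::mat& P, int i, const arma::rowvec& q, int d) {
  double s = 0;
  for (int j = 0; j < d; ++j) { double dx = P(i, j) - q(j); s += dx * dx; }
  return s;
}

} // namespace

// K nearest neighbors of every point (self excluded), sorted by increasing
// distance with exact ties broken by lower point index.
// [[Rcpp::export]]
List knn_grid(const arma::mat& P, int k) {
  int N = (int)P.n_rows, d = (int)P.n_cols;
  if (N < 2) stop("need at least 2 points");
  if (k < 1) stop("k must be >= 1");
  int kk = std::min(k, N - 1);

  arma::rowvec span = arma::max(P, 0) - arma::min(P, 0);
  double vol = 1.0; int live = 0;
  for (int j = 0; j < d; ++j) if (span(j) > 0) { vol *= span(j); ++live; }
  double h = live > 0 ? std::pow(vol / N, 1.0 / live) : 1.0;
  if (!(h > 0) || !std::isfinite(h)) h = 1.0;
  HashGrid grid(P, h);

  IntegerMatrix idx(N, kk);
  NumericMatrix dst(N, kk);
  std::vector<int> cand;
  std::vector<std::pair<double, int>> best;
  double max_span = span.max();
  long long m_cap = (long long)std::ceil((max_span > 0 ? max_span : 1.0) / h) + 1;

  for (int i = 0; i < N; ++i) {
    arma::rowvec q = P.row(i);
    long long m = 1;
    for (;;) {
      grid.gather(q, m, cand);
      best.clear();
      for (int c : cand) if (c != i) best.emplace_back(dist2_row(P, c, q, d), c);
      if ((int)best.size() >= kk) {
        std::partial_sort(best.begin(), best.begin() + kk, best.end());
        // equal-distance tail must be included before tie-breaking by index
        double kd2 = best[kk - 1].first;
        if (std::sqrt(kd2) <= m * h || m >= m_cap) {
          std::sort(best.begin(), best.end());
          break;
        }
      } else if (m >= m_cap) {
        std::sort(best.begin(), best.end());
        break;
      }
      m *= 2;
    }
    for (int j = 0; j < kk; ++j) {
      idx(i, j) = best[j].second + 1;
      dst(i, j) = std::sqrt(best[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// All points of `Q` lying within `r` of each row of `queries` (1-based lists).
// [[Rcpp::export]]
List radius_grid(const arma::mat& P, const arma::mat& queries, double r) {
  if (r <= 0) stop("radius must be positive");
  HashGrid grid(P, r);
  int nq = (int)queries.n_rows;
  List out(nq);
  std::vector<int> cand;
  for (int i = 0; i < nq; ++i) {
    arma::rowvec q = queries.row(i);
    grid.within_radius(q, r, cand);
    std::sort(cand.begin(), cand.end());
    IntegerVector v(cand.size());
    for (size_t s = 0; s < cand.size(); ++s) v[s] = cand[s] + 1;
    out[i] = v;
  }
  return out;
}

// Rolling-ball boundary edges: (A,B) is a boundary edge iff |AB| <= 2r and at
// least one of the two radius-r circles through A and B contains no other
// point strictly inside (strict means distance < r - eps).
// [[Rcpp::export]]
IntegerMatrix rollball_edges_cpp(const arma::mat& P2, double r, double eps) {
  if (P2.n_cols != 2) stop("points must be M x 2");
  int M = (int)P2.n_rows;
  if (M < 3) stop("need at least 3 points");
  if (!(r > 0)) stop("radius must be positive");
  HashGrid grid(P2, r);
  double rin = r - eps, rin2 = rin * rin, four_r2 = 4.0 * r * r;
  std::vector<int> cand, blk;
  std::vector<std::pair<int,int>> edges;

  for (int i = 0; i < M; ++i) {
    arma::rowvec a = P2.row(i);
    grid.within_radius(a, 2.0 * r, cand);
    for (int j : cand) {
      if (j <= i) continue;
      double vx = P2(j, 0) - a(0), vy = P2(j, 1) - a(1);
      double L2 = vx * vx + vy * vy;
      if (L2 > four_r2 || L2 == 0.0) continue;
      double L = std::sqrt(L2);
      double D = std::sqrt(std::max(0.0, r * r - 0.25 * L2));
      double cx = a(0) + 0.5 * vx, cy = a(1) + 0.5 * vy;
      double hx = -vy / L, hy = vx / L;
      bool edge = false;
      for (int s = -1; s <= 1 && !edge; s += 2) {
        arma::rowvec o(2);
        o(0) = cx + s * D * hx; o(1) = cy + s * D * hy;
        grid.within_radius(o, rin, blk);
        bool empty = true;
        for (int b : blk) {
          if (b == i || b == j) continue;
          double dx = P2(b, 0) - o(0), dy = P2(b, 1) - o(1);
          if (dx * dx + dy * dy < rin2) { empty = false; break; }
        }
        if (empty) edge = true;
      }
      if (edge) edges.emplace_back(i + 1, j + 1);
    }
  }
  IntegerMatrix E((int)edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) { E(e, 0) = edges[e].first; E(e, 1) = edges[e].second; }
  return E;
}

// PCA plane-fit surface features: normal = eigenvector of the neighborhood
// covariance for the smallest eigenvalue; curvature = l1/(l1+l2+l3).
// Neighborhood = the point itself plus its k listed neighbors.
// [[Rcpp::export]]
List normals_curvature_cpp(const arma::mat& P, const IntegerMatrix& nb) {
  int N = (int)P.n_rows;
  if (P.n_cols != 3) stop("points must be N x 3");
  if (nb.nrow() != N) stop("neighbor matrix rows must match point count");
  int k = nb.ncol();
  arma::mat normals(N, 3);
  arma::vec curv(N);
  LogicalVector degen(N);

  arma::mat nbh(k + 1, 3);
  for (int i = 0; i < N; ++i) {
    nbh.row(0) = P.row(i);
    for (int j = 0; j < k; ++j) nbh.row(j + 1) = P.row(nb(i, j) - 1);
    arma::rowvec mu = arma::mean(nbh, 0);
    arma::mat C = nbh.each_row() - mu;
    arma::mat S = C.t() * C / nbh.n_rows;
    double tr = arma::trace(S);
    if (tr <= 1e-300) {
      normals.row(i) = arma::rowvec({0.0, 0.0, 1.0});
      curv(i) = 0.0;
      degen[i] = true;
      continue;
    }
    arma::vec ev; arma::mat evec;
    arma::eig_sym(ev, evec, S);      // ascending eigenvalues
    arma::vec n = evec.col(0);
    normals.row(i) = n.t() / arma::norm(n);
    double rho = ev(0) / (ev(0) + ev(1) + ev(2));
    curv(i) = std::min(std::max(rho, 0.0), 1.0 / 3.0);
    degen[i] = false;
  }
  return List::create(_["normals"] = normals, _["curvatures"] = curv,
                      _["degenerate"] = degen);
}
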