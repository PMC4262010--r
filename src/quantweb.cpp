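#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline double xlx(double n) { return n > 0.5 ? n * std::log(n) : 0.0; }

// Greedy refinement of an integer matrix under fixed marginals via unit
// moves along 2x2 cycles: (i1,j1),(i2,j2) -> (i1,j2),(i2,j1). Entropy of
// p = A/m is maximised (maximize = true) or minimised. sum(n log n) along
// a cycle is convex in the number of units moved, so for minimum entropy
// the full transfer is tested, while for maximum entropy unit steps are
// repeated while they improve. Deterministic scan order.
// [[Rcpp::export]]
NumericMatrix entropy_cycle_improve_cpp(NumericMatrix A, bool maximize,
                                        int max_moves) {
  int R = A.nrow(), C = A.ncol();
  NumericMatrix M(clone(A));
  if (R < 2 || C < 2) return M;
  int moves = 0;
  bool improved = true;
  const double eps = 1e-11;
  while (improved && moves < max_moves) {
    improved = false;
    for (int i1 = 0; i1 < R - 1; ++i1)
      for (int i2 = i1 + 1; i2 < R; ++i2)
        for (int j1 = 0; j1 < C; ++j1)
          for (int j2 = 0; j2 < C; ++j2) {
            if (j1 == j2) continue;
            double a = M(i1, j1), b = M(i2, j2);
            if (a < 0.5 || b < 0.5) continue;
            double c = M(i1, j2), d = M(i2, j1);
            if (maximize) {
              // minimise sum n log n by unit steps
              while (a >= 0.5 && b >= 0.5) {
                double delta = xlx(a - 1) - xlx(a) + xlx(b - 1) - xlx(b) +
                               xlx(c + 1) - xlx(c) + xlx(d + 1) - xlx(d);
                if (delta < -eps) {
                  a -= 1; b -= 1; c += 1; d += 1;
                  ++moves; improved = true;
                  if (moves >= max_moves) break;
                } else break;
              }
            } else {
              double t = std::min(a, b);
              double delta = xlx(a - t) - xlx(a) + xlx(b - t) - xlx(b) +
                             xlx(c + t) - xlx(c) + xlx(d + t) - xlx(d);
              if (delta > eps) {
                a -= t; b -= t; c += t; d += t;
                ++moves; improved = true;
              }
            }
            M(i1, j1) = a; M(i2, j2) = b; M(i1, j2) = c; M(i2, j1) = d;
            if (moves >= max_moves) return M;
          }
  }
  return M;
}

struct SAState {
  std::vector<int> g;   // module label per node (hosts 0..R-1, parasitoids R..N-1)
  double S;             // unnormalised score sum B_ij [g_i == g_(R+j)]
};

// [[Rcpp::export]]
List sa_modularity_cpp(NumericMatrix a, int seed, int chains,
                       double cooling, int stall_limit) {
  int R = a.nrow(), C = a.ncol(), N = R + C;
  double m = 0;
  std::vector<double> rs(R, 0.0), cs(C, 0.0);
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < C; ++j) { m += a(i, j); rs[i] += a(i, j); cs[j] += a(i, j); }
  std::vector<double> B((size_t)R * C);
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < C; ++j)
      B[(size_t)i * C + j] = a(i, j) - rs[i] * cs[j] / m;

  auto full_score = [&](const std::vector<int>& g) {
    double s = 0;
    for (int i = 0; i < R; ++i)
      for (int j = 0; j < C; ++j)
        if (g[i] == g[R + j]) s += B[(size_t)i * C + j];
    return s;
  };
  // score change from relabelling node v to t
  auto delta_node = [&](const std::vector<int>& g, int v, int t) {
    double d = 0;
    if (v < R) {
      for (int j = 0; j < C; ++j) {
        int gj = g[R + j];
        if (gj == t) d += B[(size_t)v * C + j];
        if (gj == g[v]) d -= B[(size_t)v * C + j];
      }
    } else {
      int j = v - R;
      for (int i = 0; i < R; ++i) {
        if (g[i] == t) d += B[(size_t)i * C + j];
        if (g[i] == g[v]) d -= B[(size_t)i * C + j];
      }
    }
    return d;
  };

  std::vector<int> best_g(N);
  double best_S = -1e300;
  bool have_best = false;

  for (int chain = 0; chain < chains; ++chain) {
    std::mt19937 rng((unsigned)seed + 1000003u * (unsigned)chain + 12345u);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    SAState st;
    st.g.resize(N);
    for (int v = 0; v < N; ++v) st.g[v] = v;
    st.S = full_score(st.g);

    // initial temperature: accept a typical uphill-equivalent move ~50%
    double mean_abs = 0;
    for (int k = 0; k < 200; ++k) {
      int v = (int)(U(rng) * N); if (v >= N) v = N - 1;
      int t = (int)(U(rng) * N); if (t >= N) t = N - 1;
      mean_abs += std::fabs(delta_node(st.g, v, t)) / m;
    }
    mean_abs /= 200.0;
    double T = mean_abs > 0 ? mean_abs / std::log(2.0) : 1e-3;
    if (T < 1e-8) T = 1e-3;

    std::vector<int> chain_best = st.g;
    double chain_best_S = st.S;
    int stall = 0;
    long iter = 0;
    std::vector<int> members, labels;
    while (stall < stall_limit) {
      double u = U(rng);
      double dS = 0;
      bool applied = false;
      if (u < 0.8) {
        int v = (int)(U(rng) * N); if (v >= N) v = N - 1;
        int t = (int)(U(rng) * N); if (t >= N) t = N - 1;
        dS = delta_node(st.g, v, t);
        if (dS >= 0 || U(rng) < std::exp(dS / m / T)) {
          st.g[v] = t;
          applied = true;
        }
      } else {
        labels.clear();
        {
          std::vector<char> used(N, 0);
          for (int v = 0; v < N; ++v) used[st.g[v]] = 1;
          for (int l = 0; l < N; ++l) if (used[l]) labels.push_back(l);
        }
        if (u < 0.9 && labels.size() >= 2) {
          // merge two modules
          int xi = (int)(U(rng) * labels.size());
          int yi = (int)(U(rng) * labels.size());
          if (xi != yi) {
            int x = labels[xi], y = labels[yi];
            for (int i = 0; i < R; ++i)
              for (int j = 0; j < C; ++j) {
                int gi = st.g[i], gj = st.g[R + j];
                if ((gi == x && gj == y) || (gi == y && gj == x))
                  dS += B[(size_t)i * C + j];
              }
            if (dS >= 0 || U(rng) < std::exp(dS / m / T)) {
              for (int v = 0; v < N; ++v) if (st.g[v] == y) st.g[v] = x;
              applied = true;
            }
          }
        } else if (labels.size() >= 1) {
          // split a module by a random bisection
          int x = labels[(int)(U(rng) * labels.size())];
          members.clear();
          for (int v = 0; v < N; ++v) if (st.g[v] == x) members.push_back(v);
          if (members.size() >= 2) {
            int z = -1;
            {
              std::vector<char> used(N, 0);
              for (int v = 0; v < N; ++v) used[st.g[v]] = 1;
              for (int l = 0; l < N; ++l) if (!used[l]) { z = l; break; }
            }
            if (z >= 0) {
              std::vector<char> flip(members.size(), 0);
              for (size_t k = 0; k < members.size(); ++k) flip[k] = U(rng) < 0.5;
              // loss: within-module pairs split across the bisection
              for (size_t ki = 0; ki < members.size(); ++ki) {
                int vi = members[ki];
                if (vi >= R) continue;
                for (size_t kj = 0; kj < members.size(); ++kj) {
                  int vj = members[kj];
                  if (vj < R) continue;
                  if (flip[ki] != flip[kj])
                    dS -= B[(size_t)vi * C + (vj - R)];
                }
              }
              if (dS >= 0 || U(rng) < std::exp(dS / m / T)) {
                for (size_t k = 0; k < members.size(); ++k)
                  if (flip[k]) st.g[members[k]] = z;
                applied = true;
              }
            }
          }
        }
      }
      if (applied) st.S += dS;
      if (st.S > chain_best_S + 1e-12) {
        chain_best_S = st.S;
        chain_best = st.g;
        stall = 0;
      } else {
        ++stall;
      }
      ++iter;
      if (iter % N == 0) T *= cooling;
      if (T < 1e-10) T = 1e-10;
    }
    if (!have_best || chain_best_S > best_S + 1e-12) {
      best_S = chain_best_S;
      best_g = chain_best;
      have_best = true;
    }
  }

  // canonicalise labels to 0..K-1 in order of first appearance
  std::vector<int> map(N, -1);
  int next = 0;
  IntegerVector hm(R), pm(C);
  for (int v = 0; v < N; ++v) {
    int l = best_g[v];
    if (map[l] < 0) map[l] = next++;
    if (v < R) hm[v] = map[l]; else pm[v - R] = map[l];
  }
  return List::create(_["host_module"] = hm, _["parasitoid_module"] = pm,
                      _["q"] = best_S / m);
}

// Integer matrix with the given marginals that is close to the
// independence expectation r_i c_j / m: largest-remainder rounding of
// the expectation, then marginal repair by entropy-maximising unit
// moves (within columns to fix rows, then within rows to fix columns).
// [[Rcpp::export]]
NumericMatrix h2_max_matrix_cpp(NumericVector r, NumericVector c) {
  int R = r.size(), C = c.size();
  double m = 0;
  for (int i = 0; i < R; ++i) m += r[i];
  NumericMatrix A(R, C);
  std::vector<double> rem((size_t)R * C);
  double placed = 0;
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < C; ++j) {
      double e = r[i] * c[j] / m;
      double f = std::floor(e + 1e-12);
      A(i, j) = f;
      rem[(size_t)i * C + j] = e - f;
      placed += f;
    }
  int shortfall = (int)std::lround(m - placed);
  if (shortfall > 0) {
    std::vector<size_t> idx(rem.size());
    for (size_t k = 0; k < idx.size(); ++k) idx[k] = k;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](size_t a, size_t b) { return rem[a] > rem[b]; });
    for (int k = 0; k < shortfall; ++k)
      A(idx[k] / C, idx[k] % C) += 1;
  }
  // repair row totals by moving units within a column
  std::vector<double> dr(R, 0.0), dc(C, 0.0);
  auto recompute = [&]() {
    std::fill(dr.begin(), dr.end(), 0.0);
    std::fill(dc.begin(), dc.end(), 0.0);
    for (int i = 0; i < R; ++i)
      for (int j = 0; j < C; ++j) { dr[i] += A(i, j); dc[j] += A(i, j); }
    for (int i = 0; i < R; ++i) dr[i] -= r[i];
    for (int j = 0; j < C; ++j) dc[j] -= c[j];
  };
  recompute();
  bool more = true;
  while (more) {
    more = false;
    int bio = -1, biu = -1, bj = -1;
    double bdelta = 1e300;
    for (int io = 0; io < R; ++io) {
      if (dr[io] <= 0.5) continue;
      for (int iu = 0; iu < R; ++iu) {
        if (dr[iu] >= -0.5) continue;
        for (int j = 0; j < C; ++j) {
          if (A(io, j) < 0.5) continue;
          double d = xlx(A(io, j) - 1) - xlx(A(io, j)) +
                     xlx(A(iu, j) + 1) - xlx(A(iu, j));
          if (d < bdelta) { bdelta = d; bio = io; biu = iu; bj = j; }
        }
      }
    }
    if (bio >= 0) {
      A(bio, bj) -= 1; A(biu, bj) += 1;
      dr[bio] -= 1; dr[biu] += 1;
      more = true;
    }
  }
  // repair column totals by moving units within a row (rows stay fixed)
  recompute();
  more = true;
  while (more) {
    more = false;
    int bi = -1, bjo = -1, bju = -1;
    double bdelta = 1e300;
    for (int jo = 0; jo < C; ++jo) {
      if (dc[jo] <= 0.5) continue;
      for (int ju = 0; ju < C; ++ju) {
        if (dc[ju] >= -0.5) continue;
        for (int i = 0; i < R; ++i) {
          if (A(i, jo) < 0.5) continue;
          double d = xlx(A(i, jo) - 1) - xlx(A(i, jo)) +
                     xlx(A(i, ju) + 1) - xlx(A(i, ju));
          if (d < bdelta) { bdelta = d; bi = i; bjo = jo; bju = ju; }
        }
      }
    }
    if (bi >= 0) {
      A(bi, bjo) -= 1; A(bi, bju) += 1;
      dc[bjo] -= 1; dc[bju] += 1;
      more = true;
    }
  }
  return A;
}
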