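#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maximisation of weighted bipartite (Barber) modularity
//   Q = (1/F) * sum_ij [a_ij - k_i d_j / F] * delta(m_row(i), m_col(j))
// State: a joint module label per node (P rows then B columns).
//
// Search = best of (a) a deterministic greedy agglomeration from singletons
// (best positive-gain merge first) and (b) n_runs simulated-annealing runs
// (single-node reassignments + module merges, geometric cooling). Every
// candidate is polished by a hill-climb to a local optimum, and single-sided
// leftover modules are folded in by zero-loss merges so reported modules are
// joint plant-bacterium groups. Uses R's RNG: reproducible via set.seed().

namespace {

struct WebState {
  int P, B, M;
  double F;
  const NumericMatrix &a;
  std::vector<double> k, d;        // row / column totals
  std::vector<int> mod;            // node -> module label (size P+B)
  std::vector<double> rowA;        // P x M: weight of row i into cols of m
  std::vector<double> colA;        // B x M: weight of col j into rows of m
  std::vector<double> Ksum, Dsum;  // per-module row/col marginal sums
  double Q;

  explicit WebState(const NumericMatrix &a_) : a(a_) {
    P = a.nrow(); B = a.ncol(); M = P + B;
    k.assign(P, 0.0); d.assign(B, 0.0); F = 0.0;
    for (int i = 0; i < P; ++i)
      for (int j = 0; j < B; ++j) { k[i] += a(i, j); d[j] += a(i, j); F += a(i, j); }
  }

  void set_labels(const std::vector<int> &labels) {
    mod = labels;
    rebuild();
  }

  void init_singletons() {
    mod.resize(M);
    for (int u = 0; u < M; ++u) mod[u] = u;
    rebuild();
  }

  void rebuild() {
    rowA.assign((size_t)P * M, 0.0);
    colA.assign((size_t)B * M, 0.0);
    Ksum.assign(M, 0.0); Dsum.assign(M, 0.0);
    for (int i = 0; i < P; ++i) Ksum[mod[i]] += k[i];
    for (int j = 0; j < B; ++j) Dsum[mod[P + j]] += d[j];
    for (int i = 0; i < P; ++i)
      for (int j = 0; j < B; ++j) {
        rowA[(size_t)i * M + mod[P + j]] += a(i, j);
        colA[(size_t)j * M + mod[i]] += a(i, j);
      }
    Q = 0.0;
    for (int i = 0; i < P; ++i)
      Q += rowA[(size_t)i * M + mod[i]] - k[i] * Dsum[mod[i]] / F;
    Q /= F;
  }

  double move_gain(int u, int m2) const {
    int m1 = mod[u];
    if (m1 == m2) return 0.0;
    if (u < P) {
      int i = u;
      return ((rowA[(size_t)i * M + m2] - k[i] * Dsum[m2] / F) -
              (rowA[(size_t)i * M + m1] - k[i] * Dsum[m1] / F)) / F;
    }
    int j = u - P;
    return ((colA[(size_t)j * M + m2] - d[j] * Ksum[m2] / F) -
            (colA[(size_t)j * M + m1] - d[j] * Ksum[m1] / F)) / F;
  }

  void apply_move(int u, int m2, double gain) {
    int m1 = mod[u];
    mod[u] = m2;
    if (u < P) {
      int i = u;
      Ksum[m1] -= k[i]; Ksum[m2] += k[i];
      for (int j = 0; j < B; ++j) {
        double w = a(i, j);
        if (w != 0.0) {
          colA[(size_t)j * M + m1] -= w;
          colA[(size_t)j * M + m2] += w;
        }
      }
    } else {
      int j = u - P;
      Dsum[m1] -= d[j]; Dsum[m2] += d[j];
      for (int i = 0; i < P; ++i) {
        double w = a(i, j);
        if (w != 0.0) {
          rowA[(size_t)i * M + m1] -= w;
          rowA[(size_t)i * M + m2] += w;
        }
      }
    }
    Q += gain;
  }

  double merge_gain(int m1, int m2) const {
    double cross = 0.0;
    for (int i = 0; i < P; ++i) {
      if (mod[i] == m1) cross += rowA[(size_t)i * M + m2] - k[i] * Dsum[m2] / F;
      else if (mod[i] == m2) cross += rowA[(size_t)i * M + m1] - k[i] * Dsum[m1] / F;
    }
    return cross / F;
  }

  void apply_merge(int m1, int m2, double gain) {
    for (int i = 0; i < P; ++i) {
      rowA[(size_t)i * M + m1] += rowA[(size_t)i * M + m2];
      rowA[(size_t)i * M + m2] = 0.0;
    }
    for (int j = 0; j < B; ++j) {
      colA[(size_t)j * M + m1] += colA[(size_t)j * M + m2];
      colA[(size_t)j * M + m2] = 0.0;
    }
    Ksum[m1] += Ksum[m2]; Ksum[m2] = 0.0;
    Dsum[m1] += Dsum[m2]; Dsum[m2] = 0.0;
    for (int u = 0; u < M; ++u) if (mod[u] == m2) mod[u] = m1;
    Q += gain;
  }

  // local optimum under single moves and positive merges
  void hill_climb() {
    bool improved = true;
    while (improved) {
      improved = false;
      for (int u = 0; u < M; ++u) {
        double bg = 0.0; int bm = -1;
        for (int m2 = 0; m2 < M; ++m2) {
          double g = move_gain(u, m2);
          if (g > bg + 1e-12) { bg = g; bm = m2; }
        }
        if (bm >= 0) { apply_move(u, bm, bg); improved = true; }
      }
      for (int u = 0; u < M; ++u)
        for (int v = u + 1; v < M; ++v) {
          int m1 = mod[u], m2 = mod[v];
          if (m1 == m2) continue;
          double g = merge_gain(m1, m2);
          if (g > 1e-12) { apply_merge(m1, m2, g); improved = true; }
        }
    }
  }

  // best positive-gain merge first, from the current state
  void greedy_agglomerate() {
    for (;;) {
      double best = 1e-12; int bm1 = -1, bm2 = -1;
      std::vector<char> used(M, 0);
      for (int u = 0; u < M; ++u) used[mod[u]] = 1;
      for (int m1 = 0; m1 < M; ++m1) {
        if (!used[m1]) continue;
        for (int m2 = m1 + 1; m2 < M; ++m2) {
          if (!used[m2]) continue;
          double g = merge_gain(m1, m2);
          if (g > best) { best = g; bm1 = m1; bm2 = m2; }
        }
      }
      if (bm1 < 0) break;
      apply_merge(bm1, bm2, best);
    }
  }

  // fold modules lacking one side into their best partner at zero Q loss,
  // so every reported module is a joint plant-bacterium group
  void absorb_single_sided() {
    for (;;) {
      std::vector<int> nrows(M, 0), ncols(M, 0);
      for (int i = 0; i < P; ++i) nrows[mod[i]]++;
      for (int j = 0; j < B; ++j) ncols[mod[P + j]]++;
      int src = -1;
      for (int m = 0; m < M; ++m) {
        if ((nrows[m] + ncols[m]) > 0 && (nrows[m] == 0 || ncols[m] == 0)) {
          src = m; break;
        }
      }
      if (src < 0) break;
      double best = -1e-12; int tgt = -1;
      for (int m = 0; m < M; ++m) {
        if (m == src || (nrows[m] + ncols[m]) == 0) continue;
        double g = merge_gain(src, m);
        if (g > best) { best = g; tgt = m; }
      }
      if (tgt < 0 || best < -1e-12) break;
      apply_merge(src, tgt, best);
    }
  }
};

int runif_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

} // namespace

// [[Rcpp::export]]
List anneal_modules(NumericMatrix a, int n_runs, int n_steps,
                    double cooling = 0.999, double merge_prob = 0.15) {
  WebState st(a);
  int M = st.M;

  // deterministic baseline: greedy agglomeration + polish
  st.init_singletons();
  st.greedy_agglomerate();
  st.hill_climb();
  double best_Q = st.Q;
  std::vector<int> best_mod = st.mod;

  for (int run = 0; run < n_runs; ++run) {
    st.init_singletons();
    double run_best = st.Q;
    std::vector<int> run_best_mod = st.mod;

    // initial temperature from the spread of candidate single-move gains
    double t0 = 0.0;
    int probes = 50;
    for (int p = 0; p < probes; ++p) {
      int u = runif_int(M), m2 = runif_int(M);
      t0 += std::fabs(st.move_gain(u, m2));
    }
    double T = std::max(t0 / probes, 1e-4);
    int batch = std::max(M, 1);

    for (int step = 0; step < n_steps; ++step) {
      if (unif_rand() < merge_prob) {
        int u = runif_int(M), v = runif_int(M);
        int m1 = st.mod[u], m2 = st.mod[v];
        if (m1 != m2) {
          double g = st.merge_gain(m1, m2);
          if (g >= 0 || unif_rand() < std::exp(g / T)) st.apply_merge(m1, m2, g);
        }
      } else {
        int u = runif_int(M), m2 = runif_int(M);
        if (st.mod[u] != m2) {
          double g = st.move_gain(u, m2);
          if (g >= 0 || unif_rand() < std::exp(g / T)) st.apply_move(u, m2, g);
        }
      }
      if (st.Q > run_best + 1e-12) {
        run_best = st.Q;
        run_best_mod = st.mod;
      }
      if ((step + 1) % batch == 0) T *= cooling;
    }
    st.set_labels(run_best_mod);
    st.hill_climb();
    if (st.Q > best_Q + 1e-12) {
      best_Q = st.Q;
      best_mod = st.mod;
    }
  }

  st.set_labels(best_mod);
  st.absorb_single_sided();
  return List::create(_["labels"] = IntegerVector(st.mod.begin(), st.mod.end()),
                      _["Q"] = st.Q);
}
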