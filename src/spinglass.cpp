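// Signed Spinglass community detection: simulated annealing on the Potts
// Hamiltonian with separate configuration-model null terms for positive and
// negative edge weight. Deterministic given the seed (own mt19937, not R's
// RNG stream).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Coupling matrix a_ij = (w+_ij - gp * p+_ij) - (w-_ij - gn * p-_ij);
// H(sigma) = -sum_{i<j} a_ij * [sigma_i == sigma_j].
static std::vector<double> coupling(const NumericMatrix& w, double gp,
                                    double gn) {
  int n = w.nrow();
  std::vector<double> sp(n, 0.0), sn(n, 0.0);
  double mp = 0.0, mn = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double v = w(i, j);
      if (v > 0) sp[i] += v; else sn[i] += -v;
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = w(i, j);
      if (v > 0) mp += v; else mn += -v;
    }
  }
  std::vector<double> a((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double v = w(i, j);
      double wp = v > 0 ? v : 0.0;
      double wn = v < 0 ? -v : 0.0;
      double pp = mp > 0 ? sp[i] * sp[j] / (2.0 * mp) : 0.0;
      double pn = mn > 0 ? sn[i] * sn[j] / (2.0 * mn) : 0.0;
      a[(size_t)i * n + j] = (wp - gp * pp) - (wn - gn * pn);
    }
  }
  return a;
}

static double energy(const std::vector<double>& a, const std::vector<int>& s,
                     int n) {
  double h = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (s[i] == s[j]) h -= a[(size_t)i * n + j];
  return h;
}

// [[Rcpp::export]]
List spinglass_anneal_cpp(NumericMatrix w, double gamma_pos, double gamma_neg,
                          int n_spins, int seed, double t_start, double t_end,
                          double cooling, int sweeps_per_temp, int restarts) {
  int n = w.nrow();
  std::vector<double> a = coupling(w, gamma_pos, gamma_neg);
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> s(n), best_s(n);
  double best_h = R_PosInf;
  std::vector<double> field(n_spins);
  std::vector<double> prob(n_spins);

  auto local_field = [&](int i) {
    // field[k] = sum over j != i in community k of a_ij; placing i in k
    // changes H by -field[k]
    std::fill(field.begin(), field.end(), 0.0);
    for (int j = 0; j < n; ++j)
      if (j != i) field[s[j]] += a[(size_t)i * n + j];
  };

  for (int run = 0; run < restarts; ++run) {
    for (int i = 0; i < n; ++i)
      s[i] = (int)(unif(rng) * n_spins) % n_spins;

    // heat-bath annealing with geometric cooling
    for (double t = t_start; t > t_end; t *= cooling) {
      for (int sweep = 0; sweep < sweeps_per_temp; ++sweep) {
        for (int i = 0; i < n; ++i) {
          local_field(i);
          double fmax = field[0];
          for (int k = 1; k < n_spins; ++k) fmax = std::max(fmax, field[k]);
          double z = 0.0;
          for (int k = 0; k < n_spins; ++k) {
            prob[k] = std::exp((field[k] - fmax) / t);
            z += prob[k];
          }
          double u = unif(rng) * z;
          int pick = n_spins - 1;
          double acc = 0.0;
          for (int k = 0; k < n_spins; ++k) {
            acc += prob[k];
            if (u <= acc) { pick = k; break; }
          }
          s[i] = pick;
        }
      }
    }

    // zero-temperature descent to the nearest local optimum
    bool moved = true;
    int guard = 0;
    while (moved && guard++ < 1000) {
      moved = false;
      for (int i = 0; i < n; ++i) {
        local_field(i);
        int best = 0;
        for (int k = 1; k < n_spins; ++k)
          if (field[k] > field[best] + 1e-12) best = k;
        if (best != s[i] && field[best] > field[s[i]] + 1e-12) {
          s[i] = best;
          moved = true;
        }
      }
    }

    double h = energy(a, s, n);
    if (h < best_h - 1e-12) {
      best_h = h;
      best_s = s;
    }
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best_s[i];
  return List::create(_["assignment"] = out, _["hamiltonian"] = best_h);
}
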