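#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// All randomness goes through R's RNG (unif_rand) so that set.seed() in R
// fully determines every draw, including inside the samplers.

static inline int runif_int(int k) {
  int v = static_cast<int>(unif_rand() * k);
  if (v >= k) v = k - 1;
  return v;
}

// Size of the leap set S(rank) = {max(1, rank-l), ..., min(m, rank+l)} \ {rank}.
static inline int leap_set_size(int rank, int l, int m) {
  return std::min(m, rank + l) - std::max(1, rank - l);
}

struct LSProp {
  int u;      // 0-based index of the moved element
  int r_old;  // its current rank
  int r_new;  // proposed rank
  double log_fwd;
  double log_bwd;
};

// Draw a leap-and-shift proposal for the rank vector rho (1-based ranks).
// The forward/backward masses sum the probability (1/m) * (1/|S|) over every
// generating (element, rank) pair: for a move of one step there are two such
// pairs (the moved element and the displaced one), otherwise exactly one.
static LSProp ls_propose(const std::vector<int>& rho, int l) {
  const int m = static_cast<int>(rho.size());
  LSProp p;
  p.u = runif_int(m);
  p.r_old = rho[p.u];
  const int lo = std::max(1, p.r_old - l);
  const int hi = std::min(m, p.r_old + l);
  int r = lo + runif_int(hi - lo);  // uniform over the window minus the current rank
  if (r >= p.r_old) r += 1;
  p.r_new = r;
  double pf = 1.0 / (m * static_cast<double>(leap_set_size(p.r_old, l, m)));
  double pb = 1.0 / (m * static_cast<double>(leap_set_size(p.r_new, l, m)));
  if (std::abs(p.r_old - p.r_new) == 1) {
    pf += 1.0 / (m * static_cast<double>(leap_set_size(p.r_new, l, m)));
    pb += 1.0 / (m * static_cast<double>(leap_set_size(p.r_old, l, m)));
  }
  p.log_fwd = std::log(pf);
  p.log_bwd = std::log(pb);
  return p;
}

// New rank of the element currently holding `rank` after the move (r_old -> r_new);
// returns `rank` itself when unaffected.
static inline int shifted_rank(int rank, int r_old, int r_new) {
  if (rank == r_old) return r_new;
  if (r_new > r_old && rank > r_old && rank <= r_new) return rank - 1;
  if (r_new < r_old && rank >= r_new && rank < r_old) return rank + 1;
  return rank;
}

// [[Rcpp::export(name = ".leap_and_shift_cpp")]]
List leap_and_shift_cpp(IntegerVector rho, int l) {
  const int m = rho.size();
  std::vector<int> cur(rho.begin(), rho.end());
  LSProp p = ls_propose(cur, l);
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = shifted_rank(cur[i], p.r_old, p.r_new);
  return List::create(_["rho_prime"] = out,
                      _["log_forward"] = p.log_fwd,
                      _["log_backward"] = p.log_bwd,
                      _["moved"] = p.u + 1,
                      _["rank_old"] = p.r_old,
                      _["rank_new"] = p.r_new);
}

// One Metropolis move of a Mallows(rho0, alpha) chain over rankings.
// R holds item ranks, pos the inverse (pos[rank-1] = item). Returns 1 on accept.
static int mallows_move(std::vector<int>& R, std::vector<int>& pos,
                        const std::vector<int>& rho0, double alpha, int l) {
  const int m = static_cast<int>(R.size());
  LSProp p = ls_propose(R, l);
  double delta = std::abs(p.r_new - rho0[p.u]) - std::abs(p.r_old - rho0[p.u]);
  if (p.r_new > p.r_old) {
    for (int q = p.r_old + 1; q <= p.r_new; ++q) {
      const int v = pos[q - 1];
      delta += std::abs(q - 1 - rho0[v]) - std::abs(q - rho0[v]);
    }
  } else {
    for (int q = p.r_new; q <= p.r_old - 1; ++q) {
      const int v = pos[q - 1];
      delta += std::abs(q + 1 - rho0[v]) - std::abs(q - rho0[v]);
    }
  }
  const double log_acc = p.log_bwd - p.log_fwd - (alpha / m) * delta;
  if (log_acc < 0.0 && std::log(unif_rand()) >= log_acc) return 0;
  if (p.r_new > p.r_old) {
    for (int q = p.r_old + 1; q <= p.r_new; ++q) {
      const int v = pos[q - 1];
      R[v] = q - 1;
      pos[q - 2] = v;
    }
  } else {
    for (int q = p.r_old - 1; q >= p.r_new; --q) {
      const int v = pos[q - 1];
      R[v] = q + 1;
      pos[q] = v;
    }
  }
  R[p.u] = p.r_new;
  pos[p.r_new - 1] = p.u;
  return 1;
}

static void random_permutation(std::vector<int>& R, std::vector<int>& pos) {
  const int m = static_cast<int>(R.size());
  std::vector<int> items(m);
  for (int i = 0; i < m; ++i) items[i] = i;
  for (int i = m - 1; i > 0; --i) std::swap(items[i], items[runif_int(i + 1)]);
  for (int r = 0; r < m; ++r) {
    pos[r] = items[r];
    R[items[r]] = r + 1;
  }
}

// [[Rcpp::export(name = ".sample_mallows_cpp")]]
IntegerMatrix sample_mallows_cpp(IntegerVector rho0, double alpha, int count,
                                 int burnin, int thin, int l, bool random_init) {
  const int m = rho0.size();
  IntegerMatrix out(count, m);
  if (m == 1) {
    std::fill(out.begin(), out.end(), 1);
    return out;
  }
  std::vector<int> target(rho0.begin(), rho0.end());
  std::vector<int> R(m), pos(m);
  if (random_init) {
    random_permutation(R, pos);
  } else {
    for (int i = 0; i < m; ++i) {
      R[i] = target[i];
      pos[target[i] - 1] = i;
    }
  }
  for (int k = 0; k < count; ++k) {
    const int moves = (k == 0) ? burnin : thin;
    for (int t = 0; t < moves; ++t) {
      // lazy step: a small hold probability makes the chain aperiodic even
      // when every proposal would be accepted (at alpha ~ 0 with l = 1 all
      // moves are parity-flipping adjacent swaps, so a non-lazy chain cycles
      // between the parity classes deterministically)
      if (unif_rand() < 0.1) continue;
      mallows_move(R, pos, target, alpha, l);
    }
    for (int i = 0; i < m; ++i) out(k, i) = R[i];
  }
  return out;
}

// Observed ranks of row j of the data on the items in aset. The subset
// distance d_{A*}(R_j, rho) compares these raw ranks with the consensus
// ranks 1..n_star directly: items of the selected subset are rewarded for
// occupying the absolute rank that the consensus assigns them, and items
// parked far down the full ranking are penalised even when their relative
// order happens to be consistent.
static void subset_ranks(const IntegerMatrix& data, int j,
                         const std::vector<int>& aset, std::vector<int>& rst) {
  const int ns = static_cast<int>(aset.size());
  for (int k = 0; k < ns; ++k) rst[k] = data(j, aset[k]);
}

// Two-block MH sampler for the lower-dimensional Bayesian Mallows model.
// data: N x n matrix of complete rankings (rows are permutations of 1..n).
// Returns post-burn-in, thinned samples of (rho, A*) plus acceptance rates.
// [[Rcpp::export(name = ".run_lowbmm_cpp")]]
List run_lowbmm_cpp(IntegerMatrix data, int n_star, double alpha,
                    int leap_l, int swap_L, int iterations, int burnin, int thin,
                    IntegerVector init_aset, IntegerVector init_rho) {
  const int N = data.nrow();
  const int n = data.ncol();
  const int ns = n_star;

  // initial state: either the caller-supplied (data-informed) state, or a
  // uniform random subset and consensus
  std::vector<int> aset, notin;
  std::vector<int> rho(ns);
  if (init_aset.size() == ns) {
    std::vector<bool> in_set(n, false);
    for (int k = 0; k < ns; ++k) {
      aset.push_back(init_aset[k] - 1);
      in_set[init_aset[k] - 1] = true;
      rho[k] = init_rho[k];
    }
    for (int i = 0; i < n; ++i) if (!in_set[i]) notin.push_back(i);
  } else {
    std::vector<int> items(n);
    for (int i = 0; i < n; ++i) items[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(items[i], items[runif_int(i + 1)]);
    aset.assign(items.begin(), items.begin() + ns);
    notin.assign(items.begin() + ns, items.end());
    std::vector<int> rho_pos(ns);
    random_permutation(rho, rho_pos);
  }

  std::vector<int> buf(ns);
  std::vector<int> rst(static_cast<size_t>(N) * ns);
  for (int j = 0; j < N; ++j) {
    subset_ranks(data, j, aset, buf);
    std::copy(buf.begin(), buf.end(), rst.begin() + static_cast<size_t>(j) * ns);
  }
  double D = 0.0;
  for (int j = 0; j < N; ++j)
    for (int k = 0; k < ns; ++k)
      D += std::abs(rst[static_cast<size_t>(j) * ns + k] - rho[k]);

  const int n_keep = (iterations > burnin) ? (iterations - burnin) / thin : 0;
  IntegerMatrix rho_out(n_keep, ns), aset_out(n_keep, ns);
  long acc_rho = 0, acc_set = 0;
  int kept = 0;

  std::vector<int> aset2(ns), rho2(ns);
  std::vector<int> rst2(static_cast<size_t>(N) * ns);
  std::vector<int> outpos(swap_L), insel(swap_L), vac(swap_L);
  std::vector<int> posidx(ns), inidx(std::max(n - ns, 1));
  for (int k = 0; k < ns; ++k) posidx[k] = k;
  for (int k = 0; k < n - ns; ++k) inidx[k] = k;

  for (int iter = 1; iter <= iterations; ++iter) {
    // --- consensus update (leap-and-shift) ---
    if (ns >= 2) {
      LSProp p = ls_propose(rho, leap_l);
      double delta = 0.0;
      for (int k = 0; k < ns; ++k) {
        const int old_r = rho[k];
        const int new_r = shifted_rank(old_r, p.r_old, p.r_new);
        if (new_r == old_r) continue;
        for (int j = 0; j < N; ++j) {
          const int d = rst[static_cast<size_t>(j) * ns + k];
          delta += std::abs(d - new_r) - std::abs(d - old_r);
        }
      }
      const double log_acc = p.log_bwd - p.log_fwd - (alpha / ns) * delta;
      if (log_acc >= 0.0 || std::log(unif_rand()) < log_acc) {
        for (int k = 0; k < ns; ++k) rho[k] = shifted_rank(rho[k], p.r_old, p.r_new);
        D += delta;
        ++acc_rho;
      }
    }

    // --- subset update (swap L items, reassign the vacated ranks) ---
    if (ns < n) {
      for (int t = 0; t < swap_L; ++t) {
        std::swap(posidx[t], posidx[t + runif_int(ns - t)]);
        std::swap(inidx[t], inidx[t + runif_int(n - ns - t)]);
        outpos[t] = posidx[t];
        insel[t] = inidx[t];
      }
      std::copy(aset.begin(), aset.end(), aset2.begin());
      std::copy(rho.begin(), rho.end(), rho2.begin());
      for (int t = 0; t < swap_L; ++t) {
        aset2[outpos[t]] = notin[insel[t]];
        vac[t] = rho[outpos[t]];
      }
      for (int t = swap_L - 1; t > 0; --t) std::swap(vac[t], vac[runif_int(t + 1)]);
      for (int t = 0; t < swap_L; ++t) rho2[outpos[t]] = vac[t];

      double D2 = 0.0;
      for (int j = 0; j < N; ++j) {
        subset_ranks(data, j, aset2, buf);
        std::copy(buf.begin(), buf.end(), rst2.begin() + static_cast<size_t>(j) * ns);
        for (int k = 0; k < ns; ++k)
          D2 += std::abs(buf[k] - rho2[k]);
      }
      const double log_acc = -(alpha / ns) * (D2 - D);
      if (log_acc >= 0.0 || std::log(unif_rand()) < log_acc) {
        for (int t = 0; t < swap_L; ++t) notin[insel[t]] = aset[outpos[t]];
        aset.swap(aset2);
        rho.swap(rho2);
        rst.swap(rst2);
        D = D2;
        ++acc_set;
      }
    }

    if (iter > burnin && (iter - burnin) % thin == 0 && kept < n_keep) {
      for (int k = 0; k < ns; ++k) {
        rho_out(kept, k) = rho[k];
        aset_out(kept, k) = aset[k] + 1;
      }
      ++kept;
    }
  }

  return List::create(_["rho"] = rho_out,
                      _["aset"] = aset_out,
                      _["accept_rho"] = static_cast<double>(acc_rho) / iterations,
                      _["accept_set"] = (ns < n) ? static_cast<double>(acc_set) / iterations
                                                 : NA_REAL);
}
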