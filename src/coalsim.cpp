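#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Piecewise-exponential demographic trajectory, backward time in generations.
// Anchors (t_i, N_i), t_0 = 0; N(t) interpolates exponentially between
// consecutive anchors and is constant beyond the last one.
// Pair-coalescence rate at time t is 1 / (2 * N(t) * size_mult):
// 2*N*m gene copies (m = 1 diploid nuclear, m = 0.5 haploid maternal plastid).
// ---------------------------------------------------------------------------

struct Trajectory {
  std::vector<double> t, N, g; // g[i]: growth rate on [t_i, t_{i+1})
  double mult;                 // size multiplier m

  Trajectory(const std::vector<double>& at, const std::vector<double>& aN,
             double m) : t(at), N(aN), mult(m) {
    size_t k = t.size();
    g.resize(k, 0.0);
    for (size_t i = 0; i + 1 < k; ++i) {
      double dt = t[i + 1] - t[i];
      g[i] = (dt > 0.0) ? std::log(N[i + 1] / N[i]) / dt : 0.0;
    }
  }

  // integral of the pair rate over [a, b] within epoch i (a,b inside epoch)
  double epoch_integral(size_t i, double a, double b) const {
    double gi = g[i];
    double c = 2.0 * mult * N[i];
    if (std::fabs(gi) < 1e-12) return (b - a) / c;
    return (std::exp(-gi * (a - t[i])) - std::exp(-gi * (b - t[i]))) / (c * gi);
  }

  // solve, inside epoch i, for b such that integral over [a, b] equals w
  double epoch_solve(size_t i, double a, double w) const {
    double gi = g[i];
    double c = 2.0 * mult * N[i];
    if (std::fabs(gi) < 1e-12) return a + w * c;
    double rhs = std::exp(-gi * (a - t[i])) - c * gi * w;
    // caller guarantees the solution lies inside the epoch, so rhs > 0
    return t[i] - std::log(rhs) / gi;
  }

  // draw waiting time from 'from' for total exponential load 'target'
  // (target = E / C(k,2) with E ~ Exp(1))
  double wait(double from, double target) const {
    size_t k = t.size();
    double a = from;
    for (size_t i = 0; i + 1 < k; ++i) {
      if (t[i + 1] <= a) continue;
      double lo = std::max(a, t[i]);
      double avail = epoch_integral(i, lo, t[i + 1]);
      if (target <= avail) return epoch_solve(i, lo, target) - from;
      target -= avail;
    }
    // final, constant epoch
    double lo = std::max(a, t[k - 1]);
    return lo + target * 2.0 * mult * N[k - 1] - from;
  }
};

// ---------------------------------------------------------------------------
// HKY substitution model, uniformized for sparse event placement on trees.
// Codes 0=A, 1=C, 2=G, 3=T; transitions A<->G, C<->T.
// Rate matrix scaled so that the stationary mean substitution rate equals mu.
// ---------------------------------------------------------------------------

struct HKY {
  double R;                 // uniformization (dominating) event rate
  double P[4][4];           // jump-chain transition matrix (incl. self-loops)
  double cumP[4][4];
  double pi[4];

  HKY(double mu, double kappa, const double* freqs) {
    for (int i = 0; i < 4; ++i) pi[i] = freqs[i];
    int ti[4] = {2, 3, 0, 1}; // transition partner
    double q[4][4] = {{0}};
    double leave[4], mean = 0.0;
    for (int i = 0; i < 4; ++i) {
      leave[i] = 0.0;
      for (int j = 0; j < 4; ++j) {
        if (i == j) continue;
        q[i][j] = (j == ti[i] ? kappa : 1.0) * pi[j];
        leave[i] += q[i][j];
      }
      mean += pi[i] * leave[i];
    }
    double scale = mu / mean; // now mean substitution rate = mu
    R = 0.0;
    for (int i = 0; i < 4; ++i) {
      leave[i] *= scale;
      for (int j = 0; j < 4; ++j) q[i][j] *= scale;
      R = std::max(R, leave[i]);
    }
    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j < 4; ++j) P[i][j] = (i == j) ? 1.0 - leave[i] / R : q[i][j] / R;
      double c = 0.0;
      for (int j = 0; j < 4; ++j) { c += P[i][j]; cumP[i][j] = c; }
      cumP[i][3] = 1.0; // guard against rounding
    }
  }

  int jump(int s) const {
    double u = unif_rand();
    for (int j = 0; j < 3; ++j) if (u <= cumP[s][j]) return j;
    return 3;
  }

  int draw_root() const {
    double u = unif_rand(), c = 0.0;
    for (int j = 0; j < 3; ++j) { c += pi[j]; if (u <= c) return j; }
    return 3;
  }
};

// ---------------------------------------------------------------------------
// Coalescent tree: nodes 0..n-1 tips (time 0), n..2n-2 internal.
// ---------------------------------------------------------------------------

struct Tree {
  int n;
  std::vector<int> parent;        // -1 for root
  std::vector<double> time;       // node times (backward)
  std::vector<double> blen;       // branch above node
  std::vector<int> left, right;   // children of internal nodes (index - n)

  double total_length() const {
    double s = 0.0;
    for (int i = 0; i < 2 * n - 2; ++i) s += blen[i];
    return s;
  }
};

static Tree simulate_tree(int n, const Trajectory& traj) {
  Tree tr;
  tr.n = n;
  int tot = 2 * n - 1;
  tr.parent.assign(tot, -1);
  tr.time.assign(tot, 0.0);
  tr.blen.assign(tot, 0.0);
  tr.left.assign(n - 1, -1);
  tr.right.assign(n - 1, -1);

  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int next = n;
  for (int k = n; k >= 2; --k) {
    double pairs = 0.5 * k * (k - 1);
    double target = exp_rand() / pairs;
    t += traj.wait(t, target);
    int ia = (int)(unif_rand() * k); if (ia == k) ia = k - 1;
    int ib = (int)(unif_rand() * (k - 1)); if (ib == k - 1) ib = k - 2;
    if (ib >= ia) ++ib;
    int a = active[ia], b = active[ib];
    tr.time[next] = t;
    tr.parent[a] = next; tr.parent[b] = next;
    tr.blen[a] = t - tr.time[a];
    tr.blen[b] = t - tr.time[b];
    tr.left[next - n] = a; tr.right[next - n] = b;
    // replace a by new node, remove b
    active[ia] = next;
    active[ib] = active[k - 1];
    active.pop_back();
    ++next;
  }
  return tr;
}

// ---------------------------------------------------------------------------
// Sparse HKY mutation: Poisson(T * R * L) candidate events, per-site
// jump-chain evolution down the tree. Returns tip states at hit sites.
// ---------------------------------------------------------------------------

struct MutResult {
  std::vector<int> sites;                    // 0-based positions (sorted)
  std::vector<int> anc;                      // root state at each hit site
  std::vector<std::vector<uint8_t>> cols;    // tip states per hit site
};

static MutResult mutate_on_tree(const Tree& tr, const HKY& hky, int L) {
  int n = tr.n;
  int nb = 2 * n - 2; // branch above each non-root node
  std::vector<double> cum(nb);
  double s = 0.0;
  for (int i = 0; i < nb; ++i) { s += tr.blen[i]; cum[i] = s; }
  double T = s;

  int M = (int)R::rpois(T * hky.R * L);
  // events grouped per site: (node, height fraction along branch)
  // height measured backward from the node upward; applying root->tip means
  // larger height first.
  std::vector<int> ev_site(M), ev_node(M);
  std::vector<double> ev_h(M);
  for (int e = 0; e < M; ++e) {
    double u = unif_rand() * T;
    int b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (b >= nb) b = nb - 1;
    ev_node[e] = b;
    ev_h[e] = unif_rand(); // fraction along branch, 0 = node end
    int site = (int)(unif_rand() * L); if (site == L) site = L - 1;
    ev_site[e] = site;
  }
  // group events by site
  std::vector<int> order(M);
  for (int e = 0; e < M; ++e) order[e] = e;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return ev_site[a] < ev_site[b]; });

  MutResult res;
  std::vector<uint8_t> state(2 * n - 1);
  std::vector<std::vector<std::pair<double,int>>> per_node(2 * n - 1);

  int idx = 0;
  while (idx < M) {
    int site = ev_site[order[idx]];
    int j = idx;
    while (j < M && ev_site[order[j]] == site) ++j;
    // collect events for this site
    std::vector<int> touched;
    for (int k = idx; k < j; ++k) {
      int nd = ev_node[order[k]];
      if (per_node[nd].empty()) touched.push_back(nd);
      per_node[nd].push_back({ev_h[order[k]], k});
    }
    for (int nd : touched)
      std::sort(per_node[nd].begin(), per_node[nd].end(),
                [](const std::pair<double,int>& a, const std::pair<double,int>& b) {
                  return a.first > b.first; // top of branch first
                });
    // evolve down the tree (iterative preorder from root)
    int root = 2 * n - 2;
    state[root] = (uint8_t)hky.draw_root();
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      if (nd != root) {
        int st = state[tr.parent[nd]];
        for (auto& pr : per_node[nd]) st = hky.jump(st);
        state[nd] = (uint8_t)st;
      }
      if (nd >= n) {
        stack.push_back(tr.left[nd - n]);
        stack.push_back(tr.right[nd - n]);
      }
    }
    // record if segregating (or keep all hit sites; caller filters)
    uint8_t first = state[0];
    bool seg = false;
    for (int i = 1; i < n; ++i) if (state[i] != first) { seg = true; break; }
    if (seg) {
      res.sites.push_back(site);
      res.anc.push_back(state[root]);
      res.cols.emplace_back(state.begin(), state.begin() + n);
    }
    for (int nd : touched) per_node[nd].clear();
    idx = j;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Summary statistics from segregating-site columns.
// Order: VPD, TajD, PSS, MNS, VNS  (variance of pairwise differences,
// Tajima's D, singleton/private segregating sites, mean and variance of the
// rarest-nucleotide count over segregating sites).  S = 0 => all zero.
// ---------------------------------------------------------------------------

static std::array<double,5> five_stats(const std::vector<std::vector<uint8_t>>& cols,
                                       int n) {
  std::array<double,5> out = {0, 0, 0, 0, 0};
  int S = (int)cols.size();
  if (S == 0 || n < 2) return out;

  double P = 0.5 * (double)n * (n - 1);
  double sum_h = 0.0; // expected: sum over sites of pairs differing
  int pss = 0;
  double mns_sum = 0.0, mns_sq = 0.0;
  for (int s = 0; s < S; ++s) {
    int cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) cnt[cols[s][i]]++;
    double same = 0.0;
    int rare = n;
    for (int a = 0; a < 4; ++a) {
      if (cnt[a] > 0) {
        same += 0.5 * (double)cnt[a] * (cnt[a] - 1);
        rare = std::min(rare, cnt[a]);
      }
    }
    sum_h += P - same;
    if (rare == 1) ++pss;
    mns_sum += rare; mns_sq += (double)rare * rare;
  }

  // pairwise difference counts via 2-bit packing
  int W = (S + 31) / 32;
  std::vector<uint64_t> pack((size_t)n * W, 0ULL);
  for (int s = 0; s < S; ++s) {
    int w = s >> 5, off = (s & 31) << 1;
    for (int i = 0; i < n; ++i)
      pack[(size_t)i * W + w] |= ((uint64_t)cols[s][i]) << off;
  }
  const uint64_t mask = 0x5555555555555555ULL;
  double sum_d = 0.0, sum_d2 = 0.0;
  for (int i = 0; i < n; ++i) {
    const uint64_t* pi_ = &pack[(size_t)i * W];
    for (int j = i + 1; j < n; ++j) {
      const uint64_t* pj = &pack[(size_t)j * W];
      int d = 0;
      for (int w = 0; w < W; ++w) {
        uint64_t x = pi_[w] ^ pj[w];
        d += __builtin_popcountll((x | (x >> 1)) & mask);
      }
      sum_d += d;
      sum_d2 += (double)d * d;
    }
  }
  double vpd = (P > 1) ? (sum_d2 - sum_d * sum_d / P) / (P - 1.0) : 0.0;
  double pi_tot = sum_d / P;

  // Tajima's D
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double varD = e1 * S + e2 * (double)S * (S - 1.0);
  double tajd = (varD > 0.0) ? (pi_tot - S / a1) / std::sqrt(varD) : 0.0;

  double mns = mns_sum / S;
  double vns = (S > 1) ? (mns_sq - mns_sum * mns_sum / S) / (S - 1.0) : 0.0;
  out[0] = vpd; out[1] = tajd; out[2] = pss; out[3] = mns; out[4] = vns;
  return out;
}

// [[Rcpp::export(name = ".locus_stats_cpp")]]
NumericVector locus_stats_cpp(IntegerMatrix seg) {
  int n = seg.nrow(), S = seg.ncol();
  std::vector<std::vector<uint8_t>> cols(S, std::vector<uint8_t>(n));
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i) cols[s][i] = (uint8_t)seg(i, s);
  std::array<double,5> st = five_stats(cols, n);
  NumericVector out(5);
  for (int k = 0; k < 5; ++k) out[k] = st[k];
  out.names() = CharacterVector::create("VPD", "TajD", "PSS", "MNS", "VNS");
  return out;
}

// [[Rcpp::export(name = ".sim_locus_cpp")]]
List sim_locus_cpp(int n, int L, NumericVector anchor_t, NumericVector anchor_N,
                   double size_mult, double mu, double kappa,
                   NumericVector freqs, bool full_seq) {
  RNGScope scope;
  Trajectory traj(std::vector<double>(anchor_t.begin(), anchor_t.end()),
                  std::vector<double>(anchor_N.begin(), anchor_N.end()),
                  size_mult);
  HKY hky(mu, kappa, &freqs[0]);
  if (n == 1) {
    // single lineage: no coalescence, no polymorphism
    IntegerMatrix seg(1, 0);
    List out = List::create(_["seg"] = seg,
                            _["pos"] = IntegerVector(0),
                            _["anc"] = IntegerVector(0),
                            _["tmrca"] = 0.0);
    if (full_seq) {
      IntegerMatrix full(1, L);
      for (int s = 0; s < L; ++s) full(0, s) = hky.draw_root();
      out["full"] = full;
    }
    return out;
  }
  Tree tr = simulate_tree(n, traj);
  MutResult mr = mutate_on_tree(tr, hky, L);
  int S = (int)mr.sites.size();
  IntegerMatrix seg(n, S);
  IntegerVector pos(S), anc(S);
  for (int s = 0; s < S; ++s) {
    pos[s] = mr.sites[s] + 1;
    anc[s] = mr.anc[s];
    for (int i = 0; i < n; ++i) seg(i, s) = mr.cols[s][i];
  }
  List out = List::create(_["seg"] = seg, _["pos"] = pos, _["anc"] = anc,
                          _["tmrca"] = tr.time[2 * n - 2]);
  if (full_seq) {
    IntegerMatrix full(n, L);
    std::vector<int> root_seq(L);
    for (int s = 0; s < L; ++s) root_seq[s] = hky.draw_root();
    for (int s = 0; s < S; ++s) root_seq[mr.sites[s]] = -1; // placeholder
    for (int s = 0; s < L; ++s)
      if (root_seq[s] >= 0)
        for (int i = 0; i < n; ++i) full(i, s) = root_seq[s];
    IntegerVector ancfull(L);
    for (int s = 0; s < L; ++s) ancfull[s] = root_seq[s];
    for (int s = 0; s < S; ++s) {
      ancfull[mr.sites[s]] = mr.anc[s];
      for (int i = 0; i < n; ++i) full(i, mr.sites[s]) = mr.cols[s][i];
    }
    out["full"] = full;
    out["anc_full"] = ancfull;
  }
  return out;
}

// Batch ABC path: one row of summary statistics per parameter draw.
// Locus design arrays are parallel; group 0 = plastid, 1 = nuclear.
// Output columns: plastid VPD TajD PSS MNS VNS, then nuclear ditto.
// [[Rcpp::export(name = ".abc_sim_stats_cpp")]]
NumericMatrix abc_sim_stats_cpp(NumericMatrix anchors_t, NumericMatrix anchors_N,
                                IntegerVector n_anchors,
                                NumericVector mu_cp, NumericVector mu_nr,
                                IntegerVector loc_n, IntegerVector loc_L,
                                NumericVector loc_mult, IntegerVector loc_group,
                                double kappa, NumericVector freqs) {
  RNGScope scope;
  int nsim = anchors_t.nrow();
  int nloc = loc_n.size();
  NumericMatrix out(nsim, 10);
  for (int r = 0; r < nsim; ++r) {
    int m = n_anchors[r];
    std::vector<double> at(m), aN(m);
    for (int i = 0; i < m; ++i) { at[i] = anchors_t(r, i); aN[i] = anchors_N(r, i); }
    double acc[2][5] = {{0}};
    int cntg[2] = {0, 0};
    for (int l = 0; l < nloc; ++l) {
      int grp = loc_group[l];
      double mu = (grp == 0) ? mu_cp[r] : mu_nr[r];
      Trajectory traj(at, aN, loc_mult[l]);
      HKY hky(mu, kappa, &freqs[0]);
      Tree tr = simulate_tree(loc_n[l], traj);
      MutResult mr = mutate_on_tree(tr, hky, loc_L[l]);
      std::array<double,5> st = five_stats(mr.cols, loc_n[l]);
      for (int k = 0; k < 5; ++k) acc[grp][k] += st[k];
      cntg[grp]++;
    }
    for (int g = 0; g < 2; ++g)
      for (int k = 0; k < 5; ++k)
        out(r, 5 * g + k) = cntg[g] ? acc[g][k] / cntg[g] : NA_REAL;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
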