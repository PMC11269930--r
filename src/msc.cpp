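// Multispecies-coalescent genealogy sampler with directional introgression
// pulses. One genealogy per window, no intra-window recombination. Uses R's
// RNG throughout so set.seed() on the R side makes batches reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Event {
  double time;
  int type;  // 0 = branch end (lineages move to parent), 1 = pulse
  int idx;   // branch id (type 0) or pulse row (type 1)
};

inline int pair_col(int i, int j, int n) {
  // 0-based column for unordered pair (i < j) in combn(n, 2) order
  return i * n - i * (i + 1) / 2 + (j - i) - 1;
}

}  // namespace

// branch_parent: length B, 0 for the root branch (ids are 1-based)
// branch_tend:   time each branch ends (R_PosInf for the root)
// branch_ne:     relative diploid Ne per branch (coalescence rate k(k-1)/2/ne)
// sample_branch: length n, terminal branch id of each haploid lineage
// pulse_time / pulse_donor / pulse_recip: one entry per pulse
// pulse_gamma:   n_pulse x W matrix of per-window effective admixture fractions
// mut_rate:      expected mutations per unit of total genealogy branch length
// [[Rcpp::export(name = ".sim_msc_batch")]]
List sim_msc_batch(IntegerVector branch_parent, NumericVector branch_tend,
                   NumericVector branch_ne, IntegerVector sample_branch,
                   NumericVector pulse_time, IntegerVector pulse_donor,
                   IntegerVector pulse_recip, NumericMatrix pulse_gamma,
                   int n_windows, double mut_rate, bool want_pair_times) {
  const int B = branch_parent.size();
  const int n = sample_branch.size();
  const int n_pulse = pulse_time.size();
  const int n_nodes = 2 * n - 1;
  const int n_pairs = n * (n - 1) / 2;
  if (n < 2) stop("need at least two haploid lineages");

  // fixed event schedule (pulse gammas vary per window, times do not)
  std::vector<Event> events;
  for (int b = 0; b < B; ++b)
    if (branch_parent[b] > 0) events.push_back({branch_tend[b], 0, b});
  for (int p = 0; p < n_pulse; ++p) events.push_back({pulse_time[p], 1, p});
  std::stable_sort(events.begin(), events.end(),
                   [](const Event& a, const Event& b) { return a.time < b.time; });
  events.push_back({R_PosInf, -1, -1});

  IntegerMatrix parents(n_nodes, n_windows);
  NumericMatrix heights(n_nodes, n_windows);
  LogicalVector introgressed(n_windows);
  NumericMatrix pair_times(want_pair_times ? n_windows : 1,
                           want_pair_times ? n_pairs : 1);
  std::vector<int> snp_window;
  std::vector<std::vector<char> > snp_rows;

  std::vector<int> lin_node(n), lin_branch(n);
  std::vector<double> height(n_nodes);
  std::vector<int> parent(n_nodes);
  std::vector<std::vector<int> > desc(n_nodes);
  std::vector<int> pool;  // scratch: lineage slots in current branch

  for (int w = 0; w < n_windows; ++w) {
    int n_act = n;
    for (int i = 0; i < n; ++i) {
      lin_node[i] = i;
      lin_branch[i] = sample_branch[i];
    }
    std::fill(height.begin(), height.end(), 0.0);
    std::fill(parent.begin(), parent.end(), 0);
    for (int i = 0; i < n_nodes; ++i) desc[i].clear();
    for (int i = 0; i < n; ++i) desc[i].push_back(i);
    int next_node = n;
    bool intro = false;
    double cur_t = 0.0;

    for (size_t e = 0; e < events.size() && n_act > 1; ++e) {
      const double t_end = events[e].time;
      // coalesce independently within each occupied branch on [cur_t, t_end)
      for (int b = 1; b <= B && n_act > 1; ++b) {
        pool.clear();
        for (int i = 0; i < n_act; ++i)
          if (lin_branch[i] == b) pool.push_back(i);
        int k = (int)pool.size();
        if (k < 2) continue;
        double t = cur_t;
        const double ne = branch_ne[b - 1];
        while (k >= 2) {
          t += exp_rand() * (2.0 * ne) / ((double)k * (k - 1));
          if (t >= t_end) break;
          int a = (int)(unif_rand() * k); if (a == k) a = k - 1;
          int c = (int)(unif_rand() * (k - 1)); if (c == k - 1) c = k - 2;
          if (c >= a) ++c;
          const int sa = pool[a], sc = pool[c];
          const int m = next_node++;
          parent[lin_node[sa]] = m + 1;  // 1-based in output
          parent[lin_node[sc]] = m + 1;
          height[m] = t;
          desc[m] = desc[lin_node[sa]];
          desc[m].insert(desc[m].end(), desc[lin_node[sc]].begin(),
                         desc[lin_node[sc]].end());
          lin_node[sa] = m;
          // drop lineage slot sc (swap with the last active lineage)
          lin_node[sc] = lin_node[n_act - 1];
          lin_branch[sc] = lin_branch[n_act - 1];
          --n_act;
          // rebuild pool for this branch
          pool.clear();
          for (int i = 0; i < n_act; ++i)
            if (lin_branch[i] == b) pool.push_back(i);
          k = (int)pool.size();
        }
      }
      if (events[e].type == 0) {
        const int b = events[e].idx;  // 0-based branch index
        for (int i = 0; i < n_act; ++i)
          if (lin_branch[i] == b + 1) lin_branch[i] = branch_parent[b];
      } else if (events[e].type == 1) {
        const int p = events[e].idx;
        const double g = pulse_gamma(p, w);
        if (g > 0) {
          for (int i = 0; i < n_act; ++i)
            if (lin_branch[i] == pulse_recip[p] && unif_rand() < g) {
              lin_branch[i] = pulse_donor[p];
              intro = true;
            }
        }
      }
      cur_t = std::max(cur_t, events[e].type == -1 ? cur_t : t_end);
    }
    introgressed[w] = intro;

    for (int i = 0; i < n_nodes; ++i) {
      parents(i, w) = parent[i];
      heights(i, w) = height[i];
    }
    if (want_pair_times) {
      for (int m = n; m < n_nodes; ++m) {
        // pairs first joined at node m: one leaf from each child clade
        // children of m carry disjoint desc sets; identify via parent ptrs
        std::vector<int> kids;
        for (int c = 0; c < m; ++c)
          if (parent[c] == m + 1) kids.push_back(c);
        for (size_t u = 0; u + 1 < kids.size(); ++u)
          for (size_t v = u + 1; v < kids.size(); ++v)
            for (int a : desc[kids[u]])
              for (int bb : desc[kids[v]]) {
                int i = std::min(a, bb), j = std::max(a, bb);
                pair_times(w, pair_col(i, j, n)) = height[m];
              }
      }
    }
    if (mut_rate > 0) {
      double total = 0.0;
      std::vector<double> elen(n_nodes, 0.0);
      for (int c = 0; c < n_nodes; ++c)
        if (parent[c] > 0) {
          elen[c] = height[parent[c] - 1] - height[c];
          total += elen[c];
        }
      const int nmut = (int)R::rpois(mut_rate * total);
      for (int mu = 0; mu < nmut; ++mu) {
        double u = unif_rand() * total, acc = 0.0;
        int edge = -1;
        for (int c = 0; c < n_nodes; ++c) {
          if (elen[c] <= 0) continue;
          acc += elen[c];
          if (u <= acc) { edge = c; break; }
        }
        if (edge < 0) continue;
        std::vector<char> row(n, 0);
        for (int a : desc[edge]) row[a] = 1;
        // skip mutations fixed in the whole sample (not polymorphic)
        if ((int)desc[edge].size() == n) continue;
        snp_window.push_back(w + 1);
        snp_rows.push_back(row);
      }
    }
  }

  const int S = (int)snp_window.size();
  IntegerMatrix carriers(S, n);
  IntegerVector sw(S);
  for (int s = 0; s < S; ++s) {
    sw[s] = snp_window[s];
    for (int i = 0; i < n; ++i) carriers(s, i) = snp_rows[s][i];
  }
  return List::create(_["parents"] = parents, _["heights"] = heights,
                      _["introgressed"] = introgressed,
                      _["pair_times"] = pair_times, _["snp_window"] = sw,
                      _["snp_carriers"] = carriers);
}
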