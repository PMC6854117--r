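// Structured-coalescent simulation engine.
//
// Time runs backward in generations; population sizes are haploid gene-copy
// counts; migration follows the backward (lineage-movement) convention:
// mig(i, j) is the per-generation probability that a lineage currently in
// deme i traces back to deme j.
//
// The engine is event-driven (Gillespie): competing exponentials for
// within-deme coalescence and migration, interrupted by deterministic
// demographic events (population fusion, size change, migration-matrix
// replacement). Mutations are Poisson on branch length under infinite
// sites.
//
// Randomness is self-contained (xoshiro256**, splitmix64-seeded) so that a
// master seed spawns one independent stream per region: changing the region
// count never reshuffles earlier regions, and results do not depend on R's
// global RNG state.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <unordered_set>

using namespace Rcpp;

namespace {

struct XRng {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit XRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5ULL, 7) * 9ULL;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on the open interval (0, 1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }

  double expo(double rate) { return -std::log(unif()) / rate; }

  int pois(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda > 30.0) return pois(lambda * 0.5) + pois(lambda * 0.5);
    const double L = std::exp(-lambda);
    double p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }

  int randint(int n) {  // uniform on 0..n-1
    int v = static_cast<int>(unif() * n);
    return v >= n ? n - 1 : v;
  }
};

// Child stream: region index folded into the master seed.
uint64_t child_seed(double master, uint64_t idx) {
  uint64_t x = (static_cast<uint64_t>(master) << 32) ^ (idx * 0x9E3779B97F4A7C15ULL);
  return XRng::splitmix(x);
}

struct Tree {
  // nodes 0..n_leaves-1 are leaves (pop-ordered); internal nodes appended
  std::vector<int> parent, lchild, rchild;
  std::vector<double> node_time;
  int n_leaves = 0;
};

struct EventTable {
  std::vector<double> time;
  std::vector<int> kind;  // 0 fusion, 1 size_change, 2 migration_change
  std::vector<int> a, b;  // fusion: source a -> sink b; size_change: pop a
  std::vector<double> size;
  List mig;  // per-event replacement matrix (R_NilValue when unused)
};

// Core genealogy simulation for one region.
Tree sim_tree(int P, std::vector<double> N, std::vector<double> M,
              const EventTable& ev, const std::vector<int>& samples,
              XRng& rng) {
  int k_total = 0;
  for (int i = 0; i < P; ++i) k_total += samples[i];
  if (k_total < 2) stop("need at least two sampled gene copies in total");

  Tree tr;
  tr.n_leaves = k_total;
  const int n_nodes = 2 * k_total - 1;
  tr.parent.assign(n_nodes, -1);
  tr.lchild.assign(n_nodes, -1);
  tr.rchild.assign(n_nodes, -1);
  tr.node_time.assign(n_nodes, 0.0);

  std::vector<std::vector<int>> deme(P);
  int leaf = 0;
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < samples[i]; ++j) deme[i].push_back(leaf++);

  std::vector<double> mig_out(P, 0.0);
  auto refresh_mig_out = [&]() {
    for (int i = 0; i < P; ++i) {
      double m = 0.0;
      for (int j = 0; j < P; ++j) if (j != i) m += M[i * P + j];
      mig_out[i] = m;
    }
  };
  refresh_mig_out();

  double t = 0.0;
  int next_node = k_total, e = 0, alive = k_total;
  const int n_ev = static_cast<int>(ev.time.size());

  while (alive > 1) {
    double coal_total = 0.0, mig_total = 0.0;
    for (int i = 0; i < P; ++i) {
      const double ki = static_cast<double>(deme[i].size());
      coal_total += ki * (ki - 1.0) * 0.5 / N[i];
      mig_total += ki * mig_out[i];
    }
    const double total = coal_total + mig_total;
    const double t_ev = (e < n_ev) ? ev.time[e] : R_PosInf;

    if (total <= 0.0 && !R_FINITE(t_ev))
      stop("lineages cannot fully coalesce: %d lineages remain with zero "
           "coalescence and migration rate and no further demographic events",
           alive);

    const double dt = (total > 0.0) ? rng.expo(total) : R_PosInf;

    if (t + dt >= t_ev) {  // apply the demographic event and continue
      t = t_ev;
      const int kind = ev.kind[e];
      if (kind == 0) {  // fusion: all lineages in source join sink
        const int src = ev.a[e], snk = ev.b[e];
        for (int id : deme[src]) deme[snk].push_back(id);
        deme[src].clear();
        for (int j = 0; j < P; ++j) { M[src * P + j] = 0.0; M[j * P + src] = 0.0; }
        refresh_mig_out();
      } else if (kind == 1) {  // size change
        N[ev.a[e]] = ev.size[e];
      } else {  // migration matrix replacement
        NumericMatrix nm = ev.mig[e];
        for (int i = 0; i < P; ++i)
          for (int j = 0; j < P; ++j) M[i * P + j] = nm(i, j);
        refresh_mig_out();
      }
      ++e;
      continue;
    }

    t += dt;
    double u = rng.unif() * total;
    if (u < coal_total) {  // coalescence: pick deme by rate, then a pair
      int i = 0;
      for (; i < P; ++i) {
        const double ki = static_cast<double>(deme[i].size());
        const double r = ki * (ki - 1.0) * 0.5 / N[i];
        if (u < r) break;
        u -= r;
      }
      if (i >= P) i = P - 1;
      const int ki = static_cast<int>(deme[i].size());
      int ia = rng.randint(ki);
      int ib = rng.randint(ki - 1);
      if (ib >= ia) ++ib;
      const int na = deme[i][ia], nb = deme[i][ib];
      const int m = next_node++;
      tr.parent[na] = m; tr.parent[nb] = m;
      tr.lchild[m] = na; tr.rchild[m] = nb;
      tr.node_time[m] = t;
      deme[i][ia] = m;
      deme[i][ib] = deme[i].back();
      deme[i].pop_back();
      --alive;
    } else {  // migration: pick source deme, lineage, destination
      u -= coal_total;
      int i = 0;
      for (; i < P; ++i) {
        const double r = static_cast<double>(deme[i].size()) * mig_out[i];
        if (u < r) break;
        u -= r;
      }
      if (i >= P) i = P - 1;
      const int il = rng.randint(static_cast<int>(deme[i].size()));
      double v = rng.unif() * mig_out[i];
      int j = -1;
      for (int jj = 0; jj < P; ++jj) {
        if (jj == i) continue;
        if (v < M[i * P + jj]) { j = jj; break; }
        v -= M[i * P + jj];
      }
      if (j < 0) { for (int jj = P - 1; jj >= 0; --jj) if (jj != i && M[i * P + jj] > 0) { j = jj; break; } }
      deme[j].push_back(deme[i][il]);
      deme[i][il] = deme[i].back();
      deme[i].pop_back();
    }
  }
  return tr;
}

// Collect the leaves below a node.
void leaves_below(const Tree& tr, int node, std::vector<int>& out) {
  std::vector<int> stack{node};
  while (!stack.empty()) {
    const int v = stack.back(); stack.pop_back();
    if (v < tr.n_leaves) { out.push_back(v); continue; }
    stack.push_back(tr.lchild[v]);
    stack.push_back(tr.rchild[v]);
  }
}

double total_branch_length(const Tree& tr, std::vector<double>& blen) {
  const int n_nodes = static_cast<int>(tr.parent.size());
  blen.assign(n_nodes, 0.0);
  double L = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (tr.parent[v] < 0) continue;  // root
    blen[v] = tr.node_time[tr.parent[v]] - tr.node_time[v];
    L += blen[v];
  }
  return L;
}

EventTable parse_events(const List& model) {
  EventTable ev;
  ev.time = as<std::vector<double>>(model["ev_time"]);
  ev.kind = as<std::vector<int>>(model["ev_kind"]);
  ev.a = as<std::vector<int>>(model["ev_a"]);
  ev.b = as<std::vector<int>>(model["ev_b"]);
  ev.size = as<std::vector<double>>(model["ev_size"]);
  ev.mig = model["ev_mig"];
  return ev;
}

}  // namespace

// Simulate n_regions independent non-recombining regions under a
// demographic model (already flattened on the R side). Returns either full
// haplotypes per region or per-site derived-allele counts per population.
// [[Rcpp::export]]
List sim_regions_cpp(List model, IntegerVector samples, int n_regions,
                     int region_length, double mu, double seed,
                     bool return_haplotypes) {
  const int P = as<int>(model["n_pops"]);
  std::vector<double> N0 = as<std::vector<double>>(model["sizes"]);
  NumericMatrix mig0 = model["migration"];
  std::vector<double> M0(P * P, 0.0);
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < P; ++j) M0[i * P + j] = mig0(i, j);
  EventTable ev = parse_events(model);
  std::vector<int> smp = as<std::vector<int>>(samples);
  int k_total = 0;
  for (int s : smp) k_total += s;

  List hap_out(return_haplotypes ? n_regions : 0);
  std::vector<int> cnt_flat;       // per-site derived count per pop
  std::vector<int> site_region;    // 1-based region index per site
  IntegerVector s_per_region(n_regions);

  std::vector<double> blen;
  std::vector<int> below;

  for (int r = 0; r < n_regions; ++r) {
    XRng rng(child_seed(seed, static_cast<uint64_t>(r)));
    Tree tr = sim_tree(P, N0, M0, ev, smp, rng);
    const double L = total_branch_length(tr, blen);

    int nmut = rng.pois(mu * region_length * L);
    if (nmut > region_length) nmut = region_length;  // infinite-sites guard

    // distinct positions, 1-based
    std::unordered_set<int> used;
    std::vector<int> pos(nmut);
    for (int m = 0; m < nmut; ++m) {
      int p;
      do { p = rng.randint(region_length) + 1; } while (used.count(p));
      used.insert(p);
      pos[m] = p;
    }
    // branch per mutation, probability proportional to length
    std::vector<int> mut_node(nmut);
    for (int m = 0; m < nmut; ++m) {
      double u = rng.unif() * L;
      int chosen = -1;
      for (size_t v = 0; v < blen.size(); ++v) {
        if (blen[v] <= 0.0) continue;
        if (u < blen[v]) { chosen = static_cast<int>(v); break; }
        u -= blen[v];
      }
      if (chosen < 0) for (int v = static_cast<int>(blen.size()) - 1; v >= 0; --v)
        if (blen[v] > 0.0) { chosen = v; break; }
      mut_node[m] = chosen;
    }
    // order sites by position
    std::vector<int> ord(nmut);
    for (int m = 0; m < nmut; ++m) ord[m] = m;
    std::sort(ord.begin(), ord.end(), [&](int x, int y) { return pos[x] < pos[y]; });

    s_per_region[r] = nmut;
    if (return_haplotypes) {
      IntegerMatrix haps(k_total, nmut);
      IntegerVector positions(nmut);
      for (int c = 0; c < nmut; ++c) {
        const int m = ord[c];
        positions[c] = pos[m];
        below.clear();
        leaves_below(tr, mut_node[m], below);
        for (int lf : below) haps(lf, c) = 1;
      }
      hap_out[r] = List::create(_["positions"] = positions, _["haplotypes"] = haps);
    } else {
      for (int c = 0; c < nmut; ++c) {
        const int m = ord[c];
        below.clear();
        leaves_below(tr, mut_node[m], below);
        std::vector<int> per_pop(P, 0);
        for (int lf : below) {
          int acc = 0, p = 0;
          for (; p < P; ++p) { acc += smp[p]; if (lf < acc) break; }
          ++per_pop[p];
        }
        for (int p = 0; p < P; ++p) cnt_flat.push_back(per_pop[p]);
        site_region.push_back(r + 1);
      }
    }
  }

  if (return_haplotypes)
    return List::create(_["regions"] = hap_out, _["n_sites"] = s_per_region);

  const int S = static_cast<int>(site_region.size());
  IntegerMatrix counts(S, P);
  for (int s = 0; s < S; ++s)
    for (int p = 0; p < P; ++p) counts(s, p) = cnt_flat[s * P + p];
  return List::create(_["counts"] = counts,
                      _["region"] = wrap(site_region),
                      _["n_sites"] = s_per_region);
}

// Finite-island-model loci for the FDIST null: n_demes exchangeable demes
// of N haploid copies each, per-lineage backward migration rate m with a
// uniformly chosen destination. The first length(sample_sizes) demes are
// sampled. Exactly one mutation is dropped per locus, on a branch chosen
// proportionally to its length, so every locus is polymorphic in the total
// sample and the resulting allele frequencies span heterozygosities across
// (0, 1). Returns the 0/1 allele of every sampled gene copy (columns in
// sampled-deme order), so copies can be paired into pseudo-diploids.
// [[Rcpp::export]]
IntegerMatrix sim_island_loci_cpp(int n_demes, IntegerVector sample_sizes,
                                  double m, double N, int n_loci, double seed) {
  const int g = sample_sizes.size();
  if (g > n_demes) stop("more sampled demes than demes");
  std::vector<int> smp(g);
  int k_total = 0;
  for (int i = 0; i < g; ++i) { smp[i] = sample_sizes[i]; k_total += smp[i]; }
  if (k_total < 2) stop("need at least two sampled gene copies");

  IntegerMatrix out(n_loci, k_total);
  std::vector<double> blen;
  std::vector<int> below;

  for (int lc = 0; lc < n_loci; ++lc) {
    XRng rng(child_seed(seed, static_cast<uint64_t>(lc)));

    std::vector<std::vector<int>> deme(n_demes);
    int leaf = 0;
    for (int i = 0; i < g; ++i)
      for (int j = 0; j < smp[i]; ++j) deme[i].push_back(leaf++);

    Tree tr;
    tr.n_leaves = k_total;
    const int n_nodes = 2 * k_total - 1;
    tr.parent.assign(n_nodes, -1);
    tr.lchild.assign(n_nodes, -1);
    tr.rchild.assign(n_nodes, -1);
    tr.node_time.assign(n_nodes, 0.0);

    // running total of within-deme pairs for O(1) rate updates
    double sum_pairs = 0.0;
    for (int i = 0; i < n_demes; ++i) {
      const double ki = static_cast<double>(deme[i].size());
      sum_pairs += ki * (ki - 1.0) * 0.5;
    }

    double t = 0.0;
    int alive = k_total, next_node = k_total;
    while (alive > 1) {
      const double coal_total = sum_pairs / N;
      const double mig_total = static_cast<double>(alive) * m;
      const double total = coal_total + mig_total;
      t += rng.expo(total);
      double u = rng.unif() * total;
      if (u < coal_total) {
        double v = u * N;  // pick deme proportional to k(k-1)/2
        int i = 0;
        for (; i < n_demes; ++i) {
          const double ki = static_cast<double>(deme[i].size());
          const double r = ki * (ki - 1.0) * 0.5;
          if (v < r) break;
          v -= r;
        }
        if (i >= n_demes) i = n_demes - 1;
        const int ki = static_cast<int>(deme[i].size());
        int ia = rng.randint(ki), ib = rng.randint(ki - 1);
        if (ib >= ia) ++ib;
        const int na = deme[i][ia], nb = deme[i][ib];
        const int nd = next_node++;
        tr.parent[na] = nd; tr.parent[nb] = nd;
        tr.lchild[nd] = na; tr.rchild[nd] = nb;
        tr.node_time[nd] = t;
        deme[i][ia] = nd;
        deme[i][ib] = deme[i].back();
        deme[i].pop_back();
        sum_pairs -= (ki - 1.0);
        --alive;
      } else {
        // migrating lineage uniform over all lineages
        int pick = rng.randint(alive);
        int i = 0;
        for (; i < n_demes; ++i) {
          const int ki = static_cast<int>(deme[i].size());
          if (pick < ki) break;
          pick -= ki;
        }
        int j = rng.randint(n_demes - 1);
        if (j >= i) ++j;
        const double ki = static_cast<double>(deme[i].size());
        const double kj = static_cast<double>(deme[j].size());
        sum_pairs += kj - (ki - 1.0);
        deme[j].push_back(deme[i][pick]);
        deme[i][pick] = deme[i].back();
        deme[i].pop_back();
      }
    }

    const double L = total_branch_length(tr, blen);
    double u = rng.unif() * L;
    int chosen = -1;
    for (size_t v = 0; v < blen.size(); ++v) {
      if (blen[v] <= 0.0) continue;
      if (u < blen[v]) { chosen = static_cast<int>(v); break; }
      u -= blen[v];
    }
    if (chosen < 0) for (int v = static_cast<int>(blen.size()) - 1; v >= 0; --v)
      if (blen[v] > 0.0) { chosen = v; break; }

    below.clear();
    leaves_below(tr, chosen, below);
    for (int lf : below) out(lc, lf) = 1;
  }
  return out;
}
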