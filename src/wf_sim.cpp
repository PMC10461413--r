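// Forward Wright-Fisher simulation of a partially selfing diploid
// population carrying an additive quantitative trait under Gaussian
// stabilizing selection, with an optional optimum shift + bottleneck
// (colonization) at a given generation.  Infinite-sites mutation on an
// L-bp genome, uniform crossovers.  Uses R's RNG so set.seed() in R
// makes runs reproducible.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// Registry of every mutation ever created.
struct MutationRegistry {
  std::vector<int>    pos;       // 1-based bp position, unique among live
  std::vector<double> effect;    // additive trait effect per allele copy
  std::vector<int>    origin;    // generation of origin (1-based)
  std::vector<int>    fix_gen;   // generation fixation detected, -1 if never
  std::vector<char>   released;  // lost mutation, position free for reuse
  std::unordered_set<int> used_pos;

  int add(int p, double a, int gen) {
    pos.push_back(p);
    effect.push_back(a);
    origin.push_back(gen);
    fix_gen.push_back(-1);
    released.push_back(0);
    used_pos.insert(p);
    return static_cast<int>(pos.size()) - 1;
  }
  size_t size() const { return pos.size(); }
};

typedef std::vector<int> Hap;  // mutation ids, sorted by position

}  // namespace

static Hap merge_sorted(const Hap& a, const Hap& b,
                        const MutationRegistry& reg) {
  Hap out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (reg.pos[a[i]] <= reg.pos[b[j]]) out.push_back(a[i++]);
    else out.push_back(b[j++]);
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  return out;
}

static Hap gamete(const Hap& h1, const Hap& h2, MutationRegistry& reg,
                  double exp_xo, double exp_mut, int L,
                  double p_null, double sigma_effect,
                  double p_large, double sigma_large, int gen) {
  int n_xo = static_cast<int>(R::rpois(exp_xo));
  std::vector<double> xo(n_xo);
  for (int i = 0; i < n_xo; ++i) xo[i] = unif_rand() * L;
  std::sort(xo.begin(), xo.end());
  int start = (unif_rand() < 0.5) ? 0 : 1;

  auto active = [&](int p) {
    int k = static_cast<int>(std::upper_bound(xo.begin(), xo.end(),
                                              static_cast<double>(p) - 0.5) -
                             xo.begin());
    return (start + k) % 2;
  };

  Hap a, b;
  a.reserve(h1.size());
  b.reserve(h2.size());
  for (int id : h1) if (active(reg.pos[id]) == 0) a.push_back(id);
  for (int id : h2) if (active(reg.pos[id]) == 1) b.push_back(id);
  Hap out = merge_sorted(a, b, reg);

  // new mutations (infinite sites on integer positions; redraw collisions)
  int n_mut = static_cast<int>(R::rpois(exp_mut));
  for (int m = 0; m < n_mut; ++m) {
    int p = 0;
    for (int tries = 0; tries < 1000; ++tries) {
      p = static_cast<int>(unif_rand() * L) + 1;
      if (p > L) p = L;
      if (reg.used_pos.find(p) == reg.used_pos.end()) break;
      p = 0;
    }
    if (p == 0) continue;  // genome saturated; skip
    double a_eff = 0.0;
    if (unif_rand() >= p_null) {
      // causal: mostly small effects, a rare large-effect class
      double sd = (unif_rand() < p_large) ? sigma_large : sigma_effect;
      a_eff = norm_rand() * sd;
    }
    int id = reg.add(p, a_eff, gen);
    // insert keeping position order
    Hap::iterator it = std::lower_bound(
        out.begin(), out.end(), id,
        [&](int x, int y) { return reg.pos[x] < reg.pos[y]; });
    out.insert(it, id);
  }
  return out;
}

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
List wf_simulate_cpp(int N, int N_bottleneck, int t_shift, int generations,
                     int L, double mu_per_site, double rec_per_site,
                     double selfing, double p_null, double sigma_effect,
                     double p_large, double sigma_large,
                     int regime,  // 0 neutral, 1 stabilizing, 2 shifted_optimum
                     double opt0, double opt1, double omega,
                     int n_founders) {
  MutationRegistry reg;
  double exp_mut = mu_per_site * static_cast<double>(L);
  double exp_xo  = rec_per_site * static_cast<double>(L);

  int n_now = N;
  std::vector<Hap> pop(2 * n_now);  // haplotypes 2i, 2i+1 belong to ind i
  double z_base = 0.0;              // trait contribution of fixed mutations
  double opt = opt0;

  std::vector<double> mean_trait(generations);
  std::vector<int> pop_size(generations);

  std::vector<double> z(n_now), logw(n_now), cumw;

  for (int gen = 1; gen <= generations; ++gen) {
    bool shifted = (t_shift > 0 && gen > t_shift);
    if (regime == 2 && shifted) opt = opt1;
    int n_next = (shifted && N_bottleneck > 0) ? N_bottleneck : N;

    // traits and fitness of current population
    z.assign(n_now, z_base);
    for (int i = 0; i < n_now; ++i) {
      for (int id : pop[2 * i])     z[i] += reg.effect[id];
      for (int id : pop[2 * i + 1]) z[i] += reg.effect[id];
    }
    double zsum = 0.0;
    for (double v : z) zsum += v;
    mean_trait[gen - 1] = zsum / n_now;
    pop_size[gen - 1] = n_now;

    cumw.assign(n_now, 0.0);
    if (regime == 0) {
      for (int i = 0; i < n_now; ++i)
        cumw[i] = (i == 0 ? 1.0 : cumw[i - 1] + 1.0);
    } else {
      logw.assign(n_now, 0.0);
      double mx = -1e300;
      for (int i = 0; i < n_now; ++i) {
        double d = z[i] - opt;
        logw[i] = -d * d / (2.0 * omega * omega);
        if (logw[i] > mx) mx = logw[i];
      }
      double acc = 0.0;
      for (int i = 0; i < n_now; ++i) {
        acc += std::exp(logw[i] - mx);
        cumw[i] = acc;
      }
    }
    double wtot = cumw[n_now - 1];

    auto draw_parent = [&]() {
      double u = unif_rand() * wtot;
      return static_cast<int>(std::lower_bound(cumw.begin(), cumw.end(), u) -
                              cumw.begin());
    };

    // colonization founder event: the generation after the shift descends
    // from a small random group of colonists, irrespective of fitness
    std::vector<int> founders;
    bool founding = (t_shift > 0 && gen == t_shift + 1 && n_founders > 0 &&
                     n_founders < n_now);
    if (founding) {
      std::vector<int> perm(n_now);
      for (int i = 0; i < n_now; ++i) perm[i] = i;
      for (int i = 0; i < n_founders; ++i) {
        int j = i + static_cast<int>(unif_rand() * (n_now - i));
        std::swap(perm[i], perm[j]);
        founders.push_back(perm[i]);
      }
    }
    auto pick_parent = [&]() {
      if (founding)
        return founders[static_cast<int>(unif_rand() * n_founders)];
      return draw_parent();
    };

    // next generation
    std::vector<Hap> next(2 * n_next);
    for (int i = 0; i < n_next; ++i) {
      int p1 = pick_parent();
      int p2 = (unif_rand() < selfing) ? p1 : pick_parent();
      next[2 * i] = gamete(pop[2 * p1], pop[2 * p1 + 1], reg, exp_xo, exp_mut,
                           L, p_null, sigma_effect, p_large, sigma_large,
                           gen);
      next[2 * i + 1] = gamete(pop[2 * p2], pop[2 * p2 + 1], reg, exp_xo,
                               exp_mut, L, p_null, sigma_effect, p_large,
                               sigma_large, gen);
    }
    pop.swap(next);
    n_now = n_next;

    // fixation sweep: remove mutations present in every haplotype;
    // lost mutations release their position for reuse (finite-L
    // approximation of infinite sites)
    std::vector<int> count(reg.size(), 0);
    for (const Hap& h : pop)
      for (int id : h) ++count[id];
    int full = 2 * n_now;
    std::vector<char> is_fixed(reg.size(), 0);
    bool any_fixed = false;
    for (size_t id = 0; id < reg.size(); ++id) {
      if (count[id] == full && reg.fix_gen[id] < 0) {
        is_fixed[id] = 1;
        reg.fix_gen[id] = gen;
        z_base += 2.0 * reg.effect[id];
        any_fixed = true;
      } else if (count[id] == 0 && reg.fix_gen[id] < 0 && !reg.released[id]) {
        reg.released[id] = 1;
        reg.used_pos.erase(reg.pos[id]);
      }
    }
    if (any_fixed) {
      for (Hap& h : pop) {
        Hap kept;
        kept.reserve(h.size());
        for (int id : h) if (!is_fixed[id]) kept.push_back(id);
        h.swap(kept);
      }
    }
  }

  // final segregating counts
  std::vector<int> count(reg.size(), 0);
  for (const Hap& h : pop)
    for (int id : h) ++count[id];

  // report mutations that are segregating now or that fixed at some point
  std::vector<int> keep_ids;
  for (size_t id = 0; id < reg.size(); ++id)
    if (count[id] > 0 || reg.fix_gen[id] >= 0)
      keep_ids.push_back(static_cast<int>(id));

  int n_keep = static_cast<int>(keep_ids.size());
  IntegerVector out_id(n_keep), out_pos(n_keep), out_origin(n_keep),
      out_fixgen(n_keep), out_count(n_keep);
  NumericVector out_effect(n_keep), out_freq(n_keep);
  LogicalVector out_fixed(n_keep);
  for (int k = 0; k < n_keep; ++k) {
    int id = keep_ids[k];
    out_id[k] = id + 1;
    out_pos[k] = reg.pos[id];
    out_effect[k] = reg.effect[id];
    out_origin[k] = reg.origin[id];
    out_fixgen[k] = reg.fix_gen[id];
    out_count[k] = (reg.fix_gen[id] >= 0) ? 2 * n_now : count[id];
    out_freq[k] = (reg.fix_gen[id] >= 0)
                      ? 1.0
                      : static_cast<double>(count[id]) / (2.0 * n_now);
    out_fixed[k] = reg.fix_gen[id] >= 0;
  }

  List haps(2 * n_now);
  for (int i = 0; i < 2 * n_now; ++i) {
    IntegerVector h(pop[i].size());
    for (size_t j = 0; j < pop[i].size(); ++j) h[j] = pop[i][j] + 1;
    haps[i] = h;
  }

  return List::create(
      _["haplotypes"] = haps,
      _["mutations"] = DataFrame::create(
          _["id"] = out_id, _["pos"] = out_pos, _["effect"] = out_effect,
          _["origin_gen"] = out_origin, _["fix_gen"] = out_fixgen,
          _["count"] = out_count, _["freq"] = out_freq,
          _["fixed"] = out_fixed),
      _["mean_trait"] = NumericVector(mean_trait.begin(), mean_trait.end()),
      _["pop_size"] = IntegerVector(pop_size.begin(), pop_size.end()),
      _["z_base"] = z_base, _["n_final"] = n_now);
}
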