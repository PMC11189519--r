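// Forward Wright-Fisher simulator with infinite-sites mutation on a
// continuous coordinate line, Poisson recombination, partial selfing,
// piecewise-constant deme sizes, splits and migration.
//
// Haplotypes are sorted vectors of derived-mutation positions (doubles in
// [0, L)). The reference/ancestral state carries no mutations; positions
// fixed across every living haplotype are purged periodically (they have
// left the segregating set). Uses R's RNG throughout so set.seed() in R
// makes runs reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

typedef std::vector<double> Hap;
typedef std::vector<Hap> Deme; // 2N haplotypes; individual i = haps 2i, 2i+1

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void make_gamete(const Hap &h1, const Hap &h2, double rec_L,
                        double mu_L, double L, Hap &out,
                        std::vector<double> &breaks) {
  out.clear();
  int cur = unif_rand() < 0.5 ? 1 : 0;
  int k = (int)R::rpois(rec_L);
  if (k == 0) {
    const Hap &h = cur ? h2 : h1;
    out.assign(h.begin(), h.end());
  } else {
    breaks.clear();
    for (int i = 0; i < k; i++) breaks.push_back(unif_rand() * L);
    std::sort(breaks.begin(), breaks.end());
    breaks.push_back(L + 1.0);
    const Hap *src[2] = {&h1, &h2};
    double lo = 0.0;
    for (size_t b = 0; b < breaks.size(); b++) {
      double hi = breaks[b];
      const Hap &h = *src[cur];
      Hap::const_iterator it0 = std::lower_bound(h.begin(), h.end(), lo);
      Hap::const_iterator it1 = std::lower_bound(h.begin(), h.end(), hi);
      out.insert(out.end(), it0, it1);
      cur ^= 1;
      lo = hi;
    }
  }
  int nm = (int)R::rpois(mu_L);
  for (int i = 0; i < nm; i++) {
    double pos = unif_rand() * L;
    Hap::iterator it = std::lower_bound(out.begin(), out.end(), pos);
    if (it == out.end() || *it != pos) out.insert(it, pos);
  }
}

// remove positions carried by every haplotype of every living deme
static void purge_fixed(std::vector<Deme> &demes) {
  const Hap *smallest = NULL;
  size_t total = 0;
  for (size_t p = 0; p < demes.size(); p++)
    for (size_t h = 0; h < demes[p].size(); h++) {
      total++;
      if (!smallest || demes[p][h].size() < smallest->size())
        smallest = &demes[p][h];
    }
  if (!smallest || smallest->empty() || total < 2) return;
  Hap fixed;
  for (size_t i = 0; i < smallest->size(); i++) {
    double pos = (*smallest)[i];
    bool everywhere = true;
    for (size_t p = 0; p < demes.size() && everywhere; p++)
      for (size_t h = 0; h < demes[p].size(); h++) {
        const Hap &hp = demes[p][h];
        if (!std::binary_search(hp.begin(), hp.end(), pos)) {
          everywhere = false;
          break;
        }
      }
    if (everywhere) fixed.push_back(pos);
  }
  if (fixed.empty()) return;
  for (size_t p = 0; p < demes.size(); p++)
    for (size_t h = 0; h < demes[p].size(); h++) {
      Hap &hp = demes[p][h];
      Hap keep;
      keep.reserve(hp.size() - fixed.size());
      std::set_difference(hp.begin(), hp.end(), fixed.begin(), fixed.end(),
                          std::back_inserter(keep));
      hp.swap(keep);
    }
}

// ne: G x P diploid sizes per generation (row 0 oldest, row G-1 = present;
//     0 = deme not alive). parent: 0-based parent deme at creation (-1 root).
// mig: P x P row-stochastic source-deme probabilities.
// sample_ind: individuals sampled per deme at present.
// [[Rcpp::export]]
List wf_sim_cpp(IntegerMatrix ne, IntegerVector parent, NumericVector selfing,
                NumericMatrix mig, double mu_L, double rec_L, double L,
                IntegerVector sample_ind, int purge_every) {
  const int G = ne.nrow(), P = ne.ncol();
  std::vector<Deme> prev(P), next(P);
  for (int p = 0; p < P; p++)
    if (ne(0, p) > 0) prev[p].assign(2 * ne(0, p), Hap());

  std::vector<double> breaks;
  for (int g = 1; g < G; g++) {
    for (int p = 0; p < P; p++) {
      int N = ne(g, p);
      if (N == 0) {
        next[p].clear();
        continue;
      }
      next[p].resize(2 * N); // element buffers persist across generations
      bool newborn = ne(g - 1, p) == 0;
      int home = newborn ? parent[p] : p;
      for (int i = 0; i < N; i++) {
        int src = home;
        if (!newborn) {
          double u = unif_rand(), acc = 0.0;
          for (int q = 0; q < P; q++) {
            acc += mig(p, q);
            if (u <= acc) {
              src = q;
              break;
            }
          }
          if (ne(g - 1, src) == 0) src = home;
        }
        int Nsrc = ne(g - 1, src);
        int p1 = rand_int(Nsrc);
        int p2 = (unif_rand() < selfing[p]) ? p1 : rand_int(Nsrc);
        const Deme &pool = prev[src];
        make_gamete(pool[2 * p1], pool[2 * p1 + 1], rec_L, mu_L, L,
                    next[p][2 * i], breaks);
        make_gamete(pool[2 * p2], pool[2 * p2 + 1], rec_L, mu_L, L,
                    next[p][2 * i + 1], breaks);
      }
    }
    for (int p = 0; p < P; p++) prev[p].swap(next[p]);
    if (g % purge_every == 0 || g == G - 1) purge_fixed(prev);
  }

  // sample individuals without replacement; collect their haplotypes
  std::vector<const Hap *> haps;
  std::vector<int> hap_pop;
  for (int p = 0; p < P; p++) {
    int N = ne(G - 1, p), ns = sample_ind[p];
    if (ns == 0) continue;
    if (ns > N) stop("sample size exceeds deme size");
    std::vector<int> idx(N);
    for (int i = 0; i < N; i++) idx[i] = i;
    for (int i = 0; i < ns; i++) {
      int j = i + rand_int(N - i);
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < ns; i++) {
      haps.push_back(&prev[p][2 * idx[i]]);
      haps.push_back(&prev[p][2 * idx[i] + 1]);
      hap_pop.push_back(p);
      hap_pop.push_back(p);
    }
  }

  Hap all;
  for (size_t h = 0; h < haps.size(); h++)
    all.insert(all.end(), haps[h]->begin(), haps[h]->end());
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());

  const int S = (int)all.size(), H = (int)haps.size();
  IntegerMatrix geno(H, S);
  for (int h = 0; h < H; h++) {
    const Hap &hp = *haps[h];
    for (size_t i = 0; i < hp.size(); i++) {
      int col = (int)(std::lower_bound(all.begin(), all.end(), hp[i]) -
                      all.begin());
      geno(h, col) = 1;
    }
  }
  return List::create(_["positions"] = NumericVector(all.begin(), all.end()),
                      _["geno"] = geno,
                      _["hap_pop"] = IntegerVector(hap_pop.begin(),
                                                   hap_pop.end()));
}
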