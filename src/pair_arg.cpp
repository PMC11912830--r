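// Discrete-generation pairwise coalescent-with-recombination engine.
//
// Tracks the ancestral material of two sampled haplotypes (A sampled at
// generation 0 of the simulation clock, B injected dt generations later) as
// tagged intervals carried by lineages. Each generation, every lineage
// undergoes one meiosis: crossover breakpoints fall as a Poisson process at
// rate 1 per Morgan over the lineage's span and alternate chunks are split
// between the two haplotypes of a uniformly drawn diploid parent; lineages
// landing on the same parental haplotype merge. When A- and B-tagged
// material overlaps inside one merged lineage, the overlap has found its
// most recent common ancestor: it is recorded and removed from tracking.
// Maximal recorded intervals from a single coalescence event (one parental
// haplotype in one generation) are the IBD segments.
//
// Uses R's RNG throughout so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

struct Iv {
  double a, b;
  unsigned char tag; // 0 = sample A material, 1 = sample B material
};

typedef std::vector<Iv> Lineage;

static inline bool iv_less(const Iv& x, const Iv& y) { return x.a < y.a; }

// Split a lineage at sorted breakpoints into two parental groups of
// alternating chunks; `phase` selects which group takes the first chunk.
static void split_lineage(const Lineage& lin, const std::vector<double>& bp,
                          int phase, Lineage& g0, Lineage& g1) {
  g0.clear(); g1.clear();
  size_t k = 0; // next breakpoint index
  for (const Iv& iv : lin) {
    double lo = iv.a;
    while (k < bp.size() && bp[k] <= lo) { ++k; ++phase; }
    size_t kk = k;
    int ph = phase;
    while (lo < iv.b) {
      double hi = (kk < bp.size() && bp[kk] < iv.b) ? bp[kk] : iv.b;
      if (hi > lo + 1e-13) {
        Iv piece = {lo, hi, iv.tag};
        if ((ph & 1) == 0) g0.push_back(piece); else g1.push_back(piece);
      }
      lo = hi;
      if (kk < bp.size() && hi >= bp[kk]) { ++kk; ++ph; }
      else break;
    }
  }
}

// Remove A/B overlaps from a merged lineage; append the overlap intervals
// (the material that has just coalesced) to `found`.
static void resolve_overlaps(Lineage& lin, std::vector<std::pair<double,double> >& found) {
  std::vector<Iv> as, bs;
  for (const Iv& iv : lin) (iv.tag == 0 ? as : bs).push_back(iv);
  if (as.empty() || bs.empty()) return;
  std::sort(as.begin(), as.end(), iv_less);
  std::sort(bs.begin(), bs.end(), iv_less);
  std::vector<std::pair<double,double> > ov;
  size_t i = 0, j = 0;
  while (i < as.size() && j < bs.size()) {
    double lo = std::max(as[i].a, bs[j].a);
    double hi = std::min(as[i].b, bs[j].b);
    if (hi > lo + 1e-13) ov.push_back(std::make_pair(lo, hi));
    if (as[i].b < bs[j].b) ++i; else ++j;
  }
  if (ov.empty()) return;
  // subtract ov from a sorted interval list
  Lineage out;
  for (int tag = 0; tag < 2; ++tag) {
    const std::vector<Iv>& src = (tag == 0 ? as : bs);
    for (const Iv& iv : src) {
      double lo = iv.a;
      for (const std::pair<double,double>& o : ov) {
        if (o.second <= lo) continue;
        if (o.first >= iv.b) break;
        if (o.first > lo + 1e-13) {
          Iv piece = {lo, std::min(o.first, iv.b), iv.tag};
          out.push_back(piece);
        }
        lo = std::max(lo, o.second);
        if (lo >= iv.b) break;
      }
      if (lo < iv.b - 1e-13) {
        Iv piece = {lo, iv.b, iv.tag};
        out.push_back(piece);
      }
    }
  }
  lin.swap(out);
  for (const std::pair<double,double>& o : ov) found.push_back(o);
}

// Merge touching/adjacent coalesced intervals from one event into maximal
// IBD segments and append their lengths.
static void emit_segments(std::vector<std::pair<double,double> >& found,
                          std::vector<double>& out) {
  if (found.empty()) return;
  std::sort(found.begin(), found.end());
  double lo = found[0].first, hi = found[0].second;
  for (size_t i = 1; i < found.size(); ++i) {
    if (found[i].first <= hi + 1e-10) {
      if (found[i].second > hi) hi = found[i].second;
    } else {
      out.push_back(hi - lo);
      lo = found[i].first; hi = found[i].second;
    }
  }
  out.push_back(hi - lo);
}

// [[Rcpp::export]]
List sim_pair_ibd_cpp(NumericVector ne, int dt, double L, int reps) {
  const int gmax = ne.size() - 1; // last generation with a defined Ne
  List result(reps);
  std::vector<double> bp;
  Lineage g0, g1;
  std::vector<std::pair<double,double> > found;
  std::vector<size_t> merged;
  for (int rep = 0; rep < reps; ++rep) {
    std::vector<Lineage> lineages;
    std::vector<double> segs;
    {
      Lineage init;
      Iv whole = {0.0, L, 0};
      init.push_back(whole);
      lineages.push_back(init);
      if (dt == 0) {
        Lineage initB;
        Iv wholeB = {0.0, L, 1};
        initB.push_back(wholeB);
        lineages.push_back(initB);
      }
    }
    for (int g = 1; g <= gmax; ++g) {
      double Ng = ne[g];
      long nInd = (long)std::max(1.0, std::floor(Ng + 0.5));
      std::unordered_map<long long, size_t> byHap;
      byHap.reserve(2 * lineages.size() + 4);
      std::vector<Lineage> next;
      next.reserve(2 * lineages.size() + 4);
      merged.clear(); // indices in `next` that received >1 contributor
      for (Lineage& lin : lineages) {
        if (lin.empty()) continue;
        double lo = lin.front().a, hi = lin.back().b;
        double span = hi - lo;
        int nbr = (span > 0) ? (int)R::rpois(span) : 0;
        bp.clear();
        for (int k = 0; k < nbr; ++k) bp.push_back(lo + R::unif_rand() * span);
        std::sort(bp.begin(), bp.end());
        int phase = (R::unif_rand() < 0.5) ? 0 : 1;
        split_lineage(lin, bp, phase, g0, g1);
        long u = (long)(R::unif_rand() * nInd);
        if (u >= nInd) u = nInd - 1;
        int s = (R::unif_rand() < 0.5) ? 0 : 1;
        for (int grp = 0; grp < 2; ++grp) {
          Lineage& gl = (grp == 0 ? g0 : g1);
          if (gl.empty()) continue;
          long long hap = 2LL * u + ((grp == 0) ? s : 1 - s);
          std::unordered_map<long long, size_t>::iterator it = byHap.find(hap);
          if (it == byHap.end()) {
            byHap[hap] = next.size();
            next.push_back(Lineage());
            next.back().swap(gl);
          } else {
            Lineage& tgt = next[it->second];
            tgt.insert(tgt.end(), gl.begin(), gl.end());
            merged.push_back(it->second);
          }
        }
      }
      // inject sample B at its sampling generation (it may itself be an
      // ancestor of A: immediate coalescence with branch length dt)
      if (dt > 0 && g == dt) {
        Lineage linB;
        Iv wholeB = {0.0, L, 1};
        linB.push_back(wholeB);
        long long hap = (long long)(R::unif_rand() * (2.0 * nInd));
        if (hap >= 2LL * nInd) hap = 2LL * nInd - 1;
        std::unordered_map<long long, size_t>::iterator it = byHap.find(hap);
        if (it == byHap.end()) {
          byHap[hap] = next.size();
          next.push_back(linB);
        } else {
          Lineage& tgt = next[it->second];
          tgt.insert(tgt.end(), linB.begin(), linB.end());
          merged.push_back(it->second);
        }
      }
      // resolve coalesced material per merged haplotype (one event each)
      std::sort(merged.begin(), merged.end());
      merged.erase(std::unique(merged.begin(), merged.end()), merged.end());
      for (size_t idx : merged) {
        found.clear();
        resolve_overlaps(next[idx], found);
        emit_segments(found, segs);
      }
      // keep sorted interval lists and drop exhausted lineages
      lineages.clear();
      double remA = 0, remB = 0;
      for (Lineage& lin : next) {
        if (lin.empty()) continue;
        std::sort(lin.begin(), lin.end(), iv_less);
        for (const Iv& iv : lin) (iv.tag == 0 ? remA : remB) += iv.b - iv.a;
        lineages.push_back(Lineage());
        lineages.back().swap(lin);
      }
      bool bPending = (dt > 0 && g < dt);
      if (!bPending && (remA <= 1e-12 || remB <= 1e-12)) break;
      if (lineages.empty()) break;
    }
    result[rep] = NumericVector(segs.begin(), segs.end());
  }
  return result;
}
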