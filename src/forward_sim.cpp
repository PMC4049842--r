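// Forward-in-time Wright-Fisher simulator of phased biallelic haplotypes.
//
// Haplotypes are bit-packed (one bit per site column, 64 sites per word).
// Demography is a three-population clean-split topology:
//   ancestral -> (AFR, OOA) at t_ooa generations before present,
//   OOA -> (EUR, ASN) at t_split2 generations before present,
// sizes constant within an epoch, with an optional instantaneous growth of
// the leaf populations t_growth generations before present.  A selective
// sweep is modelled as a focal allele introduced in the swept scope (one
// population, or all of them), conditioned on segregating (re-introduced on
// loss, i.e. recurrent mutation) until multiplicative selection is switched
// on, scheduled so that the allele reaches the target frequency by the
// sweep's end time t_end; runs whose frequency at t_end misses the
// acceptance band are retried from a checkpoint taken at the introduction
// time, up to a bounded number of retries, and drift neutrally afterwards.
//
// All randomness comes from a std::mt19937_64 stream seeded from R; bounded
// draws and Poisson deviates are implemented here so that output is
// reproducible across platforms (std::*_distribution is
// implementation-defined).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

typedef uint64_t word;

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  uint64_t u64() { return eng(); }
  // uniform double in [0, 1)
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n), n >= 1
  int below(int n) {
    return (int)(((unsigned __int128)u64() * (unsigned __int128)(uint64_t)n) >> 64);
  }
  int pois_small(double lambda) {
    if (lambda <= 0.0) return 0;
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= unif();
    } while (p > L);
    return k - 1;
  }
  // exact Poisson via sums of small-mean draws (means here are modest)
  int pois(double lambda) {
    int total = 0;
    while (lambda > 30.0) {
      total += pois_small(30.0);
      lambda -= 30.0;
    }
    return total + pois_small(lambda);
  }
};

inline int getbit(const word* g, int s) {
  return (int)((g[s >> 6] >> (s & 63)) & 1u);
}
inline void flipbit(word* g, int s) { g[s >> 6] ^= ((word)1 << (s & 63)); }
inline void clearbit(word* g, int s) { g[s >> 6] &= ~((word)1 << (s & 63)); }

// copy bit range [from, to) from src into dst
inline void copy_bits(word* dst, const word* src, int from, int to) {
  if (from >= to) return;
  int wa = from >> 6, wb = (to - 1) >> 6;
  for (int w = wa; w <= wb; ++w) {
    word mask = ~(word)0;
    if (w == wa) mask &= (~(word)0) << (from & 63);
    if (w == wb) {
      int r = to & 63;
      if (r) mask &= (~(word)0) >> (64 - r);
    }
    dst[w] = (dst[w] & ~mask) | (src[w] & mask);
  }
}

struct Pop {
  int N = 0;  // diploid individuals; gametes = 2N
  std::vector<word> g;
  void resize(int n, int W) {
    size_t need = (size_t)2 * n * W;
    // same-size buffers are reused without zero-filling: every row is fully
    // rewritten by make_gamete and slack bits beyond the last site stay zero
    // by induction from the zero-filled initial state
    if (g.size() != need) g.assign(need, 0);
    N = n;
  }
  word* row(int i, int W) { return g.data() + (size_t)i * W; }
  const word* row(int i, int W) const { return g.data() + (size_t)i * W; }
};

enum PopId { ANC = 0, AFR = 1, OOA = 2, EUR = 3, ASN = 4, NPOP = 5 };

struct World {
  Pop p[NPOP];
  std::vector<int> alive;  // extant population ids
};

struct Sim {
  int W = 0, S = 0;
  double Lbp = 0;
  std::vector<double> pos;
  double lamMut = 0, lamRec = 0;
  Rng rng;
  bool sweep = false;
  int focal = -1;
  std::vector<int> freeCols;
  long long nReintro = 0;
  explicit Sim(uint64_t seed) : rng(seed) {}

  bool col_allowed(int s) const { return !(sweep && s == focal); }

  long long nSkipped = 0;

  int draw_mut_site() {
    if (!freeCols.empty()) {
      int idx = rng.below((int)freeCols.size());
      int s = freeCols[idx];
      freeCols[idx] = freeCols.back();
      freeCols.pop_back();
      return s;
    }
    // column capacity exhausted: drop the mutation (counted).  Only the very
    // rarest, youngest variants are affected; they fall below any
    // minor-allele-frequency filter downstream.
    ++nSkipped;
    return -1;
  }

  void make_gamete(const word* h0, const word* h1, word* out) {
    int ncx = lamRec > 0 ? rng.pois(lamRec) : 0;
    int start = rng.below(2);
    if (ncx == 0) {
      std::memcpy(out, start ? h1 : h0, (size_t)W * sizeof(word));
      return;
    }
    std::vector<int> cuts(ncx);
    for (int i = 0; i < ncx; ++i) {
      double bp = rng.unif() * Lbp;
      cuts[i] = (int)(std::lower_bound(pos.begin(), pos.end(), bp) - pos.begin());
    }
    std::sort(cuts.begin(), cuts.end());
    const word* cur = start ? h1 : h0;
    int at = 0;
    for (int c : cuts) {
      copy_bits(out, cur, at, std::min(c, S));
      at = std::max(at, std::min(c, S));
      cur = (cur == h0) ? h1 : h0;
    }
    copy_bits(out, cur, at, S);
  }

  int pick_parent(const Pop& src, const std::vector<double>& cum, double tot) {
    if (cum.empty()) return rng.below(src.N);
    double u = rng.unif() * tot;
    int i = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
    return std::min(i, src.N - 1);
  }

  void step_pop(Pop& dst, const Pop& src, int n_offspring, bool sel, double s) {
    std::vector<double> cum;
    double tot = 0.0;
    if (sel) {
      double w1 = 1.0 + s, w2 = w1 * w1;
      cum.resize(src.N);
      for (int i = 0; i < src.N; ++i) {
        int c = getbit(src.row(2 * i, W), focal) + getbit(src.row(2 * i + 1, W), focal);
        tot += (c == 0 ? 1.0 : (c == 1 ? w1 : w2));
        cum[i] = tot;
      }
    }
    dst.resize(n_offspring, W);
    for (int i = 0; i < n_offspring; ++i) {
      int pa = pick_parent(src, cum, tot);
      int pb = pick_parent(src, cum, tot);
      make_gamete(src.row(2 * pa, W), src.row(2 * pa + 1, W), dst.row(2 * i, W));
      make_gamete(src.row(2 * pb, W), src.row(2 * pb + 1, W), dst.row(2 * i + 1, W));
    }
    int nm = rng.pois(2.0 * n_offspring * lamMut);
    for (int m = 0; m < nm; ++m) {
      int s_idx = draw_mut_site();
      if (s_idx < 0) continue;
      flipbit(dst.row(rng.below(2 * n_offspring), W), s_idx);
    }
  }

  long long focal_count(const Pop& p) const {
    long long c = 0;
    for (int i = 0; i < 2 * p.N; ++i) c += getbit(p.row(i, W), focal);
    return c;
  }

  void reintroduce(Pop& p) {
    int i = rng.below(2 * p.N);
    if (!getbit(p.row(i, W), focal)) flipbit(p.row(i, W), focal);
    ++nReintro;
  }

  // reclaim monomorphic columns: zero out fixed-derived ones, rebuild free list
  void cleanup(World& w) {
    std::vector<long long> cnt(S, 0);
    long long M = 0;
    for (int id : w.alive) {
      const Pop& p = w.p[id];
      M += 2LL * p.N;
      for (int i = 0; i < 2 * p.N; ++i) {
        const word* r = p.row(i, W);
        for (int wd = 0; wd < W; ++wd) {
          word x = r[wd];
          while (x) {
            int b = __builtin_ctzll(x);
            ++cnt[(wd << 6) + b];
            x &= x - 1;
          }
        }
      }
    }
    freeCols.clear();
    for (int s = 0; s < S; ++s) {
      if (!col_allowed(s)) continue;
      if (cnt[s] == 0) {
        freeCols.push_back(s);
      } else if (cnt[s] == M) {
        for (int id : w.alive)
          for (int i = 0; i < 2 * w.p[id].N; ++i) clearbit(w.p[id].row(i, W), s);
        freeCols.push_back(s);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(rng = false)]]
List forward_sim_cpp(IntegerVector n_dip,       // ANC, AFR, OOA, EUR, ASN (scaled diploids)
                     IntegerVector n_dip_present,  // AFR, EUR, ASN after growth
                     int t_growth,              // growth onset, scaled gens before present (0 = none)
                     int burn_gens,             // scaled generations in the ancestral epoch
                     int t_ooa, int t_split2,   // scaled generations before present (0,0 = panmictic)
                     NumericVector positions,   // sorted site positions in bp
                     double region_length,
                     double lam_mut,            // expected mutations per gamete per generation
                     double lam_rec,            // expected crossovers per meiosis
                     IntegerVector n_hap_sample,// per leaf population (AFR,EUR,ASN) or length 1
                     bool sweep, int sweep_pop, int t_intro, int t_end,
                     double sel_s,
                     double f_target, double f_tol, int focal_site,
                     double sched_safety, int max_retries,
                     IntegerVector seed2) {
  Sim sim(((uint64_t)(uint32_t)seed2[0] << 32) ^ (uint64_t)(uint32_t)seed2[1]);
  sim.S = positions.size();
  sim.W = (sim.S + 63) / 64;
  sim.Lbp = region_length;
  sim.pos.assign(positions.begin(), positions.end());
  sim.lamMut = lam_mut;
  sim.lamRec = lam_rec;
  sim.sweep = sweep;
  sim.focal = sweep ? focal_site : -1;

  const bool panmictic = (t_ooa == 0);
  if (!panmictic && !(t_split2 > 0 && t_split2 < t_ooa))
    stop("split times must satisfy 0 < t_split2 < t_ooa");
  const int t_total = burn_gens + t_ooa;
  if (sweep && !(t_intro > 0 && t_intro < t_total))
    stop("sweep introduction time must fall inside the simulated span");
  if (sweep && !(t_end >= 0 && t_end < t_intro))
    stop("sweep end time must be more recent than its introduction");
  if (sweep && sweep_pop >= 0) {
    if ((sweep_pop == EUR || sweep_pop == ASN) && t_intro > t_split2)
      stop("the swept population does not exist at the introduction time");
    if (sweep_pop == AFR && t_intro > t_ooa)
      stop("the swept population does not exist at the introduction time");
    if (panmictic && sweep_pop != ANC)
      stop("a panmictic model can only sweep the single population");
  }
  // does population `id` experience selection / trajectory conditioning?
  auto in_scope = [&](int id) { return sweep_pop < 0 || id == sweep_pop; };

  World w;
  w.p[ANC].resize(n_dip[ANC], sim.W);
  w.alive = {ANC};
  sim.freeCols.resize(0);
  for (int s = 0; s < sim.S; ++s)
    if (sim.col_allowed(s)) sim.freeCols.push_back(s);

  // short interval: free columns are only reclaimed at cleanup, and the pool
  // must absorb the mutation influx of a whole interval without exhausting
  const int cleanup_every = 8;

  // epoch-dependent target size of a leaf population
  auto leaf_size = [&](int id, int tbp) -> int {
    if (t_growth > 0 && tbp < t_growth) {
      if (id == AFR) return n_dip_present[0];
      if (id == EUR) return n_dip_present[1];
      if (id == ASN) return n_dip_present[2];
    }
    return n_dip[id];
  };

  // advance the world so that the new generation lives at time tbp (gens before present)
  World wbuf;
  auto advance = [&](int tbp, bool sel) {
    auto on = [&](int id) { return sel && in_scope(id); };
    World& nw = wbuf;
    if (panmictic || tbp >= t_ooa) {
      if (!panmictic && tbp == t_ooa) {
        nw.alive = {AFR, OOA};
        sim.step_pop(nw.p[AFR], w.p[ANC], leaf_size(AFR, tbp), sel, sel_s);
        sim.step_pop(nw.p[OOA], w.p[ANC], n_dip[OOA], on(OOA), sel_s);
      } else {
        nw.alive = {ANC};
        sim.step_pop(nw.p[ANC], w.p[ANC], n_dip[ANC], on(ANC), sel_s);
      }
    } else if (tbp >= t_split2) {
      if (tbp == t_split2) {
        nw.alive = {AFR, EUR, ASN};
        sim.step_pop(nw.p[AFR], w.p[AFR], leaf_size(AFR, tbp), sel, sel_s);
        sim.step_pop(nw.p[EUR], w.p[OOA], leaf_size(EUR, tbp), sel, sel_s);
        sim.step_pop(nw.p[ASN], w.p[OOA], leaf_size(ASN, tbp), sel, sel_s);
      } else {
        nw.alive = {AFR, OOA};
        sim.step_pop(nw.p[AFR], w.p[AFR], leaf_size(AFR, tbp), sel, sel_s);
        sim.step_pop(nw.p[OOA], w.p[OOA], n_dip[OOA], on(OOA), sel_s);
      }
    } else {
      nw.alive = {AFR, EUR, ASN};
      sim.step_pop(nw.p[AFR], w.p[AFR], leaf_size(AFR, tbp), sel, sel_s);
      sim.step_pop(nw.p[EUR], w.p[EUR], leaf_size(EUR, tbp), sel, sel_s);
      sim.step_pop(nw.p[ASN], w.p[ASN], leaf_size(ASN, tbp), sel, sel_s);
    }
    std::swap(w, nw);
    if (tbp % cleanup_every == 0) sim.cleanup(w);
  };

  int t_pre_end = sweep ? t_intro : 0;
  for (int tbp = t_total - 1; tbp >= t_pre_end; --tbp) {
    advance(tbp, false);
    Rcpp::checkUserInterrupt();
  }

  long long retries_used = 0;
  double final_freq = NA_REAL;
  int onset_tbp = NA_INTEGER;
  bool ok = true;

  if (sweep) {
    World checkpoint = w;
    std::vector<int> freeCheckpoint = sim.freeCols;
    ok = false;
    for (int attempt = 0; attempt <= max_retries && !ok; ++attempt) {
      if (attempt > 0) {
        w = checkpoint;
        sim.freeCols = freeCheckpoint;
        ++retries_used;
      }
      // introduce the focal allele as a single copy within the swept scope
      {
        long long tot_g = 0;
        for (int id : w.alive) if (in_scope(id)) tot_g += 2LL * w.p[id].N;
        if (tot_g == 0) stop("swept population missing at introduction");
        long long pickg = (long long)(sim.rng.unif() * (double)tot_g);
        for (int id : w.alive) {
          if (!in_scope(id)) continue;
          long long ng = 2LL * w.p[id].N;
          if (pickg < ng) {
            word* r = w.p[id].row((int)pickg, sim.W);
            if (!getbit(r, sim.focal)) flipbit(r, sim.focal);
            break;
          }
          pickg -= ng;
        }
      }
      bool selOn = false, selStarted = false, selDone = false, failed = false;
      int onset = NA_INTEGER;
      for (int tbp = t_intro - 1; tbp >= t_end; --tbp) {
        advance(tbp, selOn);
        // focal bookkeeping
        double xmin = 1.0, xglob;
        long long X = 0, M = 0;
        for (int id : w.alive) {
          if (!in_scope(id)) continue;
          Pop& p = w.p[id];
          long long c = sim.focal_count(p);
          if (c == 0 && !selDone) {
            sim.reintroduce(p);
            c = 1;
          }
          X += c;
          M += 2LL * p.N;
          xmin = std::min(xmin, (double)c / (2.0 * p.N));
        }
        xglob = (double)X / (double)M;
        if (!selDone && X == 0) {
          failed = true;
          break;
        }
        if (!selStarted && sel_s > 0) {
          double t_need = (1.0 / sel_s) *
                          std::log(f_target * (1.0 - xmin) / (xmin * (1.0 - f_target)));
          if ((double)(tbp - t_end) <= sched_safety * t_need + 5.0) {
            selStarted = selOn = true;
            onset = tbp;
          }
        }
        if (selOn && xglob >= f_target) {
          selOn = false;
          selDone = true;
        }
        Rcpp::checkUserInterrupt();
      }
      if (!failed) {
        // frequency (within the swept scope) at the end of the sweep
        long long X = 0, M = 0;
        for (int id : w.alive) {
          if (!in_scope(id)) continue;
          X += sim.focal_count(w.p[id]);
          M += 2LL * w.p[id].N;
        }
        double x = (double)X / (double)M;
        if (X > 0 && X < M && std::fabs(x - f_target) <= f_tol) {
          ok = true;
          final_freq = x;
          onset_tbp = onset;
          // post-sweep phase: plain neutral drift to the present
          for (int tbp = t_end - 1; tbp >= 0; --tbp) {
            advance(tbp, false);
            Rcpp::checkUserInterrupt();
          }
        }
      }
    }
    if (!ok)
      stop("sweep trajectory failed to reach the target frequency after %d retries",
           (int)retries_used);
  }

  // --- sampling ---------------------------------------------------------
  std::vector<int> leafIds;
  if (panmictic)
    leafIds = {ANC};
  else
    leafIds = {AFR, EUR, ASN};
  if ((int)leafIds.size() != n_hap_sample.size())
    stop("n_hap_sample length does not match the number of sampled populations");

  std::vector<const word*> rows;
  std::vector<int> popSizesOut;
  for (size_t li = 0; li < leafIds.size(); ++li) {
    Pop& p = w.p[leafIds[li]];
    int nh = n_hap_sample[li];
    if (nh > 2 * p.N) stop("requested more haplotypes than the population holds");
    int nind = (nh + 1) / 2;
    std::vector<int> idx(p.N);
    for (int i = 0; i < p.N; ++i) idx[i] = i;
    for (int i = 0; i < nind; ++i) {
      int j = i + sim.rng.below(p.N - i);
      std::swap(idx[i], idx[j]);
    }
    int taken = 0;
    for (int i = 0; i < nind && taken < nh; ++i) {
      rows.push_back(p.row(2 * idx[i], sim.W));
      ++taken;
      if (taken < nh) {
        rows.push_back(p.row(2 * idx[i] + 1, sim.W));
        ++taken;
      }
    }
    popSizesOut.push_back(nh);
  }
  int nrow = (int)rows.size();

  std::vector<int> keep;
  std::vector<long long> cnt(sim.S, 0);
  for (int i = 0; i < nrow; ++i) {
    const word* r = rows[i];
    for (int wd = 0; wd < sim.W; ++wd) {
      word x = r[wd];
      while (x) {
        int b = __builtin_ctzll(x);
        ++cnt[(wd << 6) + b];
        x &= x - 1;
      }
    }
  }
  for (int s = 0; s < sim.S; ++s)
    if (cnt[s] > 0 && cnt[s] < nrow) keep.push_back(s);

  RawMatrix out(nrow, (int)keep.size());
  NumericVector posOut(keep.size());
  int focal_col = NA_INTEGER;
  for (size_t c = 0; c < keep.size(); ++c) {
    int s = keep[c];
    posOut[c] = sim.pos[s];
    if (sweep && s == sim.focal) focal_col = (int)c + 1;
    for (int i = 0; i < nrow; ++i) out(i, (int)c) = (Rbyte)getbit(rows[i], s);
  }

  return List::create(_["alleles"] = out, _["positions"] = posOut,
                      _["pop_sizes"] = IntegerVector(popSizesOut.begin(), popSizesOut.end()),
                      _["focal_col"] = focal_col, _["final_freq"] = final_freq,
                      _["onset_tbp"] = onset_tbp, _["retries"] = (double)retries_used,
                      _["reintroductions"] = (double)sim.nReintro,
                      _["skipped_mutations"] = (double)sim.nSkipped);
}
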