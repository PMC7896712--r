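// Forward-time Wright-Fisher core: mutation, recombination, fitness-
// proportional parent sampling, per-generation compaction of fixed/lost
// sites.  Haplotypes are stored haplotype-major as raw bytes so that
// crossover segments are memcpy's; sites are kept sorted by position.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstring>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

struct EffectParams {
  double prop_causal, mean_s, beta, rho, copula_r, trait_scale, h_const, k_ck;
  bool h_variable;
};

EffectParams as_effect_params(const List& ep) {
  EffectParams e;
  e.prop_causal = as<double>(ep["prop_causal"]);
  e.mean_s = as<double>(ep["mean_s"]);
  e.beta = as<double>(ep["beta"]);
  e.rho = as<double>(ep["rho"]);
  e.copula_r = as<double>(ep["copula_r"]);
  e.trait_scale = as<double>(ep["trait_scale"]);
  e.h_const = as<double>(ep["h_const"]);
  e.k_ck = as<double>(ep["k_ck"]);
  e.h_variable = as<bool>(ep["h_variable"]);
  return e;
}

// One mutation: neutral with prob 1-prop_causal, otherwise pleiotropic
// with |s|,|a| gamma(beta, scale=|mean_s|/beta) coupled through a
// Gaussian copula (copula_r pre-solved in R so that cor(|a|,|s|)=rho).
void draw_effect(const EffectParams& ep, int& is_qtl, double& s, double& a,
                 double& h) {
  if (unif_rand() >= ep.prop_causal) {
    is_qtl = 0; s = 0.0; a = 0.0; h = 0.0;
    return;
  }
  is_qtl = 1;
  const double scale = -ep.mean_s / ep.beta;
  double x1, x2;
  if (ep.rho >= 1.0) {
    x1 = R::rgamma(ep.beta, scale);
    x2 = x1;
  } else {
    double z1 = norm_rand();
    double z2 = ep.copula_r * z1 +
                std::sqrt(1.0 - ep.copula_r * ep.copula_r) * norm_rand();
    x1 = R::qgamma(R::pnorm(z1, 0.0, 1.0, 1, 0), ep.beta, scale, 1, 0);
    x2 = R::qgamma(R::pnorm(z2, 0.0, 1.0, 1, 0), ep.beta, scale, 1, 0);
  }
  s = -x1;
  a = -x2 * ep.trait_scale;
  // variable dominance: h ~ U[0, exp(-k|s|)], k pre-solved for E[h]
  h = ep.h_variable ? unif_rand() * std::exp(-ep.k_ck * x1) : ep.h_const;
}

struct Mut {
  int pos, is_qtl, hap;
  double s, a, h;
};

// Copy one gamete from parent strands pa/pb (length S, sites sorted by
// position `pos`) into dst.  Crossovers: Poisson(c*(L-1)) count, uniform
// positions, no interference; starting strand is a fair coin.
int make_gamete(const uint8_t* pa, const uint8_t* pb, uint8_t* dst,
                const std::vector<int>& pos, int S, double L, double c) {
  int k = (c > 0.0 && L > 1.0) ? (int)R::rpois(c * (L - 1.0)) : 0;
  int strand = (unif_rand() < 0.5) ? 0 : 1;
  if (S == 0) return k;
  if (k == 0) {
    std::memcpy(dst, strand ? pb : pa, (size_t)S);
    return 0;
  }
  std::vector<double> bp(k);
  for (int t = 0; t < k; ++t) bp[t] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  int prev = 0;
  for (int t = 0; t < k; ++t) {
    // first site with position >= bp[t] starts the next segment
    int cut = (int)(std::lower_bound(pos.begin(), pos.end(), bp[t],
                                     [](int p, double b) { return (double)p < b; }) -
                    pos.begin());
    if (cut > prev)
      std::memcpy(dst + prev, (strand ? pb : pa) + prev, (size_t)(cut - prev));
    strand ^= 1;
    prev = cut;
  }
  if (S > prev)
    std::memcpy(dst + prev, (strand ? pb : pa) + prev, (size_t)(S - prev));
  return k;
}

}  // namespace

// Draw n mutation records (testing surface for the effect sampler).
// [[Rcpp::export]]
DataFrame draw_effects_cpp(int n, List effect_params) {
  EffectParams ep = as_effect_params(effect_params);
  IntegerVector is_qtl(n);
  NumericVector s(n), a(n), h(n);
  for (int i = 0; i < n; ++i) {
    int q; double si, ai, hi;
    draw_effect(ep, q, si, ai, hi);
    is_qtl[i] = q; s[i] = si; a[i] = ai; h[i] = hi;
  }
  return DataFrame::create(_["is_qtl"] = is_qtl, _["s"] = s, _["a"] = a,
                           _["h"] = h);
}

// Single-gamete testing surface: returns the gamete and crossover count.
// [[Rcpp::export]]
List sim_gamete_cpp(IntegerVector hapA, IntegerVector hapB,
                    IntegerVector positions, double L, double c) {
  int S = hapA.size();
  if (hapB.size() != S || positions.size() != S)
    stop("hapA, hapB and positions must have equal length");
  std::vector<uint8_t> pa(S), pb(S);
  std::vector<int> pos(S);
  for (int j = 0; j < S; ++j) {
    pa[j] = (uint8_t)hapA[j];
    pb[j] = (uint8_t)hapB[j];
    pos[j] = positions[j];
  }
  std::vector<uint8_t> dst(S > 0 ? S : 1);
  int k = make_gamete(pa.data(), pb.data(), dst.data(), pos, S, L, c);
  IntegerVector out(S);
  for (int j = 0; j < S; ++j) out[j] = dst[j];
  return List::create(_["gamete"] = out, _["n_crossovers"] = k);
}

// [[Rcpp::export]]
List sim_run_cpp(int N, double L, double c, double U, int generations,
                 List effect_params, IntegerMatrix init_hap,
                 IntegerVector init_pos, IntegerVector init_is_qtl,
                 NumericVector init_s, NumericVector init_a,
                 NumericVector init_h, IntegerVector init_origin,
                 int start_gen, int track_dropped_from) {
  if (N < 2) stop("N must be >= 2");
  const int H2N = 2 * N;
  EffectParams ep = as_effect_params(effect_params);

  int S = init_pos.size();
  if (init_hap.nrow() != H2N || init_hap.ncol() != S)
    stop("init_hap must be a 2N x S matrix matching the site table");

  std::vector<uint8_t> H((size_t)H2N * S);
  for (int r = 0; r < H2N; ++r)
    for (int j = 0; j < S; ++j) H[(size_t)r * S + j] = (uint8_t)init_hap(r, j);
  std::vector<int> pos(init_pos.begin(), init_pos.end());
  std::vector<int> isq(init_is_qtl.begin(), init_is_qtl.end());
  std::vector<double> sv(init_s.begin(), init_s.end());
  std::vector<double> av(init_a.begin(), init_a.end());
  std::vector<double> hv(init_h.begin(), init_h.end());
  std::vector<int> orig(init_origin.begin(), init_origin.end());
  for (int j = 1; j < S; ++j)
    if (pos[j] <= pos[j - 1]) stop("site positions must be strictly increasing");

  std::unordered_set<int> posset(pos.begin(), pos.end());

  // dropped-site log (only from generation >= track_dropped_from, if >= 0)
  std::vector<int> drop_pos, drop_gen, drop_qtl;
  std::vector<int> drop_fixed;  // 1 = fixed, 0 = lost
  long n_fixed = 0, n_lost = 0, n_fixed_qtl = 0;
  long n_new_total = 0;
  double max_crossmean = c * (L - 1.0);
  (void)max_crossmean;

  std::vector<double> cw(N);
  std::vector<uint8_t> H2;
  std::vector<Mut> nm;
  std::vector<int> qtl_idx;

  for (int g = start_gen + 1; g <= start_gen + generations; ++g) {
    // ---- fitness (multiplicative over QTLs, floored at 0) ----
    qtl_idx.clear();
    for (int j = 0; j < S; ++j)
      if (isq[j]) qtl_idx.push_back(j);
    double wsum = 0.0;
    for (int i = 0; i < N; ++i) {
      const uint8_t* h0 = H.data() + (size_t)(2 * i) * S;
      const uint8_t* h1 = H.data() + (size_t)(2 * i + 1) * S;
      double wi = 1.0;
      for (int j : qtl_idx) {
        int gt = h0[j] + h1[j];
        if (gt == 1)
          wi *= 1.0 + sv[j] * hv[j];
        else if (gt == 2)
          wi *= 1.0 + sv[j];
      }
      if (wi < 0.0) wi = 0.0;
      wsum += wi;
      cw[i] = wsum;
    }
    if (wsum <= 0.0)
      stop("all individuals have zero fitness at generation %d; replicate aborted", g);

    // ---- offspring gametes + new mutations ----
    H2.assign((size_t)H2N * S, 0);
    nm.clear();
    std::unordered_set<int> newpos;
    for (int i = 0; i < N; ++i) {
      for (int par = 0; par < 2; ++par) {
        double u = unif_rand() * wsum;
        int p = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
        if (p >= N) p = N - 1;
        uint8_t* dst = H2.data() + (size_t)(2 * i + par) * S;
        make_gamete(H.data() + (size_t)(2 * p) * S, H.data() + (size_t)(2 * p + 1) * S, dst,
                    pos, S, L, c);
        int m = (U > 0.0) ? (int)R::rpois(U) : 0;
        for (int t = 0; t < m; ++t) {
          int q, tries = 0;
          do {
            q = (int)std::floor(unif_rand() * L);
            if (q >= (int)L) q = (int)L - 1;
            if (++tries > 100000)
              stop("could not place a new mutation: genome saturated");
          } while (posset.count(q) || newpos.count(q));
          newpos.insert(q);
          Mut mu;
          mu.pos = q; mu.hap = 2 * i + par;
          draw_effect(ep, mu.is_qtl, mu.s, mu.a, mu.h);
          nm.push_back(mu);
        }
      }
    }
    n_new_total += (long)nm.size();

    // ---- derived-allele counts on offspring; drop fixed/lost ----
    std::vector<int> cnt(S, 0);
    for (int r = 0; r < H2N; ++r) {
      const uint8_t* hr = H2.data() + (size_t)r * S;
      for (int j = 0; j < S; ++j) cnt[j] += hr[j];
    }
    std::vector<int> kept;
    kept.reserve(S);
    for (int j = 0; j < S; ++j) {
      if (cnt[j] > 0 && cnt[j] < H2N) {
        kept.push_back(j);
      } else {
        bool fixed = (cnt[j] == H2N);
        if (fixed) { ++n_fixed; if (isq[j]) ++n_fixed_qtl; }
        else ++n_lost;
        posset.erase(pos[j]);
        if (track_dropped_from >= 0 && g >= track_dropped_from) {
          drop_pos.push_back(pos[j]);
          drop_fixed.push_back(fixed ? 1 : 0);
          drop_gen.push_back(g);
          drop_qtl.push_back(isq[j]);
        }
      }
    }

    // ---- merge kept old sites with new mutations, sorted by position ----
    std::sort(nm.begin(), nm.end(),
              [](const Mut& x, const Mut& y) { return x.pos < y.pos; });
    int S2 = (int)kept.size() + (int)nm.size();
    std::vector<int> src(S2);
    std::vector<int> npos(S2), nisq(S2), norig(S2);
    std::vector<double> nsv(S2), nav(S2), nhv(S2);
    {
      size_t ki = 0, mi = 0;
      int t = 0;
      while (ki < kept.size() || mi < nm.size()) {
        bool take_old =
            (mi >= nm.size()) ||
            (ki < kept.size() && pos[kept[ki]] < nm[mi].pos);
        if (take_old) {
          int j = kept[ki++];
          src[t] = j;
          npos[t] = pos[j]; nisq[t] = isq[j]; norig[t] = orig[j];
          nsv[t] = sv[j]; nav[t] = av[j]; nhv[t] = hv[j];
        } else {
          const Mut& mu = nm[mi];
          src[t] = -1 - (int)mi;
          npos[t] = mu.pos; nisq[t] = mu.is_qtl; norig[t] = g;
          nsv[t] = mu.s; nav[t] = mu.a; nhv[t] = mu.h;
          posset.insert(mu.pos);
          ++mi;
        }
        ++t;
      }
    }
    std::vector<uint8_t> H3((size_t)H2N * S2, 0);
    for (int r = 0; r < H2N; ++r) {
      uint8_t* dst = H3.data() + (size_t)r * S2;
      const uint8_t* srow = H2.data() + (size_t)r * S;
      for (int t = 0; t < S2; ++t) {
        int sj = src[t];
        if (sj >= 0) dst[t] = srow[sj];
      }
    }
    for (size_t mi = 0; mi < nm.size(); ++mi) {
      // locate merged column of each new mutation by position
      int col = (int)(std::lower_bound(npos.begin(), npos.end(), nm[mi].pos) -
                      npos.begin());
      H3[(size_t)nm[mi].hap * S2 + col] = 1;
    }

    H.swap(H3);
    pos.swap(npos); isq.swap(nisq); orig.swap(norig);
    sv.swap(nsv); av.swap(nav); hv.swap(nhv);
    S = S2;
    if (g % 200 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix out((int)H2N, S);
  for (int r = 0; r < H2N; ++r)
    for (int j = 0; j < S; ++j) out(r, j) = H[(size_t)r * S + j];

  return List::create(
      _["haplotypes"] = out,
      _["position"] = IntegerVector(pos.begin(), pos.end()),
      _["is_qtl"] = IntegerVector(isq.begin(), isq.end()),
      _["s"] = NumericVector(sv.begin(), sv.end()),
      _["a"] = NumericVector(av.begin(), av.end()),
      _["h"] = NumericVector(hv.begin(), hv.end()),
      _["origin_gen"] = IntegerVector(orig.begin(), orig.end()),
      _["generation"] = start_gen + generations,
      _["n_fixed"] = (double)n_fixed, _["n_lost"] = (double)n_lost,
      _["n_fixed_qtl"] = (double)n_fixed_qtl,
      _["n_new_mutations"] = (double)n_new_total,
      _["dropped_pos"] = IntegerVector(drop_pos.begin(), drop_pos.end()),
      _["dropped_fixed"] = IntegerVector(drop_fixed.begin(), drop_fixed.end()),
      _["dropped_gen"] = IntegerVector(drop_gen.begin(), drop_gen.end()),
      _["dropped_is_qtl"] = IntegerVector(drop_qtl.begin(), drop_qtl.end()));
}

// Windowed LD pruning (PLINK --indep-pairwise semantics).  xs: centred
// and scaled N x S dosage matrix so that r = crossprod/(n-1); maf breaks
// ties: within a flagged pair the smaller-MAF SNP is dropped, ties drop
// the downstream SNP.
// [[Rcpp::export]]
LogicalVector ld_prune_cpp(NumericMatrix xs, int window, int step,
                           double r2max, NumericVector maf) {
  int n = xs.nrow(), S = xs.ncol();
  if (maf.size() != S) stop("maf length must match column count");
  std::vector<char> keep(S, 1);
  const double denom = (double)(n - 1);
  for (int start = 0; start < S; start += step) {
    int end = std::min(start + window, S);
    for (int i = start; i < end; ++i) {
      if (!keep[i]) continue;
      const double* xi = &xs(0, i);
      for (int j = i + 1; j < end; ++j) {
        if (!keep[j]) continue;
        const double* xj = &xs(0, j);
        double dot = 0.0;
        for (int t = 0; t < n; ++t) dot += xi[t] * xj[t];
        double r = dot / denom;
        if (r * r > r2max) {
          int drop = (maf[i] < maf[j]) ? i : j;  // tie -> downstream j
          keep[drop] = 0;
          if (drop == i) break;  // i gone; move to next i
        }
      }
    }
    if (end == S) break;
  }
  LogicalVector out(S);
  for (int j = 0; j < S; ++j) out[j] = (bool)keep[j];
  return out;
}
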