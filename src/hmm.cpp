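#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Li-Stephens haplotype-copying HMM primitives.
//
// The hidden state at marker m is which of the K reference haplotypes the
// sample haplotype is copying.  Transitions mix towards the uniform
// distribution with per-interval switch probability rho[m-1]
// (rho = 1 - exp(-4 Ne d / K), d in Morgans); emissions match the copied
// allele with probability 1 - theta.  All reference alleles are 0/1;
// observations may be missing (-1), in which case the site is
// uninformative and the forward-backward pass interpolates through it.
//
// All state arrays are laid out K-contiguous (index m*K + k) so the
// inner loops over reference haplotypes stream through memory.

struct FbResult {
  std::vector<double> pallele;  // P(copied allele = 1) per marker
  std::vector<double> loo;      // leave-one-out P(obs = 1) per marker
  double loglik;
};

static std::vector<double>& out_fwd();

// refT: K-contiguous reference alleles, refT[m*K + k] in {0,1}
static void fb_pass(const int* obs, const signed char* refT, int M, int K,
                    const double* rho, double theta, FbResult& out) {
  const double e1 = 1.0 - theta, e0 = theta;
  std::vector<double>& fwd = out_fwd();
  fwd.assign((size_t)M * K, 0.0);
  out.pallele.assign(M, 0.0);
  out.loo.assign(M, 0.0);
  out.loglik = 0.0;

  // forward
  {
    double s = 0.0;
    const signed char* r = refT;
    double* f = fwd.data();
    if (obs[0] < 0) {
      for (int k = 0; k < K; ++k) f[k] = 1.0;
      s = K;
    } else {
      for (int k = 0; k < K; ++k) {
        f[k] = (r[k] == obs[0]) ? e1 : e0;
        s += f[k];
      }
    }
    out.loglik += std::log(s / K);
    const double inv = 1.0 / s;
    for (int k = 0; k < K; ++k) f[k] *= inv;
  }
  for (int m = 1; m < M; ++m) {
    const double r_ = rho[m - 1], stay = 1.0 - r_, jump = r_ / K;
    const signed char* r = refT + (size_t)m * K;
    const double* fp = fwd.data() + (size_t)(m - 1) * K;
    double* f = fwd.data() + (size_t)m * K;
    double s = 0.0;
    if (obs[m] < 0) {
      for (int k = 0; k < K; ++k) {
        f[k] = stay * fp[k] + jump;
        s += f[k];
      }
    } else {
      const double em1 = (obs[m] == 1) ? e1 : e0;
      const double em0 = (obs[m] == 0) ? e1 : e0;
      for (int k = 0; k < K; ++k) {
        f[k] = (r[k] ? em1 : em0) * (stay * fp[k] + jump);
        s += f[k];
      }
    }
    out.loglik += std::log(s);
    const double inv = 1.0 / s;
    for (int k = 0; k < K; ++k) f[k] *= inv;
  }

  // backward (bwd_m(k) excludes the emission at m), combined on the fly
  std::vector<double> bwd(K, 1.0), u(K);
  for (int m = M - 1; m >= 0; --m) {
    const signed char* r = refT + (size_t)m * K;
    const double* f = fwd.data() + (size_t)m * K;
    // posterior gamma_m ~ fwd_m * bwd_m
    double sg = 0.0, pa = 0.0;
    for (int k = 0; k < K; ++k) {
      const double g = f[k] * bwd[k];
      sg += g;
      if (r[k]) pa += g;
    }
    out.pallele[m] = pa / sg;

    // leave-one-out predictive: prior_m(k) * bwd_m(k)
    double sp = 0.0, p1 = 0.0;
    if (m == 0) {
      for (int k = 0; k < K; ++k) {
        sp += bwd[k];
        if (r[k]) p1 += bwd[k];
      }
      p1 = (p1 * e1 + (sp - p1) * e0);
    } else {
      const double r_ = rho[m - 1], stay = 1.0 - r_, jump = r_ / K;
      const double* fp = fwd.data() + (size_t)(m - 1) * K;
      double s1 = 0.0;
      for (int k = 0; k < K; ++k) {
        const double p = (stay * fp[k] + jump) * bwd[k];
        sp += p;
        if (r[k]) s1 += p;
      }
      p1 = s1 * e1 + (sp - s1) * e0;
    }
    out.loo[m] = p1 / sp;

    // recurse bwd to m-1
    if (m > 0) {
      const double r_ = rho[m - 1], stay = 1.0 - r_, jump = r_ / K;
      double su = 0.0, smax = 0.0;
      if (obs[m] < 0) {
        for (int k = 0; k < K; ++k) { u[k] = bwd[k]; su += u[k]; }
      } else {
        const double em1 = (obs[m] == 1) ? e1 : e0;
        const double em0 = (obs[m] == 0) ? e1 : e0;
        for (int k = 0; k < K; ++k) {
          u[k] = (r[k] ? em1 : em0) * bwd[k];
          su += u[k];
        }
      }
      const double add = jump * su;
      for (int k = 0; k < K; ++k) {
        bwd[k] = stay * u[k] + add;
        if (bwd[k] > smax) smax = bwd[k];
      }
      const double inv = 1.0 / smax;
      for (int k = 0; k < K; ++k) bwd[k] *= inv;  // rescale
    }
  }
}

// forward-variable scratch buffer reused across calls
static std::vector<double>& out_fwd() {
  static std::vector<double> buf;
  return buf;
}

static std::vector<signed char> transpose_ref(const IntegerMatrix& ref) {
  const int M = ref.nrow(), K = ref.ncol();
  std::vector<signed char> refT((size_t)M * K);
  for (int k = 0; k < K; ++k) {
    for (int m = 0; m < M; ++m) refT[(size_t)m * K + k] = (signed char)ref(m, k);
  }
  return refT;
}

// [[Rcpp::export(name = ".ls_fb_cpp")]]
List ls_fb_cpp(IntegerVector obs, IntegerMatrix ref, NumericVector rho,
               double theta) {
  const int M = ref.nrow(), K = ref.ncol();
  if (obs.size() != M) stop("obs length does not match reference markers");
  if (M > 1 && rho.size() != M - 1) stop("rho must have length M-1");
  std::vector<signed char> refT = transpose_ref(ref);
  FbResult res;
  fb_pass(&obs[0], refT.data(), M, K, rho.begin(), theta, res);
  return List::create(_["pallele"] = NumericVector(res.pallele.begin(),
                                                   res.pallele.end()),
                      _["loo"] = NumericVector(res.loo.begin(),
                                               res.loo.end()),
                      _["loglik"] = res.loglik);
}

// Iterative conditional phasing of one diploid individual.  geno:
// 0/1/2/-1 at the typed markers; init1: initial allele of haplotype 1
// at het sites (from the caller's seeded RNG).  Each sweep runs
// forward-backward for both current haplotypes and re-orients every het
// site towards the jointly likelier configuration under the
// leave-one-out predictives.
static void phase_core(const IntegerVector& geno,
                       const std::vector<signed char>& refT, int M, int K,
                       const double* rho, double theta, int sweeps,
                       const IntegerVector& init1,
                       std::vector<int>& h1, std::vector<int>& h2,
                       FbResult& fb1, FbResult& fb2) {
  h1.assign(M, -1); h2.assign(M, -1);
  for (int m = 0; m < M; ++m) {
    if (geno[m] < 0) continue;
    if (geno[m] == 0) { h1[m] = 0; h2[m] = 0; }
    else if (geno[m] == 2) { h1[m] = 1; h2[m] = 1; }
    else { h1[m] = init1[m]; h2[m] = 1 - init1[m]; }
  }
  for (int it = 0; it < sweeps; ++it) {
    fb_pass(h1.data(), refT.data(), M, K, rho, theta, fb1);
    fb_pass(h2.data(), refT.data(), M, K, rho, theta, fb2);
    bool changed = false;
    for (int m = 0; m < M; ++m) {
      if (geno[m] != 1) continue;
      const double la = std::log(fb1.loo[m]) + std::log(1.0 - fb2.loo[m]);
      const double lb = std::log(1.0 - fb1.loo[m]) + std::log(fb2.loo[m]);
      const int want = (la >= lb) ? 1 : 0;
      if (h1[m] != want) { h1[m] = want; h2[m] = 1 - want; changed = true; }
    }
    if (!changed && it > 0) break;
  }
  fb_pass(h1.data(), refT.data(), M, K, rho, theta, fb1);
  fb_pass(h2.data(), refT.data(), M, K, rho, theta, fb2);
  for (int m = 0; m < M; ++m) {
    if (geno[m] >= 0) continue;
    h1[m] = (fb1.pallele[m] > 0.5) ? 1 : 0;
    h2[m] = (fb2.pallele[m] > 0.5) ? 1 : 0;
  }
}

// Exact diploid phasing by Viterbi decoding over ordered reference
// haplotype pairs (k1,k2).  Transitions factorize per haplotype
// (stay 1-rho+rho/K, switch rho/K), heterozygous emissions maximize
// over the two orientations and record the choice.  O(M K^2) time via
// two sequential maximizations; used for modest K where the pair state
// space is affordable.
static void pair_viterbi_core(const IntegerVector& geno,
                              const std::vector<signed char>& refT,
                              int M, int K, const double* rho, double theta,
                              std::vector<int>& h1, std::vector<int>& h2) {
  const double e1l = std::log(1.0 - theta), e0l = std::log(theta);
  const size_t KK = (size_t)K * K;
  std::vector<double> V(KK), B(KK), W(KK), tmp(KK);
  std::vector<unsigned char> bt1(M * KK), bt2(M * KK), ori(M * KK);
  auto emis = [&](int m, int k1, int k2, unsigned char& o) -> double {
    const int g = geno[m];
    o = 0;
    if (g < 0) return 0.0;
    const signed char a1 = refT[(size_t)m * K + k1];
    const signed char a2 = refT[(size_t)m * K + k2];
    if (g == 0) return (a1 == 0 ? e1l : e0l) + (a2 == 0 ? e1l : e0l);
    if (g == 2) return (a1 == 1 ? e1l : e0l) + (a2 == 1 ? e1l : e0l);
    const double l10 = (a1 == 1 ? e1l : e0l) + (a2 == 0 ? e1l : e0l);
    const double l01 = (a1 == 0 ? e1l : e0l) + (a2 == 1 ? e1l : e0l);
    if (l10 >= l01) { o = 1; return l10; }
    return l01;
  };
  for (int k1 = 0; k1 < K; ++k1) {
    for (int k2 = 0; k2 < K; ++k2) {
      unsigned char o;
      V[(size_t)k1 * K + k2] = -2.0 * std::log((double)K) +
        emis(0, k1, k2, o);
      ori[(size_t)k1 * K + k2] = o;
    }
  }
  for (int m = 1; m < M; ++m) {
    const double r_ = rho[m - 1];
    const double lsame = std::log(1.0 - r_ + r_ / K);
    const double ljump = std::log(r_ / K);
    // B(j1,k2) = max_j2 V(j1,j2) + log t(j2,k2); record argmax j2
    for (int j1 = 0; j1 < K; ++j1) {
      const double* v = V.data() + (size_t)j1 * K;
      int amax = 0;
      for (int j2 = 1; j2 < K; ++j2) if (v[j2] > v[amax]) amax = j2;
      double* b = B.data() + (size_t)j1 * K;
      unsigned char* bt = bt2.data() + (size_t)m * KK + (size_t)j1 * K;
      const double jumped = v[amax] + ljump;
      for (int k2 = 0; k2 < K; ++k2) {
        const double stayed = v[k2] + lsame;
        if (stayed >= jumped) { b[k2] = stayed; bt[k2] = (unsigned char)k2; }
        else { b[k2] = jumped; bt[k2] = (unsigned char)amax; }
      }
    }
    // W(k1,k2) = max_j1 B(j1,k2) + log t(j1,k1); record argmax j1
    for (int k2 = 0; k2 < K; ++k2) {
      int amax = 0;
      for (int j1 = 1; j1 < K; ++j1) {
        if (B[(size_t)j1 * K + k2] > B[(size_t)amax * K + k2]) amax = j1;
      }
      const double jumped = B[(size_t)amax * K + k2] + ljump;
      for (int k1 = 0; k1 < K; ++k1) {
        const double stayed = B[(size_t)k1 * K + k2] + lsame;
        unsigned char* bt = bt1.data() + (size_t)m * KK;
        if (stayed >= jumped) {
          W[(size_t)k1 * K + k2] = stayed;
          bt[(size_t)k1 * K + k2] = (unsigned char)k1;
        } else {
          W[(size_t)k1 * K + k2] = jumped;
          bt[(size_t)k1 * K + k2] = (unsigned char)amax;
        }
      }
    }
    for (size_t s = 0; s < KK; ++s) {
      unsigned char o;
      const int k1 = (int)(s / K), k2 = (int)(s % K);
      V[s] = W[s] + emis(m, k1, k2, o);
      ori[(size_t)m * KK + s] = o;
    }
  }
  // traceback
  size_t best = 0;
  for (size_t s = 1; s < KK; ++s) if (V[s] > V[best]) best = s;
  h1.assign(M, 0); h2.assign(M, 0);
  int k1 = (int)(best / K), k2 = (int)(best % K);
  for (int m = M - 1; m >= 0; --m) {
    const int g = geno[m];
    const signed char a1 = refT[(size_t)m * K + k1];
    const signed char a2 = refT[(size_t)m * K + k2];
    if (g == 0) { h1[m] = 0; h2[m] = 0; }
    else if (g == 2) { h1[m] = 1; h2[m] = 1; }
    else if (g == 1) {
      const int o = ori[(size_t)m * KK + (size_t)k1 * K + k2];
      h1[m] = o; h2[m] = 1 - o;
    } else {  // missing: copy the decoded references
      h1[m] = a1; h2[m] = a2;
    }
    if (m > 0) {
      const int pk1 = bt1[(size_t)m * KK + (size_t)k1 * K + k2];
      const int pk2 = bt2[(size_t)m * KK + (size_t)pk1 * K + k2];
      k1 = pk1; k2 = pk2;
    }
  }
}

// largest K for which the exact pair decoder is used
static const int PAIR_VITERBI_MAX_K = 64;

// [[Rcpp::export(name = ".ls_phase_cpp")]]
List ls_phase_cpp(IntegerVector geno, IntegerMatrix ref, NumericVector rho,
                  double theta, int sweeps, IntegerVector init1) {
  const int M = ref.nrow(), K = ref.ncol();
  std::vector<signed char> refT = transpose_ref(ref);
  std::vector<int> h1, h2;
  if (K <= PAIR_VITERBI_MAX_K) {
    pair_viterbi_core(geno, refT, M, K, rho.begin(), theta, h1, h2);
  } else {
    FbResult fb1, fb2;
    phase_core(geno, refT, M, K, rho.begin(), theta, sweeps, init1,
               h1, h2, fb1, fb2);
  }
  return List::create(_["h1"] = IntegerVector(h1.begin(), h1.end()),
                      _["h2"] = IntegerVector(h2.begin(), h2.end()));
}

// Phase one individual at the typed markers, then run a haploid
// forward-backward for each phased haplotype along the full marker chain
// (typed sites observed, untyped sites uninformative) and return the
// posterior copied-allele probabilities at every panel marker.
// typed_idx is 0-based into the full chain.
// [[Rcpp::export(name = ".ls_impute_cpp")]]
List ls_impute_cpp(IntegerVector geno, IntegerVector typed_idx,
                   IntegerMatrix ref_full, NumericVector rho_full,
                   double theta, int sweeps, IntegerVector init1) {
  const int M = ref_full.nrow(), K = ref_full.ncol();
  const int T = typed_idx.size();
  std::vector<signed char> refT = transpose_ref(ref_full);

  // typed-subset reference and switch rates (distances compose)
  std::vector<signed char> refT_t((size_t)T * K);
  std::vector<double> rho_t(std::max(T - 1, 0));
  for (int t = 0; t < T; ++t) {
    std::copy(refT.begin() + (size_t)typed_idx[t] * K,
              refT.begin() + (size_t)(typed_idx[t] + 1) * K,
              refT_t.begin() + (size_t)t * K);
  }
  for (int t = 0; t + 1 < T; ++t) {
    double keep = 1.0;
    for (int m = typed_idx[t]; m < typed_idx[t + 1]; ++m)
      keep *= 1.0 - rho_full[m];
    rho_t[t] = 1.0 - keep;
  }
  std::vector<int> h1t, h2t;
  FbResult fb1, fb2;
  if (K <= PAIR_VITERBI_MAX_K) {
    pair_viterbi_core(geno, refT_t, T, K, rho_t.data(), theta, h1t, h2t);
  } else {
    phase_core(geno, refT_t, T, K, rho_t.data(), theta, sweeps, init1,
               h1t, h2t, fb1, fb2);
  }

  std::vector<int> obs1(M, -1), obs2(M, -1);
  for (int t = 0; t < T; ++t) {
    obs1[typed_idx[t]] = h1t[t];
    obs2[typed_idx[t]] = h2t[t];
  }
  fb_pass(obs1.data(), refT.data(), M, K, rho_full.begin(), theta, fb1);
  double ll1 = fb1.loglik;
  NumericVector p1(fb1.pallele.begin(), fb1.pallele.end());
  fb_pass(obs2.data(), refT.data(), M, K, rho_full.begin(), theta, fb2);
  return List::create(_["p1"] = p1,
                      _["p2"] = NumericVector(fb2.pallele.begin(),
                                              fb2.pallele.end()),
                      _["h1"] = IntegerVector(h1t.begin(), h1t.end()),
                      _["h2"] = IntegerVector(h2t.begin(), h2t.end()),
                      _["loglik"] = ll1 + fb2.loglik);
}
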