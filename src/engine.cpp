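#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Direct-method Gillespie engine for the discretized transcription cycle.
//
// State per gene: UAS flag (STM only), promoter sub-state
// (0 = empty, 1 = polymerase pre-TFIIH, 2 = polymerase post-TFIIH),
// one flag per transcript bin, terminator flag.  Hard-core exclusion:
// a move whose target compartment is occupied has zero propensity.
//
// Gene classes: 0 = TFO (direct promoter recruitment, no UAS),
// 1 = STM (UAS recruitment then transfer), 2 = minimal (promoter
// permanently occupied post-TFIIH; escape gated on bin 1).
//
// Per-gene RNG streams are derived from (master seed, gene index) with
// splitmix64 -> xoshiro256++, so population results are independent of
// execution order.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (0xD1B54A32D192ED03ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() {
    double u = (next() >> 11) * 1.1102230246251565e-16;
    return (u <= 0.0) ? 5e-324 : u;
  }
};

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(NumericVector ratev, int n_bins, bool has_uas,
                  double t_total, double w0, double w1,
                  int n_genes, double seed, int gene_offset,
                  bool per_gene) {
  const double k1 = ratev[0], krev1 = ratev[1], k2 = ratev[2],
               krev2 = ratev[3], k3 = ratev[4], krev3 = ratev[5],
               k4 = ratev[6], k5 = ratev[7], khop = ratev[8],
               k7 = ratev[9];
  const int cls = (int)ratev[10];  // 0 TFO, 1 STM, 2 minimal
  const int n_comp = (has_uas ? 1 : 0) + 1 + n_bins + 1;
  const int uas_idx = has_uas ? 0 : -1;
  const int prom_idx = has_uas ? 1 : 0;
  const int bin0_idx = prom_idx + 1;
  const int term_idx = bin0_idx + n_bins;
  const double wlen = w1 - w0;

  std::vector<double> occ_sum(n_comp, 0.0), occ_sumsq(n_comp, 0.0);
  std::vector<double> occ_g(n_comp);
  NumericMatrix occ_mat = per_gene ? NumericMatrix(n_genes, n_comp)
                                   : NumericMatrix(0, 0);
  double recruits = 0, initiations = 0, terminations = 0;
  double w_initiations = 0, w_terminations = 0;
  double n_events = 0;
  long long violations = 0;

  const int n_chan = 8 + n_bins + 1;
  std::vector<double> prop(n_chan);
  std::vector<int> bins(n_bins);

  const uint64_t master = (uint64_t)seed;
  Xoshiro rng;

  for (int g = 0; g < n_genes; ++g) {
    rng.seed(master, (uint64_t)(gene_offset + g));
    int uas = 0, prom = (cls == 2) ? 2 : 0, term = 0;
    std::fill(bins.begin(), bins.end(), 0);
    std::fill(occ_g.begin(), occ_g.end(), 0.0);
    double t = 0.0;

    for (;;) {
      // propensities; exclusion -> blocked moves have zero propensity
      double A = 0.0;
      std::fill(prop.begin(), prop.end(), 0.0);
      if (cls == 1) {
        if (!uas) prop[0] = k1;                       // UAS recruitment
        if (uas)  prop[1] = krev1;                    // UAS dissociation
        if (uas && prom == 0) prop[2] = k2;           // UAS -> promoter
        if (prom == 1 && !uas) prop[3] = krev2;       // promoter -> UAS
      } else if (cls == 0) {
        if (prom == 0) prop[4] = k3;                  // direct recruitment
      }
      if (cls != 2) {
        if (prom == 1) { prop[5] = krev3; prop[6] = k4; }
      }
      if (prom == 2 && !bins[0]) prop[7] = k5;        // initiation
      for (int i = 0; i < n_bins - 1; ++i)
        if (bins[i] && !bins[i + 1]) prop[8 + i] = khop;
      if (n_bins > 0 && bins[n_bins - 1] && !term) prop[8 + n_bins - 1] = khop;
      if (term) prop[8 + n_bins] = k7;                // terminator release
      for (int c = 0; c < n_chan; ++c) A += prop[c];

      double t2;
      if (A <= 0.0) {
        t2 = t_total;  // absorbing: fast-forward the clock
      } else {
        t2 = t - std::log(rng.unif()) / A;
      }
      // time-weighted occupancy over the measurement window
      double lo = (t > w0) ? t : w0;
      double hi = (t2 < w1) ? t2 : w1;
      if (hi > lo) {
        if (has_uas && uas) occ_g[uas_idx] += hi - lo;
        if (prom != 0) occ_g[prom_idx] += hi - lo;
        for (int i = 0; i < n_bins; ++i)
          if (bins[i]) occ_g[bin0_idx + i] += hi - lo;
        if (term) occ_g[term_idx] += hi - lo;
      }
      if (A <= 0.0 || t2 >= t_total) break;
      t = t2;

      // select channel
      double r = rng.unif() * A, cum = 0.0;
      int ch = n_chan - 1;
      for (int c = 0; c < n_chan; ++c) {
        cum += prop[c];
        if (r <= cum) { ch = c; break; }
      }
      n_events += 1;
      switch (ch) {
      case 0: if (uas) { ++violations; break; } uas = 1; recruits += 1; break;
      case 1: uas = 0; break;
      case 2: if (prom != 0) { ++violations; break; } uas = 0; prom = 1; break;
      case 3: if (uas) { ++violations; break; } prom = 0; uas = 1; break;
      case 4: if (prom != 0) { ++violations; break; } prom = 1; recruits += 1; break;
      case 5: prom = 0; break;
      case 6: prom = 2; break;
      case 7:
        if (bins[0]) { ++violations; break; }
        bins[0] = 1; prom = (cls == 2) ? 2 : 0; initiations += 1;
        if (t >= w0 && t < w1) w_initiations += 1;
        break;
      default:
        if (ch == 8 + n_bins) {
          term = 0; terminations += 1;
          if (t >= w0 && t < w1) w_terminations += 1;
        }
        else {
          int i = ch - 8;
          if (i == n_bins - 1) {
            if (term) { ++violations; break; }
            bins[i] = 0; term = 1;
          } else {
            if (bins[i + 1]) { ++violations; break; }
            bins[i] = 0; bins[i + 1] = 1;
          }
        }
      }
    }

    for (int c = 0; c < n_comp; ++c) {
      double o = occ_g[c] / wlen;
      occ_sum[c] += o; occ_sumsq[c] += o * o;
      if (per_gene) occ_mat(g, c) = o;
    }
  }

  NumericVector mean_(n_comp), se_(n_comp);
  for (int c = 0; c < n_comp; ++c) {
    double m = occ_sum[c] / n_genes;
    mean_[c] = m;
    if (n_genes > 1) {
      double var = (occ_sumsq[c] - n_genes * m * m) / (n_genes - 1.0);
      se_[c] = std::sqrt((var > 0 ? var : 0.0) / n_genes);
    } else {
      se_[c] = NA_REAL;
    }
  }

  List out = List::create(
    _["mean"] = mean_, _["se"] = se_,
    _["recruitments"] = recruits, _["initiations"] = initiations,
    _["terminations"] = terminations,
    _["window_initiations"] = w_initiations,
    _["window_terminations"] = w_terminations,
    _["n_events"] = n_events,
    _["exclusion_violations"] = (double)violations);
  if (per_gene) out["per_gene"] = occ_mat;
  return out;
}
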