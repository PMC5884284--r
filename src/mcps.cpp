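#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <vector>
using namespace Rcpp;

// Channel-set clustering by circular variance at one time sample.
//
// Channels are represented as bits of a uint64 mask (bit i = channel i,
// 0-based in montage order). The *encoded label integer* used for
// tie-breaking and for hexadecimal labels puts channel 1 at the most
// significant bit of a word of `total_bits` bits (montage order,
// MSB-first, padded to a multiple of 4).

static inline int popcount64(uint64_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

static inline uint64_t encode_label_int(uint64_t mask, int total_bits) {
  uint64_t code = 0;
  for (int i = 0; i < 64; ++i) {
    if (mask & (uint64_t(1) << i)) code |= uint64_t(1) << (total_bits - 1 - i);
  }
  return code;
}

struct Fuzzy {
  uint64_t mask;
  double rbar;
  int size;
};

// Greedy seed-and-grow fuzzy clusters: one seed per channel; repeatedly
// add the channel maximising the joint mean-resultant magnitude, stopping
// before any addition that would drop it below r. Duplicate member sets
// are merged.
static std::vector<Fuzzy> fuzzy_clusters(const double* cs, const double* sn,
                                         int nch, double r) {
  std::vector<Fuzzy> out;
  std::set<uint64_t> seen;
  for (int seed = 0; seed < nch; ++seed) {
    uint64_t mask = uint64_t(1) << seed;
    double A = cs[seed], B = sn[seed];
    int size = 1;
    while (size < nch) {
      int best = -1;
      double bestR = -1.0;
      for (int m = 0; m < nch; ++m) {
        if (mask & (uint64_t(1) << m)) continue;
        double R = std::sqrt((A + cs[m]) * (A + cs[m]) +
                             (B + sn[m]) * (B + sn[m])) / (size + 1);
        if (R > bestR) { bestR = R; best = m; }
      }
      if (best < 0 || bestR < r) break;
      mask |= uint64_t(1) << best;
      A += cs[best];
      B += sn[best];
      ++size;
    }
    if (seen.insert(mask).second) {
      double rbar = std::sqrt(A * A + B * B) / size;
      out.push_back({mask, rbar, size});
    }
  }
  return out;
}

static double rbar_of(uint64_t mask, const double* cs, const double* sn) {
  double A = 0, B = 0;
  int size = 0;
  for (int i = 0; i < 64; ++i) {
    if (mask & (uint64_t(1) << i)) { A += cs[i]; B += sn[i]; ++size; }
  }
  if (size == 0) return 0.0;
  return std::sqrt(A * A + B * B) / size;
}

// Reduce overlapping fuzzy clusters to a disjoint covering partition:
// repeatedly accept the candidate with highest rbar (ties: larger
// cardinality, then smallest encoded label integer), strip its members
// from the survivors, recompute their rbar on the reduced sets, and drop
// any multi-channel survivor falling below r. Channels never accepted
// into a multi-channel cluster end as singletons.
static void hard_partition(std::vector<Fuzzy> cand, const double* cs,
                           const double* sn, int nch, double r,
                           int total_bits, uint64_t* cluster_of) {
  uint64_t taken = 0;
  uint64_t all = (nch >= 64) ? ~uint64_t(0) : ((uint64_t(1) << nch) - 1);
  while (true) {
    // reduce and filter
    std::vector<Fuzzy> pool;
    std::set<uint64_t> seen;
    for (const Fuzzy& f : cand) {
      uint64_t m = f.mask & ~taken;
      if (!m || !seen.insert(m).second) continue;
      int sz = popcount64(m);
      double rb = rbar_of(m, cs, sn);
      if (sz > 1 && rb < r) continue;
      pool.push_back({m, rb, sz});
    }
    if (pool.empty()) break;
    int best = 0;
    for (int i = 1; i < (int)pool.size(); ++i) {
      const Fuzzy &a = pool[i], &b = pool[best];
      bool better = false;
      if (a.rbar > b.rbar + 1e-15) better = true;
      else if (a.rbar > b.rbar - 1e-15) {
        if (a.size > b.size) better = true;
        else if (a.size == b.size &&
                 encode_label_int(a.mask, total_bits) <
                 encode_label_int(b.mask, total_bits)) better = true;
      }
      if (better) best = i;
    }
    uint64_t m = pool[best].mask;
    for (int i = 0; i < nch; ++i) {
      if (m & (uint64_t(1) << i)) cluster_of[i] = m;
    }
    taken |= m;
    cand.swap(pool);
    if (taken == all) break;
  }
  for (int i = 0; i < nch; ++i) {
    if (!(taken & (uint64_t(1) << i))) cluster_of[i] = uint64_t(1) << i;
  }
}

// [[Rcpp::export]]
List cpp_fuzzy_clusters(NumericVector cos_t, NumericVector sin_t, double r) {
  int nch = cos_t.size();
  if (nch > 63) stop("at most 63 channels supported");
  std::vector<Fuzzy> fc = fuzzy_clusters(REAL(cos_t), REAL(sin_t), nch, r);
  List members(fc.size());
  NumericVector rbar(fc.size());
  for (size_t i = 0; i < fc.size(); ++i) {
    std::vector<int> idx;
    for (int j = 0; j < nch; ++j)
      if (fc[i].mask & (uint64_t(1) << j)) idx.push_back(j + 1);
    members[i] = wrap(idx);
    rbar[i] = fc[i].rbar;
  }
  return List::create(_["members"] = members, _["rbar"] = rbar);
}

// [[Rcpp::export]]
IntegerVector cpp_hard_partition(NumericVector cos_t, NumericVector sin_t,
                                 double r, int total_bits) {
  int nch = cos_t.size();
  if (nch > 31) stop("hard partition codes limited to 31 channels");
  std::vector<Fuzzy> fc = fuzzy_clusters(REAL(cos_t), REAL(sin_t), nch, r);
  std::vector<uint64_t> cl(nch, 0);
  hard_partition(fc, REAL(cos_t), REAL(sin_t), nch, r, total_bits, cl.data());
  IntegerVector out(nch);
  for (int i = 0; i < nch; ++i)
    out[i] = (int)encode_label_int(cl[i], total_bits);
  return out;
}

// Clustering over a whole channels x samples phase matrix for one band.
// [[Rcpp::export]]
IntegerMatrix cpp_cluster_matrix(NumericMatrix cos_t, NumericMatrix sin_t,
                                 double r, int total_bits) {
  int nch = cos_t.nrow(), N = cos_t.ncol();
  if (nch > 31) stop("hard partition codes limited to 31 channels");
  IntegerMatrix out(nch, N);
  std::vector<double> cs(nch), sn(nch);
  std::vector<uint64_t> cl(nch);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < nch; ++j) { cs[j] = cos_t(j, n); sn[j] = sin_t(j, n); }
    std::vector<Fuzzy> fc = fuzzy_clusters(cs.data(), sn.data(), nch, r);
    hard_partition(fc, cs.data(), sn.data(), nch, r, total_bits, cl.data());
    for (int j = 0; j < nch; ++j)
      out(j, n) = (int)encode_label_int(cl[j], total_bits);
  }
  return out;
}
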