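#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Exhaustive end-to-end scan: every sense-strand offset of every
// transcript is tested against every read; offsets with Hamming distance
// <= max_mm are reported. Reads longer than a transcript have no valid
// offset there (no terminal overhang is allowed).
//
// Sequences are packed 2 bits per base so that one XOR + popcount
// compares 32 bases at a time; the per-word early exit keeps the scan
// linear in practice.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

// 2-bit code per base; any non-ACGT byte maps to 0 (A)
static inline uint64_t base_code(char c) {
  switch (c) {
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return 0;
  }
}

static std::vector<uint64_t> pack2bit(const char *s, int len) {
  // one zero pad word so shifted extraction never reads past the end
  std::vector<uint64_t> w(len / 32 + 2, 0ULL);
  for (int i = 0; i < len; ++i)
    w[i >> 5] |= base_code(s[i]) << ((i & 31) << 1);
  return w;
}

static const uint64_t ODD_MASK = 0x5555555555555555ULL;

// [[Rcpp::export(name = ".hamming_scan")]]
DataFrame hamming_scan(CharacterVector reads, CharacterVector txs,
                       int max_mm) {
  std::vector<int> out_read, out_tx, out_start, out_mm;
  const int n_tx = txs.size();
  std::vector<std::vector<uint64_t> > tw(n_tx);
  std::vector<int> tlen(n_tx);
  for (int t = 0; t < n_tx; ++t) {
    const char *ts = CHAR(STRING_ELT(txs, t));
    tlen[t] = std::strlen(ts);
    tw[t] = pack2bit(ts, tlen[t]);
  }
  for (int r = 0; r < reads.size(); ++r) {
    const char *rs = CHAR(STRING_ELT(reads, r));
    const int rl = std::strlen(rs);
    const std::vector<uint64_t> rw = pack2bit(rs, rl);
    const int n_words = (rl + 31) / 32;
    const int tail_bases = rl - 32 * (n_words - 1);
    const uint64_t tail_mask =
      tail_bases == 32 ? ~0ULL : ((1ULL << (2 * tail_bases)) - 1ULL);
    for (int t = 0; t < n_tx; ++t) {
      const uint64_t *W = tw[t].data();
      const int last = tlen[t] - rl;
      for (int s = 0; s <= last; ++s) {
        int mm = 0;
        for (int j = 0; j < n_words; ++j) {
          const int idx = s + 32 * j;
          const int q = idx >> 5;
          const int p = (idx & 31) << 1;
          uint64_t w = W[q] >> p;
          if (p) w |= W[q + 1] << (64 - p);
          uint64_t x = w ^ rw[j];
          if (j == n_words - 1) x &= tail_mask;
          mm += popcount64((x | (x >> 1)) & ODD_MASK);
          if (mm > max_mm) break;
        }
        if (mm <= max_mm) {
          out_read.push_back(r + 1);
          out_tx.push_back(t + 1);
          out_start.push_back(s + 1);
          out_mm.push_back(mm);
        }
      }
    }
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["read"] = out_read, _["tx"] = out_tx,
                           _["start"] = out_start,
                           _["mismatches"] = out_mm);
}
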