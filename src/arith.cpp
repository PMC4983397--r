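#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Adaptive order-0 arithmetic coder (Witten-Neal-Cleary style, 32-bit range,
// E3 underflow handling). Symbols are 1..nsym at the R level; an implicit
// end-of-stream symbol (index nsym, 0-based) terminates every stream. All
// counts start at 1 and are halved (rounding up) when the total reaches 2^16.

static const uint64_t TOPV = 0xFFFFFFFFULL;
static const uint64_t HALF = 0x80000000ULL;
static const uint64_t QTR  = 0x40000000ULL;
static const uint64_t TQTR = 0xC0000000ULL;
static const uint64_t RESCALE_AT = 65536ULL;

struct AdaptiveModel {
  std::vector<uint32_t> cnt;
  uint64_t total;
  int ns; // alphabet size including EOS

  explicit AdaptiveModel(int nsym_with_eos)
    : cnt(nsym_with_eos, 1u), total(nsym_with_eos), ns(nsym_with_eos) {}

  void bounds(int s, uint64_t &lo, uint64_t &hi) const {
    lo = 0;
    for (int i = 0; i < s; ++i) lo += cnt[i];
    hi = lo + cnt[s];
  }

  void update(int s) {
    cnt[s]++;
    total++;
    if (total >= RESCALE_AT) {
      total = 0;
      for (int i = 0; i < ns; ++i) {
        cnt[i] = (cnt[i] + 1u) >> 1; // >= 1 since cnt >= 1
        total += cnt[i];
      }
    }
  }
};

// [[Rcpp::export(name = ".ac_encode_core")]]
IntegerVector ac_encode_core(IntegerVector syms, int nsym) {
  if (nsym < 1) stop("alphabet size must be >= 1");
  AdaptiveModel m(nsym + 1);
  std::vector<int> out;
  out.reserve(static_cast<size_t>(syms.size()) * 2 + 64);
  uint64_t low = 0, high = TOPV;
  long pending = 0;

  auto emit = [&](int b) {
    out.push_back(b);
    for (; pending > 0; --pending) out.push_back(1 - b);
  };

  auto code = [&](int s) {
    uint64_t clo, chi;
    m.bounds(s, clo, chi);
    uint64_t range = high - low + 1;
    high = low + range * chi / m.total - 1;
    low  = low + range * clo / m.total;
    for (;;) {
      if (high < HALF) {
        emit(0);
      } else if (low >= HALF) {
        emit(1); low -= HALF; high -= HALF;
      } else if (low >= QTR && high < TQTR) {
        ++pending; low -= QTR; high -= QTR;
      } else {
        break;
      }
      low <<= 1;
      high = (high << 1) | 1;
    }
    m.update(s);
  };

  for (R_xlen_t idx = 0; idx < syms.size(); ++idx) {
    int s = syms[idx] - 1;
    if (s < 0 || s >= nsym) stop("symbol outside the coder alphabet");
    code(s);
  }
  code(nsym); // end-of-stream

  ++pending;
  if (low < QTR) emit(0); else emit(1);
  return wrap(out);
}

// Decode one stream. `bits` is the payload only (length prefix handled at the
// R level). Reads of up to 96 phantom zero bits past the payload are part of
// normal register drain; if the EOS symbol has not appeared by then, or more
// than max_symbols are produced, the stream is malformed.
// [[Rcpp::export(name = ".ac_decode_core")]]
List ac_decode_core(IntegerVector bits, int nsym, double max_symbols) {
  if (nsym < 1) stop("alphabet size must be >= 1");
  AdaptiveModel m(nsym + 1);
  R_xlen_t nb = bits.size();
  R_xlen_t pos = 0;
  long phantom = 0;

  auto read_bit = [&]() -> uint64_t {
    if (pos < nb) return static_cast<uint64_t>(bits[pos++] != 0);
    if (++phantom > 96) stop("malformed stream: end-of-stream marker not found");
    return 0;
  };

  uint64_t low = 0, high = TOPV, value = 0;
  for (int i = 0; i < 32; ++i) value = (value << 1) | read_bit();

  std::vector<int> out;
  for (;;) {
    uint64_t range = high - low + 1;
    uint64_t scaled = ((value - low + 1) * m.total - 1) / range;
    int s = 0;
    uint64_t clo = 0;
    while (clo + m.cnt[s] <= scaled) { clo += m.cnt[s]; ++s; }
    uint64_t chi = clo + m.cnt[s];
    high = low + range * chi / m.total - 1;
    low  = low + range * clo / m.total;
    for (;;) {
      if (high < HALF) {
        // nothing
      } else if (low >= HALF) {
        low -= HALF; high -= HALF; value -= HALF;
      } else if (low >= QTR && high < TQTR) {
        low -= QTR; high -= QTR; value -= QTR;
      } else {
        break;
      }
      low <<= 1;
      high = (high << 1) | 1;
      value = (value << 1) | read_bit();
    }
    if (s == nsym) break; // end-of-stream
    out.push_back(s + 1);
    if (static_cast<double>(out.size()) > max_symbols)
      stop("malformed stream: decoded symbol limit exceeded");
    m.update(s);
  }

  return List::create(_["symbols"] = wrap(out),
                      _["bits_used"] = static_cast<double>(pos));
}
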