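#include <Rcpp.h>
#include <cstdint>

using namespace Rcpp;

// 32-bit FNV-1a over the UTF-8 bytes of each string. Returned as doubles
// because R has no unsigned 32-bit integer type; every value is an exact
// integer in [0, 2^32), well inside double precision.
// [[Rcpp::export]]
NumericVector fnv1a_hash32(CharacterVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) {
      out[i] = NA_REAL;
      continue;
    }
    const char *s = Rf_translateCharUTF8(STRING_ELT(x, i));
    uint32_t h = 2166136261u;
    for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
      h ^= (uint32_t)(*p);
      h *= 16777619u;
    }
    out[i] = (double)h;
  }
  return out;
}
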