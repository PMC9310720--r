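#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// splitmix64: well-mixed 64-bit finalizer, used as a counter-based generator.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

//' Counter-based uniform variates on per-person substreams
//'
//' Deterministic uniforms in (0, 1) keyed by (seed, stream, counter). Each
//' (stream, counter) pair addresses one draw, so simulated persons own
//' disjoint substreams: adding persons to a simulation never perturbs the
//' draws of existing ones, and the whole simulation is reproducible from the
//' scalar seed alone.
//'
//' @param seed integer scalar; the global simulation seed.
//' @param stream numeric vector of non-negative stream ids (person index).
//' @param counter numeric vector of non-negative draw counters, recycled
//'   against `stream`.
//' @return numeric vector of uniforms in (0, 1).
//' @keywords internal
// [[Rcpp::export]]
NumericVector hash_unif(double seed, NumericVector stream, NumericVector counter) {
  R_xlen_t ns = stream.size(), nc = counter.size();
  R_xlen_t n = ns > nc ? ns : nc;
  if (ns == 0 || nc == 0) return NumericVector(0);
  NumericVector out(n);
  uint64_t s = splitmix64((uint64_t)(int64_t)seed);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t h = splitmix64(s ^ splitmix64((uint64_t)(int64_t)stream[i % ns] * 0x9E3779B97F4A7C15ULL));
    h = splitmix64(h ^ (uint64_t)(int64_t)counter[i % nc]);
    // 53 random bits -> (0,1); offset by half an ulp so 0 is never returned
    out[i] = ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  return out;
}
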