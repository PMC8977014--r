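#include <Rcpp.h>
using namespace Rcpp;

// Exact modular products for field elements stored in doubles.
// Requires p < 2^53 and all inputs in [0, p) so that the double -> uint64_t
// conversion is lossless; the up-to-106-bit intermediate lives in __int128.

// [[Rcpp::export]]
NumericVector field_mulmod_cpp(NumericVector x, NumericVector y, double p) {
  R_xlen_t nx = x.size(), ny = y.size();
  if (nx != ny && nx != 1 && ny != 1)
    stop("field_mulmod: incompatible lengths");
  R_xlen_t n = std::max(nx, ny);
  uint64_t up = (uint64_t)p;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t xi = (uint64_t)x[nx == 1 ? 0 : i];
    uint64_t yi = (uint64_t)y[ny == 1 ? 0 : i];
    unsigned __int128 prod = (unsigned __int128)xi * yi;
    out[i] = (double)(uint64_t)(prod % up);
  }
  return out;
}
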