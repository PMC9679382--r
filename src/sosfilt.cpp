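// Cascaded biquad filtering, forward-backward (zero phase).  Each section
// is a direct-form-II-transposed second-order filter; the caller supplies
// the already-padded signal.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

void biquadForward(std::vector<double>& x, const double* b,
                   const double* a) {
  double z1 = 0.0, z2 = 0.0;
  for (size_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z1;
    z1 = b[1] * xi - a[1] * yi + z2;
    z2 = b[2] * xi - a[2] * yi;
    x[i] = yi;
  }
}

} // namespace

// [[Rcpp::export(name = ".sosFiltFiltC")]]
NumericVector sosFiltFiltC(NumericVector x, NumericMatrix b,
                           NumericMatrix a) {
  std::vector<double> v(x.begin(), x.end());
  const int ns = b.nrow();
  for (int s = 0; s < ns; ++s) {
    double bs[3] = {b(s, 0), b(s, 1), b(s, 2)};
    double as[3] = {a(s, 0), a(s, 1), a(s, 2)};
    biquadForward(v, bs, as);
    std::reverse(v.begin(), v.end());
    biquadForward(v, bs, as);
    std::reverse(v.begin(), v.end());
  }
  return NumericVector(v.begin(), v.end());
}
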