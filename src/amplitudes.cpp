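#include <Rcpp.h>
using namespace Rcpp;

// Scattering amplitude A(q) = sum_j f_j exp(-i q . r_j) evaluated for a set
// of q-vectors.  coords: N x 3 (Angstrom), f: N form-factor values at |q|,
// qvecs: J x 3 (1/Angstrom).  Returns a complex vector of length J.
// [[Rcpp::export(name = ".sw_amplitudes_cpp")]]
ComplexVector sw_amplitudes_cpp(NumericMatrix coords, NumericVector f,
                                NumericMatrix qvecs) {
  const int n = coords.nrow();
  const int j = qvecs.nrow();
  if (f.size() != n) stop("coords and f are not aligned");
  ComplexVector out(j);
  const double* x = &coords(0, 0);
  const double* y = &coords(0, 1);
  const double* z = &coords(0, 2);
  for (int q = 0; q < j; ++q) {
    const double qx = qvecs(q, 0), qy = qvecs(q, 1), qz = qvecs(q, 2);
    double re = 0.0, im = 0.0;
    for (int a = 0; a < n; ++a) {
      const double phase = qx * x[a] + qy * y[a] + qz * z[a];
      re += f[a] * std::cos(phase);
      im -= f[a] * std::sin(phase);
    }
    out[q].r = re;
    out[q].i = im;
  }
  return out;
}
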