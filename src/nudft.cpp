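#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;

// Dense nonuniform discrete Fourier transform:
//   F(q_i) = sum_j w_j * exp(-i * q_i . r_j)
// q: n x 3 scattering vectors (1/m), r: m x 3 point positions (m),
// w: m complex weights. Exact (no approximation); the fast path that the
// literal R brute-force oracle checks against.
// [[Rcpp::export(name = ".nudft_cpp")]]
ComplexVector nudft_cpp(NumericMatrix q, NumericMatrix r, ComplexVector w) {
  const R_xlen_t nq = q.nrow();
  const R_xlen_t np = r.nrow();
  if (r.ncol() != 3 || q.ncol() != 3)
    stop("q and r must have 3 columns");
  if (w.size() != np)
    stop("weights must match the number of points");

  std::vector<double> rx(np), ry(np), rz(np), wre(np), wim(np);
  for (R_xlen_t j = 0; j < np; ++j) {
    rx[j] = r(j, 0); ry[j] = r(j, 1); rz[j] = r(j, 2);
    wre[j] = w[j].r; wim[j] = w[j].i;
  }

  ComplexVector out(nq);
  for (R_xlen_t i = 0; i < nq; ++i) {
    const double qx = q(i, 0), qy = q(i, 1), qz = q(i, 2);
    double sre = 0.0, sim = 0.0;
    for (R_xlen_t j = 0; j < np; ++j) {
      const double ph = -(qx * rx[j] + qy * ry[j] + qz * rz[j]);
      const double cph = std::cos(ph), sph = std::sin(ph);
      // (wre + i wim) * (cph + i sph)
      sre += wre[j] * cph - wim[j] * sph;
      sim += wre[j] * sph + wim[j] * cph;
    }
    out[i].r = sre;
    out[i].i = sim;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
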