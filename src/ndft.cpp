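#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact non-uniform discrete Fourier transform between a Cartesian image
// grid and arbitrary k-space sample locations. Image coordinates are
// x_i = (i - n/2)/n in units of the field of view (i = 0..n-1), k-space
// coordinates in cycles per field of view, so the phase is
// 2*pi*(kx*x + ky*y [+ kz*z]). Forward and adjoint are exact conjugate
// transposes of each other, which the reconstruction tests rely on.
//
// The per-sample phase factors are separable across axes, so each sample
// costs one complex multiply-add per voxel plus O(nx+ny+nz) sincos calls.

static inline void axis_phases(double k, int n, std::vector< std::complex<double> > &ph) {
  ph.resize(n);
  for (int i = 0; i < n; ++i) {
    double x = (i - n / 2) / static_cast<double>(n);
    double ang = -2.0 * M_PI * k * x;
    ph[i] = std::complex<double>(std::cos(ang), std::sin(ang));
  }
}

// [[Rcpp::export]]
ComplexVector ndft_forward_cpp(NumericMatrix kpts, ComplexVector img, IntegerVector dims) {
  const int d = kpts.ncol();
  const int M = kpts.nrow();
  if (d != dims.size() || (d != 2 && d != 3))
    stop("kpts must have 2 or 3 columns matching dims");
  const int nx = dims[0], ny = dims[1], nz = (d == 3) ? dims[2] : 1;
  if (img.size() != (R_xlen_t)nx * ny * nz) stop("image size does not match dims");

  const std::complex<double> *im =
      reinterpret_cast<const std::complex<double> *>(COMPLEX(img));
  ComplexVector out(M);
  std::complex<double> *o = reinterpret_cast<std::complex<double> *>(COMPLEX(out));

  std::vector< std::complex<double> > px, py, pz;
  for (int m = 0; m < M; ++m) {
    axis_phases(kpts(m, 0), nx, px);
    axis_phases(kpts(m, 1), ny, py);
    if (d == 3) axis_phases(kpts(m, 2), nz, pz);
    std::complex<double> acc(0.0, 0.0);
    for (int k = 0; k < nz; ++k) {
      std::complex<double> wz = (d == 3) ? pz[k] : std::complex<double>(1.0, 0.0);
      for (int j = 0; j < ny; ++j) {
        std::complex<double> w = wz * py[j];
        const std::complex<double> *col = im + (R_xlen_t)(k * ny + j) * nx;
        std::complex<double> s(0.0, 0.0);
        for (int i = 0; i < nx; ++i) s += col[i] * px[i];
        acc += w * s;
      }
    }
    o[m] = acc;
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector ndft_adjoint_cpp(NumericMatrix kpts, ComplexVector data, IntegerVector dims) {
  const int d = kpts.ncol();
  const int M = kpts.nrow();
  if (d != dims.size() || (d != 2 && d != 3))
    stop("kpts must have 2 or 3 columns matching dims");
  if (data.size() != M) stop("data length must match number of k-space samples");
  const int nx = dims[0], ny = dims[1], nz = (d == 3) ? dims[2] : 1;

  ComplexVector out((R_xlen_t)nx * ny * nz);
  std::complex<double> *im = reinterpret_cast<std::complex<double> *>(COMPLEX(out));
  std::fill(im, im + (R_xlen_t)nx * ny * nz, std::complex<double>(0.0, 0.0));
  const std::complex<double> *y =
      reinterpret_cast<const std::complex<double> *>(COMPLEX(data));

  std::vector< std::complex<double> > px, py, pz;
  for (int m = 0; m < M; ++m) {
    axis_phases(kpts(m, 0), nx, px);
    axis_phases(kpts(m, 1), ny, py);
    if (d == 3) axis_phases(kpts(m, 2), nz, pz);
    for (int k = 0; k < nz; ++k) {
      std::complex<double> wz = (d == 3) ? std::conj(pz[k]) : std::complex<double>(1.0, 0.0);
      for (int j = 0; j < ny; ++j) {
        std::complex<double> w = y[m] * wz * std::conj(py[j]);
        std::complex<double> *col = im + (R_xlen_t)(k * ny + j) * nx;
        for (int i = 0; i < nx; ++i) col[i] += w * std::conj(px[i]);
      }
    }
  }
  return out;
}
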