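// FFT-based imaging kernels: Richardson-Lucy deconvolution, linear
// convolution with reflective boundaries, and the pupil-to-PSF transform.
// These sit in compiled code because they run inside the annealer's inner
// loop (hundreds of FFT pairs per optimized patch); the RL loop works on
// preallocated complex buffers to keep per-iteration allocation low.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Symmetric (edge-inclusive) reflection padding by b pixels on every side.
static mat pad_reflect(const mat& x, const int b) {
  const int nr = x.n_rows, nc = x.n_cols;
  mat out(nr + 2 * b, nc + 2 * b);
  for (int i = 0; i < nr + 2 * b; ++i) {
    int ii = i - b;
    while (ii < 0 || ii >= nr) {
      if (ii < 0) ii = -1 - ii;
      if (ii >= nr) ii = 2 * nr - 1 - ii;
    }
    for (int j = 0; j < nc + 2 * b; ++j) {
      int jj = j - b;
      while (jj < 0 || jj >= nc) {
        if (jj < 0) jj = -1 - jj;
        if (jj >= nc) jj = 2 * nc - 1 - jj;
      }
      out(i, j) = x(ii, jj);
    }
  }
  return out;
}

// Embed an odd-sized kernel into an nr x nc array with its center wrapped
// to the (0, 0) element, so multiplication in frequency space performs a
// centered convolution; returns its DFT.
static cx_mat otf_embed(const mat& kernel, const int nr, const int nc) {
  const int kr = kernel.n_rows, kc = kernel.n_cols;
  const int cr = (kr - 1) / 2, cc = (kc - 1) / 2;
  mat k0(nr, nc, fill::zeros);
  for (int i = 0; i < kr; ++i) {
    const int ii = ((i - cr) % nr + nr) % nr;
    for (int j = 0; j < kc; ++j) {
      const int jj = ((j - cc) % nc + nc) % nc;
      k0(ii, jj) = kernel(i, j);
    }
  }
  return fft2(cx_mat(k0, mat(nr, nc, fill::zeros)));
}

// Richardson-Lucy deconvolution with a unit-sum PSF.  The observed image
// is reflect-padded by the kernel radius so the circular convolutions of
// the update behave as linear convolutions over the original support; the
// iterate starts from the observed image itself, and the multiplicative
// updates preserve non-negativity.
// [[Rcpp::export]]
arma::mat rl_deconv_cpp(const arma::mat& observed, const arma::mat& psf,
                        const int iterations) {
  const int b = (std::max(psf.n_rows, psf.n_cols) - 1) / 2;
  const int nr0 = observed.n_rows, nc0 = observed.n_cols;
  const mat obs = pad_reflect(observed, b);
  const int nr = obs.n_rows, nc = obs.n_cols;
  const cx_mat otf = otf_embed(psf, nr, nc);
  const cx_mat otf_c = conj(otf);
  const double eps = 1e-12;
  const uword N = obs.n_elem;

  cx_mat est(obs, mat(nr, nc, fill::zeros));
  cx_mat ratio(nr, nc);
  cx_mat tmp;
  for (int it = 0; it < iterations; ++it) {
    tmp = fft2(est); tmp %= otf; tmp = ifft2(tmp);
    const cx_double* dp = tmp.memptr();
    const double* op = obs.memptr();
    cx_double* rp = ratio.memptr();
    for (uword i = 0; i < N; ++i) {
      double d = dp[i].real();
      if (d < eps) d = eps;
      rp[i] = cx_double(op[i] / d, 0.0);
    }
    tmp = fft2(ratio); tmp %= otf_c; tmp = ifft2(tmp);
    const cx_double* cp = tmp.memptr();
    cx_double* ep = est.memptr();
    for (uword i = 0; i < N; ++i) {
      double v = ep[i].real() * cp[i].real();
      ep[i] = cx_double(v < 0.0 ? 0.0 : v, 0.0);
    }
  }
  return real(est.submat(b, b, b + nr0 - 1, b + nc0 - 1));
}

// 'Same'-sized linear convolution with reflective boundary handling.
// [[Rcpp::export]]
arma::mat conv2_reflect_cpp(const arma::mat& image, const arma::mat& kernel) {
  const int b = (std::max(kernel.n_rows, kernel.n_cols) - 1) / 2;
  const mat img = pad_reflect(image, b);
  const int nr = img.n_rows, nc = img.n_cols;
  const cx_mat otf = otf_embed(kernel, nr, nc);
  mat out = real(ifft2(fft2(cx_mat(img, mat(nr, nc, fill::zeros))) % otf));
  return out.submat(b, b, b + image.n_rows - 1, b + image.n_cols - 1);
}

// Squared modulus of the 2-D DFT of the complex pupil, with the zero
// frequency shifted to the center of an even-sized grid.
// [[Rcpp::export]]
arma::mat pupil_intensity_cpp(const arma::cx_mat& pupil) {
  mat inten = square(abs(fft2(pupil)));
  inten = shift(inten, inten.n_rows / 2, 0);
  inten = shift(inten, inten.n_cols / 2, 1);
  return inten;
}
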