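// Separable 3D convolution with a 1D kernel (replicated borders), used to
// give simulated speckle a finite spatial correlation length.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void conv_dim(cube& x, const vec& k, const int dim) {
  const int r = (k.n_elem - 1) / 2;
  const int d1 = x.n_rows, d2 = x.n_cols, d3 = x.n_slices;
  cube out(d1, d2, d3, fill::zeros);
  for (int s = 0; s < d3; ++s)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int ii = i, jj = j, ss = s;
          if (dim == 0) ii = std::min(std::max(i + t, 0), d1 - 1);
          else if (dim == 1) jj = std::min(std::max(j + t, 0), d2 - 1);
          else ss = std::min(std::max(s + t, 0), d3 - 1);
          acc += k(t + r) * x(ii, jj, ss);
        }
        out(i, j, s) = acc;
      }
  x = out;
}

// [[Rcpp::export]]
arma::cube nn_sepconv3(const arma::cube& x, const arma::vec& kernel) {
  cube y = x;
  conv_dim(y, kernel, 0);
  conv_dim(y, kernel, 1);
  conv_dim(y, kernel, 2);
  return y;
}
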