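#include <Rcpp.h>
using namespace Rcpp;

// Voxelize the peripheral-lung geometry: homogeneous surrounding tissue
// (label 0), a spherical tumor (label 1) and an air-filled cylindrical
// bronchus along z (label 2), both centered at `center`. Cell-centered
// label assignment with precedence air > tumor > surrounding.

// [[Rcpp::export]]
RawVector build_phantom_cpp(IntegerVector dims, double h, NumericVector origin,
                            NumericVector center, double tumor_r,
                            double bronchus_r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  RawVector labels((R_xlen_t)nx * ny * nz);
  const double cx = center[0], cy = center[1], cz = center[2];
  const double rt2 = tumor_r * tumor_r, rb2 = bronchus_r * bronchus_r;

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = origin[2] + (k + 0.5) * h;
    const double dz2 = (z - cz) * (z - cz);
    for (int j = 0; j < ny; ++j) {
      const double y = origin[1] + (j + 0.5) * h;
      const double dy2 = (y - cy) * (y - cy);
      for (int i = 0; i < nx; ++i, ++idx) {
        const double x = origin[0] + (i + 0.5) * h;
        const double dx2 = (x - cx) * (x - cx);
        unsigned char lab = 0;
        if (dx2 + dy2 < rb2)
          lab = 2;
        else if (dx2 + dy2 + dz2 < rt2)
          lab = 1;
        labels[idx] = lab;
      }
    }
  }
  return labels;
}

// [[Rcpp::export]]
NumericVector count_labels_cpp(RawVector labels, int n_labels) {
  NumericVector out(n_labels);
  const R_xlen_t n = labels.size();
  for (R_xlen_t i = 0; i < n; ++i) out[(int)labels[i]] += 1.0;
  return out;
}
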