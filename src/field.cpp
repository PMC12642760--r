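#include <Rcpp.h>
using namespace Rcpp;

// Sum of ideal point-dipole fields at a set of evaluation points.
// E(r) = kappa * (3 (p . rhat) rhat - p) / max(|r|, rmin)^3,
// r the vector from source to point.  Singularities are softened by rmin.
// [[Rcpp::export(name = ".dipole_field_cpp")]]
NumericMatrix dipole_field_cpp(NumericMatrix pts, NumericMatrix src_pos,
                               NumericMatrix src_mom, double kappa,
                               double rmin) {
  const int np = pts.nrow(), ns = src_pos.nrow();
  NumericMatrix out(np, 2);
  for (int i = 0; i < np; ++i) {
    double ex = 0.0, ey = 0.0;
    const double px = pts(i, 0), py = pts(i, 1);
    for (int j = 0; j < ns; ++j) {
      double rx = px - src_pos(j, 0);
      double ry = py - src_pos(j, 1);
      double r = std::sqrt(rx * rx + ry * ry);
      double reff = r < rmin ? rmin : r;
      double r3 = reff * reff * reff;
      double mx = src_mom(j, 0), my = src_mom(j, 1);
      if (r > 0.0) {
        double ux = rx / r, uy = ry / r;
        double pdotu = mx * ux + my * uy;
        ex += kappa * (3.0 * pdotu * ux - mx) / r3;
        ey += kappa * (3.0 * pdotu * uy - my) / r3;
      } else {
        // coincident point: no preferred direction; -p/rmin^3 term only
        ex += kappa * (-mx) / r3;
        ey += kappa * (-my) / r3;
      }
    }
    out(i, 0) = ex;
    out(i, 1) = ey;
  }
  return out;
}
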