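#include <Rcpp.h>
using namespace Rcpp;

// Elliptical Hough accumulator over an explicit parameter grid.
//
// A candidate ellipse (cr, cc, a, b, theta) receives one vote per edge pixel
// whose approximate Euclidean distance to the ellipse curve is <= tol.
// For an edge point p, with (x', y') its coordinates in the ellipse frame
// (theta measured from the column axis, a along x'),
//   f(p)    = sqrt((x'/a)^2 + (y'/b)^2)
//   |grad f| = sqrt(x'^2/a^4 + y'^2/b^4) / f
//   dist(p) ~ |f - 1| / |grad f|
// which is first-order accurate near the curve.

static inline double ellipse_dist(double xp, double yp, double a, double b) {
  double xa = xp / a, yb = yp / b;
  double f2 = xa * xa + yb * yb;
  double f = std::sqrt(f2);
  if (f < 1e-9) return std::min(a, b);  // at the center
  double g = std::sqrt(xa * xa / (a * a) + yb * yb / (b * b)) / f;
  return std::fabs(f - 1.0) / g;
}

// [[Rcpp::export(name = ".hough_accumulate")]]
NumericVector hough_accumulate(NumericVector er, NumericVector ec,
                               NumericVector cr, NumericVector cc,
                               NumericVector a, NumericVector b,
                               NumericVector theta, double tol) {
  const int np = er.size();
  const int n1 = cr.size(), n2 = cc.size(), n3 = a.size(), n4 = b.size(),
            n5 = theta.size();
  NumericVector acc(n1 * n2 * n3 * n4 * n5);
  std::vector<double> xp(np), yp(np);

  for (int it = 0; it < n5; ++it) {
    double ct = std::cos(theta[it]), st = std::sin(theta[it]);
    for (int icr = 0; icr < n1; ++icr) {
      for (int icc = 0; icc < n2; ++icc) {
        for (int p = 0; p < np; ++p) {
          double dr = er[p] - cr[icr], dc = ec[p] - cc[icc];
          xp[p] = dc * ct + dr * st;
          yp[p] = -dc * st + dr * ct;
        }
        for (int ia = 0; ia < n3; ++ia) {
          for (int ib = 0; ib < n4; ++ib) {
            if (b[ib] > a[ia]) continue;  // enforce semi_major >= semi_minor
            int votes = 0;
            for (int p = 0; p < np; ++p)
              if (ellipse_dist(xp[p], yp[p], a[ia], b[ib]) <= tol) ++votes;
            // index order: cr fastest, then cc, a, b, theta
            acc[icr + n1 * (icc + n2 * ((R_xlen_t)ia + n3 * (ib + (R_xlen_t)n4 * it)))] =
              votes;
          }
        }
      }
    }
  }
  acc.attr("dim") = IntegerVector::create(n1, n2, n3, n4, n5);
  return acc;
}

// [[Rcpp::export(name = ".ellipse_support")]]
int ellipse_support(NumericVector er, NumericVector ec, double cr, double cc,
                    double a, double b, double theta, double tol) {
  const int np = er.size();
  double ct = std::cos(theta), st = std::sin(theta);
  int votes = 0;
  for (int p = 0; p < np; ++p) {
    double dr = er[p] - cr, dc = ec[p] - cc;
    double xp = dc * ct + dr * st;
    double yp = -dc * st + dr * ct;
    if (ellipse_dist(xp, yp, a, b) <= tol) ++votes;
  }
  return votes;
}
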