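#include <Rcpp.h>
using namespace Rcpp;

// k x k median filter with reflective border padding (k odd).

// [[Rcpp::export(name = ".median_filter")]]
NumericMatrix median_filter_cpp(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("window size must be a positive odd integer");
  const int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> win(k * k);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int n = 0;
      for (int dr = -h; dr <= h; ++dr) {
        int rr = r + dr;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        for (int dc = -h; dc <= h; ++dc) {
          int cc = c + dc;
          if (cc < 0) cc = -cc - 1;
          if (cc >= nc) cc = 2 * nc - cc - 1;
          win[n++] = x(rr, cc);
        }
      }
      std::nth_element(win.begin(), win.begin() + n / 2, win.begin() + n);
      out(r, c) = win[n / 2];
    }
  }
  return out;
}
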