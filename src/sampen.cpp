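#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// Templates are x[i..i+m-1] for i = 0..n-m-1 (so every length-m template
// has a length-(m+1) extension). B counts unordered pairs i < j whose
// length-m templates are within r in Chebyshev distance; A counts the
// subset whose length-(m+1) extensions also match. Self-matches excluded.
//
// Counting is organised by lag d = j - i: with c[i] = 1 when
// |x[i] - x[i+d]| <= r, a length-m template pair at (i, i+d) matches
// exactly when c[i..i+m-1] are all 1, tracked by a running count of
// consecutive hits. One comparison per (i, d) pair.
//
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1) stop("m must be >= 1");
  if (n < m + 2) stop("series too short for template length m");
  const int nt = n - m;          // number of templates
  const double *px = x.begin();
  double a = 0.0, b = 0.0;
  for (int d = 1; d <= nt - 1; ++d) {
    const int last = n - d;      // c[i] defined for i = 0..last-1
    int run = 0;
    for (int i = 0; i < last; ++i) {
      run = (std::fabs(px[i] - px[i + d]) <= r) ? run + 1 : 0;
      // template pair (i - m + 1, i - m + 1 + d), needs start <= nt-1-d
      if (run >= m && i - m + 1 <= nt - 1 - d) b += 1.0;
      if (run >= m + 1 && i - m <= nt - 1 - d) a += 1.0;
    }
  }
  return NumericVector::create(a, b);
}
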