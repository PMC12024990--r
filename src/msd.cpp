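// Time-origin-averaged mean squared displacement.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// traj: nrec x np x 3 array of unwrapped positions (m); lags: record indices.
// Averages over all overlapping time origins and all particles, per axis.
// [[Rcpp::export]]
NumericMatrix cpp_msd(NumericVector traj, IntegerVector lags) {
  IntegerVector dims = traj.attr("dim");
  int nrec = dims[0], np = dims[1];
  int nl = lags.size();
  NumericMatrix out(nl, 3);
  for (int li = 0; li < nl; ++li) {
    int lag = lags[li];
    if (lag <= 0 || lag >= nrec) {
      for (int a = 0; a < 3; ++a) out(li, a) = NA_REAL;
      continue;
    }
    double acc[3] = {0, 0, 0};
    long cnt = 0;
    for (int p = 0; p < np; ++p) {
      for (int t0 = 0; t0 + lag < nrec; ++t0) {
        for (int a = 0; a < 3; ++a) {
          double d = traj[(t0 + lag) + (R_xlen_t)nrec * (p + (R_xlen_t)np * a)] -
                     traj[t0 + (R_xlen_t)nrec * (p + (R_xlen_t)np * a)];
          acc[a] += d * d;
        }
        ++cnt;
      }
    }
    for (int a = 0; a < 3; ++a) out(li, a) = acc[a] / cnt;
  }
  return out;
}
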