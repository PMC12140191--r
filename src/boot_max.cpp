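#include <Rcpp.h>
using namespace Rcpp;

// Max-statistic bootstrap kernel: for each iteration, average one
// length-L segment per mouse (start frames drawn in R so all randomness
// stays on R's RNG) and return the maximum of the averaged series.
// `baseline` is frames x mice so the inner loop walks contiguous memory.
// [[Rcpp::export(name = ".boot_max_stat")]]
NumericVector boot_max_stat(NumericMatrix baseline, IntegerMatrix starts,
                            int L, bool absolute) {
  const int nboot = starts.nrow();
  const int m = starts.ncol();
  NumericVector out(nboot);
  std::vector<double> acc(L);
  for (int b = 0; b < nboot; ++b) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < m; ++i) {
      const double *col = &baseline(starts(b, i), i);
      for (int j = 0; j < L; ++j) acc[j] += col[j];
    }
    double best = R_NegInf;
    for (int j = 0; j < L; ++j) {
      double v = acc[j] / m;
      if (absolute) v = std::fabs(v);
      if (v > best) best = v;
    }
    out[b] = best;
  }
  return out;
}
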