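#include <Rcpp.h>
using namespace Rcpp;

// Local maxima of a 1-D signal. Plateaus count once, at their middle sample,
// and only when flanked by strictly smaller values on both sides.
// Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector local_maxima_cpp(NumericVector x) {
  int n = x.size();
  std::vector<int> out;
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1]) {
      int j = i;
      while (j + 1 < n && x[j + 1] == x[i]) ++j;
      if (j + 1 < n && x[j + 1] < x[i]) {
        out.push_back((i + j) / 2 + 1);
      }
      i = j + 1;
    } else {
      ++i;
    }
  }
  return wrap(out);
}

// Topographic prominence of each candidate peak: walk outward on each side,
// tracking the running minimum, until a strictly higher sample (or the signal
// edge) is reached; prominence is peak height minus the higher of the two
// side minima.
// [[Rcpp::export]]
NumericVector peak_prominence_cpp(NumericVector x, IntegerVector peaks) {
  int n = x.size();
  int m = peaks.size();
  NumericVector prom(m);
  for (int k = 0; k < m; ++k) {
    int p = peaks[k] - 1;
    double h = x[p];
    double lmin = h, rmin = h;
    for (int i = p - 1; i >= 0; --i) {
      if (x[i] > h) break;
      if (x[i] < lmin) lmin = x[i];
    }
    for (int i = p + 1; i < n; ++i) {
      if (x[i] > h) break;
      if (x[i] < rmin) rmin = x[i];
    }
    prom[k] = h - std::max(lmin, rmin);
  }
  return prom;
}

// 8-connected component labelling of a logical mask (column-major matrix).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) && lab(r, c) == 0) {
        ++next;
        stack.push_back(std::make_pair(r, c));
        lab(r, c) = next;
        while (!stack.empty()) {
          std::pair<int, int> rc = stack.back();
          stack.pop_back();
          for (int dc = -1; dc <= 1; ++dc) {
            for (int dr = -1; dr <= 1; ++dr) {
              int rr = rc.first + dr, cc = rc.second + dc;
              if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
                  mask(rr, cc) && lab(rr, cc) == 0) {
                lab(rr, cc) = next;
                stack.push_back(std::make_pair(rr, cc));
              }
            }
          }
        }
      }
    }
  }
  return lab;
}
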