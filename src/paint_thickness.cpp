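#include <Rcpp.h>
using namespace Rcpp;

// Local-thickness disc painting. For each foreground pixel q with inscribed
// disc radius r(q) (Euclidean distance transform), assign to every pixel p
// with |p - q| < r(q) the value max(2 r(q)).
// [[Rcpp::export(name = "paint_local_thickness")]]
NumericMatrix paint_local_thickness(IntegerMatrix fg, NumericMatrix edt) {
  int nr = fg.nrow(), nc = fg.ncol();
  NumericMatrix out(nr, nc);
  std::vector<std::pair<double, int> > centres;
  centres.reserve(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (fg(i, j) == 1 && edt(i, j) > 0)
        centres.push_back(std::make_pair(edt(i, j), j * nr + i));
  for (size_t k = 0; k < centres.size(); ++k) {
    double r = centres[k].first;
    int idx = centres[k].second;
    int qi = idx % nr, qj = idx / nr;
    double d = 2.0 * r;
    int rad = (int)std::ceil(r);
    double r2 = r * r;
    for (int dj = -rad; dj <= rad; ++dj) {
      int pj = qj + dj;
      if (pj < 0 || pj >= nc) continue;
      for (int di = -rad; di <= rad; ++di) {
        int pi = qi + di;
        if (pi < 0 || pi >= nr) continue;
        double dist2 = (double)di * di + (double)dj * dj;
        if (dist2 < r2 && fg(pi, pj) == 1 && out(pi, pj) < d)
          out(pi, pj) = d;
      }
    }
  }
  return out;
}
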