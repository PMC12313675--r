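#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Abundance-weighted between-sample mean nearest taxon distance:
//   0.5 * [ sum_{i in A} f_i min_{j in B} d(i,j) + sum_{j in B} f_j min_{i in A} d(i,j) ]
// relab: samples x taxa relative abundances; dfull: tip x tip cophenetic
// distances; idx maps table taxa to rows/cols of dfull (0-based).  The
// tip-shuffling null is expressed purely through idx, so the distance matrix
// is never copied.

static void presence_lists(const NumericMatrix& relab,
                           std::vector< std::vector<int> >& pres) {
  const int ns = relab.nrow(), nt = relab.ncol();
  pres.assign(ns, std::vector<int>());
  for (int s = 0; s < ns; ++s)
    for (int t = 0; t < nt; ++t)
      if (relab(s, t) > 0) pres[s].push_back(t);
}

static double half_mntd(const NumericMatrix& relab, const NumericMatrix& d,
                        const IntegerVector& idx,
                        const std::vector<int>& pa, const std::vector<int>& pb,
                        int a, bool weighted) {
  double acc = 0.0, wsum = 0.0;
  for (size_t ii = 0; ii < pa.size(); ++ii) {
    const int ti = idx[pa[ii]];
    double mn = R_PosInf;
    for (size_t jj = 0; jj < pb.size(); ++jj) {
      const double v = d(ti, idx[pb[jj]]);
      if (v < mn) mn = v;
    }
    const double w = weighted ? relab(a, pa[ii]) : 1.0;
    acc += w * mn;
    wsum += w;
  }
  return acc / wsum;
}

static void bmntd_fill(const NumericMatrix& relab, const NumericMatrix& dfull,
                       const IntegerVector& idx,
                       const std::vector< std::vector<int> >& pres,
                       bool weighted, NumericMatrix& out) {
  const int ns = relab.nrow();
  for (int a = 0; a < ns; ++a) {
    out(a, a) = 0.0;
    for (int b = a + 1; b < ns; ++b) {
      const double v = 0.5 * (half_mntd(relab, dfull, idx, pres[a], pres[b], a, weighted) +
                              half_mntd(relab, dfull, idx, pres[b], pres[a], b, weighted));
      out(a, b) = v;
      out(b, a) = v;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix bmntd_cpp(NumericMatrix relab, NumericMatrix dfull,
                        IntegerVector idx, bool weighted) {
  const int ns = relab.nrow();
  std::vector< std::vector<int> > pres;
  presence_lists(relab, pres);
  NumericMatrix out(ns, ns);
  bmntd_fill(relab, dfull, idx, pres, weighted, out);
  return out;
}

// Null mean/sd per pair across tip-shuffling replicates (rows of idx_null),
// via Welford accumulation.
// [[Rcpp::export]]
List bmntd_null_stats_cpp(NumericMatrix relab, NumericMatrix dfull,
                          IntegerMatrix idx_null, bool weighted) {
  const int ns = relab.nrow(), nt = relab.ncol();
  const int nrep = idx_null.nrow();
  std::vector< std::vector<int> > pres;
  presence_lists(relab, pres);
  NumericMatrix mean(ns, ns), m2(ns, ns), rep(ns, ns);
  IntegerVector idx(nt);
  for (int r = 0; r < nrep; ++r) {
    for (int t = 0; t < nt; ++t) idx[t] = idx_null(r, t);
    bmntd_fill(relab, dfull, idx, pres, weighted, rep);
    for (int a = 0; a < ns; ++a)
      for (int b = a + 1; b < ns; ++b) {
        const double x = rep(a, b);
        const double delta = x - mean(a, b);
        mean(a, b) += delta / (r + 1);
        m2(a, b) += delta * (x - mean(a, b));
      }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix sdm(ns, ns);
  for (int a = 0; a < ns; ++a)
    for (int b = a + 1; b < ns; ++b) {
      const double s = nrep > 1 ? std::sqrt(m2(a, b) / (nrep - 1)) : 0.0;
      sdm(a, b) = s; sdm(b, a) = s;
      mean(b, a) = mean(a, b);
    }
  return List::create(_["mean"] = mean, _["sd"] = sdm);
}
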