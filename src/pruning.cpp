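#include <Rcpp.h>
using namespace Rcpp;

// Postorder pruning sweep for Mk likelihoods.  Pf holds vec(P(t_i)) in
// column i (column-major s x s); partials are accumulated per node with
// per-node log scaling to avoid underflow.
// [[Rcpp::export]]
List prune_sweep(IntegerVector parents, IntegerVector kids,
                 IntegerVector post, NumericMatrix Pf,
                 NumericMatrix Lp, int nn, int s) {
  int n = Lp.nrow();
  NumericMatrix part(nn, s);
  NumericVector logscale(nn);
  LogicalVector done(nn);
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < s; ++a) part(i, a) = Lp(i, a);
    done[i] = true;
  }
  std::vector<double> msg(s);
  for (int e = 0; e < post.size(); ++e) {
    int i = post[e] - 1;
    int p = parents[i] - 1;
    int ch = kids[i] - 1;
    for (int a = 0; a < s; ++a) {
      double acc = 0.0;
      for (int b = 0; b < s; ++b) acc += Pf(a + b * s, i) * part(ch, b);
      msg[a] = acc;
    }
    if (!done[p]) {
      for (int a = 0; a < s; ++a) part(p, a) = msg[a];
      done[p] = true;
    } else {
      for (int a = 0; a < s; ++a) part(p, a) *= msg[a];
    }
    logscale[p] += logscale[ch];
    double mx = 0.0;
    for (int a = 0; a < s; ++a) if (part(p, a) > mx) mx = part(p, a);
    if (mx > 0 && (mx < 1e-100 || mx > 1e100)) {
      for (int a = 0; a < s; ++a) part(p, a) /= mx;
      logscale[p] += std::log(mx);
    }
  }
  return List::create(_["part"] = part, _["logscale"] = logscale);
}
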