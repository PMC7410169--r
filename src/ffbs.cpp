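#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward filtering + stochastic backward sampling for the threading
// HMM. The chain is organized in spans (one fixed local tree each). Within a
// span the transition matrix between adjacent columns factorizes as
//   T_c = diag(p0_c) + diag(1 - p0_c) * Rhat,
// where p0_c[i] = q[i]^w[c] is the no-recombination probability over the
// column's base-pair width and Rhat is the re-coalescence kernel. Between
// spans a boundary matrix B maps the previous span's states to the next.
//
// spans: list of lists with elements
//   Rhat (S x S), E (S x L), q (S), w (L; w[c] spans columns c -> c+1)
// pi: initial distribution over the first span's states
// bmats: list of boundary matrices (S_prev x S_next), length n_spans - 1
//
static int sample_index(NumericVector w) {
  double tot = 0.0;
  for (int i = 0; i < w.size(); ++i) tot += w[i];
  if (!(tot > 0.0)) stop("zero weight vector in backward sampling");
  double u = unif_rand() * tot, acc = 0.0;
  for (int i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return w.size() - 1;
}

// Returns sampled state indices (1-based, per span) and the log-likelihood.
// [[Rcpp::export]]
List ffbs_cpp(List spans, NumericVector pi, List bmats) {
  int nspan = spans.size();
  std::vector<NumericMatrix> alphas(nspan);
  double loglik = 0.0;

  NumericVector prev;  // scaled alpha at the last processed column
  for (int s = 0; s < nspan; ++s) {
    List sp = spans[s];
    NumericMatrix Rhat = sp["Rhat"];
    NumericMatrix E = sp["E"];
    NumericVector q = sp["q"];
    NumericVector w = sp["w"];
    int S = E.nrow(), L = E.ncol();
    NumericMatrix alpha(S, L);

    NumericVector a(S);
    if (s == 0) {
      for (int i = 0; i < S; ++i) a[i] = pi[i] * E(i, 0);
    } else {
      NumericMatrix B = bmats[s - 1];
      for (int t = 0; t < S; ++t) {
        double acc = 0.0;
        for (int i = 0; i < B.nrow(); ++i) acc += prev[i] * B(i, t);
        a[t] = acc * E(t, 0);
      }
    }
    double tot = 0.0;
    for (int i = 0; i < S; ++i) tot += a[i];
    if (!(tot > 0.0)) stop("zero likelihood at span %d column 1", s + 1);
    for (int i = 0; i < S; ++i) alpha(i, 0) = a[i] / tot;
    loglik += std::log(tot);

    for (int c = 1; c < L; ++c) {
      double wid = w[c - 1];
      // rec[i] = alpha[i] * (1 - p0[i]); stay[i] = alpha[i] * p0[i]
      NumericVector rec(S), stay(S);
      for (int i = 0; i < S; ++i) {
        double p0 = std::pow(q[i], wid);
        double al = alpha(i, c - 1);
        stay[i] = al * p0;
        rec[i] = al * (1.0 - p0);
      }
      tot = 0.0;
      for (int t = 0; t < S; ++t) {
        double acc = stay[t];
        for (int i = 0; i < S; ++i) acc += rec[i] * Rhat(i, t);
        acc *= E(t, c);
        a[t] = acc;
        tot += acc;
      }
      if (!(tot > 0.0)) stop("zero likelihood at span %d column %d", s + 1, c + 1);
      for (int i = 0; i < S; ++i) alpha(i, c) = a[i] / tot;
      loglik += std::log(tot);
    }
    alphas[s] = alpha;
    prev = alpha(_, L - 1);
  }

  // backward sampling
  List out_idx(nspan);
  int cur = -1;
  for (int s = nspan - 1; s >= 0; --s) {
    List sp = spans[s];
    NumericMatrix Rhat = sp["Rhat"];
    NumericVector q = sp["q"];
    NumericVector w = sp["w"];
    NumericMatrix alpha = alphas[s];
    int S = alpha.nrow(), L = alpha.ncol();
    IntegerVector idx(L);

    if (s == nspan - 1) {
      NumericVector wts = alpha(_, L - 1);
      cur = sample_index(wts);
    } else {
      List spn = spans[s + 1];
      NumericMatrix B = bmats[s];
      NumericVector wts(S);
      for (int i = 0; i < S; ++i) wts[i] = alpha(i, L - 1) * B(i, cur);
      cur = sample_index(wts);
    }
    idx[L - 1] = cur + 1;
    for (int c = L - 2; c >= 0; --c) {
      double wid = w[c];
      NumericVector wts(S);
      for (int i = 0; i < S; ++i) {
        double p0 = std::pow(q[i], wid);
        double v = alpha(i, c) * (1.0 - p0) * Rhat(i, cur);
        if (i == cur) v += alpha(i, c) * p0;
        wts[i] = v;
      }
      cur = sample_index(wts);
      idx[c] = cur + 1;
    }
    out_idx[s] = idx;
  }
  return List::create(_["states"] = out_idx, _["loglik"] = loglik);
}
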