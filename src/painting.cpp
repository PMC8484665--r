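#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward for one recipient haplotype under the Li-Stephens
// copying model. H: L x K donor haplotypes (0/1), rec: length-L recipient,
// q: length L-1 per-step switch probabilities, w: length-L site span
// weights (bp), miscopy: emission error rate.
// Returns expected copied weight per donor, the log-likelihood, and the
// expected number of switch events per inter-site step.
// [[Rcpp::export]]
List ls_paint_hap(const IntegerMatrix& H, const IntegerVector& rec,
                  const NumericVector& q, const NumericVector& w,
                  double miscopy) {
  const int L = H.nrow(), K = H.ncol();
  if (rec.size() != L) stop("recipient length mismatch");
  if (q.size() != L - 1) stop("switch-probability length mismatch");
  const double e1 = 1.0 - miscopy, e0 = miscopy;

  NumericMatrix alpha(L, K);
  NumericVector c(L);
  double loglik = 0.0;

  // forward with per-site normalization
  {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = (H(0, k) == rec[0] ? e1 : e0) / K;
      alpha(0, k) = a; s += a;
    }
    c[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    loglik += std::log(s);
  }
  for (int l = 1; l < L; ++l) {
    const double ql = q[l - 1], stay = 1.0 - ql, jump = ql / K;
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = (H(l, k) == rec[l] ? e1 : e0);
      double a = e * (stay * alpha(l - 1, k) + jump);
      alpha(l, k) = a; s += a;
    }
    c[l] = s;
    for (int k = 0; k < K; ++k) alpha(l, k) /= s;
    loglik += std::log(s);
  }

  // backward (scaled by the forward normalizers) + accumulation
  NumericVector beta(K, 1.0), betan(K);
  NumericVector copied(K);
  NumericVector exp_switch(L - 1);
  {
    // site L-1 posterior = alpha (beta = 1)
    for (int k = 0; k < K; ++k) copied[k] += alpha(L - 1, k) * w[L - 1];
  }
  for (int l = L - 2; l >= 0; --l) {
    const double ql = q[l], stay = 1.0 - ql, jump = ql / K;
    double eb_sum = 0.0, a_sum = 0.0, ns = 0.0;
    for (int k = 0; k < K; ++k) {
      double eb = (H(l + 1, k) == rec[l + 1] ? e1 : e0) * beta[k];
      betan[k] = eb;          // e_{l+1}(k) * beta_{l+1}(k), pre-transition
      eb_sum += eb;
      a_sum += alpha(l, k);
      ns += alpha(l, k) * eb; // no-switch joint mass
    }
    // expected switch probability at this step
    double sw = jump * a_sum * eb_sum;
    double nsw = stay * ns;
    exp_switch[l] = sw / (sw + nsw);
    // beta_l(k) = (stay * betan[k] + jump * eb_sum) / c_{l+1}
    double g_sum = 0.0;
    for (int k = 0; k < K; ++k) {
      beta[k] = (stay * betan[k] + jump * eb_sum) / c[l + 1];
      betan[k] = alpha(l, k) * beta[k]; // unnormalized gamma
      g_sum += betan[k];
    }
    for (int k = 0; k < K; ++k) copied[k] += betan[k] / g_sum * w[l];
  }
  return List::create(_["copied"] = copied, _["loglik"] = loglik,
                      _["exp_switch"] = exp_switch);
}
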