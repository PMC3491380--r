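#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for the discretised-coalescent HMM with the
// rank-one SMC transition A[i][j] = stay[i]*delta(i,j) + (1-stay[i])*pi[j].
// Symbols: 0 = T (all-hom callable bin), 1 = K (>=1 het), 2 = N (missing).
// segStart gives the 0-based first bin of each independent segment
// (chromosome or bootstrap block); each segment starts from the stationary
// distribution pi.
//
// Returns the total log-likelihood and the expected sufficient statistics
// needed for the EM M-step:
//   nK[j], nT[j]   expected emission counts per state
//   init[j]        summed first-bin posteriors over segments
//   sDiag[j]       expected diagonal transition counts (stay or self-jump)
//   rowOff[i]      expected off-diagonal transitions out of i
//   colOff[j]      expected off-diagonal transitions into j
// [[Rcpp::export(name = ".smcForwardBackward")]]
List smcForwardBackward(IntegerVector symbols, IntegerVector segStart,
                        NumericVector pi, NumericVector jumpq,
                        NumericVector stay, NumericVector emitK,
                        bool returnPosteriors = false) {
  const int n = symbols.size();
  const int K = pi.size();
  if (stay.size() != K || emitK.size() != K || jumpq.size() != K)
    stop("parameter vectors must have equal length");
  const int nSeg = segStart.size();

  NumericVector nK(K), nT(K), init(K), sDiag(K), rowOff(K), colOff(K);
  double loglik = 0.0;
  NumericMatrix post;
  if (returnPosteriors) post = NumericMatrix(n, K);

  std::vector<double> alpha((size_t)n * K);
  std::vector<double> beta(K), betaNext(K), cvec(n), evec(K);

  auto emit = [&](int sym, int j) -> double {
    if (sym == 2) return 1.0;
    return sym == 1 ? emitK[j] : 1.0 - emitK[j];
  };

  for (int s = 0; s < nSeg; ++s) {
    const int from = segStart[s];
    const int to = (s + 1 < nSeg) ? segStart[s + 1] : n;
    if (from >= to) continue;

    // forward, scaled
    for (int t = from; t < to; ++t) {
      double c = 0.0;
      double *a = &alpha[(size_t)t * K];
      if (t == from) {
        for (int j = 0; j < K; ++j) {
          a[j] = pi[j] * emit(symbols[t], j);
          c += a[j];
        }
      } else {
        const double *ap = &alpha[(size_t)(t - 1) * K];
        double jumpMass = 0.0;
        for (int i = 0; i < K; ++i) jumpMass += ap[i] * (1.0 - stay[i]);
        for (int j = 0; j < K; ++j) {
          a[j] = emit(symbols[t], j) * (ap[j] * stay[j] + jumpq[j] * jumpMass);
          c += a[j];
        }
      }
      if (c <= 0.0) stop("zero forward mass: impossible observation");
      for (int j = 0; j < K; ++j) a[j] /= c;
      cvec[t] = c;
      loglik += std::log(c);
    }

    // backward, scaled by the same c's, accumulating statistics
    for (int j = 0; j < K; ++j) beta[j] = 1.0;
    for (int t = to - 1; t >= from; --t) {
      const double *a = &alpha[(size_t)t * K];
      // gamma_t = alpha_hat * beta_hat
      for (int j = 0; j < K; ++j) {
        double g = a[j] * beta[j];
        if (symbols[t] == 1) nK[j] += g;
        else if (symbols[t] == 0) nT[j] += g;
        if (t == from) init[j] += g;
        if (returnPosteriors) post(t, j) = g;
      }
      if (t > from) {
        // transition t-1 -> t
        const double *ap = &alpha[(size_t)(t - 1) * K];
        const double invc = 1.0 / cvec[t];
        double U = 0.0, V = 0.0;
        for (int j = 0; j < K; ++j) {
          evec[j] = jumpq[j] * emit(symbols[t], j) * beta[j] * invc; // v_j
          V += evec[j];
        }
        for (int i = 0; i < K; ++i) U += ap[i] * (1.0 - stay[i]);
        for (int j = 0; j < K; ++j) {
          const double u = ap[j] * (1.0 - stay[j]);
          const double selfTerm =
            ap[j] * (stay[j] + (1.0 - stay[j]) * jumpq[j]) *
            emit(symbols[t], j) * beta[j] * invc;
          sDiag[j] += selfTerm;
          rowOff[j] += u * (V - evec[j]);
          colOff[j] += (U - u) * evec[j];
        }
        // new beta at t-1
        double bm = 0.0;
        for (int j = 0; j < K; ++j) {
          const double eb = emit(symbols[t], j) * beta[j];
          betaNext[j] = eb; // temp: e_t(j) * beta_t(j)
          bm += jumpq[j] * eb;
        }
        for (int i = 0; i < K; ++i)
          beta[i] = (stay[i] * betaNext[i] + (1.0 - stay[i]) * bm) / cvec[t];
      }
    }
  }

  List out = List::create(
    _["loglik"] = loglik, _["nK"] = nK, _["nT"] = nT, _["init"] = init,
    _["sDiag"] = sDiag, _["rowOff"] = rowOff, _["colOff"] = colOff);
  if (returnPosteriors) out["posteriors"] = post;
  return out;
}
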