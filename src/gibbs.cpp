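#include <Rcpp.h>
using namespace Rcpp;

// One collapsed-Gibbs update of every mutation token, repeated nSweeps
// times.  Tokens carry a 1-based sample index ti, category index mi, a
// covariate value xi in {0, 1} and a current 1-based assignment z.  The
// conditional for a token of covariate 0 is
//   p(z = k) proportional to (n0[t,k] + alpha[t,k]) * gamma[k,m]
// after decrementing the token's own assignment (the normalizing
// denominator is constant in k and drops out); covariate-1 tokens use n1
// and beta.  alpha/beta are the per-sample Dirichlet parameters e_t * a
// (unit e for the unguided models).  Draws come from R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List gibbs_sweep_cpp(IntegerVector ti, IntegerVector mi, IntegerVector xi,
                     IntegerVector z, IntegerMatrix n0, IntegerMatrix n1,
                     NumericMatrix alpha, NumericMatrix beta,
                     NumericMatrix gamma, int nSweeps) {
  const int n = ti.size();
  const int K = gamma.nrow();
  const int T = n0.nrow();
  IntegerVector zz = clone(z);
  IntegerMatrix N0 = clone(n0), N1 = clone(n1);

  const int *tp = INTEGER(ti), *mp = INTEGER(mi), *xp = INTEGER(xi);
  int *zp = INTEGER(zz);
  int *c0 = INTEGER(N0), *c1 = INTEGER(N1);
  const double *ap = REAL(alpha), *bp = REAL(beta), *gp = REAL(gamma);
  std::vector<double> p(K);

  for (int s = 0; s < nSweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      const int t = tp[i] - 1, m = mp[i] - 1;
      int *cnt;
      const double *par;
      if (xp[i] == 0) { cnt = c0; par = ap; } else { cnt = c1; par = bp; }
      cnt[t + (size_t)(zp[i] - 1) * T]--;
      const double *gcol = gp + (size_t)m * K;  // gamma(, m), stride 1 in k
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        const size_t tk = t + (size_t)k * T;
        const double v = (cnt[tk] + par[tk]) * gcol[k];
        p[k] = v;
        tot += v;
      }
      if (tot <= 0.0)
        stop("token in category %d has zero emission probability under every signature",
             m + 1);
      const double u = unif_rand() * tot;
      double acc = 0.0;
      int kNew = K - 1;
      for (int k = 0; k < K; ++k) {
        acc += p[k];
        if (u <= acc) { kNew = k; break; }
      }
      zp[i] = kNew + 1;
      cnt[t + (size_t)kNew * T]++;
    }
  }
  return List::create(_["z"] = zz, _["n0"] = N0, _["n1"] = N1);
}
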