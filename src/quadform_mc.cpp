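#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo upper tail of Q = sum_k wpos_k * U_k - sum_k wneg_k * V_k,
// U, V iid chi-square(1). Uses R's RNG so results are reproducible under
// set.seed() from the calling R session. Draws are streamed, never stored.
// [[Rcpp::export]]
double mc_quadform_tail_cpp(NumericVector wpos, NumericVector wneg,
                            double x, int ndraw) {
  const int kp = wpos.size(), kn = wneg.size();
  long hits = 0;
  for (int i = 0; i < ndraw; ++i) {
    double q = 0.0;
    for (int j = 0; j < kp; ++j) {
      double z = norm_rand();
      q += wpos[j] * z * z;
    }
    for (int j = 0; j < kn; ++j) {
      double z = norm_rand();
      q -= wneg[j] * z * z;
    }
    if (q >= x) ++hits;
  }
  // floor away exact 0/1 so downstream -log10 and Phi^-1 stay finite
  double p = (hits + (hits == 0 ? 1.0 : 0.0)) / (double)(ndraw + 1);
  if (hits == ndraw) p = (double)ndraw / (double)(ndraw + 1);
  return p;
}

// Monte-Carlo upper tail of D = sum_k lambda_k a_k b_k with (a_k, b_k)
// standard bivariate normal, corr rho: direct simulation of the gene-level
// coherence statistic used as an independent oracle for the CF inversion.
// [[Rcpp::export]]
double mc_bilinear_tail_cpp(NumericVector lambda, double rho,
                            double x, int ndraw) {
  const int k = lambda.size();
  const double s = std::sqrt(1.0 - rho * rho);
  long hits = 0;
  for (int i = 0; i < ndraw; ++i) {
    double d = 0.0;
    for (int j = 0; j < k; ++j) {
      double a = norm_rand();
      double b = rho * a + s * norm_rand();
      d += lambda[j] * a * b;
    }
    if (d >= x) ++hits;
  }
  double p = (hits + (hits == 0 ? 1.0 : 0.0)) / (double)(ndraw + 1);
  if (hits == ndraw) p = (double)ndraw / (double)(ndraw + 1);
  return p;
}
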