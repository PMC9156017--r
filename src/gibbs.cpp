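#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// J is a flat n x n x q x q array: J[i + n*j + n*n*a + n*n*q*b] = J_ij(a, b).
// h is a flat n x q matrix: h[i + n*a].
// mode: 0 = CE (couplings + fields), 1 = IE (fields only), 2 = UE (neither).

static inline void conditional_log_weights(const double* J, const double* h,
                                           int n, int q, const int* seq,
                                           int site, int mode, double* lw) {
  if (mode == 2) {
    for (int a = 0; a < q; ++a) lw[a] = 0.0;
    return;
  }
  for (int a = 0; a < q; ++a) lw[a] = h[site + (size_t)n * a];
  if (mode == 0) {
    const size_t nn = (size_t)n * n;
    for (int j = 0; j < n; ++j) {
      if (j == site) continue;
      const double* base = J + site + (size_t)n * j + nn * q * (size_t)seq[j];
      for (int a = 0; a < q; ++a) lw[a] += base[nn * (size_t)a];
    }
  }
}

// Inverse-CDF draw from the normalized conditional, one uniform variate per
// call; log-weights are max-shifted before exponentiation.
static inline int sample_state(const double* lw, int q, double u) {
  double mx = lw[0];
  for (int a = 1; a < q; ++a) if (lw[a] > mx) mx = lw[a];
  double tot = 0.0;
  std::vector<double> w(q);
  for (int a = 0; a < q; ++a) { w[a] = std::exp(lw[a] - mx); tot += w[a]; }
  double target = u * tot, cum = 0.0;
  for (int a = 0; a < q; ++a) {
    cum += w[a];
    if (cum >= target) return a;
  }
  return q - 1;
}

// [[Rcpp::export]]
NumericVector potts_conditional_cpp(NumericVector J, NumericVector h,
                                    int n, int q, IntegerVector seq0,
                                    int site0, int mode) {
  std::vector<int> seq(seq0.begin(), seq0.end());
  std::vector<double> lw(q);
  conditional_log_weights(J.begin(), h.begin(), n, q, seq.data(), site0, mode,
                          lw.data());
  double mx = lw[0];
  for (int a = 1; a < q; ++a) if (lw[a] > mx) mx = lw[a];
  NumericVector p(q);
  double tot = 0.0;
  for (int a = 0; a < q; ++a) { p[a] = std::exp(lw[a] - mx); tot += p[a]; }
  for (int a = 0; a < q; ++a) p[a] /= tot;
  return p;
}

// Runs `total` single-site Gibbs updates. sites0 (0-based) and u must each
// have length `total`; randomness is supplied entirely by the caller so the
// site stream can be shared across modes. Generations after `burn_in` are
// recorded in full. If tally_thin > 0 the visited joint states (encoded
// sum_k seq[k] * q^k) are tallied every tally_thin post-burn-in generations;
// the caller must ensure q^n fits an int.
// [[Rcpp::export]]
List potts_gibbs_cpp(NumericVector J, NumericVector h, int n, int q,
                     IntegerVector start0, int mode, IntegerVector sites0,
                     NumericVector u, int burn_in, int tally_thin) {
  const int total = sites0.size();
  if (u.size() != total) stop("site and residue streams differ in length");
  if (burn_in < 0 || burn_in >= total) stop("burn_in must be in [0, total)");
  std::vector<int> seq(start0.begin(), start0.end());
  const int tracked = total - burn_in;

  IntegerVector site_rec(tracked), before_rec(tracked), prop_rec(tracked);
  LogicalVector acc_rec(tracked);
  IntegerVector reference(n);

  std::vector<int> tally;
  if (tally_thin > 0) {
    double nstates = std::pow((double)q, (double)n);
    if (nstates > 2e9) stop("state space too large to tally");
    tally.assign((size_t)nstates, 0);
  }

  std::vector<double> lw(q);
  const double* Jp = J.begin();
  const double* hp = h.begin();

  for (int g = 0; g < total; ++g) {
    if (g == burn_in)
      for (int k = 0; k < n; ++k) reference[k] = seq[k];
    const int site = sites0[g];
    conditional_log_weights(Jp, hp, n, q, seq.data(), site, mode, lw.data());
    const int before = seq[site];
    const int proposed = sample_state(lw.data(), q, u[g]);
    seq[site] = proposed;
    if (g >= burn_in) {
      const int t = g - burn_in;
      site_rec[t] = site;
      before_rec[t] = before;
      prop_rec[t] = proposed;
      acc_rec[t] = proposed != before;
      if (tally_thin > 0 && t % tally_thin == 0) {
        long idx = 0, mult = 1;
        for (int k = 0; k < n; ++k) { idx += (long)seq[k] * mult; mult *= q; }
        ++tally[idx];
      }
    }
  }

  IntegerVector final_seq(n);
  for (int k = 0; k < n; ++k) final_seq[k] = seq[k];

  List out = List::create(
      _["reference"] = reference, _["final"] = final_seq,
      _["site"] = site_rec, _["before"] = before_rec,
      _["proposed"] = prop_rec, _["accepted"] = acc_rec);
  if (tally_thin > 0) out["tally"] = IntegerVector(tally.begin(), tally.end());
  return out;
}
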