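#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Negative log-pseudo-likelihood (one conditioned site) plus L2 penalties,
// with its exact gradient.
//
// Parameter vector layout (length q + N*q*q + n_g):
//   theta[0 .. q-1]                    h_r(a)
//   theta[q + a + q*b + q*q*i]         J_{r,i}(a, b), partner column i (0-based)
//   theta[q + N*q*q + m]               gap-run parameters active at this site
//
// The slice i == r-1 and any masked slice are held at zero: they contribute
// neither energy nor penalty and their gradient entries are returned as zero.
//
// gidx0/gidxL/gidxR are per-row 1-based indices into the active gap-parameter
// set (0 = no entry): gidx0 selects the run obtained when site r is a gap
// (left run + r + right run merged); gidxL/gidxR select the flanking runs
// present when site r is not a gap.
// [[Rcpp::export]]
List plm_site_obj_grad(const IntegerMatrix& X, const NumericVector& w,
                       int r1, const NumericVector& theta, int q,
                       double lambda_h, double lambda_J, double lambda_g,
                       const LogicalVector& mask, bool use_gaps,
                       const IntegerVector& gidx0, const IntegerVector& gidxL,
                       const IntegerVector& gidxR, int n_g) {
  const int B = X.nrow(), N = X.ncol(), r = r1 - 1;
  const int qq = q * q, joff = q, goff = q + N * qq;
  if (r < 0 || r >= N) stop("site index out of range");
  if ((int)theta.size() != goff + n_g) stop("parameter vector has wrong length");

  NumericVector grad(theta.size());
  const double* th = theta.begin();
  double* gr = grad.begin();
  double beff = 0.0;
  for (int s = 0; s < B; ++s) beff += w[s];
  if (beff <= 0.0) stop("degenerate weights: b_eff is zero");

  std::vector<double> e(q), p(q);
  double nll = 0.0;

  for (int s = 0; s < B; ++s) {
    const double ws = w[s];
    for (int k = 0; k < q; ++k) e[k] = th[k];
    for (int i = 0; i < N; ++i) {
      if (i == r || mask[i]) continue;
      const double* Ji = th + joff + qq * i + q * X(s, i);
      for (int k = 0; k < q; ++k) e[k] += Ji[k];
    }
    double gL = 0.0, gR = 0.0, g0 = 0.0;
    if (use_gaps) {
      if (gidx0[s] > 0) g0 = th[goff + gidx0[s] - 1];
      if (gidxL[s] > 0) gL = th[goff + gidxL[s] - 1];
      if (gidxR[s] > 0) gR = th[goff + gidxR[s] - 1];
      e[0] += g0;
      for (int k = 1; k < q; ++k) e[k] += gL + gR;
    }
    double m = e[0];
    for (int k = 1; k < q; ++k) if (e[k] > m) m = e[k];
    double Z = 0.0;
    for (int k = 0; k < q; ++k) { p[k] = std::exp(e[k] - m); Z += p[k]; }
    const int obs = X(s, r);
    nll += ws * (std::log(Z) + m - e[obs]);
    const double invZ = 1.0 / Z;
    for (int k = 0; k < q; ++k) p[k] *= invZ;

    // d[k] = w_s * (p_k - [k == obs]); accumulate into each parameter touched
    for (int k = 0; k < q; ++k) {
      double d = ws * p[k];
      if (k == obs) d -= ws;
      gr[k] += d;
      p[k] = d;  // reuse as residual
    }
    for (int i = 0; i < N; ++i) {
      if (i == r || mask[i]) continue;
      double* Gi = gr + joff + qq * i + q * X(s, i);
      for (int k = 0; k < q; ++k) Gi[k] += p[k];
    }
    if (use_gaps) {
      const double d0 = p[0];        // residual of the gap state
      if (gidx0[s] > 0) gr[goff + gidx0[s] - 1] += d0;
      if (gidxL[s] > 0) gr[goff + gidxL[s] - 1] -= d0;
      if (gidxR[s] > 0) gr[goff + gidxR[s] - 1] -= d0;
    }
  }

  nll /= beff;
  const double invb = 1.0 / beff;
  for (int t = 0; t < (int)theta.size(); ++t) gr[t] *= invb;

  // quadratic penalties on the weight-normalised objective
  double pen = 0.0;
  for (int k = 0; k < q; ++k) { pen += lambda_h * th[k] * th[k]; gr[k] += 2.0 * lambda_h * th[k]; }
  for (int i = 0; i < N; ++i) {
    if (i == r || mask[i]) {
      for (int t = joff + qq * i; t < joff + qq * (i + 1); ++t) gr[t] = 0.0;
      continue;
    }
    for (int t = joff + qq * i; t < joff + qq * (i + 1); ++t) {
      pen += lambda_J * th[t] * th[t];
      gr[t] += 2.0 * lambda_J * th[t];
    }
  }
  for (int t = goff; t < goff + n_g; ++t) {
    pen += lambda_g * th[t] * th[t];
    gr[t] += 2.0 * lambda_g * th[t];
  }

  return List::create(_["objective"] = nll + pen, _["gradient"] = grad);
}

// Reweighting: weight of sequence s is 1 / #{t : identity(s,t) >= 1 - x},
// the neighbourhood including s itself. Identity counts all q states,
// the gap state included.
// [[Rcpp::export]]
NumericVector msa_weights_cpp(const IntegerMatrix& X, double threshold_x) {
  const int B = X.nrow(), N = X.ncol();
  std::vector<int> nnb(B, 1);  // self
  const double cut = (1.0 - threshold_x) * N - 1e-9;
  for (int s = 0; s < B; ++s) {
    for (int t = s + 1; t < B; ++t) {
      int m = 0;
      for (int i = 0; i < N; ++i) if (X(s, i) == X(t, i)) ++m;
      if ((double)m >= cut) { ++nnb[s]; ++nnb[t]; }
    }
  }
  NumericVector wt(B);
  for (int s = 0; s < B; ++s) wt[s] = 1.0 / nnb[s];
  return wt;
}

static inline double gap_energy_state(const std::vector<int>& x, int r, int k,
                                      const NumericMatrix& gtab, int N) {
  // gtab is N x Lmax, gtab(i, l-1) = g_i^l; entries outside are absent (0)
  int lam = 0, rho = 0;
  for (int i = r - 1; i >= 0 && x[i] == 0; --i) ++lam;
  for (int i = r + 1; i < N && x[i] == 0; ++i) ++rho;
  const int Lmax = gtab.ncol();
  double ge = 0.0;
  if (k == 0) {
    int l = lam + rho + 1;
    if (l <= Lmax) ge += gtab(r - lam, l - 1);
  } else {
    if (lam > 0 && lam <= Lmax) ge += gtab(r - lam, lam - 1);
    if (rho > 0 && rho <= Lmax) ge += gtab(r + 1, rho - 1);
  }
  return ge;
}

// Single-chain Gibbs sampler for the Potts(+gap-run) model. Couplings are the
// full symmetric store Jflat[a + q*b + q*q*(i + N*j)] = J_ij(a, b). Uses R's
// RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(const NumericMatrix& h, const NumericVector& Jflat,
                               int q, int B, int burn_in, int thinning,
                               bool use_gaps, const NumericMatrix& gtab) {
  const int N = h.ncol();
  const int qq = q * q;
  IntegerMatrix out(B, N);
  std::vector<int> x(N);
  std::vector<double> e(q), cum(q);
  RNGScope scope;

  for (int i = 0; i < N; ++i) x[i] = (int)std::floor(unif_rand() * q) % q;

  const long total = (long)burn_in + (long)thinning * B;
  int row = 0;
  for (long sweep = 1; sweep <= total; ++sweep) {
    for (int r = 0; r < N; ++r) {
      for (int k = 0; k < q; ++k) e[k] = h(k, r);
      for (int j = 0; j < N; ++j) {
        if (j == r) continue;
        const double* Jc = Jflat.begin() + qq * (r + (long)N * j) + q * x[j];
        for (int k = 0; k < q; ++k) e[k] += Jc[k];
      }
      if (use_gaps)
        for (int k = 0; k < q; ++k) e[k] += gap_energy_state(x, r, k, gtab, N);
      double m = e[0];
      for (int k = 1; k < q; ++k) if (e[k] > m) m = e[k];
      double Z = 0.0;
      for (int k = 0; k < q; ++k) { Z += std::exp(e[k] - m); cum[k] = Z; }
      const double u = unif_rand() * Z;
      int k = 0;
      while (k < q - 1 && cum[k] < u) ++k;
      x[r] = k;
    }
    if (sweep > burn_in && (sweep - burn_in) % thinning == 0 && row < B) {
      for (int i = 0; i < N; ++i) out(row, i) = x[i];
      ++row;
    }
  }
  return out;
}
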