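#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log(sum(exp(eta))) with max-shift for stability
static double logsumexp(const std::vector<double>& eta) {
  double m = eta[0];
  for (double e : eta) if (e > m) m = e;
  double s = 0.0;
  for (double e : eta) s += std::exp(e - m);
  return m + std::log(s);
}

static inline double soft(double x, double c) {
  if (x > c) return x - c;
  if (x < -c) return x + c;
  return 0.0;
}

// Penalized Maxent objective for current background linear predictor.
//   obj = -sum(fpmean * lambda) + logsumexp(eta_b) - log(N) + sum(reg * |lambda|)
static double objective(const NumericVector& fpmean, const NumericVector& reg,
                        const std::vector<double>& lambda,
                        const std::vector<double>& etab, int nbg) {
  double lin = 0.0, pen = 0.0;
  for (int j = 0; j < fpmean.size(); ++j) {
    lin += fpmean[j] * lambda[j];
    pen += reg[j] * std::fabs(lambda[j]);
  }
  return -lin + logsumexp(etab) - std::log((double)nbg) + pen;
}

// Cyclic coordinate descent with soft-thresholding for the L1-penalized
// presence-background maximum-entropy objective. Fb is the background
// feature matrix (N x J, values in [0,1]); fpmean the presence feature means.
// Each coordinate takes a proximal Newton step, backtracking (step halving)
// whenever the full objective would increase.
// Coefficients are confined to [-lambdaMax, lambdaMax]: with completely
// separable presences the penalized objective can be unbounded below, and
// the box keeps the optimum finite without affecting interior solutions.
// [[Rcpp::export(name = ".maxentCCD")]]
List maxentCCD(NumericMatrix Fb, NumericVector fpmean, NumericVector reg,
               double tol, int maxit, double lambdaMax) {
  const int N = Fb.nrow(), J = Fb.ncol();
  std::vector<double> lambda(J, 0.0), etab(N, 0.0);
  double obj = objective(fpmean, reg, lambda, etab, N);
  bool converged = false;
  int sweep = 0;

  for (sweep = 1; sweep <= maxit; ++sweep) {
    double objStart = obj;
    for (int j = 0; j < J; ++j) {
      // weighted moments of feature j under the current Gibbs distribution
      double m = etab[0];
      for (int i = 1; i < N; ++i) if (etab[i] > m) m = etab[i];
      double sw = 0.0, s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < N; ++i) {
        double w = std::exp(etab[i] - m);
        double f = Fb(i, j);
        sw += w; s1 += w * f; s2 += w * f * f;
      }
      double ef = s1 / sw;                 // E_q[f_j]
      double vf = s2 / sw - ef * ef;       // Var_q[f_j]
      if (vf < 1e-12) vf = 1e-12;
      double g = -fpmean[j] + ef;          // smooth-part gradient
      double cand = soft(lambda[j] - g / vf, reg[j] / vf);
      if (cand > lambdaMax) cand = lambdaMax;
      if (cand < -lambdaMax) cand = -lambdaMax;
      double delta = cand - lambda[j];
      if (std::fabs(delta) < 1e-15) continue;

      // backtracking on the full objective (Newton step may overshoot)
      for (int half = 0; half < 30; ++half) {
        double lnew = lambda[j] + delta;
        // shifted logsumexp of eta + delta * f without committing the step
        double mx = -INFINITY;
        for (int i = 0; i < N; ++i) {
          double e = etab[i] + delta * Fb(i, j);
          if (e > mx) mx = e;
        }
        double se = 0.0;
        for (int i = 0; i < N; ++i)
          se += std::exp(etab[i] + delta * Fb(i, j) - mx);
        double lseNew = mx + std::log(se);
        double lin = 0.0, pen = 0.0;
        for (int jj = 0; jj < J; ++jj) {
          double l = (jj == j) ? lnew : lambda[jj];
          lin += fpmean[jj] * l;
          pen += reg[jj] * std::fabs(l);
        }
        double objNew = -lin + lseNew - std::log((double)N) + pen;
        if (objNew <= obj + 1e-12) {
          for (int i = 0; i < N; ++i) etab[i] += delta * Fb(i, j);
          lambda[j] = lnew;
          obj = objNew;
          break;
        }
        delta *= 0.5;
        if (std::fabs(delta) < 1e-15) break;
      }
    }
    double rel = std::fabs(objStart - obj) / (std::fabs(objStart) + 1.0);
    if (rel < tol) { converged = true; break; }
    if (sweep % 20 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["lambda"] = NumericVector(lambda.begin(), lambda.end()),
                      _["objective"] = obj,
                      _["iterations"] = sweep,
                      _["converged"] = converged);
}
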