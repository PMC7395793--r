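// Inner simulation loops: forward-Euler integration of the coupled M/T,
// granule and piriform rate equations, and the sparse-coding MAP inference
// loop.  The posterior transfer functions implemented here mirror the R
// implementations in R/varposterior.R exactly; a test asserts agreement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SQRT_2PI = 2.5066282746310002;

// Posterior moments of the spike-and-slab concentration posterior as a
// function of the standardized argument alpha, the pseudo-precision lam,
// and the slab mixing weight mix (the prior cO, or the top-down presence
// probability in the feedback-modulated circuit).  Two regimes: exact
// Mills-ratio evaluation for alpha >= -16, asymptotic expansion of the
// slab integrals below (the exact form suffers O(alpha^8 * eps)
// cancellation there).
static inline void ss_moments(double alpha, double lam, double mix,
                              double &first, double &second, double &prob) {
  if (alpha >= -16.0) {
    double a2 = alpha * alpha;
    double phi = ::Rf_pnorm5(alpha, 0.0, 1.0, 1, 0);  // same code path as R
    double ip = std::exp(-a2 / 2.0) / (SQRT_2PI * phi);
    double s = 2.0 * (1.0 - mix) / (27.0 * mix);
    double denom = s * lam * std::sqrt(lam) * ip + alpha * ip + (1.0 + a2);
    first = ((2.0 + a2) * ip + alpha * (3.0 + a2)) /
      (std::sqrt(lam) * denom);
    second = (alpha * (5.0 + a2) * ip + (3.0 + 6.0 * a2 + a2 * a2)) /
      (lam * denom);
    prob = (alpha * ip + (1.0 + a2)) / denom;
  } else {
    double beta = std::sqrt(lam) * std::fabs(alpha);
    double i2 = 1.0 / (alpha * alpha);
    double b3 = beta * beta * beta;
    double A2 = (2.0 / b3) *
      (1.0 - i2 * (6.0 - i2 * (45.0 - i2 * (420.0 - i2 * 4725.0))));
    double A3 = (6.0 / (b3 * beta)) *
      (1.0 - i2 * (10.0 - i2 * (105.0 - i2 * (1260.0 - i2 * 17325.0))));
    double A4 = (24.0 / (b3 * beta * beta)) *
      (1.0 - i2 * (15.0 - i2 * (210.0 - i2 * (3150.0 - i2 * 51975.0))));
    double slabW = 13.5 * mix;
    double z = (1.0 - mix) + slabW * A2;
    first = slabW * A3 / z;
    second = slabW * A4 / z;
    prob = slabW * A2 / z;
  }
  if (first < 0.0) first = 0.0;
  if (second < 0.0) second = 0.0;
  if (prob < 0.0) prob = 0.0;
  if (prob > 1.0) prob = 1.0;
}

static inline double clamp_mix(double p) {
  if (p < 1e-6) return 1e-6;
  if (p > 1.0 - 1e-6) return 1.0 - 1e-6;
  return p;
}

// [[Rcpp::export(name = ".cppMoments")]]
List cpp_moments(arma::vec alpha, arma::vec lam, arma::vec mix) {
  int n = alpha.n_elem;
  arma::vec f(n), g(n), h(n);
  for (int j = 0; j < n; ++j)
    ss_moments(alpha[j], lam[j], mix[j], f[j], g[j], h[j]);
  return List::create(_["first"] = f, _["second"] = g,
                      _["probPresent"] = h);
}

// Forward-Euler integration of one odor presentation.
//
// pMode: 0 = bulb only; 1 = piriform mirrors the bulb posterior
// (weight-copy reference, pbar relaxes to the bulb's own H); 2 = piriform
// with its own readout weights, lateral inhibition J (scaled by kappaJ in
// the dynamics only) and, if feedback, top-down modulation of the granule
// transfer functions (mixing weight cO replaced by pbar).
//
// Rates are floored (m >= -msp, cbar >= 0, pbar in [0,1]) after every
// step.  Integration stops early once the largest rate derivative (per
// ms) falls below ssTol.  Weights are frozen throughout (two-step
// schedule: dynamics first, plasticity afterwards).
// [[Rcpp::export(name = ".cppCircuitTrial")]]
List cpp_circuit_trial(arma::vec x, arma::mat wF, arma::mat wL,
                       arma::vec wF2rs, arma::vec lambda,
                       double co, double sigma2, double msp,
                       double tau, double dt, int maxSteps, double ssTol,
                       int pMode, bool feedback,
                       arma::mat wP, arma::vec wP2rs, arma::vec lambdaP,
                       arma::mat J, double kappaJ) {
  const int N = x.n_elem, M = wF.n_rows;
  arma::vec m(N, arma::fill::zeros);
  arma::vec cbar(M), pbar(M);
  cbar.fill(co);
  pbar.fill(co);
  arma::vec sqlam = arma::sqrt(lambda);
  arma::vec sqlamP = (pMode == 2) ? arma::sqrt(lambdaP) : arma::vec();
  arma::vec Fb(M), Gb(M), Hb(M), alphaB(M);
  arma::vec Hp(M), alphaP(M);
  int step = 0;
  bool converged = false;

  for (step = 1; step <= maxSteps; ++step) {
    arma::vec y = wF * m;
    alphaB = (y + wF2rs % cbar - 3.0 * sigma2) / (sqlam * sigma2);
    for (int j = 0; j < M; ++j) {
      double mix = (pMode == 2 && feedback) ? clamp_mix(pbar[j]) : co;
      ss_moments(alphaB[j], lambda[j], mix, Fb[j], Gb[j], Hb[j]);
    }
    arma::vec dm = (x - m - wL * cbar) / tau;
    arma::vec dc = (-cbar + Fb) / tau;
    double maxd = std::max(arma::abs(dm).max(), arma::abs(dc).max());

    if (pMode == 1) {
      arma::vec dp = (-pbar + Hb) / tau;
      pbar += dt * dp;
      maxd = std::max(maxd, arma::abs(dp).max());
    } else if (pMode == 2) {
      arma::vec yp = wP * m;
      arma::vec lat = kappaJ * (J * pbar);
      alphaP = (yp + wP2rs % pbar -
                sigma2 * (3.0 + lambdaP % lat)) / (sqlamP * sigma2);
      for (int j = 0; j < M; ++j) {
        double f, g;
        ss_moments(alphaP[j], lambdaP[j], co, f, g, Hp[j]);
      }
      arma::vec dp = (-pbar + Hp) / tau;
      pbar += dt * dp;
      maxd = std::max(maxd, arma::abs(dp).max());
    }

    m += dt * dm;
    cbar += dt * dc;
    m.clamp(-msp, arma::datum::inf);
    cbar.clamp(0.0, arma::datum::inf);
    if (pMode > 0) pbar.clamp(0.0, 1.0);

    if (!m.is_finite() || !cbar.is_finite())
      stop("rate dynamics diverged at integration step %d (dt = %g ms)",
           step, dt);
    if (ssTol > 0.0 && maxd < ssTol) { converged = true; break; }
  }

  // steady-state transfer function values for the plasticity updates,
  // evaluated at the final rates with the same mixing weights as above
  arma::vec y = wF * m;
  alphaB = (y + wF2rs % cbar - 3.0 * sigma2) / (sqlam * sigma2);
  for (int j = 0; j < M; ++j) {
    double mix = (pMode == 2 && feedback) ? clamp_mix(pbar[j]) : co;
    ss_moments(alphaB[j], lambda[j], mix, Fb[j], Gb[j], Hb[j]);
  }
  arma::vec Fp(M, arma::fill::zeros), Gp(M, arma::fill::zeros);
  if (pMode == 2) {
    arma::vec yp = wP * m;
    arma::vec lat = kappaJ * (J * pbar);
    alphaP = (yp + wP2rs % pbar -
              sigma2 * (3.0 + lambdaP % lat)) / (sqlamP * sigma2);
    for (int j = 0; j < M; ++j) {
      double h;
      ss_moments(alphaP[j], lambdaP[j], co, Fp[j], Gp[j], h);
    }
  } else if (pMode == 1) {
    pbar = Hb;  // reference variant reads out the bulb posterior directly
  }

  return List::create(_["m"] = m, _["cbar"] = cbar, _["pbar"] = pbar,
                      _["F"] = Fb, _["G"] = Gb, _["H"] = Hb,
                      _["Fp"] = Fp, _["Gp"] = Gp,
                      _["alpha"] = alphaB,
                      _["steps"] = std::min(step, maxSteps),
                      _["converged"] = converged);
}

// Gradient-ascent MAP inference of the sparse-coding model: maximizes the
// log posterior of the concentrations under a Gamma(3, 3/cO) prior
// surrogate.  chat is floored at `floorC` to keep the log term finite;
// stops early when the largest per-step change drops below stepTol.
// [[Rcpp::export(name = ".cppScInfer")]]
List cpp_sc_infer(arma::vec x, arma::mat w, arma::vec c0,
                  double etaC, double sigma2, double co,
                  int maxSteps, double stepTol, double floorC) {
  arma::vec chat = c0;
  int step = 0;
  bool converged = false;
  for (step = 1; step <= maxSteps; ++step) {
    arma::vec mhat = x - w * chat;
    arma::vec grad = w.t() * mhat + sigma2 * (2.0 / chat - 3.0 / co);
    arma::vec delta = etaC * grad;
    chat += delta;
    chat.clamp(floorC, arma::datum::inf);
    if (!chat.is_finite())
      stop("sparse-coding inference diverged at step %d", step);
    if (stepTol > 0.0 && arma::abs(delta).max() < stepTol) {
      converged = true; break;
    }
  }
  arma::vec mhat = x - w * chat;
  return List::create(_["cHat"] = chat, _["mHat"] = mhat,
                      _["steps"] = std::min(step, maxSteps),
                      _["converged"] = converged);
}
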