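# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the Picard solver iterates the fixed-point
# equations directly, the closed-form plasticity re-derivation applies the
# algebraically equivalent update, and the error-neuron loop is a literal
# Euler integration.

# Damped Picard iteration of the steady-state equations
#   m = x - wL cbar,  cbar = F(wF m + |wF|^2 cbar; lambda)
# independent of the Euler integrator.
picardFixedPoint <- function(state, x, damping = 0.1, maxIter = 20000,
                             tol = 1e-12) {
  cfg <- state@config
  lambda <- olfbayes:::.bulbLambda(state)
  wF2 <- rowSums(state@wF^2)
  m <- numeric(cfg$N)
  cbar <- rep(cfg$cO, cfg$M)
  for (i in seq_len(maxIter)) {
    alpha <- (drop(state@wF %*% m) + wF2 * cbar - 3 * cfg$sigmaX^2) /
      (sqrt(lambda) * cfg$sigmaX^2)
    f <- spikeSlabMoments(alpha / sqrt(lambda) + 3 / lambda, lambda,
                          cfg$cO)$first
    mNew <- pmax((1 - damping) * m +
                   damping * (x - drop(state@wL %*% cbar)), -cfg$mSp)
    cNew <- pmax((1 - damping) * cbar + damping * f, 0)
    if (max(abs(mNew - m), abs(cNew - cbar)) < tol) {
      m <- mNew; cbar <- cNew
      break
    }
    m <- mNew; cbar <- cNew
  }
  list(m = m, cbar = cbar)
}

# The weight update written in its primitive form,
#   w' = (1 - 1/t) (rho_{t-1}/rho_t) w + [1/(t rho_t sigma^2)] cbar (m + w cbar),
# algebraically equal to the discount-factor form used by the package.
plasticityClosedForm <- function(wF, rhoPrev, rhoNew, t, sigma2, m, cbar) {
  hebb <- outer(cbar, m) + wF * cbar^2      # cbar_j (m_i + w_ji cbar_j)
  sweep(wF, 1, (1 - 1 / t) * rhoPrev / rhoNew, `*`) +
    sweep(hebb, 1, 1 / (t * rhoNew * sigma2), `*`)
}

# Literal forward-Euler integration of the error-neuron ODE with a
# constant prediction drive.
eulerErrorNeuron <- function(P, R, tauR, dt, TMax, rewardOnset = 2500,
                             readTime = 2450) {
  nSteps <- round(TMax / dt)
  e <- 0
  eHat <- NA_real_
  for (k in seq_len(nSteps)) {
    rhat <- if ((k - 1) * dt >= rewardOnset) R else 0
    e <- e + (dt / tauR) * (-e + rhat - P)
    if (k == round(readTime / dt)) eHat <- e
  }
  list(eHat = eHat, ePost = e)
}

# Two-pass variance over all matrix entries.
twoPassVariance <- function(x) {
  v <- as.vector(x)
  mu <- sum(v) / length(v)
  sum((v - mu)^2) / (length(v) - 1)
}
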