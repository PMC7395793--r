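## Olfactory-bulb rate network: initialization, within-trial dynamics
## (delegated to the compiled Euler integrator), and the between-trial
## plasticity updates with uncertainty-adaptive learning rates.

#' Initialize the bulb circuit state
#'
#' Feedforward and lateral weights are drawn log-normal with `sdlog = 0.1`
#' and `meanlog = (1 - 0.1^2)/2 - log(cO * M)`, and the lateral matrix is
#' set to the transpose of the feedforward one (dendro-dendritic synapses
#' share their initial condition, and the updates preserve the symmetry).
#' Precisions start at `rho = cO / (sigmaX^2 * ZRho)` and the effective
#' trial counter at `tMin`.
#'
#' @param config a [simConfig()] list.
#' @param seed optional integer seed (sub-stream `"init"`).
#' @return a [BulbState-class] object.
#' @export
#' @examples
#' st <- initBulb(simConfig(M = 10, N = 40), seed = 1)
#' st
initBulb <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simConfig"))
  if (!is.null(seed)) set.seed(subSeed(seed, "init"))
  M <- config$M; N <- config$N
  sdg <- 0.1
  mug <- 0.5 * (1 - sdg^2) - log(config$cO * M)
  wF <- matrix(rlnorm(M * N, meanlog = mug, sdlog = sdg), M, N)
  rho <- rep(config$cO / (config$sigmaX^2 * config$ZRho), M)
  new("BulbState", wF = wF, wL = t(wF), rho = rho, t = config$tMin,
      m = numeric(N), cbar = rep(config$cO, M), config = config)
}

## Pseudo-precision of the concentration likelihood for the coming trial,
## from the frozen weights and precisions (the counter in `state` is the
## previous trial's, matching the two-step update schedule).
.bulbLambda <- function(state) {
  cfg <- state@config
  if (cfg$gainMode == "fixed")
    return(rep(cfg$lambdaFixed, cfg$M))
  s2 <- cfg$sigmaX^2
  if (cfg$rateMode == "fixed")
    return((rowSums(state@wF^2) + cfg$N * cfg$etaFixed) / s2)
  rowSums(state@wF^2) / s2 + cfg$N / (s2 * state@t * state@rho)
}

.piriformLambda <- function(pstate, state) {
  cfg <- state@config
  s2 <- cfg$sigmaX^2
  rowSums(pstate@wP^2) / s2 + cfg$N / (s2 * state@t * pstate@rhoP)
}

#' Integrate one odor presentation to steady state
#'
#' Forward-Euler integration of the coupled M/T and granule (and,
#' optionally, piriform) rate equations with all weights frozen, starting
#' from `m = 0`, `cbar = cO` (and `pbar = cO`).  Rates are floored at
#' `m >= -mSp`, `cbar >= 0`, `pbar` in `[0, 1]`.  Integration exits early
#' once the largest rate derivative falls below `config$ssTol` per ms.
#'
#' @param state a [BulbState-class].
#' @param x length-`N` glomerular response vector.
#' @param piriform optional [PiriformState-class] integrated jointly; for
#'   variant `"bayes_copy"` the piriform rate relaxes to the bulb's own
#'   presence probability, for the local variants it evolves under its own
#'   readout weights, lateral inhibition and (variant
#'   `"local_lateral_feedback"`) top-down modulation of the granule
#'   transfer functions.
#' @param duration presentation length in ms (default `config$TMax`).
#' @return list with steady-state rates `m`, `cbar`, `pbar`, the transfer
#'   function values `F`, `G`, `H` (bulb) and `Fp`, `Gp` (piriform) at the
#'   steady state, the pseudo-precisions `lambda` and `lambdaP`, the
#'   standardized argument `alpha`, the number of Euler `steps` taken and
#'   a `converged` flag.
#' @export
runTrialDynamics <- function(state, x, piriform = NULL,
                             duration = state@config$TMax) {
  cfg <- state@config
  if (length(x) != cfg$N)
    stop("input has length ", length(x), " but N = ", cfg$N, call. = FALSE)
  lambda <- .bulbLambda(state)
  pMode <- 0L
  wP <- matrix(0, 0, 0); wP2rs <- numeric(0); lambdaP <- numeric(0)
  J <- matrix(0, 0, 0); kappaJ <- 0; feedback <- FALSE
  if (!is.null(piriform)) {
    if (piriform@variant == "bayes_copy") {
      pMode <- 1L
    } else {
      pMode <- 2L
      wP <- piriform@wP
      wP2rs <- rowSums(wP^2)
      lambdaP <- .piriformLambda(piriform, state)
      J <- if (piriform@variant == "local") {
        matrix(0, cfg$M, cfg$M)
      } else {
        piriform@J
      }
      kappaJ <- piriform@kappaJ
      feedback <- piriform@variant == "local_lateral_feedback"
    }
  }
  maxSteps <- max(1L, as.integer(round(duration / cfg$dt)))
  out <- .cppCircuitTrial(x, state@wF, state@wL, rowSums(state@wF^2),
                          lambda, cfg$cO, cfg$sigmaX^2, cfg$mSp,
                          cfg$tauR, cfg$dt, maxSteps, cfg$ssTol,
                          pMode, feedback, wP, wP2rs, lambdaP, J, kappaJ)
  for (nm in c("m", "cbar", "pbar", "F", "G", "H", "Fp", "Gp", "alpha"))
    out[[nm]] <- drop(out[[nm]])
  out$lambda <- lambda
  out$lambdaP <- lambdaP
  out
}

#' Adaptive Hebbian plasticity update of the bulb weights
#'
#' Applied once per trial, after the dynamics has reached steady state.
#' The precision is updated first, as a running average of the posterior
#' second moment `G / sigmaX^2`; the weights then receive a Hebbian
#' increment `cbar_j m_i` scaled by the adaptive learning rate
#' `1/(t rho_j sigmaX^2)`, together with a discount factor that implements
#' the Bayesian forgetting of the previous estimate.  Weights are clipped
#' at zero and the effective trial counter advances by one.  With
#' `rateMode = "fixed"` the constant-learning-rate rule is used instead.
#'
#' @param state a [BulbState-class].
#' @param dyn the steady-state list returned by [runTrialDynamics()].
#' @return the updated [BulbState-class].
#' @export
updatePlasticity <- function(state, dyn) {
  cfg <- state@config
  if (cfg$rateMode == "fixed")
    return(fixedRateUpdate(state, dyn, cfg$etaFixed))
  s2 <- cfg$sigmaX^2
  t <- state@t + 1
  m <- dyn$m; cbar <- dyn$cbar
  rhoNew <- (1 - 1 / t) * state@rho + dyn$G / (t * s2)
  if (any(rhoNew <= 0))
    stop("precision became non-positive; G must be non-negative",
         call. = FALSE)
  delta <- 1 / t + (1 - 1 / t) * (1 - state@rho / rhoNew) -
    cbar^2 / (t * rhoNew * s2)
  gain <- cbar / (t * rhoNew * s2)             # per-granule Hebbian gain
  wF <- pmax((1 - delta) * state@wF + outer(gain, m), 0)
  wL <- pmax(sweep(state@wL, 2, 1 - delta, `*`) + outer(m, gain), 0)
  methods::initialize(state, wF = wF, wL = wL, rho = rhoNew, t = t,
                      m = m, cbar = cbar)
}

#' Constant-learning-rate ablation of the weight update
#'
#' Replaces the adaptive learning rate `1/(t rho)` by a constant `eta`:
#' `w <- w + (eta/sigmaX^2) cbar (m + cbar w)`.  The precision is still
#' tracked, but the pseudo-precision seen by the dynamics gains an
#' `N * eta` term in place of the precision correction.  Reference sweep
#' values are `eta` in 0.01, 0.1, 1.0.
#'
#' @inheritParams updatePlasticity
#' @param eta fixed learning rate.
#' @return the updated [BulbState-class].
#' @export
fixedRateUpdate <- function(state, dyn, eta) {
  cfg <- state@config
  s2 <- cfg$sigmaX^2
  t <- state@t + 1
  m <- dyn$m; cbar <- dyn$cbar
  rhoNew <- (1 - 1 / t) * state@rho + dyn$G / (t * s2)
  wF <- pmax(state@wF + (eta / s2) * sweep(state@wF, 1, cbar^2, `*`) +
               (eta / s2) * outer(cbar, m), 0)
  wL <- pmax(state@wL +
               (eta / s2) * sweep(state@wL, 2, cbar^2, `*`) +
               (eta / s2) * outer(m, cbar), 0)
  methods::initialize(state, wF = wF, wL = wL, rho = rhoNew, t = t,
                      m = m, cbar = cbar)
}
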