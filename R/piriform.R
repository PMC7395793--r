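## Concentration-invariant piriform readout.  Four circuit variants of
## increasing biological plausibility:
##   bayes_copy             readout weights copied from the bulb every
##                          trial (non-biological reference)
##   local                  readout weights learned with the local rule
##   local_lateral          + Hebbian lateral inhibition among piriform
##                          cells
##   local_lateral_feedback + top-down modulation of the granule transfer
##                          functions by the piriform presence estimate

#' Initialize the piriform readout state
#'
#' Readout weights and precisions start from the same log-normal /
#' precision initialization as the bulb (the learning rule then keeps them
#' tracking the bulb weights); lateral inhibition starts at 0.02 off the
#' diagonal.
#'
#' @param config a [simConfig()] list.
#' @param variant circuit variant, one of `"bayes_copy"`, `"local"`,
#'   `"local_lateral"`, `"local_lateral_feedback"`.
#' @param kappaJ multiplier on the lateral weights inside the dynamics
#'   (plasticity always uses the unscaled weights).
#' @param seed optional integer seed (sub-stream `"piriform"`).
#' @return a [PiriformState-class] object.
#' @export
initPiriform <- function(config, variant = c("local_lateral_feedback",
                                             "bayes_copy", "local",
                                             "local_lateral"),
                         kappaJ = 1, seed = NULL) {
  stopifnot(inherits(config, "simConfig"))
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(subSeed(seed, "piriform"))
  M <- config$M; N <- config$N
  sdg <- 0.1
  mug <- 0.5 * (1 - sdg^2) - log(config$cO * M)
  wP <- matrix(rlnorm(M * N, meanlog = mug, sdlog = sdg), M, N)
  J <- matrix(0.02, M, M); diag(J) <- 0
  new("PiriformState", wP = wP,
      rhoP = rep(config$cO / (config$sigmaX^2 * config$ZRho), M),
      J = J, pbar = rep(config$cO, M), variant = variant, kappaJ = kappaJ)
}

#' Local plasticity of the piriform readout weights
#'
#' Mirrors the bulb rule with the piriform cell's own estimate of the
#' concentration posterior in place of the granule rate: the Hebbian
#' increment is `F(alpha^p) * m_i`, the precision tracks `G(alpha^p)`,
#' both evaluated at the piriform standardized argument (which includes
#' the lateral-inhibition term).  For variant `"bayes_copy"` the weights
#' and precisions are instead copied from the bulb.
#'
#' @param pstate a [PiriformState-class].
#' @param state the [BulbState-class] *after* its own update for this
#'   trial (supplies the shared trial counter and, for `"bayes_copy"`,
#'   the weights to copy).
#' @param dyn the steady-state list from [runTrialDynamics()].
#' @return the updated [PiriformState-class].
#' @export
updatePiriformPlasticity <- function(pstate, state, dyn) {
  cfg <- state@config
  if (pstate@variant == "bayes_copy")
    return(methods::initialize(pstate, wP = state@wF, rhoP = state@rho,
                               pbar = dyn$pbar))
  s2 <- cfg$sigmaX^2
  t <- state@t                       # already incremented by the bulb update
  m <- dyn$m; Fp <- dyn$Fp; Gp <- dyn$Gp
  rhoPNew <- (1 - 1 / t) * pstate@rhoP + Gp / (t * s2)
  deltaP <- 1 / t + (1 - 1 / t) * (1 - pstate@rhoP / rhoPNew) -
    Fp^2 / (t * rhoPNew * s2)
  gain <- Fp / (t * rhoPNew * s2)
  wP <- pmax((1 - deltaP) * pstate@wP + outer(gain, m), 0)
  pstate <- methods::initialize(pstate, wP = wP, rhoP = rhoPNew,
                                pbar = dyn$pbar)
  if (pstate@variant %in% c("local_lateral", "local_lateral_feedback"))
    pstate@J <- updateLateralInhibition(pstate@J, dyn$pbar, cfg$cO)
  pstate
}

#' Hebbian plasticity of the piriform lateral inhibition
#'
#' `dJ[j,k] = 0.1 * pbar_k * (-5 cO J[j,k] + pbar_j)`; weights are kept
#' non-negative with a zero diagonal.  At the fixed point
#' `J[j,k] = pbar_j / (5 cO)`, co-active cells inhibit each other in
#' proportion to their activity, enforcing sparse piriform firing.
#'
#' @param J current `M x M` lateral weight matrix (zero diagonal).
#' @param pbar converged piriform rates.
#' @param cO prior presence probability.
#' @return the updated lateral weight matrix.
#' @export
updateLateralInhibition <- function(J, pbar, cO) {
  dJ <- 0.1 * sweep(-5 * cO * J + outer(pbar, rep(1, length(pbar))),
                    2, pbar, `*`)
  J <- pmax(J + dJ, 0)
  diag(J) <- 0
  J
}
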