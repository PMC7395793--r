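## Reward-prediction learning on top of the pretrained circuit.  A single
## error neuron receives the (delayed) reward and an inhibitory prediction
## -- either from the piriform presence code or directly from the
## glomeruli -- and its post-reward activity gates Hebbian learning of the
## association weights.

#' Initialize the reward-association state
#'
#' Both routes start from zero weights; learning rates default to the
#' largest stable values, `etaA = 0.5` (piriform route) and
#' `etaH = 0.0015` (glomerular route).
#'
#' @param M number of piriform cells.
#' @param N number of glomeruli.
#' @param etaA,etaH Hebbian learning rates of the two routes.
#' @return a [RewardState-class].
#' @export
initReward <- function(M, N, etaA = 0.5, etaH = 0.0015) {
  new("RewardState", abar = numeric(M), h = numeric(N), eP = 0, eX = 0,
      etaA = etaA, etaH = etaH)
}

## Euler solution of the scalar error-neuron ODE
##   tau de/dtau = -e + Rhat(tau) - P
## with constant prediction drive P, Rhat = 0 before rewardOnset and R
## after.  The geometric closed form below is exactly the forward-Euler
## recursion evaluated at the requested times.
.errorNeuronTrace <- function(P, R, tauR, dt, TMax, rewardOnset = 2500,
                              readTime = 2450) {
  stopifnot(readTime < rewardOnset, rewardOnset <= TMax)
  q <- 1 - dt / tauR
  nRead <- round(readTime / dt)
  nOn <- round(rewardOnset / dt)
  nEnd <- round(TMax / dt)
  u1 <- -P
  eHat <- u1 * (1 - q^nRead)
  eOn <- u1 * (1 - q^nOn)
  u2 <- R - P
  ePost <- u2 + (eOn - u2) * q^(nEnd - nOn)
  list(eHat = eHat, ePost = ePost)
}

#' Run one delayed-reward trial
#'
#' Presents a single odor at the given concentration to the frozen
#' pretrained circuit, integrates the error neuron with the reward
#' withheld for the first 2.5 s, and reads the reward prediction
#' `eHat = e(2.45 s)` just before delivery and `ePost = e(TMax)` after.
#' `-eHat` is the circuit's reward prediction; `ePost` is the
#' reward-prediction error that drives learning.
#'
#' @param bulb pretrained, frozen [BulbState-class].
#' @param piriform pretrained, frozen [PiriformState-class] (piriform
#'   route).
#' @param rstate a [RewardState-class].
#' @param world the [OdorWorld-class].
#' @param odorId index of the presented odor.
#' @param concentration its amplitude.
#' @param a noiseless reward amplitude associated with the odor.
#' @param route `"piriform"` (prediction from `sum(abar * pbar)`) or
#'   `"glomeruli"` (prediction from `sum(h * x)`).
#' @param rewardSd standard deviation of the reward noise (variance 0.01).
#' @param trialLength,rewardOnset,readTime timing of the reward protocol
#'   in ms (fixed by the task, independent of the circuit's training
#'   trial length): 5 s trials, reward at 2.5 s, prediction read at
#'   2.45 s.
#' @return list with `eHat`, `ePost`, realized reward `R`, and the
#'   prediction drive (`pbar` or `x`).
#' @export
runRewardTrial <- function(bulb, piriform, rstate, world, odorId,
                           concentration, a, route = c("piriform",
                                                       "glomeruli"),
                           rewardSd = 0.1, trialLength = 5000,
                           rewardOnset = 2500, readTime = 2450) {
  route <- match.arg(route)
  cfg <- bulb@config
  cvec <- numeric(world@M); cvec[odorId] <- concentration
  x <- glomeruliResponse(world, cvec)
  R <- a * (concentration > 0) + rewardSd * rnorm(1)
  if (route == "piriform") {
    if (is.null(piriform))
      stop("the piriform route requires a piriform state", call. = FALSE)
    dyn <- runTrialDynamics(bulb, x, piriform = piriform)
    drive <- dyn$pbar
    P <- sum(rstate@abar * drive)
  } else {
    drive <- x
    P <- sum(rstate@h * drive)
  }
  tr <- .errorNeuronTrace(P, R, cfg$tauR, cfg$dt, trialLength,
                          rewardOnset, readTime)
  list(eHat = tr$eHat, ePost = tr$ePost, R = R, drive = drive)
}

#' Hebbian update of the reward-association weights
#'
#' `abar <- abar + etaA * ePost * pbar` (piriform route) or
#' `h <- h + etaH * ePost * x` (glomerular route); applied only after the
#' reward has been presented.
#'
#' @param rstate a [RewardState-class].
#' @param ePost post-reward error-neuron activity.
#' @param drive the presynaptic drive (`pbar` or `x`).
#' @param route which set of weights to update.
#' @return the updated [RewardState-class].
#' @export
updateRewardWeights <- function(rstate, ePost, drive,
                                route = c("piriform", "glomeruli")) {
  route <- match.arg(route)
  if (route == "piriform")
    methods::initialize(rstate, abar = rstate@abar + rstate@etaA * ePost *
                          drive, eP = ePost)
  else
    methods::initialize(rstate, h = rstate@h + rstate@etaH * ePost * drive,
                        eX = ePost)
}

#' Go/no-go classification performance
#'
#' Fraction of trials on which predicted and actual reward fall on the
#' same side of 0.5: `mean((R - 0.5) * (-eHat - 0.5) > 0)`.
#'
#' @param R realized rewards.
#' @param eHat pre-reward error-neuron readings.
#' @return the classification probability.
#' @export
classificationPerformance <- function(R, eHat) {
  if (!length(R)) stop("no trials supplied", call. = FALSE)
  mean((R - 0.5) * (-eHat - 0.5) > 0)
}

#' Root-mean-square reward-prediction error
#'
#' `sqrt(mean((R + eHat)^2))`: zero for a perfect predictor
#' (`eHat = -R`).
#'
#' @inheritParams classificationPerformance
#' @return the average error.
#' @export
averageError <- function(R, eHat) {
  if (!length(R)) stop("no trials supplied", call. = FALSE)
  sqrt(mean((R + eHat)^2))
}

#' Run the go/no-go reward-association task
#'
#' Two odors are selected at random; one carries reward `a = 1`, the
#' other `a = 0`.  On each trial one of the two is presented (equal
#' probability) at a unit-mean Gamma concentration (always present), the
#' frozen circuit predicts the reward, and the association weights are
#' updated from the post-reward error.  The task is repeated over
#' independently seeded simulations.
#'
#' @param bulb,piriform pretrained, frozen circuit.
#' @param world the training world.
#' @param nRewardTrials reward trials per simulation.
#' @param nSims number of simulations.
#' @param route `"piriform"` or `"glomeruli"`.
#' @param seed integer seed; simulation `s` uses sub-stream
#'   `subSeed(seed, paste0("gonogo", s))`.
#' @param rewardSd reward noise standard deviation.
#' @return list with matrices `correct`, `R`, `eHat` (simulations x
#'   trials), and per-trial curves `performance` and `avgError` averaged
#'   over simulations.
#' @export
runGoNogo <- function(bulb, piriform, world, nRewardTrials = 20,
                      nSims = 50, route = c("piriform", "glomeruli"),
                      seed = 1, rewardSd = 0.1) {
  route <- match.arg(route)
  correct <- Rmat <- eMat <- matrix(NA_real_, nSims, nRewardTrials)
  for (s in seq_len(nSims)) {
    set.seed(subSeed(seed, paste0("gonogo", s)))
    pair <- sample(world@M, 2)
    rstate <- initReward(world@M, world@N)
    for (tr in seq_len(nRewardTrials)) {
      go <- runif(1) < 0.5
      odor <- if (go) pair[1] else pair[2]
      a <- if (go) 1.0 else 0.0
      conc <- rgamma(1, shape = world@gammaShape, rate = world@gammaShape)
      res <- runRewardTrial(bulb, piriform, rstate, world, odor, conc, a,
                            route = route, rewardSd = rewardSd)
      correct[s, tr] <- (res$R - 0.5) * (-res$eHat - 0.5) > 0
      Rmat[s, tr] <- res$R
      eMat[s, tr] <- res$eHat
      rstate <- updateRewardWeights(rstate, res$ePost, res$drive,
                                    route = route)
    }
  }
  list(correct = correct, R = Rmat, eHat = eMat,
       performance = colMeans(correct),
       avgError = sqrt(colMeans((Rmat + eMat)^2)))
}
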