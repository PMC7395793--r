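## Unsupervised training loop: sample a trial, integrate the dynamics with
## frozen weights, update plasticity, log metrics.

#' Train the bulb (and optionally piriform) circuit on an odor world
#'
#' Runs `nTrials` odor presentations.  Each trial samples a stimulus from
#' the world, integrates the rate dynamics to steady state with frozen
#' weights, then applies the plasticity updates (bulb precision and
#' weights first, then the piriform readout and lateral inhibition).
#' Reconstruction uses the selectivity assignment computed from the
#' weights *before* the trial's update.
#'
#' @param world an [OdorWorld-class].
#' @param config a [simConfig()]; defaults to the world's dimensions.
#' @param nTrials number of training trials.
#' @param piriform optional [PiriformState-class] trained jointly, or a
#'   variant name passed to [initPiriform()].
#' @param kappaJ lateral-inhibition strength when `piriform` is a variant
#'   name.
#' @param seed optional integer seed; odor/noise draws use sub-stream
#'   `"trials"`, initialization uses `"init"` / `"piriform"`.
#' @param bulb optional pre-built [BulbState-class] to continue training.
#' @param recordM also log the steady-state M/T rates (memory scales with
#'   `nTrials * N`).
#' @param dwEvery record the weight error every this many trials
#'   (0 disables).
#' @return list with elements `bulb`, `piriform` (or `NULL`), and
#'   `history`: per-trial matrices `cTrue`, `cbar`, `cHat` (and `pbar`,
#'   `pHat` with a piriform state; `m` when `recordM`), and a data frame
#'   `dw` of weight errors.
#' @export
#' @examples
#' world <- odorWorld(M = 5, N = 20, cO = 0.3, seed = 1)
#' cfg <- simConfig(M = 5, N = 20, cO = 0.3, tMin = 10, TMax = 1000)
#' fit <- trainCircuit(world, cfg, nTrials = 20, seed = 1)
#' fit$bulb
trainCircuit <- function(world, config = NULL, nTrials,
                         piriform = NULL, kappaJ = 1, seed = NULL,
                         bulb = NULL, recordM = FALSE, dwEvery = 25) {
  if (is.null(config))
    config <- simConfig(world@M, world@N, cO = world@cO,
                        sigmaX = world@sigmaX)
  stopifnot(inherits(config, "simConfig"))
  if (is.null(bulb)) bulb <- initBulb(config, seed = seed)
  if (is.character(piriform))
    piriform <- initPiriform(config, variant = piriform, kappaJ = kappaJ,
                             seed = seed)
  if (!is.null(seed)) set.seed(subSeed(seed, "trials"))
  M <- config$M; N <- config$N
  hasP <- !is.null(piriform)

  cTrue <- matrix(0, nTrials, M)
  cbarLog <- matrix(0, nTrials, M)
  cHatLog <- matrix(0, nTrials, M)
  pbarLog <- if (hasP) matrix(0, nTrials, M) else NULL
  pHatLog <- if (hasP) matrix(0, nTrials, M) else NULL
  mLog <- if (recordM) matrix(0, nTrials, N) else NULL
  dwTrial <- integer(0); dwVal <- numeric(0)

  for (tr in seq_len(nTrials)) {
    stim <- sampleTrial(world, tr)
    dyn <- runTrialDynamics(bulb, stim$x, piriform = piriform)

    sel <- assignSelectivity(bulb@wF, world@W)   # pre-update weights
    cTrue[tr, ] <- stim$c
    cbarLog[tr, ] <- dyn$cbar
    cHatLog[tr, ] <- reconstructOdors(dyn$cbar, sel, M)
    if (hasP) {
      selP <- if (piriform@variant == "bayes_copy") sel else
        assignSelectivity(piriform@wP, world@W)
      pbarLog[tr, ] <- dyn$pbar
      pHatLog[tr, ] <- reconstructOdors(dyn$pbar, selP, M)
    }
    if (recordM) mLog[tr, ] <- dyn$m
    if (dwEvery > 0 && (tr == 1L || tr %% dwEvery == 0L)) {
      dwTrial <- c(dwTrial, tr)
      dwVal <- c(dwVal, weightError(bulb@wF, world@W, sel))
    }

    bulb <- updatePlasticity(bulb, dyn)
    if (hasP) piriform <- updatePiriformPlasticity(piriform, bulb, dyn)
  }

  list(bulb = bulb, piriform = piriform,
       history = list(cTrue = cTrue, cbar = cbarLog, cHat = cHatLog,
                      pbar = pbarLog, pHat = pHatLog, m = mLog,
                      dw = data.frame(trial = dwTrial, dw = dwVal)))
}

#' Probe single-odor responses of a trained circuit
#'
#' Presents each odor in isolation (optionally at several concentrations)
#' with frozen weights and records the steady-state granule and piriform
#' rates; used for lifetime sparseness and concentration-invariance
#' analyses.
#'
#' @param bulb trained [BulbState-class].
#' @param world the [OdorWorld-class] it was trained on.
#' @param piriform optional trained [PiriformState-class].
#' @param concentrations vector of probe concentrations.
#' @param noise if `TRUE`, glomerular noise is included in the probes.
#' @return list of arrays `cbar` and `pbar` with dimensions
#'   (odor, concentration, cell).
#' @export
probeResponses <- function(bulb, world, piriform = NULL,
                           concentrations = 1, noise = TRUE) {
  M <- world@M
  cb <- array(0, c(M, length(concentrations), M))
  pb <- if (!is.null(piriform)) array(0, c(M, length(concentrations), M))
  for (j in seq_len(M)) {
    for (ci in seq_along(concentrations)) {
      cvec <- numeric(M); cvec[j] <- concentrations[ci]
      x <- if (noise) glomeruliResponse(world, cvec) else
        drop(world@W %*% cvec)
      dyn <- runTrialDynamics(bulb, x, piriform = piriform)
      cb[j, ci, ] <- dyn$cbar
      if (!is.null(piriform)) pb[j, ci, ] <- dyn$pbar
    }
  }
  list(cbar = cb, pbar = pb)
}
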