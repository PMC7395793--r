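## S4 classes for the central state objects.  All updates are functional:
## the plasticity and training functions return modified copies.

#' Simulation configuration
#'
#' Assembles and validates the circuit parameters.  Defaults are the
#' standard simulation settings: `cO = 3/M` (three odors present per trial
#' on average), unit glomerular noise, 5 Hz spontaneous M/T rate, 50 ms
#' rate time constant, 5 s trials integrated at 1 ms, initial trial counter
#' 100, precision initialization scale 0.5.
#'
#' @param M number of odors (and granule cells).
#' @param N number of glomeruli (and M/T cells).
#' @param cO prior presence probability of each odor.
#' @param sigmaX glomerular noise standard deviation.
#' @param gammaShape slab shape parameter of the odor prior.
#' @param mSp spontaneous M/T firing rate (Hz); rates are floored at `-mSp`.
#' @param tauR rate time constant (ms).
#' @param dt Euler step (ms); must be smaller than `tauR`.
#' @param TMax trial duration (ms).
#' @param tMin initial value of the effective trial counter.
#' @param ZRho precision initialization scale: `rho = cO / (sigmaX^2 ZRho)`.
#' @param ssTol steady-state early-exit threshold on the largest rate
#'   derivative (per ms); set to 0 to always integrate the full `TMax`.
#' @param gainMode `"adaptive"` (pseudo-precision recomputed from the
#'   weights every trial) or `"fixed"` (pinned at `lambdaFixed`).
#' @param lambdaFixed pinned pseudo-precision for `gainMode = "fixed"`;
#'   the reference settings are 200 and 342.
#' @param rateMode `"adaptive"` (learning rate `1/(t rho)`) or `"fixed"`
#'   (constant `etaFixed`).
#' @param etaFixed fixed learning rate for `rateMode = "fixed"`.
#' @return a validated named list of class `"simConfig"`.
#' @export
#' @examples
#' cfg <- simConfig(M = 20, N = 100)
#' cfg$cO
simConfig <- function(M, N, cO = 3 / M, sigmaX = 1.0, gammaShape = 3,
                      mSp = 5, tauR = 50, dt = 1, TMax = 5000, tMin = 100,
                      ZRho = 0.5, ssTol = 1e-7,
                      gainMode = c("adaptive", "fixed"), lambdaFixed = NA,
                      rateMode = c("adaptive", "fixed"), etaFixed = NA) {
  .checkScalar(M, "M", 1, Inf); .checkScalar(N, "N", 1, Inf)
  .checkScalar(cO, "cO", 0, 1, strict = TRUE)
  .checkScalar(sigmaX, "sigmaX", 0, Inf)
  .checkScalar(gammaShape, "gammaShape", 0, Inf, strict = TRUE)
  .checkScalar(mSp, "mSp", 0, Inf)
  .checkScalar(tauR, "tauR", 0, Inf, strict = TRUE)
  .checkScalar(dt, "dt", 0, tauR, strict = TRUE)
  .checkScalar(TMax, "TMax", dt, Inf)
  .checkScalar(tMin, "tMin", 1, Inf)
  .checkScalar(ZRho, "ZRho", 0, Inf, strict = TRUE)
  .checkScalar(ssTol, "ssTol", 0, Inf)
  gainMode <- match.arg(gainMode)
  rateMode <- match.arg(rateMode)
  if (gainMode == "fixed") .checkScalar(lambdaFixed, "lambdaFixed", 0, Inf,
                                        strict = TRUE)
  if (rateMode == "fixed") .checkScalar(etaFixed, "etaFixed", 0, Inf)
  structure(list(M = as.integer(M), N = as.integer(N), cO = cO,
                 sigmaX = sigmaX, gammaShape = gammaShape, mSp = mSp,
                 tauR = tauR, dt = dt, TMax = TMax, tMin = tMin,
                 ZRho = ZRho, ssTol = ssTol, gainMode = gainMode,
                 lambdaFixed = lambdaFixed, rateMode = rateMode,
                 etaFixed = etaFixed),
            class = "simConfig")
}

#' @rdname OdorWorld-class
#' @export
setClass("OdorWorld",
  representation(W = "matrix", sigmaX = "numeric", cO = "numeric",
                 gammaShape = "numeric", M = "integer", N = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@W) == c(object@N, object@M)))
      msg <- c(msg, "W must be N x M")
    if (any(object@W < 0)) msg <- c(msg, "mixing weights must be >= 0")
    rs <- rowSums(object@W)
    if (length(rs) && diff(range(rs)) > 1e-8 * max(mean(rs), 1e-300))
      msg <- c(msg, "row sums of W must be identical across glomeruli")
    if (object@sigmaX < 0) msg <- c(msg, "sigmaX must be >= 0")
    if (object@cO <= 0 || object@cO >= 1)
      msg <- c(msg, "cO must be in (0, 1)")
    if (object@gammaShape <= 0) msg <- c(msg, "gammaShape must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname BulbState-class
#' @export
setClass("BulbState",
  representation(wF = "matrix", wL = "matrix", rho = "numeric",
                 t = "numeric", m = "numeric", cbar = "numeric",
                 config = "ANY"),
  validity = function(object) {
    cfg <- object@config
    msg <- character()
    if (!inherits(cfg, "simConfig"))
      return("config must be built by simConfig()")
    if (!all(dim(object@wF) == c(cfg$M, cfg$N)))
      msg <- c(msg, "wF must be M x N")
    if (!all(dim(object@wL) == c(cfg$N, cfg$M)))
      msg <- c(msg, "wL must be N x M")
    if (any(object@wF < 0) || any(object@wL < 0))
      msg <- c(msg, "weights must be >= 0")
    if (any(object@rho <= 0)) msg <- c(msg, "precisions must be > 0")
    if (object@t < cfg$tMin) msg <- c(msg, "counter below tMin")
    if (any(object@cbar < 0)) msg <- c(msg, "granule rates must be >= 0")
    if (any(object@m < -cfg$mSp - 1e-9))
      msg <- c(msg, "M/T rates must be >= -mSp")
    if (length(msg)) msg else TRUE
  })

#' @rdname PiriformState-class
#' @export
setClass("PiriformState",
  representation(wP = "matrix", rhoP = "numeric", J = "matrix",
                 pbar = "numeric", variant = "character",
                 kappaJ = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@variant %in% c("bayes_copy", "local", "local_lateral",
                               "local_lateral_feedback"))
      msg <- c(msg, "unknown circuit variant")
    if (any(object@J < 0)) msg <- c(msg, "lateral weights must be >= 0")
    if (nrow(object@J) && any(diag(object@J) != 0))
      msg <- c(msg, "lateral weights must have zero diagonal")
    if (any(object@pbar < -1e-9) || any(object@pbar > 1 + 1e-9))
      msg <- c(msg, "pbar must lie in [0, 1]")
    if (object@kappaJ < 0) msg <- c(msg, "kappaJ must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname RewardState-class
#' @export
setClass("RewardState",
  representation(abar = "numeric", h = "numeric", eP = "numeric",
                 eX = "numeric", etaA = "numeric", etaH = "numeric"))

#' @rdname SparseCodingState-class
#' @export
setClass("SparseCodingState",
  representation(wHat = "matrix", cHat = "numeric", etaC = "numeric",
                 etaW = "numeric", kC = "numeric", thetaC = "numeric",
                 cO = "numeric", sigmaX = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@cHat <= 0))
      msg <- c(msg, "concentration estimates must stay strictly positive")
    if (object@etaC <= 0 || object@etaW < 0)
      msg <- c(msg, "learning rates must be positive")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "OdorWorld", function(object) {
  cat("OdorWorld:", object@N, "glomeruli x", object@M, "odors\n")
  cat("  presence probability cO =", object@cO,
      "| slab shape =", object@gammaShape,
      "| noise sd =", object@sigmaX, "\n")
  cat("  common row sum of W =", signif(sum(object@W[1, ]), 6), "\n")
})

setMethod("show", "BulbState", function(object) {
  cfg <- object@config
  cat("BulbState:", cfg$M, "granule x", cfg$N, "M/T cells\n")
  cat("  effective trial counter t =", object@t,
      "(started at", cfg$tMin, ")\n")
  cat("  precision range: [", signif(min(object@rho), 4), ",",
      signif(max(object@rho), 4), "]\n")
  cat("  mean feedforward weight:", signif(mean(object@wF), 4), "\n")
})

setMethod("show", "PiriformState", function(object) {
  cat("PiriformState (variant", object@variant, "):",
      nrow(object@wP), "piriform cells\n")
  cat("  lateral inhibition: mean J =", signif(mean(object@J), 4),
      "| kappaJ =", object@kappaJ, "\n")
})

setMethod("show", "RewardState", function(object) {
  cat("RewardState:", length(object@abar), "piriform-route weights,",
      length(object@h), "glomerular-route weights\n")
  cat("  etaA =", object@etaA, "| etaH =", object@etaH, "\n")
})

setMethod("show", "SparseCodingState", function(object) {
  cat("SparseCodingState:", nrow(object@wHat), "glomeruli x",
      ncol(object@wHat), "odors; etaC =", object@etaC,
      "etaW =", object@etaW, "\n")
})
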