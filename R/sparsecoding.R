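## Sparse-coding baseline: MAP inference of the concentrations by gradient
## ascent on the log posterior, stochastic-gradient dictionary learning
## with per-column L2 normalization.  The spike-and-slab prior is replaced
## by a differentiable Gamma(kC, kC/cO) surrogate with mean cO.

#' Initialize the sparse-coding model
#'
#' The dictionary starts from the same log-normal ensemble as the true
#' mixing weights (and is immediately L2-normalized to the fixed column
#' scale, see [scUpdateWeights()]).
#'
#' @param M,N numbers of odors and glomeruli.
#' @param cO prior presence probability of the matched Bayesian model;
#'   sets the surrogate prior scale `thetaC = cO / 3`.
#' @param sigmaX glomerular noise standard deviation.
#' @param etaC inference step size.
#' @param etaW dictionary learning rate (reference sweep: 0.3, 0.5, 1.0).
#' @param seed optional integer seed (sub-stream `"scinit"`).
#' @return a [SparseCodingState-class].
#' @export
initSparseCoding <- function(M, N, cO, sigmaX = 1.0, etaC = 1e-5,
                             etaW = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(subSeed(seed, "scinit"))
  wHat <- matrix(rlnorm(N * M, meanlog = -log(cO * M), sdlog = 1), N, M)
  wHat <- .scNormalize(wHat, cO, M, N)
  new("SparseCodingState", wHat = wHat, cHat = rep(cO, M), etaC = etaC,
      etaW = etaW, kC = 3, thetaC = cO / 3, cO = cO, sigmaX = sigmaX)
}

## per-column L2 normalization to root-mean-square e/(cO*M): the Euler
## constant numerator matches the scale of the log-normal generative
## weights (E[w] = exp(1/2)/(cO*M), so E[w^2]^(1/2) = e/(cO*M) under the
## unit log-variance)
.scNormalize <- function(wHat, cO, M, N) {
  nrm <- sqrt(colSums(wHat^2) / N)
  if (any(nrm == 0)) stop("dictionary column collapsed to zero",
                          call. = FALSE)
  sweep(wHat, 2, (exp(1) / (cO * M)) / nrm, `*`)
}

#' Sparse-coding objective (log posterior up to a constant)
#'
#' Quadratic data term plus the Gamma surrogate prior term
#' `sum_j (2 log cHat_j - 3 cHat_j / cO)`.
#'
#' @param x glomerular response vector.
#' @param cHat strictly positive concentration estimate.
#' @param wHat `N x M` dictionary.
#' @param sigmaX noise standard deviation.
#' @param cO prior scale.
#' @return the scalar objective value.
#' @export
scObjective <- function(x, cHat, wHat, sigmaX, cO) {
  if (any(cHat <= 0))
    stop("the objective requires strictly positive concentrations",
         call. = FALSE)
  resid <- x - drop(wHat %*% cHat)
  -sum(resid^2) / (2 * sigmaX^2) + sum(2 * log(cHat) - 3 * cHat / cO)
}

#' Analytic gradient of the sparse-coding objective
#'
#' `d E / d cHat_j = sum_i mHat_i wHat_ij / sigmaX^2 + 2/cHat_j - 3/cO`,
#' with `mHat = x - wHat cHat` the residual.
#'
#' @inheritParams scObjective
#' @return length-`M` gradient vector.
#' @export
scGradient <- function(x, cHat, wHat, sigmaX, cO) {
  mHat <- x - drop(wHat %*% cHat)
  drop(crossprod(wHat, mHat)) / sigmaX^2 + 2 / cHat - 3 / cO
}

#' MAP inference of the concentrations by gradient ascent
#'
#' Iterates `cHat <- cHat + etaC * (wHat' mHat + sigmaX^2 (2/cHat - 3/cO))`
#' with the residual recomputed every step; the estimate is floored at
#' `floorC` to keep the log prior finite.  The reference setting runs
#' 100,000 steps per trial; `stepTol` adds an early exit on the largest
#' per-step change.
#'
#' @param sc a [SparseCodingState-class].
#' @param x glomerular response vector.
#' @param maxSteps iteration budget.
#' @param stepTol early-exit threshold on `max |delta cHat|` (0 disables).
#' @param floorC lower bound on the estimates.
#' @return list with `cHat`, residual `mHat`, `steps` and `converged`.
#' @export
scInfer <- function(sc, x, maxSteps = 1e5, stepTol = 0, floorC = 1e-8) {
  out <- .cppScInfer(x, sc@wHat, rep(sc@cO, ncol(sc@wHat)), sc@etaC,
                     sc@sigmaX^2, sc@cO, as.integer(maxSteps), stepTol,
                     floorC)
  out$cHat <- drop(out$cHat); out$mHat <- drop(out$mHat)
  out
}

#' Stochastic-gradient dictionary update with column normalization
#'
#' Gradient step `wHat <- wHat + etaW * mHat cHat'` followed by per-column
#' L2 normalization to the fixed scale `e / (cO * M)` (root mean square
#' over glomeruli), which prevents weight divergence.
#'
#' @param sc a [SparseCodingState-class].
#' @param mHat residual at the inferred concentrations.
#' @param cHat inferred concentrations.
#' @return the updated [SparseCodingState-class].
#' @export
scUpdateWeights <- function(sc, mHat, cHat) {
  M <- ncol(sc@wHat); N <- nrow(sc@wHat)
  wHat <- sc@wHat + sc@etaW * outer(mHat, cHat)
  methods::initialize(sc, wHat = .scNormalize(wHat, sc@cO, M, N),
                      cHat = pmax(cHat, 1e-8))
}

#' Train the sparse-coding baseline on an odor world
#'
#' Per trial: MAP inference of the concentrations, then one dictionary
#' gradient step with normalization.
#'
#' @param world an [OdorWorld-class].
#' @param nTrials number of trials.
#' @param etaW dictionary learning rate.
#' @param etaC inference step size.
#' @param maxSteps,stepTol inference budget per trial (see [scInfer()]).
#' @param seed optional integer seed.
#' @param dwEvery record the weight error every this many trials.
#' @return list with the final `sc` state and a `history` data frame of
#'   weight errors.
#' @export
trainSparseCoding <- function(world, nTrials, etaW = 0.5, etaC = 1e-5,
                              maxSteps = 1e5, stepTol = 0, seed = NULL,
                              dwEvery = 25) {
  sc <- initSparseCoding(world@M, world@N, world@cO, world@sigmaX,
                         etaC = etaC, etaW = etaW, seed = seed)
  if (!is.null(seed)) set.seed(subSeed(seed, "sctrials"))
  dwTrial <- integer(0); dwVal <- numeric(0)
  for (tr in seq_len(nTrials)) {
    stim <- sampleTrial(world, tr)
    inf <- scInfer(sc, stim$x, maxSteps = maxSteps, stepTol = stepTol)
    if (dwEvery > 0 && (tr == 1L || tr %% dwEvery == 0L)) {
      sel <- assignSelectivity(t(sc@wHat), world@W)
      dwTrial <- c(dwTrial, tr)
      dwVal <- c(dwVal, weightError(t(sc@wHat), world@W, sel))
    }
    sc <- scUpdateWeights(sc, inf$mHat, inf$cHat)
  }
  list(sc = sc, history = list(dw = data.frame(trial = dwTrial,
                                               dw = dwVal)))
}
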