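## Synthetic odor environment: log-normal mixing weights with row-sum
## normalization, spike-and-slab odor draws, Gaussian glomerular noise.

#' Sample a row-normalized log-normal mixing matrix
#'
#' Affinities are drawn i.i.d. log-normal, `log w ~ N(-log(cO * M), 1)`, so
#' that the expected total glomerular drive is order one, then each row is
#' rescaled by (grand mean)/(row mean).  The rescaling factor is 1 on
#' average but forces every row sum to be exactly equal, which removes one
#' source of noise from the learning problem.
#'
#' @param M number of odors.
#' @param N number of glomeruli.
#' @param cO presence probability (sets the log-normal location).
#' @return an `N x M` matrix of non-negative affinities with identical
#'   row sums.
#' @export
#' @examples
#' W <- sampleMixingWeights(M = 10, N = 40, cO = 0.3)
#' range(rowSums(W))  # identical up to floating error
sampleMixingWeights <- function(M, N, cO) {
  .checkScalar(M, "M", 1, Inf); .checkScalar(N, "N", 1, Inf)
  .checkScalar(cO, "cO", 0, 1, strict = TRUE)
  wTilde <- matrix(rlnorm(N * M, meanlog = -log(cO * M), sdlog = 1), N, M)
  grand <- mean(wTilde)
  rowMean <- rowMeans(wTilde)
  wTilde * (grand / rowMean)
}

#' Construct a synthetic odor world
#'
#' Bundles the mixing matrix, noise scale and prior parameters into a
#' validated [OdorWorld-class] object.
#'
#' @inheritParams sampleMixingWeights
#' @param sigmaX glomerular noise standard deviation.
#' @param gammaShape slab shape of the odor prior (unit-mean Gamma).
#' @param seed optional integer seed; when given, the weights are drawn
#'   from the sub-stream `subSeed(seed, "weights")`.
#' @return an [OdorWorld-class] object.
#' @export
#' @examples
#' world <- odorWorld(M = 10, N = 40, cO = 0.3, seed = 1)
#' world
odorWorld <- function(M, N, cO = 3 / M, sigmaX = 1.0, gammaShape = 3,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(subSeed(seed, "weights"))
  W <- sampleMixingWeights(M, N, cO)
  new("OdorWorld", W = W, sigmaX = sigmaX, cO = cO,
      gammaShape = gammaShape, M = as.integer(M), N = as.integer(N))
}

#' Draw one odor concentration vector from the spike-and-slab prior
#'
#' Each odor is independently absent (0) with probability `1 - cO`, or
#' present with an amplitude drawn from a Gamma distribution with shape
#' `gammaShape` and rate `gammaShape` (unit mean).  All-zero draws are
#' rejected and redrawn, so every returned trial contains at least one
#' odor.
#'
#' @param world an [OdorWorld-class] object, or `NULL` if `M`, `cO`,
#'   `gammaShape` are supplied directly.
#' @param M,cO,gammaShape prior parameters (ignored when `world` is given).
#' @param maxTries rejection cap; exceeding it signals a degenerate `cO`.
#' @return length-`M` concentration vector with at least one positive
#'   entry.
#' @export
#' @examples
#' set.seed(1)
#' sampleOdors(M = 10, cO = 0.3)
sampleOdors <- function(world = NULL, M = world@M, cO = world@cO,
                        gammaShape = if (is.null(world)) 3 else
                          world@gammaShape,
                        maxTries = 1e6) {
  .checkScalar(cO, "cO", 0, 1, strict = TRUE)
  for (i in seq_len(maxTries)) {
    present <- runif(M) < cO
    if (any(present)) {
      cvec <- numeric(M)
      cvec[present] <- rgamma(sum(present), shape = gammaShape,
                              rate = gammaShape)
      return(cvec)
    }
  }
  stop("no non-null odor vector after ", maxTries,
       " draws; cO is degenerate", call. = FALSE)
}

#' Noisy glomerular response to an odor vector
#'
#' `x = W c + sigmaX * xi` with `xi` i.i.d. standard Gaussian.
#'
#' @param world an [OdorWorld-class] object.
#' @param cvec length-`M` concentration vector.
#' @return length-`N` response vector.
#' @export
glomeruliResponse <- function(world, cvec) {
  if (length(cvec) != world@M)
    stop("concentration vector has length ", length(cvec),
         " but the world has M = ", world@M, " odors", call. = FALSE)
  drop(world@W %*% cvec) + world@sigmaX * rnorm(world@N)
}

#' Sample a complete trial stimulus
#'
#' Draws a concentration vector from the prior and the corresponding noisy
#' glomerular response.
#'
#' @param world an [OdorWorld-class] object.
#' @param trialIndex optional trial label carried through to the output.
#' @return list with elements `c` (odors), `x` (response) and
#'   `trialIndex`.
#' @export
sampleTrial <- function(world, trialIndex = NA_integer_) {
  cvec <- sampleOdors(world)
  list(c = cvec, x = glomeruliResponse(world, cvec),
       trialIndex = trialIndex)
}
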