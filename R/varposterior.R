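## Closed-form variational posterior machinery for the spike-and-slab odor
## prior.  The posterior over one odor concentration is
##
##   q(c) \propto p_c(c) exp(-lam (c - mu)^2 / 2),
##
## with p_c a mixture of a point mass at zero (weight 1 - cO) and a
## shape-3 Gamma slab with unit mean.  Its first moment (F), second moment
## (G) and presence probability (H) have closed forms in terms of the
## standardized argument alpha = sqrt(lam) mu - 3/sqrt(lam) and the scaled
## Mills ratio Psi(alpha) = sqrt(2 pi) exp(alpha^2/2) Phi(alpha).  Psi
## itself overflows for moderate alpha, so all expressions are evaluated in
## terms of 1/Psi, which is bounded.

#' Numerically stable reciprocal of the scaled Mills ratio
#'
#' Computes `1/Psi(alpha)` where `Psi(alpha) = sqrt(2*pi) * exp(alpha^2/2) *
#' pnorm(alpha)`.  A three-branch approximation keeps the evaluation stable:
#' for `alpha/sqrt(2) < -10` the asymptotic value `-alpha` is used, for
#' `alpha/sqrt(2) > 10` the result is 0, and in between the exact expression
#' `exp(-alpha^2/2) / (sqrt(2*pi) * pnorm(alpha))` is evaluated (both factors
#' are representable in double precision on this range).
#'
#' @param alpha numeric vector of standardized arguments.
#' @return numeric vector of the same length as `alpha`.
#' @export
#' @examples
#' invPsi(0)            # 2 / sqrt(2*pi), since pnorm(0) = 1/2
#' invPsi(c(-20, 15))   # asymptotic branches: 20 and 0
invPsi <- function(alpha) {
  stopifnot(is.numeric(alpha), all(is.finite(alpha)))
  out <- numeric(length(alpha))
  b <- alpha / sqrt(2)
  lo <- b < -10
  hi <- b > 10
  mid <- !lo & !hi
  out[lo] <- -alpha[lo]
  out[hi] <- 0
  if (any(mid)) {
    a <- alpha[mid]
    out[mid] <- exp(-a^2 / 2) / (sqrt(2 * pi) * pnorm(a))
  }
  out
}

## Moments from the standardized argument alpha directly.  `mix` is the
## slab weight in the prior odds (cO for the bulb; the top-down presence
## probability pbar for feedback-modulated granule cells).
##
## Numerics: the closed forms group terms as (polynomial in alpha) +
## (polynomial) * Psi(alpha).  For alpha << 0 those groups cancel almost
## exactly -- the second moment extracts an O(alpha^-4) residual from
## O(alpha^4) terms, a condition number of alpha^8 -- so no form of 1/Psi
## rescues relative accuracy there.  We therefore evaluate the exact
## expressions for alpha >= -16 and switch, below that, to an asymptotic
## expansion of the slab integrals themselves, which has no cancellation;
## both sides agree to ~1e-6 relative at the switch.  The exported
## invPsi() keeps the plain three-branch form used inside the network
## dynamics.
.ssMomentsAlpha <- function(alpha, lam, mix) {
  n <- max(length(alpha), length(lam), length(mix))
  alpha <- rep_len(alpha, n); lam <- rep_len(lam, n); mix <- rep_len(mix, n)
  first <- second <- prob <- numeric(n)
  deep <- alpha < -16

  if (any(!deep)) {
    a <- alpha[!deep]; l <- lam[!deep]; mx <- mix[!deep]
    a2 <- a * a
    ip <- exp(-a2 / 2) / (sqrt(2 * pi) * pnorm(a))   # underflows to 0 for a >> 0
    s <- 2 * (1 - mx) / (27 * mx)
    ## numerator and denominator both divided by Psi: every term is finite
    denom <- s * l * sqrt(l) * ip + a * ip + (1 + a2)
    first[!deep] <- ((2 + a2) * ip + a * (3 + a2)) / (sqrt(l) * denom)
    second[!deep] <- (a * (5 + a2) * ip + (3 + 6 * a2 + a2 * a2)) /
      (l * denom)
    prob[!deep] <- (a * ip + (1 + a2)) / denom
  }

  if (any(deep)) {
    ## spike-dominated tail: the slab integrals reduce to
    ##   A_n = int_0^inf c^n exp(-beta c - lam c^2/2) dc,  beta = sqrt(lam)|alpha|,
    ## expanded in 1/alpha^2 (relative truncation error ~1e-6 at the switch)
    a <- alpha[deep]; l <- lam[deep]; mx <- mix[deep]
    beta <- sqrt(l) * abs(a)
    i2 <- 1 / a^2
    A2 <- (2 / beta^3) *
      (1 - i2 * (6 - i2 * (45 - i2 * (420 - i2 * 4725))))
    A3 <- (6 / beta^4) *
      (1 - i2 * (10 - i2 * (105 - i2 * (1260 - i2 * 17325))))
    A4 <- (24 / beta^5) *
      (1 - i2 * (15 - i2 * (210 - i2 * (3150 - i2 * 51975))))
    slabW <- 13.5 * mx
    z <- (1 - mx) + slabW * A2
    first[deep] <- slabW * A3 / z
    second[deep] <- slabW * A4 / z
    prob[deep] <- slabW * A2 / z
  }

  list(first = pmax(first, 0), second = pmax(second, 0),
       probPresent = .clamp(prob, 0, 1))
}

#' Posterior moments under the spike-and-slab prior
#'
#' First moment `F`, second moment `G` and presence probability `H` of the
#' variational concentration posterior, as functions of the Gaussian
#' pseudo-mean `mu`, pseudo-precision `lam` and prior presence probability
#' `cO`.  These are the granule-cell transfer functions: `F` is the firing
#' rate nonlinearity, `G` drives the precision update and `H` is the
#' concentration-invariant readout decoded by piriform cells.
#'
#' The closed forms are specific to a Gamma slab of shape 3 (unit mean);
#' any other shape is routed through [quadratureMoments()].
#'
#' @param mu numeric vector, Gaussian pseudo-mean of the concentration
#'   likelihood.
#' @param lam numeric vector of pseudo-precisions, `> 0`.
#' @param cO prior presence probability, in (0, 1).
#' @param gammaShape slab shape parameter; closed forms require 3.
#' @return a list with components `first`, `second` and `probPresent`,
#'   vectors of the length of `mu`.
#' @export
#' @examples
#' spikeSlabMoments(1, 50, 0.03)
spikeSlabMoments <- function(mu, lam, cO, gammaShape = 3) {
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("'lam' must be positive and finite", call. = FALSE)
  .checkScalar(cO, "cO", 0, 1, strict = TRUE)
  if (!identical(gammaShape, 3) && !isTRUE(all.equal(gammaShape, 3))) {
    warning("closed forms require a shape-3 slab; falling back to quadrature")
    n <- max(length(mu), length(lam))
    mu <- rep_len(mu, n); lam <- rep_len(lam, n)
    res <- lapply(seq_len(n), function(i)
      quadratureMoments(mu[i], lam[i], cO = cO, gammaShape = gammaShape))
    return(list(first = vapply(res, `[[`, 0, "first"),
                second = vapply(res, `[[`, 0, "second"),
                probPresent = vapply(res, `[[`, 0, "probPresent")))
  }
  alpha <- sqrt(lam) * mu - 3 / sqrt(lam)
  .ssMomentsAlpha(alpha, lam, cO)
}

#' Transfer functions under a flat non-negative prior
#'
#' Posterior mean `F` and second moment `G` when the concentration prior is
#' the improper flat density on `c > 0`.  The resulting gain function is
#' approximately rectified-linear: `F = mu + 1/(sqrt(lam) Psi(sqrt(lam) mu))`
#' and `G = mu * F + 1/lam`.
#'
#' @inheritParams spikeSlabMoments
#' @return list with components `first` and `second`.
#' @export
nonnegTransfer <- function(mu, lam) {
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("'lam' must be positive and finite", call. = FALSE)
  f <- mu + invPsi(sqrt(lam) * mu) / sqrt(lam)
  list(first = f, second = mu * f + 1 / lam)
}

#' Transfer functions under an exponentially decaying prior
#'
#' Posterior mean `F` and second moment `G` when the prior is
#' `p(c) = exp(-c/cO)/cO` on `c > 0`: the non-negative transfer function
#' with the pseudo-mean shifted by `1/(cO * lam)`.  Recovers
#' [nonnegTransfer()] as `cO` grows large.
#'
#' @inheritParams spikeSlabMoments
#' @return list with components `first` and `second`.
#' @export
expDecayTransfer <- function(mu, lam, cO) {
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("'lam' must be positive and finite", call. = FALSE)
  .checkScalar(cO, "cO", 0, Inf, strict = TRUE)
  mus <- mu - 1 / (cO * lam)
  f <- mus + invPsi(sqrt(lam) * mus) / sqrt(lam)
  list(first = f, second = mus * f + 1 / lam)
}

#' Feedback-modulated granule transfer function
#'
#' In the full circuit the piriform presence estimate feeds back to the
#' granule cells: the prior mixing weight `cO` in the denominators of the
#' transfer functions is replaced by the top-down probability `pbar`,
#' sharpening the granule response for odors the cortex believes present.
#' Parameterized directly by the standardized argument `alpha` (which is
#' unchanged by the substitution).
#'
#' @param alpha standardized argument, `sqrt(lam)*mu - 3/sqrt(lam)`.
#' @param lam pseudo-precision, `> 0`.
#' @param pbar top-down presence probability; clamped to
#'   `[1e-6, 1 - 1e-6]` to keep the mixture odds finite.
#' @return list with components `first`, `second` and `probPresent`.
#' @export
granuleTopdownTransfer <- function(alpha, lam, pbar) {
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("'lam' must be positive and finite", call. = FALSE)
  .ssMomentsAlpha(alpha, lam, .clamp(pbar, 1e-6, 1 - 1e-6))
}

#' Posterior moments by numeric quadrature
#'
#' Independent oracle for the closed-form moments: integrates the posterior
#' `p_c(c) exp(-lam (c - mu)^2/2)` on `[0, upper]` with a composite Simpson
#' rule, refined until successive estimates agree to `tol` (relative).  The
#' spike mass and the slab integrand are combined in log space so that the
#' result is well defined even when all unnormalized masses underflow.
#'
#' Used in tests, and as the fallback path for non-shape-3 slabs.
#'
#' @inheritParams spikeSlabMoments
#' @param gammaShape slab shape (Gamma with rate equal to shape, unit mean).
#' @param slabLogDensity optional function `(c) -> log density` replacing the
#'   Gamma slab (may be unnormalized up to a constant); use with `cO = 1`
#'   for spike-free priors.
#' @param tol relative convergence tolerance of the panel refinement.
#' @param maxPoints refinement cap on the number of grid points.
#' @return list with components `first`, `second` and `probPresent`.
#' @export
#' @examples
#' # half-normal mean: flat slab, no spike, mu = 0
#' quadratureMoments(0, 4, cO = 1, slabLogDensity = function(c) 0)$first
#' sqrt(2 / (pi * 4))
quadratureMoments <- function(mu, lam, cO, gammaShape = 3,
                              slabLogDensity = NULL,
                              tol = 1e-8, maxPoints = 2^21 + 1) {
  .checkScalar(mu, "mu")
  .checkScalar(lam, "lam", 0, Inf, strict = TRUE)
  .checkScalar(cO, "cO", 0, 1)
  if (cO == 0)
    return(list(first = 0, second = 0, probPresent = 0))
  if (is.null(slabLogDensity))
    slabLogDensity <- function(c)
      stats::dgamma(c, shape = gammaShape, rate = gammaShape, log = TRUE)
  logSpike <- if (cO < 1) log(1 - cO) - lam * mu^2 / 2 else -Inf
  logIntegrand <- function(c)
    log(cO) + slabLogDensity(c) - lam * (c - mu)^2 / 2
  ## domain: covers the Gaussian bulk, the slab tail, and -- when mu < 0 --
  ## tightens to the exponential boundary layer of width ~ 1/(lam |mu|)
  upper <- max(mu, 0) + 12 / sqrt(lam) + 60 / (lam * max(-mu, 0) + 3)

  simpson <- function(n) {
    cc <- seq(0, upper, length.out = n)
    h <- cc[2] - cc[1]
    lw <- logIntegrand(cc)               # -Inf at c = 0 for vanishing slabs
    shift <- max(lw, logSpike)
    if (!is.finite(shift)) return(c(0, 0, 0))
    w <- exp(lw - shift)
    sw <- rep(c(2, 4), length.out = n); sw[1] <- 1; sw[n] <- 1
    slab0 <- sum(sw * w) * h / 3
    slab1 <- sum(sw * w * cc) * h / 3
    slab2 <- sum(sw * w * cc^2) * h / 3
    spike <- exp(logSpike - shift)
    z <- spike + slab0
    if (!is.finite(z) || z <= 0) return(c(0, 0, 0))
    c(slab1 / z, slab2 / z, slab0 / z)
  }

  n <- 4097L
  est <- simpson(n)
  repeat {
    n <- 2L * (n - 1L) + 1L
    if (n > maxPoints) break
    nxt <- simpson(n)
    if (all(abs(nxt - est) <= tol * pmax(abs(nxt), 1e-300))) {
      est <- nxt; break
    }
    est <- nxt
  }
  if (any(!is.finite(est)))
    stop("quadrature failed to converge to a finite value", call. = FALSE)
  list(first = est[1], second = est[2], probPresent = est[3])
}
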