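# Posterior transfer-function machinery: stable Mills ratio, closed-form
# moments vs the quadrature oracle, alternative priors, top-down
# modulation.

test_that("invPsi reproduces the three branches and their values", {
  expect_equal(invPsi(15), 0)                       # far positive branch
  expect_equal(invPsi(-20), 20)                     # far negative branch
  expect_equal(invPsi(0), 2 / sqrt(2 * pi), tolerance = 1e-12)
  # mid branch equals the definition 1/(sqrt(2 pi) exp(a^2/2) pnorm(a))
  a <- seq(-14, 14, by = 0.5)
  expect_equal(invPsi(a), exp(-a^2 / 2) / (sqrt(2 * pi) * pnorm(a)),
               tolerance = 1e-12)
})

test_that("invPsi branch continuity: exact at +, Mills-limited at -", {
  bp <- 10 * sqrt(2)
  expect_lt(abs(invPsi(bp - 1e-9) - invPsi(bp + 1e-9)), 1e-8)
  # at the negative boundary the truncated branch omits the 1/|alpha|
  # Mills correction; the discontinuity is that correction, about 0.5%
  jump <- abs(invPsi(-bp - 1e-9) - invPsi(-bp + 1e-9))
  expect_lt(jump / bp, 1e-2)
  expect_gt(jump, 1e-4)   # the correction is real, not a rounding artifact
})

test_that("spike-slab moments match the quadrature oracle on the grid", {
  mus <- seq(-2, 4, by = 0.5)
  lams <- 10^seq(0, 4, by = 0.5)
  worst <- 0
  for (mu in mus) for (lam in lams) {
    cl <- spikeSlabMoments(mu, lam, 0.03)
    qd <- quadratureMoments(mu, lam, 0.03)
    err <- max(abs(unlist(cl) - unlist(qd)) /
                 pmax(abs(unlist(qd)), 1e-10))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-4)
})

test_that("specific moment values agree with quadrature to 1e-5", {
  cl <- spikeSlabMoments(1.0, 50.0, 0.03)
  qd <- quadratureMoments(1.0, 50.0, 0.03)
  expect_equal(cl$first, qd$first, tolerance = 1e-5)
  expect_equal(cl$second, qd$second, tolerance = 1e-5)
  expect_equal(cl$probPresent, qd$probPresent, tolerance = 1e-5)
})

test_that("moment limits: spike-dominated and slab-dominated", {
  # overwhelming evidence for absence (decay is polynomial in |mu|, not
  # exponential: the slab keeps mass next to zero)
  lo <- spikeSlabMoments(-50, 10, 0.03)
  expect_lt(lo$first, 1e-9)
  expect_lt(lo$probPresent, 1e-6)
  expect_gt(lo$probPresent, 0)
  loDeeper <- spikeSlabMoments(-500, 10, 0.03)
  expect_lt(loDeeper$first, lo$first)
  expect_lt(loDeeper$probPresent, lo$probPresent)
  # cO -> 1 with strong evidence: spike term vanishes from the normalizer
  hi <- spikeSlabMoments(2, 100, 1 - 1e-12)
  qd <- quadratureMoments(2, 100, 1)      # zero spike mass
  expect_equal(hi$first, qd$first, tolerance = 1e-6)
  expect_equal(hi$probPresent, 1, tolerance = 1e-9)
})

test_that("moments are monotone in mu with valid ranges (property)", {
  mus <- seq(-6, 8, by = 0.02)
  for (lam in c(1, 20, 500, 5000)) {
    mm <- spikeSlabMoments(mus, lam, 0.03)
    expect_true(all(diff(mm$first) >= -1e-10))
    expect_true(all(diff(mm$second) >= -1e-10))
    expect_true(all(diff(mm$probPresent) >= -1e-10))
    expect_true(all(mm$first >= 0))
    expect_true(all(mm$probPresent >= 0 & mm$probPresent <= 1))
    expect_true(all(mm$second - mm$first^2 >= -1e-10))   # Jensen
  }
})

test_that("nonneg transfer equals the truncated-normal closed form", {
  set.seed(41)
  mu <- runif(80, -3, 3)
  lam <- 10^runif(80, -1, 3)
  # stay inside the exact Mills branch: beyond it the transfer function
  # deliberately zeroes the (already vanishing) tail
  keep <- sqrt(lam) * mu > -10 * sqrt(2)
  mu <- mu[keep]; lam <- lam[keep]
  tf <- nonnegTransfer(mu, lam)
  s <- 1 / sqrt(lam)
  tnMean <- mu + s * dnorm(mu / s) / pnorm(mu / s)
  expect_equal(tf$first, tnMean, tolerance = 1e-8)
  # G - mu F - 1/lam = 0 exactly by construction
  expect_equal(tf$second - mu * tf$first - 1 / lam,
               numeric(length(mu)))
  # rectifier regime: correction below 1e-10
  expect_lt(abs(nonnegTransfer(30 / sqrt(1), 1)$first - 30), 1e-10)
})

test_that("exponential-decay transfer: shift, limit and quadrature", {
  mu <- c(-0.5, 0.3, 1.5); lam <- c(5, 50, 200)
  # shift term is exactly 1/(cO lam)
  cO <- 0.2
  a <- expDecayTransfer(mu, lam, cO)
  b <- nonnegTransfer(mu - 1 / (cO * lam), lam)
  expect_equal(a$first, b$first)
  expect_equal(a$second, b$second)
  # cO -> infinity reduces to the flat non-negative prior
  big <- expDecayTransfer(mu, lam, 1e9)
  flat <- nonnegTransfer(mu, lam)
  expect_equal(big$first, flat$first, tolerance = 1e-6)
  # against quadrature with the exponential prior density
  for (i in seq_along(mu)) {
    qd <- quadratureMoments(mu[i], lam[i], cO = 1,
                            slabLogDensity = function(c) -c / 0.2)
    ed <- expDecayTransfer(mu[i], lam[i], 0.2)
    expect_equal(ed$first, qd$first, tolerance = 1e-6)
    expect_equal(ed$second, qd$second, tolerance = 1e-6)
  }
})

test_that("quadrature oracle closed-form cases", {
  # flat slab, no spike, mu = 0: half-normal mean
  for (lam in c(0.5, 4, 80)) {
    hn <- quadratureMoments(0, lam, cO = 1, slabLogDensity = function(c) 0)
    expect_equal(hn$first, sqrt(2 / (pi * lam)), tolerance = 1e-7)
    expect_equal(hn$second, 1 / lam, tolerance = 1e-7)
  }
  # cO = 0: pure spike
  z <- quadratureMoments(1, 10, cO = 0)
  expect_identical(unlist(z), c(first = 0, second = 0, probPresent = 0))
})

test_that("top-down transfer: identity at pbar = cO, monotone, slab limit", {
  lam <- 60
  alpha <- seq(-4, 6, by = 0.5)
  base <- spikeSlabMoments(alpha / sqrt(lam) + 3 / lam, lam, 0.03)
  td <- granuleTopdownTransfer(alpha, lam, 0.03)
  expect_equal(td$first, base$first, tolerance = 1e-12)
  expect_equal(td$second, base$second, tolerance = 1e-12)
  # monotone increasing in pbar at fixed (alpha, lam)
  pb <- seq(0.01, 0.99, by = 0.01)
  f <- granuleTopdownTransfer(rep(1.2, length(pb)), lam, pb)$first
  expect_true(all(diff(f) >= -1e-12))
  # pbar -> 1 approaches the pure-slab posterior mean
  top <- granuleTopdownTransfer(1.2, lam, 1)
  mu <- 1.2 / sqrt(lam) + 3 / lam
  qd <- quadratureMoments(mu, lam, cO = 1)
  expect_equal(top$first, qd$first, tolerance = 1e-4)
})

test_that("non-shape-3 slabs route through quadrature with a warning", {
  expect_warning(m1 <- spikeSlabMoments(0.5, 20, 0.1, gammaShape = 1),
                 "quadrature")
  qd <- quadratureMoments(0.5, 20, 0.1, gammaShape = 1)
  expect_equal(m1$first, qd$first, tolerance = 1e-8)
})

test_that("R and compiled moment implementations agree to 1e-12", {
  al <- seq(-40, 40, by = 0.137)
  for (lam in c(1, 50, 3000)) for (mx in c(0.03, 0.3)) {
    rr <- olfbayes:::.ssMomentsAlpha(al, rep(lam, length(al)),
                                     rep(mx, length(al)))
    cc <- olfbayes:::.cppMoments(al, rep(lam, length(al)),
                                 rep(mx, length(al)))
    for (comp in c("first", "second", "probPresent"))
      expect_lt(max(abs(drop(cc[[comp]]) - rr[[comp]]) /
                      pmax(abs(rr[[comp]]), 1e-300)), 1e-12)
  }
})

test_that("degenerate parameters are rejected", {
  expect_error(spikeSlabMoments(1, -1, 0.03), "lam")
  expect_error(spikeSlabMoments(1, 10, 1.5), "cO")
  expect_error(nonnegTransfer(1, 0), "lam")
})
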