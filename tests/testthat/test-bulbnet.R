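# Bulb network: initialization, steady-state dynamics, adaptive
# plasticity, ablations.

tinyConfig <- function(M = 6, N = 24, cO = 0.25, ...)
  simConfig(M = M, N = N, cO = cO, tMin = 20, TMax = 2000, ...)

test_that("initialization matches the prescribed ensembles", {
  cfg <- simConfig(M = 50, N = 2000, cO = 0.03, ZRho = 0.5, sigmaX = 1)
  st <- initBulb(cfg, seed = 1)
  # log-normal mean: exp(mu_g + sd_g^2/2) = exp(1/2)/(cO M)
  expect_equal(mean(feedforwardWeights(st)),
               exp(0.5) / (0.03 * 50), tolerance = 0.01)
  # precision init: cO/(sigma^2 Z_rho) = 0.06
  expect_equal(precisions(st), rep(0.06, 50))
  # lateral weights are exactly the transpose at initialization
  expect_identical(lateralWeights(st), t(feedforwardWeights(st)))
  expect_equal(trialCount(st), cfg$tMin)
})

test_that("zero weights decouple the M/T equation: steady state m = x", {
  cfg <- tinyConfig()
  st <- initBulb(cfg, seed = 2)
  st@wF[] <- 0; st@wL[] <- 0
  x <- rnorm(cfg$N)
  dyn <- runTrialDynamics(st, x, duration = 4000)
  expect_equal(dyn$m, pmax(x, -cfg$mSp), tolerance = 1e-5)
  # granule rates equal F at the zero-input argument
  lam <- olfbayes:::.bulbLambda(st)
  alpha0 <- (-3 * cfg$sigmaX^2) / (sqrt(lam) * cfg$sigmaX^2)
  f0 <- olfbayes:::.ssMomentsAlpha(alpha0, lam, cfg$cO)$first
  expect_equal(dyn$cbar, f0, tolerance = 1e-5)
})

test_that("steady state satisfies the fixed-point equations and matches
           an independent Picard solver", {
  cfg <- tinyConfig()
  world <- odorWorld(cfg$M, cfg$N, cO = cfg$cO, seed = 3)
  st <- initBulb(cfg, seed = 3)
  set.seed(33)
  # push the state through a few trials so weights are 'learned-ish'
  for (i in 1:5) {
    tr <- sampleTrial(world)
    st <- updatePlasticity(st, runTrialDynamics(st, tr$x))
  }
  tr <- sampleTrial(world)
  dyn <- runTrialDynamics(st, tr$x, duration = 20000)
  # residuals of both fixed-point equations
  resM <- tr$x - dyn$m - drop(st@wL %*% dyn$cbar)
  lam <- olfbayes:::.bulbLambda(st)
  alpha <- (drop(st@wF %*% dyn$m) + rowSums(st@wF^2) * dyn$cbar -
              3 * cfg$sigmaX^2) / (sqrt(lam) * cfg$sigmaX^2)
  f <- olfbayes:::.ssMomentsAlpha(alpha, lam, cfg$cO)$first
  expect_lt(max(abs(resM)), 1e-4)
  expect_lt(max(abs(dyn$cbar - f)), 1e-4)
  # agreement with the damped Picard iteration
  pf <- picardFixedPoint(st, tr$x)
  expect_lt(max(abs(dyn$m - pf$m)), 1e-3)
  expect_lt(max(abs(dyn$cbar - pf$cbar)), 1e-3)
})

test_that("plasticity update equals the primitive closed form to 1e-12", {
  set.seed(4)
  cfg <- tinyConfig()
  for (rep in 1:100) {
    st <- initBulb(cfg)
    st@rho <- runif(cfg$M, 0.05, 2)
    st@t <- sample(20:500, 1)
    m <- rnorm(cfg$N)
    cbar <- rexp(cfg$M, 2)
    G <- rexp(cfg$M, 1)
    dyn <- list(m = m, cbar = cbar, G = G)
    up <- updatePlasticity(st, dyn)
    tNew <- st@t + 1
    rhoNew <- (1 - 1 / tNew) * st@rho + G / (tNew * cfg$sigmaX^2)
    ref <- plasticityClosedForm(st@wF, st@rho, rhoNew, tNew,
                                cfg$sigmaX^2, m, cbar)
    expect_lt(max(abs(up@wF - pmax(ref, 0))), 1e-12)
    expect_equal(up@rho, rhoNew, tolerance = 1e-14)
    expect_equal(up@t, tNew)
  }
})

test_that("silent granule cell receives no Hebbian increment", {
  cfg <- tinyConfig()
  st <- initBulb(cfg, seed = 5)
  m <- rnorm(cfg$N)
  cbar <- rexp(cfg$M); cbar[3] <- 0
  up <- updatePlasticity(st, list(m = m, cbar = cbar, G = rexp(cfg$M)))
  # row 3 changed only by the scalar decay/rescale factor
  ratio <- up@wF[3, ] / st@wF[3, ]
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("feedforward/lateral symmetry is preserved over many trials", {
  cfg <- simConfig(M = 5, N = 15, cO = 0.3, tMin = 20, TMax = 1500)
  world <- odorWorld(5, 15, cO = 0.3, seed = 6)
  st <- initBulb(cfg, seed = 6)
  set.seed(66)
  for (i in 1:1000) {
    tr <- sampleTrial(world)
    st <- updatePlasticity(st, runTrialDynamics(st, tr$x))
  }
  expect_lt(max(abs(st@wF - t(st@wL))), 1e-10)
  expect_equal(trialCount(st), cfg$tMin + 1000)
})

test_that("precision trajectory equals the unrolled running average", {
  cfg <- tinyConfig()
  world <- odorWorld(cfg$M, cfg$N, cO = cfg$cO, seed = 7)
  st <- initBulb(cfg, seed = 7)
  set.seed(77)
  gLog <- list(); rho0 <- st@rho
  for (i in 1:40) {
    dyn <- runTrialDynamics(st, sampleTrial(world)$x)
    gLog[[i]] <- dyn$G
    st <- updatePlasticity(st, dyn)
  }
  # closed-form unrolling: rho_T = (t0/T) rho_0 + (1/T) sum G_i / sigma^2
  t0 <- cfg$tMin; T <- t0 + 40
  ref <- (t0 / T) * rho0 +
    Reduce(`+`, gLog) / (T * cfg$sigmaX^2)
  expect_lt(max(abs(st@rho - ref)), 1e-10)
})

test_that("constant G at its matched precision is a fixed point", {
  cfg <- tinyConfig()
  st <- initBulb(cfg, seed = 8)
  g <- 0.42
  st@rho <- rep(g / cfg$sigmaX^2, cfg$M)
  up <- updatePlasticity(st, list(m = numeric(cfg$N),
                                  cbar = numeric(cfg$M),
                                  G = rep(g, cfg$M)))
  expect_equal(up@rho, st@rho, tolerance = 1e-14)
})

test_that("fixed-learning-rate ablation: eta = 0 freezes the weights", {
  cfg <- tinyConfig(rateMode = "fixed", etaFixed = 0)
  st <- initBulb(cfg, seed = 9)
  up <- fixedRateUpdate(st, list(m = rnorm(cfg$N), cbar = rexp(cfg$M),
                                 G = rexp(cfg$M)), eta = 0)
  expect_identical(up@wF, st@wF)
  expect_identical(up@wL, st@wL)
  # eta = 0 pseudo-precision reduces to the weight term alone
  lam0 <- olfbayes:::.bulbLambda(st)
  expect_equal(lam0, rowSums(st@wF^2) / cfg$sigmaX^2)
})

test_that("fixed-rate pseudo-precision gains the N*eta term", {
  for (eta in c(0.01, 0.1, 1.0)) {    # reference ablation sweep values
    cfg <- tinyConfig(rateMode = "fixed", etaFixed = eta)
    st <- initBulb(cfg, seed = 10)
    expect_equal(olfbayes:::.bulbLambda(st),
                 (rowSums(st@wF^2) + cfg$N * eta) / cfg$sigmaX^2)
  }
})

test_that("fixed-gain ablation pins lambda while plasticity continues", {
  for (lf in c(200, 342)) {           # the two reference settings
    cfg <- tinyConfig(gainMode = "fixed", lambdaFixed = lf)
    st <- initBulb(cfg, seed = 11)
    expect_equal(olfbayes:::.bulbLambda(st), rep(lf, cfg$M))
    dyn <- runTrialDynamics(st, rnorm(cfg$N))
    expect_equal(dyn$lambda, rep(lf, cfg$M))
    # precision still follows the running-average rule
    up <- updatePlasticity(st, dyn)
    tNew <- st@t + 1
    expect_equal(up@rho, (1 - 1 / tNew) * st@rho +
                   dyn$G / (tNew * cfg$sigmaX^2), tolerance = 1e-14)
    # F stays monotone in its input with lambda pinned
    alphas <- seq(-5, 5, by = 0.05)
    f <- olfbayes:::.ssMomentsAlpha(alphas, lf, cfg$cO)$first
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("trial dynamics start from m = 0, cbar = cO", {
  cfg <- tinyConfig()
  st <- initBulb(cfg, seed = 12)
  set.seed(12)
  x <- rnorm(cfg$N)
  dyn <- runTrialDynamics(st, x, duration = cfg$dt)   # exactly one step
  # predict the single Euler step from the prescribed initial condition
  lam <- olfbayes:::.bulbLambda(st)
  alpha0 <- (rowSums(st@wF^2) * cfg$cO - 3 * cfg$sigmaX^2) /
    (sqrt(lam) * cfg$sigmaX^2)
  f0 <- olfbayes:::.ssMomentsAlpha(alpha0, lam, cfg$cO)$first
  r <- cfg$dt / cfg$tauR
  expect_equal(dyn$m,
               pmax(r * (x - drop(st@wL %*% rep(cfg$cO, cfg$M))),
                    -cfg$mSp), tolerance = 1e-12)
  expect_equal(dyn$cbar, pmax(cfg$cO + r * (f0 - cfg$cO), 0),
               tolerance = 1e-12)
})
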