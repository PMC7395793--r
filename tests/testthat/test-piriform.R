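# Piriform readout: variant equivalences, plasticity identities, lateral
# inhibition, top-down coupling.

test_that("weight-copy variant reads out the bulb's own posterior", {
  cfg <- simConfig(M = 8, N = 30, cO = 0.2, tMin = 20)
  st <- initBulb(cfg, seed = 20)
  pir <- initPiriform(cfg, variant = "bayes_copy", seed = 20)
  set.seed(21)
  world <- odorWorld(8, 30, cO = 0.2, seed = 20)
  tr <- sampleTrial(world)
  dyn <- runTrialDynamics(st, tr$x, piriform = pir)
  expect_equal(dyn$pbar, dyn$H, tolerance = 1e-10)
  expect_true(all(dyn$pbar >= 0 & dyn$pbar <= 1))
  # copying keeps the readout state in lockstep with the bulb
  st2 <- updatePlasticity(st, dyn)
  pir2 <- updatePiriformPlasticity(pir, st2, dyn)
  expect_identical(readoutWeights(pir2), feedforwardWeights(st2))
  expect_identical(precisions(pir2), precisions(st2))
})

test_that("piriform rates stay in [0, 1] across variants", {
  cfg <- simConfig(M = 8, N = 30, cO = 0.2, tMin = 20)
  world <- odorWorld(8, 30, cO = 0.2, seed = 22)
  st <- initBulb(cfg, seed = 22)
  for (v in c("local", "local_lateral", "local_lateral_feedback")) {
    pir <- initPiriform(cfg, variant = v, seed = 22)
    set.seed(23)
    tr <- sampleTrial(world)
    dyn <- runTrialDynamics(st, tr$x, piriform = pir)
    expect_true(all(dyn$pbar >= 0 & dyn$pbar <= 1))
  }
})

test_that("stronger lateral inhibition weakly decreases piriform rates", {
  cfg <- simConfig(M = 8, N = 30, cO = 0.2, tMin = 20)
  world <- odorWorld(8, 30, cO = 0.2, seed = 24)
  st <- initBulb(cfg, seed = 24)
  set.seed(25)
  tr <- sampleTrial(world)
  prev <- NULL
  for (k in c(0, 0.5, 1, 2, 3)) {
    pir <- initPiriform(cfg, variant = "local_lateral", kappaJ = k,
                        seed = 24)
    pir@J <- matrix(0.5, 8, 8); diag(pir@J) <- 0   # appreciable inhibition
    dyn <- runTrialDynamics(st, tr$x, piriform = pir)
    if (!is.null(prev)) expect_true(all(dyn$pbar <= prev + 1e-6))
    prev <- dyn$pbar
  }
})

test_that("piriform plasticity matches its primitive closed form", {
  set.seed(26)
  cfg <- simConfig(M = 8, N = 30, cO = 0.2, tMin = 20)
  for (rep in 1:50) {
    st <- initBulb(cfg)
    st@t <- sample(30:300, 1)
    pir <- initPiriform(cfg, variant = "local")
    pir@rhoP <- runif(cfg$M, 0.05, 2)
    dyn <- list(m = rnorm(cfg$N), pbar = runif(cfg$M),
                Fp = rexp(cfg$M, 2), Gp = rexp(cfg$M, 1))
    pir2 <- updatePiriformPlasticity(pir, st, dyn)
    t <- st@t
    rhoNew <- (1 - 1 / t) * pir@rhoP + dyn$Gp / (t * cfg$sigmaX^2)
    ref <- plasticityClosedForm(pir@wP, pir@rhoP, rhoNew, t,
                                cfg$sigmaX^2, dyn$m, dyn$Fp)
    expect_lt(max(abs(pir2@wP - pmax(ref, 0))), 1e-12)
    expect_equal(pir2@rhoP, rhoNew, tolerance = 1e-14)
  }
})

test_that("silent piriform cell only decays", {
  cfg <- simConfig(M = 8, N = 30, cO = 0.2, tMin = 20)
  st <- initBulb(cfg, seed = 27); st@t <- 50
  pir <- initPiriform(cfg, variant = "local", seed = 27)
  dyn <- list(m = rnorm(cfg$N), pbar = runif(cfg$M),
              Fp = rexp(cfg$M), Gp = rexp(cfg$M))
  dyn$Fp[4] <- 0
  pir2 <- updatePiriformPlasticity(pir, st, dyn)
  ratio <- pir2@wP[4, ] / pir@wP[4, ]
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("piriform precision follows the unrolled running average", {
  circ <- pretrainedCircuit()
  cfg <- circ$cfg
  st <- initBulb(cfg, seed = 28)
  pir <- initPiriform(cfg, variant = "local_lateral", seed = 28)
  rho0 <- pir@rhoP; t0 <- st@t
  set.seed(29)
  gpLog <- list()
  for (i in 1:25) {
    tr <- sampleTrial(circ$world)
    dyn <- runTrialDynamics(st, tr$x, piriform = pir)
    gpLog[[i]] <- dyn$Gp
    st <- updatePlasticity(st, dyn)
    pir <- updatePiriformPlasticity(pir, st, dyn)
  }
  T <- t0 + 25
  ref <- (t0 / T) * rho0 + Reduce(`+`, gpLog) / (T * cfg$sigmaX^2)
  expect_lt(max(abs(pir@rhoP - ref)), 1e-10)
})

test_that("lateral-inhibition plasticity: init, fixed point, silence", {
  cfg <- simConfig(M = 6, N = 20, cO = 0.2)
  pir <- initPiriform(cfg, variant = "local_lateral", seed = 30)
  # initialization: 0.02 off-diagonal, zero diagonal
  expect_true(all(pir@J[upper.tri(pir@J)] == 0.02))
  expect_true(all(diag(pir@J) == 0))
  # silent population leaves J unchanged
  expect_identical(updateLateralInhibition(pir@J, numeric(6), 0.2),
                   pir@J)
  # fixed point J[j,k] = pbar_j / (5 cO)
  pbar <- runif(6, 0.1, 0.9)
  Jfix <- outer(pbar, rep(1, 6)) / (5 * 0.2)
  diag(Jfix) <- 0
  J2 <- updateLateralInhibition(Jfix, pbar, 0.2)
  expect_equal(J2, Jfix, tolerance = 1e-12)
  # J stays non-negative with zero diagonal under arbitrary updates
  J3 <- updateLateralInhibition(matrix(0.01, 6, 6) - diag(0.01, 6),
                                runif(6), 0.2)
  expect_true(all(J3 >= 0) && all(diag(J3) == 0))
})

test_that("top-down feedback sharpens responses for believed-present odors", {
  # F^D is increasing in pbar, so feedback raises the granule gain for
  # cells whose piriform partner is active
  lam <- 80
  f_low <- granuleTopdownTransfer(1, lam, 0.05)$first
  f_high <- granuleTopdownTransfer(1, lam, 0.95)$first
  expect_gt(f_high, f_low)
})
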