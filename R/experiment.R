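## Experiment orchestration and plain-text serialization.  Experiments are
## described by validated spec lists (optionally read from YAML), run
## deterministically from a seed, and written to disk as CSV metrics plus
## a JSON manifest.

#' Build and validate an experiment specification
#'
#' @param name identifier used for output files.
#' @param model `"bayes"`, `"sparse_coding"` or `"gonogo"` (unsupervised
#'   pretraining chained with the reward phase).
#' @param M,N,cO world dimensions and sparsity (`cO` defaults to `3/M`).
#' @param nTrials unsupervised training trials.
#' @param nSims number of simulations (seeds `seed`, `seed+1`, ...).
#' @param variant piriform circuit variant (Bayesian models).
#' @param etaW sparse-coding dictionary learning rate(s).
#' @param nRewardTrials,rewardSims go/no-go settings (model `"gonogo"`;
#'   `rewardSims` reward simulations reuse one pretrained circuit).
#' @param seed master seed.
#' @param config optional list of [simConfig()] overrides.
#' @return a validated list of class `"experimentSpec"`.
#' @export
experimentSpec <- function(name, model = c("bayes", "sparse_coding",
                                           "gonogo"),
                           M = 20, N = 100, cO = 3 / M, nTrials = 500,
                           nSims = 1, variant = NULL, etaW = 0.5,
                           nRewardTrials = 20, rewardSims = 50,
                           seed = 1, config = list()) {
  model <- match.arg(model)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .checkScalar(M, "M", 1, Inf); .checkScalar(N, "N", 1, Inf)
  .checkScalar(cO, "cO", 0, 1, strict = TRUE)
  .checkScalar(nTrials, "nTrials", 1, Inf)
  .checkScalar(nSims, "nSims", 1, Inf)
  .checkScalar(seed, "seed", -Inf, Inf)
  if (!is.list(config)) stop("'config' must be a list", call. = FALSE)
  structure(list(name = name, model = model, M = as.integer(M),
                 N = as.integer(N), cO = cO, nTrials = as.integer(nTrials),
                 nSims = as.integer(nSims), variant = variant, etaW = etaW,
                 nRewardTrials = as.integer(nRewardTrials),
                 rewardSims = as.integer(rewardSims),
                 seed = as.integer(seed), config = config),
            class = "experimentSpec")
}

#' Read an experiment specification from a YAML file
#'
#' @param path YAML file whose keys mirror the [experimentSpec()]
#'   arguments.  Note YAML 1.1 reads a bare `N` key as a boolean; quote
#'   it (`"N": 40`) or rely on the repair performed here.
#' @return a validated `"experimentSpec"`.
#' @export
readExperimentSpec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML specs requires the 'yaml' package", call. = FALSE)
  sp <- yaml::read_yaml(path)
  # undo the YAML-1.1 boolean-key convention for the N field
  bad <- names(sp) %in% c("FALSE", "n")
  if (any(bad) && !"N" %in% names(sp)) names(sp)[which(bad)[1]] <- "N"
  do.call(experimentSpec, sp)
}

.specConfig <- function(spec) {
  args <- c(list(M = spec$M, N = spec$N, cO = spec$cO), spec$config)
  do.call(simConfig, args)
}

#' Run an experiment to disk
#'
#' Deterministic given the spec (all randomness derives from its seed).
#' Writes per-simulation metric CSVs and a JSON manifest (spec, package
#' version, wall time) into `outDir`, and returns the collected results
#' invisibly.
#'
#' @param spec an [experimentSpec()].
#' @param outDir output directory, created if missing.
#' @return invisibly, a list of per-simulation results.
#' @export
runExperiment <- function(spec, outDir = tempfile("olfbayes_")) {
  stopifnot(inherits(spec, "experimentSpec"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  cfg <- .specConfig(spec)
  results <- vector("list", spec$nSims)
  rows <- list()
  for (s in seq_len(spec$nSims)) {
    sd <- spec$seed + s - 1L
    world <- odorWorld(spec$M, spec$N, cO = spec$cO,
                       sigmaX = cfg$sigmaX, seed = sd)
    if (spec$model == "sparse_coding") {
      fit <- trainSparseCoding(world, spec$nTrials, etaW = spec$etaW,
                               seed = sd, maxSteps = 8000,
                               stepTol = 1e-9)
      results[[s]] <- fit
      rows[[s]] <- cbind(sim = s, fit$history$dw)
    } else {
      fit <- trainCircuit(world, cfg, spec$nTrials,
                          piriform = spec$variant, seed = sd)
      if (spec$model == "gonogo") {
        gg <- runGoNogo(fit$bulb, fit$piriform, world,
                        nRewardTrials = spec$nRewardTrials,
                        nSims = spec$rewardSims, seed = sd)
        fit$gonogo <- gg
        rows[[s]] <- data.frame(sim = s,
                                trial = seq_along(gg$performance),
                                performance = gg$performance,
                                avgError = gg$avgError)
      } else {
        rows[[s]] <- cbind(sim = s, fit$history$dw)
      }
      results[[s]] <- fit
    }
  }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(outDir, paste0(spec$name, "_metrics.csv")),
            row.names = FALSE)
  manifest <- list(spec = unclass(spec),
                   package = as.character(utils::packageVersion("olfbayes")),
                   wallTimeSec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  jsonlite::write_json(manifest,
                       file.path(outDir, paste0(spec$name,
                                                "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, metrics = metrics, outDir = outDir))
}

#' Generate a deterministic test fixture
#'
#' `"tiny"` builds an M=10, N=40 world with 200 trials; `"small"` an
#' M=20, N=100 world with 1500 trials.  Regenerates bit-identically from
#' its seed; optionally serialized to disk.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed integer seed.
#' @param dir optional directory; when given, the world is written with
#'   [saveCheckpoint()] conventions and the trial stream as CSV.
#' @return list with the `world`, matrices `c` and `x` of the trial
#'   stream, and the `seed`.
#' @export
makeFixture <- function(size = c("tiny", "small"), seed = 1, dir = NULL) {
  size <- match.arg(size)
  dims <- switch(size, tiny = c(10L, 40L, 200L),
                 small = c(20L, 100L, 1500L))
  world <- odorWorld(dims[1], dims[2], seed = seed)
  set.seed(subSeed(seed, "fixture"))
  cMat <- matrix(0, dims[3], dims[1])
  xMat <- matrix(0, dims[3], dims[2])
  for (i in seq_len(dims[3])) {
    tr <- sampleTrial(world, i)
    cMat[i, ] <- tr$c
    xMat[i, ] <- tr$x
  }
  fx <- list(world = world, c = cMat, x = xMat, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(size = size, seed = seed, M = dims[1], N = dims[2],
           nTrials = dims[3], sigmaX = world@sigmaX, cO = world@cO),
      file.path(dir, "fixture_manifest.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(as.data.frame(cMat), file.path(dir, "odors.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(xMat), file.path(dir, "responses.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(world@W), file.path(dir, "mixing.csv"),
              row.names = FALSE)
  }
  fx
}

## matrices serialized as flat vectors + dims; 17 significant digits give
## exact IEEE round-trip
.packMatrix <- function(x) list(dim = dim(x), data = as.vector(x))
.unpackMatrix <- function(p)
  matrix(unlist(p$data), unlist(p$dim)[1], unlist(p$dim)[2])

#' Serialize a trained circuit to a JSON checkpoint
#'
#' Stores the bulb weights, precisions, counter and configuration, plus
#' the piriform state when given, at full double precision in a single
#' plain-text JSON file.
#'
#' @param path output file.
#' @param bulb a [BulbState-class].
#' @param piriform optional [PiriformState-class].
#' @param world optional [OdorWorld-class], stored for reproducibility.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(path, bulb, piriform = NULL, world = NULL) {
  ck <- list(config = unclass(bulb@config),
             wF = .packMatrix(bulb@wF), wL = .packMatrix(bulb@wL),
             rho = bulb@rho, t = bulb@t, m = bulb@m, cbar = bulb@cbar)
  if (!is.null(piriform))
    ck$piriform <- list(wP = .packMatrix(piriform@wP),
                        rhoP = piriform@rhoP,
                        J = .packMatrix(piriform@J),
                        pbar = piriform@pbar, variant = piriform@variant,
                        kappaJ = piriform@kappaJ)
  if (!is.null(world))
    ck$world <- list(W = .packMatrix(world@W), sigmaX = world@sigmaX,
                     cO = world@cO, gammaShape = world@gammaShape)
  jsonlite::write_json(ck, path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Restore a circuit from a JSON checkpoint
#'
#' @param path file written by [saveCheckpoint()].
#' @return list with `bulb`, and `piriform` / `world` when present.
#' @export
loadCheckpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgIn <- ck$config
  if (is.null(cfgIn$lambdaFixed)) cfgIn$lambdaFixed <- NA
  if (is.null(cfgIn$etaFixed)) cfgIn$etaFixed <- NA
  cfg <- simConfig(M = cfgIn$M, N = cfgIn$N, cO = cfgIn$cO,
                   sigmaX = cfgIn$sigmaX, gammaShape = cfgIn$gammaShape,
                   mSp = cfgIn$mSp, tauR = cfgIn$tauR, dt = cfgIn$dt,
                   TMax = cfgIn$TMax, tMin = cfgIn$tMin,
                   ZRho = cfgIn$ZRho, ssTol = cfgIn$ssTol,
                   gainMode = cfgIn$gainMode,
                   lambdaFixed = cfgIn$lambdaFixed,
                   rateMode = cfgIn$rateMode, etaFixed = cfgIn$etaFixed)
  out <- list(bulb = new("BulbState", wF = .unpackMatrix(ck$wF),
                         wL = .unpackMatrix(ck$wL), rho = ck$rho,
                         t = as.numeric(ck$t), m = as.numeric(ck$m),
                         cbar = as.numeric(ck$cbar),
                         config = cfg))
  if (!is.null(ck$piriform))
    out$piriform <- new("PiriformState",
                        wP = .unpackMatrix(ck$piriform$wP),
                        rhoP = ck$piriform$rhoP,
                        J = .unpackMatrix(ck$piriform$J),
                        pbar = ck$piriform$pbar,
                        variant = ck$piriform$variant,
                        kappaJ = ck$piriform$kappaJ)
  if (!is.null(ck$world))
    out$world <- new("OdorWorld", W = .unpackMatrix(ck$world$W),
                     sigmaX = ck$world$sigmaX, cO = ck$world$cO,
                     gammaShape = ck$world$gammaShape,
                     M = ncol(.unpackMatrix(ck$world$W)),
                     N = nrow(.unpackMatrix(ck$world$W)))
  out
}
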