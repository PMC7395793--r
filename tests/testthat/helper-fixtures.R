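# Shared fixtures.  The pretrained circuit is expensive, so it is built
# once per test run and cached in this environment.

.fixtureCache <- new.env(parent = emptyenv())

# A modest trained circuit (variant d) shared by the piriform and reward
# tests: M = 15 odors, N = 60 glomeruli, 400 unsupervised trials.
pretrainedCircuit <- function() {
  if (!is.null(.fixtureCache$circuit)) return(.fixtureCache$circuit)
  world <- odorWorld(15, 60, cO = 0.2, seed = 100)
  cfg <- simConfig(M = 15, N = 60, cO = 0.2)
  fit <- trainCircuit(world, cfg, nTrials = 400,
                      piriform = "local_lateral_feedback", seed = 100)
  .fixtureCache$circuit <- list(world = world, cfg = cfg,
                                bulb = fit$bulb,
                                piriform = fit$piriform,
                                history = fit$history)
  .fixtureCache$circuit
}
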