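# Example experiment specification for runExperiment()/readExperimentSpec().
# Unset parameters fall back to the standard defaults (cO = 3/M,
# sigmaX = 1, tauR = 50 ms, TMax = 5000 ms, tMin = 100, ZRho = 0.5).
name: demo_bayes
model: bayes
M: 10
"N": 40   # quoted: a bare N is YAML shorthand for a boolean
cO: 0.3
nTrials: 50
nSims: 1
seed: 1
config:
  tMin: 20
  TMax: 2000
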