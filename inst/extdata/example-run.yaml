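# Example pipeline configuration for `breedpls all --config ...`
# or readRunConfig(); keys mirror runConfig() / SimulationConfig().
outDir: breedpls-run
simulation:
  nBreeds: 6
  samplesPerBreed: [20, 20, 20, 20, 20, 20]
  nSnps: 3000
  fst: 0.05
  nPlantedPerBreed: 5
  plantedDelta: 0.5
  missingRate: 0.02
  seed: 7
mafThreshold: 0.05
alpha: 0.01
enrichmentAlphas: [0.05, 0.01]
scoreThreshold: 2
flankBp: 10000
nComponents: 1
pMethod: zscore
seed: 7
makePlots: yes
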