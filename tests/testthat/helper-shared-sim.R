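# One simulated genome plus its structural-detector run, shared across test
# files (detection is the expensive step; memoise it).

.sharedEnv <- new.env()

sharedSim <- function() {
  if (is.null(.sharedEnv$sim))
    .sharedEnv$sim <- simulateGenome(simulationConfig(seed = 17L))
  .sharedEnv$sim
}

sharedDetection <- function() {
  if (is.null(.sharedEnv$det)) {
    sim <- sharedSim()
    .sharedEnv$det <- callStructuralElements(sim$genome, trnaSet = sim$trna)
  }
  .sharedEnv$det
}
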