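# Shared fixtures: all built in code, sized for fast test runs.

# A small model configuration that trains in well under a second.
tinyConfig <- function(seed = 1, ...) {
  args <- list(singleHiddenDims = 16, drugEmbeddingDim = 4, bilinearDim = 4,
               combinationHiddenDims = 4, batchSize = 32, learningRate = 5e-3,
               weightDecay = 1e-5, maxEpochs = 30, patience = 30, seed = seed)
  args[names(list(...))] <- list(...)
  args$patience <- min(args$patience, args$maxEpochs)
  do.call(synergyModelConfig, args)
}

# The configuration used for the learning-behaviour tests (bigger capacity).
learnConfig <- function(seed = 1, ...) {
  args <- list(singleHiddenDims = 64, drugEmbeddingDim = 16, bilinearDim = 16,
               combinationHiddenDims = 16, batchSize = 32, learningRate = 3e-3,
               weightDecay = 1e-5, maxEpochs = 100, patience = 15, seed = seed)
  args[names(list(...))] <- list(...)
  args$patience <- min(args$patience, args$maxEpochs)
  do.call(synergyModelConfig, args)
}

# A deterministic toy library with hand-set fingerprints.
toyLibrary <- function(n = 6, bits = 16, seed = 42) {
  fp <- withr::with_seed(seed, matrix(stats::rbinom(n * bits, 1, 0.3), n))
  ids <- paste0("drug", seq_len(n))
  rownames(fp) <- ids
  drugLibrary(ids, fingerprints = fp)
}

# Build a dose-response block from single-agent responses and an excess
# surface: I12 = I1 + I2 - I1*I2 + excess over the nonzero grid.
blockFromCurves <- function(I1, I2, excess = 0, nRep = 1, noiseSd = 0,
                            seed = 1, drugA = "a", drugB = "b") {
  concA <- seq(0, length.out = length(I1) + 1)
  concB <- seq(0, length.out = length(I2) + 1)
  I1 <- c(0, I1); I2 <- c(0, I2)
  surface <- outer(I1, I2, function(x, y) x + y - x * y)
  if (length(excess) == 1) excess <- matrix(excess, length(I1) - 1, length(I2) - 1)
  surface[-1, -1] <- surface[-1, -1] + excess
  surface <- pmin(pmax(surface, 0), 1)
  inh <- array(rep(surface, each = nRep), c(nRep, dim(surface)))
  if (noiseSd > 0) {
    inh <- withr::with_seed(seed, {
      pmin(pmax(inh + array(stats::rnorm(length(inh), 0, noiseSd), dim(inh)), 0), 1)
    })
  }
  doseResponseBlock(drugA, drugB, "CL1", concA, concB, inh)
}

# A small synthetic study with learnable structure, used across modules.
smallStudy <- function(seed = 101, nDrugs = 46, nMechanisms = 10,
                       plantedMechPairs = 2, eta = 5, nReplicates = 1) {
  syntheticStudy(landscapeParams(nDrugs = nDrugs, nMechanisms = nMechanisms,
                                 fpBits = 128, plantedMechPairs = plantedMechPairs,
                                 mechanismSd = 4, backgroundSd = 3, eta = eta,
                                 seed = seed),
                 nReplicates = nReplicates)
}

# Replicate-averaged observed synergy table aligned with the truth rows.
meanObserved <- function(study) {
  obs <- stats::aggregate(synergy ~ drug_a + drug_b, data = study@observed,
                          FUN = mean)
  truth <- study@truth
  obs[match(paste(truth$drug_a, truth$drug_b), paste(obs$drug_a, obs$drug_b)), ]
}
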