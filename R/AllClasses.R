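#' @import methods
NULL

#' Dose-response block for one drug pair on one cell line
#'
#' Holds the replicate-indexed matrix of fractional growth inhibition
#' \eqn{I(c_1, c_2) \in [0, 1]} measured over a dose grid for two drugs, the
#' raw material for Bliss synergy scoring. The zero-dose row/column carries the
#' single-agent responses: \eqn{I(c_1, 0) = I(c_1)}, \eqn{I(0, c_2) = I(c_2)}
#' and \eqn{I(0, 0) = 0} under exact normalization.
#'
#' @slot drugA,drugB drug identifiers.
#' @slot cellLine cell line identifier.
#' @slot concA,concB strictly increasing concentration vectors (uM); the first
#'   entry may be 0, in which case that row/column holds single-agent data.
#' @slot inhibition numeric array of dimension
#'   \code{n_replicates x length(concA) x length(concB)}.
#'
#' @seealso [doseResponseBlock()], [blissExcessMatrix()]
#' @export
setClass("DoseResponseBlock",
  representation(
    drugA = "character", drugB = "character", cellLine = "character",
    concA = "numeric", concB = "numeric", inhibition = "array"
  )
)

setValidity("DoseResponseBlock", function(object) {
  msg <- character()
  d <- dim(object@inhibition)
  if (length(d) != 3) msg <- c(msg, "inhibition must be a 3-d array (replicate x concA x concB)")
  else {
    if (d[2] != length(object@concA) || d[3] != length(object@concB)) {
      msg <- c(msg, "inhibition dimensions do not match concentration vectors")
    }
    if (d[1] < 1) msg <- c(msg, "at least one replicate required")
  }
  if (length(object@concA) < 1 || length(object@concB) < 1) {
    msg <- c(msg, "concentration vectors must be non-empty")
  }
  if (is.unsorted(object@concA, strictly = TRUE)) msg <- c(msg, "concA must be strictly increasing")
  if (is.unsorted(object@concB, strictly = TRUE)) msg <- c(msg, "concB must be strictly increasing")
  ok <- object@inhibition[is.finite(object@inhibition)]
  if (length(ok) && (min(ok) < -1e-8 || max(ok) > 1 + 1e-8)) {
    msg <- c(msg, "inhibition values must lie in [0, 1] (fractional units)")
  }
  if (length(msg)) msg else TRUE
})

#' Replicate-noise estimate for pooled synergy scores
#'
#' @slot etaBar mean per-triplet standard deviation of the pooled synergy
#'   score, on the x100 percentage scale.
#' @slot nTriplets number of replicated (drug, drug, cell line) triplets used.
#' @seealso [estimateReplicateNoise()]
#' @export
setClass("NoiseEstimate",
  representation(etaBar = "numeric", nTriplets = "integer")
)

setValidity("NoiseEstimate", function(object) {
  if (length(object@etaBar) != 1 || object@etaBar < 0) return("etaBar must be a single value >= 0")
  if (object@nTriplets < 1L) return("nTriplets must be >= 1")
  TRUE
})

#' Drug library: identifiers, structures and fingerprints
#'
#' @slot ids unique drug identifiers.
#' @slot smiles SMILES strings (may be NA for synthetic drugs that carry
#'   generator-supplied pseudo-fingerprints).
#' @slot fingerprints 0/1 matrix, one row per drug.
#' @slot mechanism integer latent-mechanism labels (NA for real drugs).
#' @export
setClass("DrugLibrary",
  representation(
    ids = "character", smiles = "character",
    fingerprints = "matrix", mechanism = "integer"
  )
)

setValidity("DrugLibrary", function(object) {
  n <- length(object@ids)
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "drug ids must be unique")
  if (length(object@smiles) != n) msg <- c(msg, "smiles length mismatch")
  if (nrow(object@fingerprints) != n) msg <- c(msg, "fingerprint rows must match ids")
  if (length(object@mechanism) != n) msg <- c(msg, "mechanism length mismatch")
  if (length(object@fingerprints) && !all(object@fingerprints %in% c(0, 1))) {
    msg <- c(msg, "fingerprints must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Drug feature matrix with fingerprint and one-hot blocks
#'
#' Concatenated \code{[fingerprint | one-hot]} layout. Disabled blocks are
#' zero-filled so the total dimension is invariant to which blocks are active.
#'
#' @slot features numeric matrix, drugs in rows (rownames = drug ids).
#' @slot fpBits number of fingerprint columns (leading block).
#' @slot useFingerprint,useOnehot active-block flags.
#' @export
setClass("DrugFeatureMatrix",
  representation(
    features = "matrix", fpBits = "integer",
    useFingerprint = "logical", useOnehot = "logical"
  )
)

setValidity("DrugFeatureMatrix", function(object) {
  if (is.null(rownames(object@features))) return("features must carry drug ids as rownames")
  if (object@fpBits + nrow(object@features) != ncol(object@features)) {
    return("column count must equal fpBits + number of drugs (one-hot block)")
  }
  if (!object@useFingerprint && !object@useOnehot) return("at least one feature block must be active")
  TRUE
})

#' Configuration of the pairwise synergy regression model
#'
#' @slot singleHiddenDims hidden layer widths of the single-drug MLP encoder.
#' @slot drugEmbeddingDim output dimension of the encoder (k_D).
#' @slot bilinearDim number of symmetric bilinear slices (k); by default tied
#'   to the first combination-head hidden width.
#' @slot combinationHiddenDims hidden widths of the combination head MLP.
#' @slot batchSize,learningRate,weightDecay Adam optimisation settings.
#' @slot maxEpochs,patience early-stopping settings (validation MSE monitored).
#' @slot seed integer seed controlling initialization and batch shuffling.
#' @seealso [synergyModelConfig()]
#' @export
setClass("SynergyModelConfig",
  representation(
    singleHiddenDims = "numeric", drugEmbeddingDim = "numeric",
    bilinearDim = "numeric", combinationHiddenDims = "numeric",
    batchSize = "numeric", learningRate = "numeric", weightDecay = "numeric",
    maxEpochs = "numeric", patience = "numeric", seed = "numeric"
  )
)

setValidity("SynergyModelConfig", function(object) {
  msg <- character()
  dims <- c(object@singleHiddenDims, object@drugEmbeddingDim,
            object@bilinearDim, object@combinationHiddenDims)
  if (any(dims < 1)) msg <- c(msg, "all dimensions must be positive")
  if (object@patience > object@maxEpochs) msg <- c(msg, "patience must be <= maxEpochs")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Permutation-invariant pairwise synergy model
#'
#' An MLP encoder maps each drug's feature row to an embedding; a bilinear
#' tensor with symmetric slices combines the two embeddings order-invariantly;
#' a small MLP head maps the combined vector to a scalar synergy prediction.
#' Both MLPs can be conditioned on cell-line features via FiLM (a learned
#' per-layer affine transform of the activations).
#'
#' @slot config the [SynergyModelConfig-class] used to build the model.
#' @slot params nested list of weight matrices (encoder, bilinear slices, head,
#'   FiLM maps).
#' @slot inputDim drug feature dimension l_D.
#' @slot cellDim cell feature dimension l_C (0 when unconditioned).
#' @slot trained logical flag.
#' @export
setClass("SynergyModel",
  representation(
    config = "SynergyModelConfig", params = "list",
    inputDim = "integer", cellDim = "integer", trained = "logical",
    outputCenter = "numeric", outputScale = "numeric"
  )
)

#' Training report
#'
#' @slot epochsRun number of epochs actually run.
#' @slot bestValidationMse best validation MSE reached (weights are restored to
#'   this checkpoint).
#' @slot trainLossTrace per-epoch training loss.
#' @slot valLossTrace per-epoch validation loss.
#' @export
setClass("TrainReport",
  representation(
    epochsRun = "integer", bestValidationMse = "numeric",
    trainLossTrace = "numeric", valLossTrace = "numeric"
  )
)

setValidity("TrainReport", function(object) {
  # NA marks fits under a non-MSE criterion (e.g. the NLL-trained uncertainty
  # head), whose validation trace lives in valLossTrace instead
  if (length(object@bestValidationMse) == 1 && is.finite(object@bestValidationMse) &&
      object@bestValidationMse < 0) return("bestValidationMse must be >= 0")
  TRUE
})

#' Predictive distribution over candidate combinations
#'
#' Per-candidate mean \eqn{\hat\mu} and uncertainty \eqn{\hat\sigma} (standard
#' deviation of the predictive distribution), the input to acquisition.
#'
#' @slot pairs data.frame with columns drug_a, drug_b (and optionally
#'   cell_line).
#' @slot mu,sigma numeric vectors aligned with \code{pairs}.
#' @slot method "ensemble" or "deup".
#' @export
setClass("PredictiveDistribution",
  representation(pairs = "data.frame", mu = "numeric", sigma = "numeric",
                 method = "character")
)

setValidity("PredictiveDistribution", function(object) {
  msg <- character()
  n <- nrow(object@pairs)
  if (length(object@mu) != n || length(object@sigma) != n) msg <- c(msg, "mu/sigma length mismatch")
  if (any(!is.finite(object@mu))) msg <- c(msg, "mu must be finite")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be >= 0")
  if (!object@method %in% c("ensemble", "deup")) msg <- c(msg, "method must be 'ensemble' or 'deup'")
  if (length(msg)) msg else TRUE
})

#' Deep ensemble of synergy models
#'
#' Members are trained on identical data and differ only in their
#' initialization seed; the spread of their predictions estimates uncertainty.
#'
#' @slot members list of [SynergyModel-class] objects.
#' @export
setClass("SynergyEnsemble", representation(members = "list"))

setValidity("SynergyEnsemble", function(object) {
  if (length(object@members) < 1) return("ensemble must have at least one member")
  if (!all(vapply(object@members, is, logical(1), "SynergyModel"))) {
    return("all members must be SynergyModel objects")
  }
  TRUE
})

#' Direct uncertainty predictor (DEUP-style mean/uncertainty pair)
#'
#' @slot meanModel model trained with MSE to predict the expected synergy.
#' @slot uncertaintyModel model trained with a Gaussian negative log-likelihood
#'   against the frozen mean predictor's residuals; its output parameterizes
#'   \eqn{\log\hat\sigma^2}.
#' @slot sigmaFloor lower bound applied to \eqn{\hat\sigma}.
#' @export
setClass("DeupPredictor",
  representation(meanModel = "SynergyModel", uncertaintyModel = "SynergyModel",
                 sigmaFloor = "numeric")
)

#' Acquisition strategy specification
#'
#' @slot strategy one of "brute_force", "greedy", "pure_exploration", "ucb".
#' @slot kappa exploration weight of UCB (default 1).
#' @slot seed seed for brute-force noise and tie-breaking.
#' @seealso [acquisitionSpec()], [acquisitionScores()]
#' @export
setClass("AcquisitionSpec",
  representation(strategy = "character", kappa = "numeric", seed = "numeric")
)

setValidity("AcquisitionSpec", function(object) {
  if (!object@strategy %in% c("brute_force", "greedy", "pure_exploration", "ucb")) {
    return("unknown strategy")
  }
  if (!is.finite(object@kappa)) return("kappa must be finite")
  TRUE
})

#' Batch-selection constraints
#'
#' @slot regime one of "unconstrained", "drug_disjoint", "diversity_first",
#'   "per_drug_cap".
#' @slot batchSize number of candidates per batch.
#' @slot cap per-drug appearance cap for the "per_drug_cap" regime.
#' @slot cumulative when TRUE the cap also counts appearances in earlier
#'   rounds (per-batch counting is the default).
#' @export
setClass("BatchConstraints",
  representation(regime = "character", batchSize = "numeric", cap = "numeric",
                 cumulative = "logical")
)

setValidity("BatchConstraints", function(object) {
  if (!object@regime %in% c("unconstrained", "drug_disjoint", "diversity_first", "per_drug_cap")) {
    return("unknown constraint regime")
  }
  if (object@batchSize < 1) return("batchSize must be >= 1")
  if (object@cap < 1) return("cap must be >= 1")
  TRUE
})

#' Audit trail of a sequential-optimization run
#'
#' @slot rounds list of per-round records (queried candidates, observed
#'   synergies, model metrics, acquisition spec).
#' @slot pool the full candidate pool.
#' @slot seed study seed.
#' @slot configSnapshot model configuration used for retraining.
#' @export
setClass("SMOTrajectory",
  representation(rounds = "list", pool = "data.frame", seed = "numeric",
                 configSnapshot = "SynergyModelConfig")
)

#' Parameters of the synthetic synergy landscape
#'
#' Emulates the statistical structure of large combination screens: a
#' heavy-tailed synergy distribution concentrated near zero, drugs carrying
#' latent mechanisms correlated with their fingerprints, and Gaussian replicate
#' noise of configurable level eta.
#'
#' @slot nDrugs,nMechanisms library size and number of latent mechanisms.
#' @slot fpBits pseudo-fingerprint length.
#' @slot fpDensity expected fraction of set bits in a mechanism's base pattern.
#' @slot bitFlipProb per-bit flip probability applied to each drug's copy of
#'   its mechanism pattern.
#' @slot plantedMechPairs number of mechanism pairs carrying a planted
#'   synergistic effect.
#' @slot effectLocation,effectScale location and scale of the exponential tail
#'   from which planted effect sizes are drawn (x100 synergy scale).
#' @slot mechanismSd standard deviation of the mechanism-pair-level
#'   component of the non-synergistic background (the learnable structure).
#' @slot backgroundSd pair-level jitter around the mechanism-pair component.
#' @slot eta observation noise standard deviation (x100 synergy scale).
#' @slot seed study seed; all randomness flows from it via named substreams.
#' @seealso [landscapeParams()], [syntheticStudy()]
#' @export
setClass("LandscapeParams",
  representation(
    nDrugs = "numeric", nMechanisms = "numeric", fpBits = "numeric",
    fpDensity = "numeric", bitFlipProb = "numeric",
    plantedMechPairs = "numeric", effectLocation = "numeric",
    effectScale = "numeric", mechanismSd = "numeric",
    backgroundSd = "numeric", eta = "numeric",
    seed = "numeric"
  )
)

setValidity("LandscapeParams", function(object) {
  msg <- character()
  if (object@nDrugs < 2) msg <- c(msg, "nDrugs must be >= 2")
  if (object@nMechanisms > object@nDrugs) msg <- c(msg, "nMechanisms must be <= nDrugs")
  if (object@eta < 0) msg <- c(msg, "eta must be >= 0")
  if (object@bitFlipProb < 0 || object@bitFlipProb > 0.5) msg <- c(msg, "bitFlipProb must be in [0, 0.5]")
  nMechPairs <- object@nMechanisms * (object@nMechanisms + 1) / 2
  if (object@plantedMechPairs > nMechPairs) {
    msg <- c(msg, "more planted mechanism pairs than mechanism pairs")
  }
  # expected planted pair fraction under balanced mechanism assignment
  if (object@plantedMechPairs / max(nMechPairs, 1) > 0.10 + 1e-9) {
    msg <- c(msg, "planted synergies would exceed 10% of pairs")
  }
  if (length(msg)) msg else TRUE
})

#' A generated synthetic study
#'
#' @slot library the generated [DrugLibrary-class] with pseudo-fingerprints.
#' @slot truth data.frame of true pair synergies (drug_a, drug_b, synergy,
#'   planted).
#' @slot observed data.frame of noisy observations (adds replicate, observed).
#' @slot params the [LandscapeParams-class] used.
#' @export
setClass("SyntheticStudy",
  representation(library = "DrugLibrary", truth = "data.frame",
                 observed = "data.frame", params = "LandscapeParams")
)
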