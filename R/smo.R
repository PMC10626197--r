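#' Run the sequential-model-optimization loop
#'
#' Simulates (or drives) iterative querying of an expensive synergy oracle.
#' Round 0 seeds the visible set with \code{initSize} uniformly random
#' candidates. Each subsequent round: (1) splits the visible set 80/20 into
#' train/validation, (2) trains a fresh model ensemble from scratch with early
#' stopping (retraining from scratch avoids overfitting to early
#' acquisitions), (3) scores the hidden pool with the acquisition function,
#' (4) selects a batch under the constraints, (5) queries the oracle and moves
#' the batch to the visible set. Terminates after \code{nRounds} or pool
#' exhaustion. With the \code{brute_force} strategy no model is trained
#' (scores are seeded noise).
#'
#' @param pool data.frame of candidate pairs (drug_a, drug_b, optional
#'   cell_line).
#' @param oracle function taking a pairs data.frame and returning observed
#'   synergies (NA marks a failed measurement; failed candidates are recorded
#'   and never retried).
#' @param drugFeatures a [DrugFeatureMatrix-class] covering the pool.
#' @param spec an [AcquisitionSpec-class].
#' @param constraints a [BatchConstraints-class]; its batchSize is the
#'   per-round query budget.
#' @param config a [SynergyModelConfig-class] for the retrained models.
#' @param cellFeatures optional cell feature matrix.
#' @param initSize size of the random initial visible set (default 30).
#' @param nRounds number of acquisition rounds after the initial set.
#' @param uncertaintyMethod "ensemble" (default) or "deup".
#' @param nMembers ensemble size used when retraining each round (in-silico
#'   default 5).
#' @param seed study seed; every random choice derives from it.
#' @return an [SMOTrajectory-class].
#' @export
runSmo <- function(pool, oracle, drugFeatures, spec = acquisitionSpec("ucb"),
                   constraints = batchConstraints("unconstrained"),
                   config = synergyModelConfig(), cellFeatures = NULL,
                   initSize = 30, nRounds = 10,
                   uncertaintyMethod = c("ensemble", "deup"), nMembers = 5,
                   seed = 1) {
  uncertaintyMethod <- match.arg(uncertaintyMethod)
  .assertColumns(pool, c("drug_a", "drug_b"), "candidate pool")
  if (nrow(pool) < initSize) stop("pool smaller than initSize")
  pool$.id <- seq_len(nrow(pool))
  hidden <- pool
  visible <- pool[0, ]
  labels <- numeric(0)
  rounds <- list()
  failed <- integer(0)

  queryOracle <- function(cand) {
    y <- oracle(cand[, setdiff(names(cand), ".id"), drop = FALSE])
    ok <- !is.na(y)
    list(cand = cand[ok, , drop = FALSE], y = y[ok],
         failedIds = cand$.id[!ok])
  }

  # round 0: random initial set
  initIdx <- .withSeed(.substream(seed, "smo_init"),
                       sample.int(nrow(hidden), initSize))
  q <- queryOracle(hidden[initIdx, , drop = FALSE])
  visible <- q$cand
  labels <- q$y
  failed <- c(failed, q$failedIds)
  hidden <- hidden[-initIdx, , drop = FALSE]
  rounds[[1]] <- list(round = 0L,
                      queried = .dropId(q$cand), observed = q$y,
                      strategy = "random_init", valMse = NA_real_,
                      nFailed = length(q$failedIds))

  for (t in seq_len(nRounds)) {
    if (nrow(hidden) == 0) break
    roundSeed <- .substream(seed, paste0("smo_round_", t))
    if (spec@strategy == "brute_force") {
      n <- nrow(hidden)
      scores <- .withSeed(.substream(roundSeed, "brute_force"), stats::runif(n))
      valMse <- NA_real_
    } else {
      trainDf <- .dropId(visible)
      trainDf$synergy <- labels
      if (uncertaintyMethod == "ensemble") {
        ens <- trainEnsemble(trainDf, drugFeatures, config,
                             nMembers = nMembers, baseSeed = roundSeed,
                             cellFeatures = cellFeatures)
        pred <- ensemblePredict(ens, .dropId(hidden), drugFeatures, cellFeatures)
        valMse <- NA_real_
      } else {
        dp <- trainDeupPair(trainDf, drugFeatures, config,
                            cellFeatures = cellFeatures, seed = roundSeed)
        pred <- deupPredict(dp, .dropId(hidden), drugFeatures, cellFeatures)
        valMse <- NA_real_
      }
      scores <- acquisitionScores(pred, spec)
    }
    usedDrugs <- unique(c(visible$drug_a, visible$drug_b))
    histCounts <- table(c(visible$drug_a, visible$drug_b))
    sel <- withCallingHandlers(
      selectBatch(scores, hidden, constraints, seed = roundSeed,
                  usedDrugs = usedDrugs,
                  historyCounts = stats::setNames(as.integer(histCounts),
                                                  names(histCounts))),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(sel$selected) == 0) break
    cand <- hidden[sel$selected, , drop = FALSE]
    q <- queryOracle(cand)
    visible <- rbind(visible, q$cand)
    labels <- c(labels, q$y)
    failed <- c(failed, q$failedIds)
    hidden <- hidden[-sel$selected, , drop = FALSE]
    rounds[[t + 1]] <- list(round = t, queried = .dropId(q$cand),
                            observed = q$y, strategy = spec@strategy,
                            valMse = valMse, nFailed = length(q$failedIds))
  }
  new("SMOTrajectory", rounds = rounds, pool = .dropId(pool), seed = seed,
      configSnapshot = config)
}

.dropId <- function(df) df[, setdiff(names(df), ".id"), drop = FALSE]

#' Fine-tune a set of pretrained models into a recommendation ensemble
#'
#' Each pretrained member's weights are loaded and trained further on the new
#' data only, with early stopping, once per fine-tune seed. With 3 pretrained
#' models and 12 fine-tune seeds this yields the 36-member recommendation
#' ensemble.
#'
#' @param pretrained list of trained [SynergyModel-class] objects.
#' @param newData data.frame (drug_a, drug_b, synergy, optional cell_line) of
#'   newly generated measurements.
#' @inheritParams trainModel
#' @param nFinetuneSeeds number of fine-tuning seeds per pretrained model.
#' @param baseSeed first fine-tune seed.
#' @return a [SynergyEnsemble-class] of size
#'   \code{length(pretrained) * nFinetuneSeeds}.
#' @export
fineTuneEnsemble <- function(pretrained, newData, drugFeatures,
                             config = synergyModelConfig(),
                             cellFeatures = NULL, nFinetuneSeeds = 12,
                             baseSeed = 1) {
  if (length(pretrained) == 0) stop("no pretrained models supplied")
  if (nrow(newData) == 0) stop("empty fine-tuning dataset")
  if (nFinetuneSeeds < 1) stop("nFinetuneSeeds must be >= 1 (empty ensemble forbidden)")
  members <- list()
  for (p in seq_along(pretrained)) {
    for (s in seq_len(nFinetuneSeeds)) {
      ftSeed <- .substream(baseSeed, paste0("finetune_", p, "_", s))
      fit <- trainModel(newData, drugFeatures, config,
                        cellFeatures = cellFeatures, seed = ftSeed,
                        model = pretrained[[p]])
      members[[length(members) + 1]] <- fit$model
    }
  }
  new("SynergyEnsemble", members = members)
}

#' Serialize / restore a trajectory as JSON
#'
#' @param trajectory an [SMOTrajectory-class].
#' @param path JSON file path.
#' @export
writeTrajectoryJson <- function(trajectory, path) {
  obj <- list(
    seed = trajectory@seed,
    rounds = lapply(trajectory@rounds, function(r) {
      list(round = r$round, strategy = r$strategy,
           queried = r$queried, observed = r$observed, nFailed = r$nFailed)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
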