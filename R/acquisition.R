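#' Create an acquisition specification
#'
#' Strategies: \code{brute_force} (seeded uniform noise, i.e. random
#' selection), \code{greedy} (\eqn{\hat\mu}, pure exploitation),
#' \code{pure_exploration} (\eqn{\hat\sigma}), and \code{ucb}
#' (\eqn{\hat\mu + \kappa\hat\sigma}, balancing the two; default
#' \eqn{\kappa = 1}).
#'
#' @param strategy one of "brute_force", "greedy", "pure_exploration", "ucb".
#' @param kappa exploration weight for UCB.
#' @param seed seed for brute-force noise and tie-breaking.
#' @return an [AcquisitionSpec-class].
#' @export
acquisitionSpec <- function(strategy = c("ucb", "greedy", "pure_exploration",
                                         "brute_force"),
                            kappa = 1, seed = 1) {
  strategy <- match.arg(strategy)
  new("AcquisitionSpec", strategy = strategy, kappa = kappa, seed = seed)
}

#' Create batch-selection constraints
#'
#' @param regime "unconstrained", "drug_disjoint" (each drug at most once per
#'   batch), "diversity_first" (prioritise candidates introducing an unused
#'   drug), or "per_drug_cap" (each drug at most \code{cap} times per batch).
#' @param batchSize candidates per batch.
#' @param cap per-drug cap (default 5).
#' @param cumulative count appearances across earlier rounds too (default
#'   FALSE: per-batch counting).
#' @return a [BatchConstraints-class].
#' @export
batchConstraints <- function(regime = c("unconstrained", "drug_disjoint",
                                        "diversity_first", "per_drug_cap"),
                             batchSize = 30, cap = 5, cumulative = FALSE) {
  regime <- match.arg(regime)
  new("BatchConstraints", regime = regime, batchSize = batchSize, cap = cap,
      cumulative = cumulative)
}

#' Score candidates with an acquisition strategy
#'
#' @param pred a [PredictiveDistribution-class].
#' @param spec an [AcquisitionSpec-class].
#' @return numeric score per candidate (higher = acquired earlier).
#' @export
acquisitionScores <- function(pred, spec) {
  n <- length(pred@mu)
  switch(spec@strategy,
    brute_force = .withSeed(.substream(spec@seed, "brute_force"), stats::runif(n)),
    greedy = pred@mu,
    pure_exploration = pred@sigma,
    ucb = pred@mu + spec@kappa * pred@sigma,
    stop("unknown strategy: ", spec@strategy)
  )
}

# Descending-score ranking with seeded random tie-breaking (stable).
.rankCandidates <- function(scores, seed) {
  key <- .withSeed(.substream(seed, "tie_break"), stats::runif(length(scores)))
  order(-scores, key)
}

.selectGreedy <- function(scores, pairs, batchSize, seed, eligible) {
  ranking <- .rankCandidates(scores, seed)
  chosen <- integer(0)
  state <- NULL
  for (i in ranking) {
    ok <- eligible(i, chosen)
    if (isTRUE(ok$keep)) {
      chosen <- c(chosen, i)
      if (length(chosen) == batchSize) break
    }
  }
  warn <- length(chosen) < batchSize
  if (warn) {
    warning("only ", length(chosen), " eligible candidate(s) for a batch of ",
            batchSize, call. = FALSE)
  }
  list(selected = chosen, partial = warn)
}

#' Top-k batch selection (optionally drug-disjoint)
#'
#' Greedy descending-score selection; under \code{drugDisjoint} a candidate
#' is skipped when either of its drugs already appears in the batch. Ties are
#' resolved by a seeded random key, reproducibly.
#'
#' @param scores acquisition scores.
#' @param pairs data.frame with drug_a, drug_b aligned with \code{scores}.
#' @param batchSize number of candidates to select.
#' @param drugDisjoint enforce each drug appearing at most once per batch.
#' @param seed tie-break seed.
#' @return list with \code{selected} (row indices into \code{pairs}, in
#'   selection order) and \code{partial} (TRUE when fewer eligible candidates
#'   than \code{batchSize} were available).
#' @export
selectBatchTopk <- function(scores, pairs, batchSize, drugDisjoint = FALSE,
                            seed = 1) {
  eligible <- function(i, chosen) {
    if (!drugDisjoint) return(list(keep = TRUE))
    used <- c(pairs$drug_a[chosen], pairs$drug_b[chosen])
    list(keep = !(pairs$drug_a[i] %in% used || pairs$drug_b[i] %in% used))
  }
  .selectGreedy(scores, pairs, batchSize, seed, eligible)
}

#' Diversity-first batch selection
#'
#' Walks down the ranking and adds the first candidate involving at least one
#' drug absent from \code{usedDrugs} and from the drugs of the current batch;
#' repeats until the batch is full or the ranking is exhausted. Ensures every
#' single drug is observed quickly.
#'
#' @inheritParams selectBatchTopk
#' @param usedDrugs character vector of drugs already used in earlier rounds.
#' @export
selectBatchDiverse <- function(scores, pairs, usedDrugs = character(0),
                               batchSize = 30, seed = 1) {
  eligible <- function(i, chosen) {
    seen <- c(usedDrugs, pairs$drug_a[chosen], pairs$drug_b[chosen])
    list(keep = !(pairs$drug_a[i] %in% seen) || !(pairs$drug_b[i] %in% seen))
  }
  .selectGreedy(scores, pairs, batchSize, seed, eligible)
}

#' Per-drug-capped batch selection
#'
#' Descending-score selection skipping any candidate that would push either
#' drug's appearance count above \code{cap} (within the batch; optionally
#' counting earlier-round appearances too). Prevents oversampling and
#' depletion of chemical stock. \code{cap = 1} reduces to drug-disjoint
#' selection; \code{cap >= batchSize} to unconstrained top-k.
#'
#' @inheritParams selectBatchTopk
#' @param cap maximum appearances per drug.
#' @param historyCounts optional named integer vector of per-drug appearance
#'   counts from earlier rounds (cumulative mode).
#' @export
selectBatchCapped <- function(scores, pairs, cap = 5, batchSize = 30,
                              seed = 1, historyCounts = NULL) {
  baseCount <- function(d) {
    if (is.null(historyCounts)) 0L
    else if (d %in% names(historyCounts)) historyCounts[[d]]
    else 0L
  }
  eligible <- function(i, chosen) {
    drugs <- c(pairs$drug_a[chosen], pairs$drug_b[chosen])
    a <- pairs$drug_a[i]; b <- pairs$drug_b[i]
    list(keep = (sum(drugs == a) + baseCount(a) < cap) &&
                (sum(drugs == b) + baseCount(b) < cap))
  }
  .selectGreedy(scores, pairs, batchSize, seed, eligible)
}

#' Select a batch under a constraint regime
#'
#' Dispatches to the top-k, diversity-first or per-drug-cap rule according to
#' the constraints object.
#'
#' @inheritParams selectBatchTopk
#' @param constraints a [BatchConstraints-class].
#' @param usedDrugs drugs used in earlier rounds (diversity regime).
#' @param historyCounts per-drug counts from earlier rounds (cumulative cap).
#' @export
selectBatch <- function(scores, pairs, constraints, seed = 1,
                        usedDrugs = character(0), historyCounts = NULL) {
  switch(constraints@regime,
    unconstrained = selectBatchTopk(scores, pairs, constraints@batchSize,
                                    drugDisjoint = FALSE, seed = seed),
    drug_disjoint = selectBatchTopk(scores, pairs, constraints@batchSize,
                                    drugDisjoint = TRUE, seed = seed),
    diversity_first = selectBatchDiverse(scores, pairs, usedDrugs,
                                         constraints@batchSize, seed = seed),
    per_drug_cap = selectBatchCapped(scores, pairs, constraints@cap,
                                     constraints@batchSize, seed = seed,
                                     historyCounts = if (constraints@cumulative)
                                       historyCounts else NULL)
  )
}
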