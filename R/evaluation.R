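#' Construct train/validation/test splits for the generalization tasks
#'
#' Tasks: \code{default} splits combinations uniformly 70/20/10;
#' \code{one_unseen_drug} holds out 30\% of drugs — the test set consists of
#' pairs between a seen and a held-out drug, while seen-seen pairs split 80/20
#' into train/validation; \code{two_unseen_drugs} is the same but the test set
#' consists of pairs of two held-out drugs; \code{shuffled_labels} uses the
#' default split and signals that drug features should be whole-row permuted
#' (see [randomizeFeatures()] at fraction 1) before training.
#'
#' @param records data.frame with columns drug_a, drug_b (plus the response).
#' @param task one of "default", "one_unseen_drug", "two_unseen_drugs",
#'   "shuffled_labels".
#' @param fractions train/validation/test fractions for the default split.
#' @param unseenFraction fraction of drugs held out for the unseen-drug tasks.
#' @param seed split seed.
#' @return list with data.frames \code{train}, \code{validation}, \code{test},
#'   plus \code{heldOutDrugs} (character, possibly empty) and
#'   \code{shuffleFeatures} (logical).
#' @export
makeTaskSplit <- function(records, task = c("default", "one_unseen_drug",
                                            "two_unseen_drugs", "shuffled_labels"),
                          fractions = c(0.70, 0.20, 0.10),
                          unseenFraction = 0.30, seed = 1) {
  task <- match.arg(task)
  if (nrow(records) == 0) stop("records must be non-empty")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (unseenFraction <= 0 || unseenFraction >= 1) {
    stop("unseenFraction must be in (0, 1)")
  }
  n <- nrow(records)
  if (task %in% c("default", "shuffled_labels")) {
    idx <- .withSeed(.substream(seed, "split_default"), sample.int(n))
    nTr <- round(fractions[1] * n)
    nVa <- round(fractions[2] * n)
    out <- list(train = records[idx[seq_len(nTr)], , drop = FALSE],
                validation = records[idx[nTr + seq_len(nVa)], , drop = FALSE],
                test = records[idx[-seq_len(nTr + nVa)], , drop = FALSE],
                heldOutDrugs = character(0),
                shuffleFeatures = task == "shuffled_labels")
  } else {
    drugs <- sort(unique(c(records$drug_a, records$drug_b)))
    nHold <- max(1L, round(unseenFraction * length(drugs)))
    held <- .withSeed(.substream(seed, "split_heldout"),
                      sample(drugs, nHold))
    aHeld <- records$drug_a %in% held
    bHeld <- records$drug_b %in% held
    nUnseen <- aHeld + bHeld
    testMask <- if (task == "one_unseen_drug") nUnseen == 1L else nUnseen == 2L
    seenSeen <- which(nUnseen == 0L)
    idx <- .withSeed(.substream(seed, "split_seen"), sample(seenSeen))
    nTr <- round(0.80 * length(idx))
    out <- list(train = records[idx[seq_len(nTr)], , drop = FALSE],
                validation = records[idx[-seq_len(nTr)], , drop = FALSE],
                test = records[testMask, , drop = FALSE],
                heldOutDrugs = held, shuffleFeatures = FALSE)
  }
  if (nrow(out$test) == 0) {
    stop("task '", task, "' yields an empty test set (n = ", n,
         " records, ", length(unique(c(records$drug_a, records$drug_b))),
         " drugs)")
  }
  out
}

#' Regression metrics with optional uncertainty weighting
#'
#' Reports the coefficient of determination R^2, the Spearman rank
#' correlation (average ranks on ties), and — when per-prediction
#' uncertainties are supplied — the weighted explained variance with weights
#' \eqn{w_i = 1/\sigma_i}:
#' \deqn{EV_w = 1 - Var_w(y - \hat y) / Var_w(y)}
#' where the weighted variances use weighted means.
#'
#' @param y observed values.
#' @param yhat predictions.
#' @param sigma optional per-prediction uncertainties (> 0).
#' @return list with \code{r2}, \code{spearman},
#'   \code{weighted_explained_variance} (NA when sigma absent) and \code{n}.
#' @export
regressionMetrics <- function(y, yhat, sigma = NULL) {
  if (length(y) != length(yhat) || length(y) < 2) {
    stop("y and yhat must have equal length >= 2")
  }
  if (stats::var(y) == 0) {
    warning("zero variance in y: R2 and explained variance undefined")
    return(list(r2 = NA_real_, spearman = NA_real_,
                weighted_explained_variance = NA_real_, n = length(y)))
  }
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  rho <- stats::cor(y, yhat, method = "spearman")
  evw <- NA_real_
  if (!is.null(sigma)) {
    w <- 1 / sigma
    wvar <- function(z) {
      mu <- sum(w * z) / sum(w)
      sum(w * (z - mu)^2) / sum(w)
    }
    evw <- 1 - wvar(y - yhat) / wvar(y)
  }
  list(r2 = r2, spearman = rho, weighted_explained_variance = evw,
       n = length(y))
}

#' Reversed cumulative density
#'
#' For each threshold s, the fraction of values >= s; non-increasing in s and
#' equal to 1 at thresholds at or below the minimum.
#'
#' @param synergies numeric vector (non-empty).
#' @param thresholds numeric vector of thresholds.
#' @return numeric vector of P(S >= s).
#' @export
reversedCdf <- function(synergies, thresholds) {
  if (length(synergies) == 0) stop("synergies must be non-empty")
  vapply(thresholds, function(s) mean(synergies >= s), numeric(1))
}

#' Enrichment of a query strategy over random selection
#'
#' The elementwise ratio of the reversed cumulative densities of the
#' strategy's queried synergies and of a random sample; a ratio of r at
#' threshold s means the strategy found r times as many combinations with
#' synergy >= s. Thresholds where the random density is zero are undefined
#' and returned as NA.
#'
#' @param strategySynergies,randomSynergies numeric samples (non-empty).
#' @param thresholds numeric thresholds.
#' @return numeric enrichment curve (NA marks undefined points).
#' @export
enrichmentRatio <- function(strategySynergies, randomSynergies, thresholds) {
  a <- reversedCdf(strategySynergies, thresholds)
  b <- reversedCdf(randomSynergies, thresholds)
  out <- ifelse(b == 0, NA_real_, a / b)
  out
}

#' Per-round discovery rate of the top synergistic set
#'
#' For a simulation-mode trajectory (true labels known), the cumulative
#' fraction of the top set (e.g. the top 1\% of combinations by true synergy)
#' that has been unblinded by the end of each round. Non-decreasing; reaches
#' 1 iff the whole top set was queried.
#'
#' @param trajectory an [SMOTrajectory-class].
#' @param topSet data.frame with drug_a, drug_b rows defining the top set.
#' @return data.frame with columns round and fraction.
#' @export
discoveryRateCurve <- function(trajectory, topSet) {
  if (nrow(topSet) == 0) stop("empty top set")
  topKeys <- .pairKey(topSet$drug_a, topSet$drug_b)
  found <- character(0)
  out <- data.frame(round = integer(0), fraction = numeric(0))
  for (r in trajectory@rounds) {
    if (nrow(r$queried) > 0) {
      keys <- .pairKey(r$queried$drug_a, r$queried$drug_b)
      found <- union(found, intersect(keys, topKeys))
    }
    out <- rbind(out, data.frame(round = r$round,
                                 fraction = length(found) / length(topKeys)))
  }
  out
}

#' Noise-derived upper bound on regression performance
#'
#' Simulates a perfect regression model that fits noisy observations exactly:
#' for each simulation the true synergies are corrupted with Gaussian noise
#' of standard deviation eta, the corrupted values are taken as predictions,
#' and the chosen metric is evaluated against the true values. The average
#' over simulations bounds the performance achievable by any model trained on
#' observations at that noise level.
#'
#' @param trueSynergies numeric vector of true scores (non-constant).
#' @param eta noise standard deviation (>= 0).
#' @param metric "r2" or "spearman".
#' @param nSims number of Monte-Carlo simulations.
#' @param seed simulation seed.
#' @return the bound estimate (scalar).
#' @export
noiseUpperBound <- function(trueSynergies, eta, metric = c("r2", "spearman"),
                            nSims = 100, seed = 1) {
  metric <- match.arg(metric)
  if (eta < 0) stop("eta must be >= 0")
  if (nSims < 1) stop("nSims must be >= 1")
  if (stats::var(trueSynergies) == 0) {
    stop("degenerate (constant) true synergy distribution")
  }
  if (eta == 0) return(1)
  scoreFun <- if (metric == "r2") {
    function(truth, noisy) 1 - sum((truth - noisy)^2) / sum((truth - mean(truth))^2)
  } else {
    function(truth, noisy) stats::cor(truth, noisy, method = "spearman")
  }
  .withSeed(.substream(seed, "noise_bound"), {
    mean(vapply(seq_len(nSims), function(i) {
      noisy <- trueSynergies + stats::rnorm(length(trueSynergies), sd = eta)
      scoreFun(trueSynergies, noisy)
    }, numeric(1)))
  })
}

#' Read / write combination-level synergy CSV
#'
#' Columns: drug_a, drug_b, cell_line, synergy, study (extra columns pass
#' through). Pairs are canonicalised to sorted order on read.
#'
#' @param path CSV path.
#' @export
readSynergyCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assertColumns(df, c("drug_a", "drug_b", "synergy"), "synergy CSV")
  p <- .canonicalPair(df$drug_a, df$drug_b)
  df$drug_a <- p$a; df$drug_b <- p$b
  df
}

#' @rdname readSynergyCsv
#' @param records synergy data.frame to write.
#' @export
writeSynergyCsv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
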