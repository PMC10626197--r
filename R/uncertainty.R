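#' Train a deep ensemble
#'
#' Trains \code{nMembers} models independently on identical data; members
#' differ only in their initialization/shuffling seed
#' (\code{baseSeed .. baseSeed + nMembers - 1}). The spread of member
#' predictions estimates the predictive uncertainty. The in-silico default
#' ensemble size is 5; recommendation mode uses 36.
#'
#' @inheritParams trainModel
#' @param nMembers ensemble size (>= 1).
#' @param baseSeed first member seed.
#' @return a [SynergyEnsemble-class].
#' @export
trainEnsemble <- function(data, drugFeatures, config = synergyModelConfig(),
                          nMembers = 5, baseSeed = 1, cellFeatures = NULL) {
  if (nMembers < 1) stop("nMembers must be >= 1")
  members <- lapply(seq_len(nMembers), function(i) {
    trainModel(data, drugFeatures, config, cellFeatures = cellFeatures,
               seed = baseSeed + i - 1)$model
  })
  new("SynergyEnsemble", members = members)
}

#' Ensemble predictive distribution
#'
#' mu is the member mean; sigma is the member standard deviation in the
#' population (n) convention — the ensemble is the full predictive sample,
#' not a subsample. A single-member ensemble therefore has sigma identically
#' zero.
#'
#' @param ensemble a [SynergyEnsemble-class].
#' @param pairs data.frame of candidates (drug_a, drug_b, optional cell_line).
#' @inheritParams trainModel
#' @return a [PredictiveDistribution-class].
#' @export
ensemblePredict <- function(ensemble, pairs, drugFeatures, cellFeatures = NULL) {
  if (length(ensemble@members) == 0) stop("empty ensemble")
  preds <- vapply(ensemble@members, function(m) {
    predictSynergy(m, pairs, drugFeatures, cellFeatures)
  }, numeric(nrow(pairs)))
  preds <- matrix(preds, nrow = nrow(pairs))
  mu <- rowMeans(preds)
  sigma <- sqrt(rowMeans(preds^2) - mu^2)
  sigma[!is.finite(sigma) | sigma < 0] <- 0
  new("PredictiveDistribution", pairs = pairs, mu = mu, sigma = sigma,
      method = "ensemble")
}

#' Gaussian negative log-likelihood of an observation
#'
#' \deqn{NLL = \log(\sigma^2)/2 + (y - \mu)^2 / (2\sigma^2)}
#' (the constant \eqn{\log(2\pi)/2} dropped). With sigma fixed at 1 this
#' reduces to half the squared error, i.e. the MSE criterion.
#'
#' @param y observed synergy.
#' @param mu predicted mean.
#' @param sigma predicted standard deviation (> 0).
#' @return the per-observation NLL (vectorised).
#' @export
nllLoss <- function(y, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  log(sigma^2) / 2 + (y - mu)^2 / (2 * sigma^2)
}

#' Train a direct (DEUP-style) mean/uncertainty predictor pair
#'
#' The mean predictor is trained with MSE (found more stable than a joint
#' likelihood fit). The uncertainty predictor — an independent model of the
#' same architecture whose scalar output parameterizes \eqn{\log\hat\sigma^2}
#' — is then trained with the Gaussian negative log-likelihood against the
#' frozen mean predictor's residuals. The produced sigma is strictly
#' positive (floored at \code{sigmaFloor}).
#'
#' @inheritParams trainModel
#' @param sigmaFloor lower bound on the predicted standard deviation.
#' @return a [DeupPredictor-class].
#' @export
trainDeupPair <- function(data, drugFeatures, config = synergyModelConfig(),
                          cellFeatures = NULL, seed = NULL,
                          sigmaFloor = 1e-3) {
  if (nrow(data) == 0) stop("empty dataset")
  if (is.null(seed)) seed <- config@seed
  meanFit <- trainModel(data, drugFeatures, config, cellFeatures = cellFeatures,
                        seed = seed)
  mu <- predictSynergy(meanFit$model, data, drugFeatures, cellFeatures)
  r2 <- (data$synergy - mu)^2
  # uncertainty head: output s = log(sigma^2); NLL = s/2 + r2 * exp(-s) / 2
  nll <- list(
    grad = function(s, r2, n) (0.5 - 0.5 * r2 * exp(-s)) / n,
    value = function(s, r2) mean(0.5 * s + 0.5 * r2 * exp(-s))
  )
  X <- .pairFeatureRows(data, drugFeatures)
  C <- .cellFeatureRows(data, cellFeatures)
  uModel <- initSynergyModel(config, ncol(featureMatrix(drugFeatures)),
                             if (is.null(C)) 0L else ncol(C),
                             seed = .substream(seed, "deup_uncertainty"))
  # start from the marginal residual variance so the log-variance head only
  # has to learn deviations from it
  nb <- length(uModel@params$head$b)
  uModel@params$head$b[[nb]] <- log(mean(r2) + 1e-6)
  uFit <- .fitModel(uModel, X$Xa, X$Xb, C, r2, config, loss = nll,
                    seed = .substream(seed, "deup_uncertainty"))
  new("DeupPredictor", meanModel = meanFit$model,
      uncertaintyModel = uFit$model, sigmaFloor = sigmaFloor)
}

#' @rdname trainDeupPair
#' @param predictor a [DeupPredictor-class].
#' @param pairs data.frame of candidates.
#' @export
deupPredict <- function(predictor, pairs, drugFeatures, cellFeatures = NULL) {
  mu <- predictSynergy(predictor@meanModel, pairs, drugFeatures, cellFeatures)
  s <- predictSynergy(predictor@uncertaintyModel, pairs, drugFeatures, cellFeatures)
  sigma <- pmax(sqrt(exp(s)), predictor@sigmaFloor)
  new("PredictiveDistribution", pairs = pairs, mu = mu, sigma = sigma,
      method = "deup")
}

#' Export a predictive distribution as CSV
#'
#' Columns: drug_a, drug_b, (cell_line,) mu, sigma, method.
#' @param pred a [PredictiveDistribution-class].
#' @param path output CSV path.
#' @export
writePredictiveDistribution <- function(pred, path) {
  df <- cbind(pred@pairs, mu = pred@mu, sigma = pred@sigma,
              method = pred@method)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
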