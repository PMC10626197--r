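#' Create a model configuration
#'
#' Defaults follow the selected values of the architecture search: a single
#' hidden layer of 1024 in the drug encoder, 128-dimensional drug embeddings,
#' 64 bilinear slices (tied to the combination-head width), batch size 128.
#' Learning rate 1e-4 and weight decay 1e-4 are the package's defaults from
#' within the searched grids; both are exposed here.
#'
#' @param singleHiddenDims hidden widths of the single-drug MLP.
#' @param drugEmbeddingDim embedding dimension k_D.
#' @param bilinearDim number of symmetric bilinear slices k.
#' @param combinationHiddenDims hidden widths of the combination head.
#' @param batchSize,learningRate,weightDecay Adam settings.
#' @param maxEpochs,patience early stopping (validation MSE, best-checkpoint
#'   restore).
#' @param seed integer seed for initialization and shuffling.
#' @return a [SynergyModelConfig-class].
#' @export
synergyModelConfig <- function(singleHiddenDims = 1024, drugEmbeddingDim = 128,
                               bilinearDim = 64, combinationHiddenDims = 64,
                               batchSize = 128, learningRate = 1e-4,
                               weightDecay = 1e-4, maxEpochs = 500,
                               patience = 20, seed = 1) {
  new("SynergyModelConfig", singleHiddenDims = singleHiddenDims,
      drugEmbeddingDim = drugEmbeddingDim, bilinearDim = bilinearDim,
      combinationHiddenDims = combinationHiddenDims, batchSize = batchSize,
      learningRate = learningRate, weightDecay = weightDecay,
      maxEpochs = maxEpochs, patience = patience, seed = seed)
}

#' Initialise an untrained synergy model
#'
#' @param config a [SynergyModelConfig-class].
#' @param inputDim drug feature dimension l_D.
#' @param cellDim cell feature dimension l_C (0 for unconditioned models).
#' @param seed overrides \code{config@seed} when given.
#' @return an untrained [SynergyModel-class].
#' @export
initSynergyModel <- function(config, inputDim, cellDim = 0, seed = NULL) {
  if (is.null(seed)) seed <- config@seed
  kD <- config@drugEmbeddingDim
  k <- config@bilinearDim
  params <- .withSeed(.substream(seed, "model_init"), {
    list(
      enc = .mlpInit(c(inputDim, config@singleHiddenDims, kD),
                     lC = cellDim, film = cellDim > 0),
      bil = list(W = lapply(seq_len(k), function(i) {
        matrix(stats::rnorm(kD * kD, sd = 1 / sqrt(kD)), kD, kD)
      })),
      head = .mlpInit(c(k, config@combinationHiddenDims, 1),
                      lC = cellDim, film = cellDim > 0)
    )
  })
  new("SynergyModel", config = config, params = params,
      inputDim = as.integer(inputDim), cellDim = as.integer(cellDim),
      trained = FALSE, outputCenter = 0, outputScale = 1)
}

# Full forward pass over feature matrices; returns prediction and caches.
.modelForward <- function(params, X1, X2, C = NULL) {
  f1 <- .mlpForward(params$enc, X1, C)
  f2 <- .mlpForward(params$enc, X2, C)
  bl <- .bilinearForward(params$bil$W, f1$out, f2$out)
  fh <- .mlpForward(params$head, bl$Z, C)
  list(yhat = as.numeric(fh$out), f1 = f1, f2 = f2, bl = bl, fh = fh)
}

# Backward pass given dL/dyhat (length-n vector); returns grads mirroring params.
.modelBackward <- function(params, fw, dY) {
  bh <- .mlpBackward(params$head, fw$fh$cache, matrix(dY, ncol = 1))
  bb <- .bilinearBackward(params$bil$W, fw$bl$S, fw$f1$out, fw$f2$out, bh$dX)
  b1 <- .mlpBackward(params$enc, fw$f1$cache, bb$dE1)
  b2 <- .mlpBackward(params$enc, fw$f2$cache, bb$dE2)
  encGrads <- b1$grads
  for (nm in names(encGrads)) {
    for (i in seq_along(encGrads[[nm]])) {
      encGrads[[nm]][[i]] <- encGrads[[nm]][[i]] + b2$grads[[nm]][[i]]
    }
  }
  list(enc = encGrads, bil = list(W = bb$gW), head = bh$grads)
}

# Resolve feature rows for drug pairs; errors list the unknown ids.
.pairFeatureRows <- function(pairs, drugFeatures) {
  feats <- featureMatrix(drugFeatures)
  ids <- c(pairs$drug_a, pairs$drug_b)
  unknown <- unique(ids[!ids %in% rownames(feats)])
  if (length(unknown)) {
    stop("unknown drug id(s): ", paste(unknown, collapse = ", "))
  }
  list(Xa = feats[pairs$drug_a, , drop = FALSE],
       Xb = feats[pairs$drug_b, , drop = FALSE])
}

.cellFeatureRows <- function(pairs, cellFeatures) {
  if (is.null(cellFeatures) || is.null(pairs$cell_line)) return(NULL)
  unknown <- unique(pairs$cell_line[!pairs$cell_line %in% rownames(cellFeatures)])
  if (length(unknown)) stop("unknown cell line(s): ", paste(unknown, collapse = ", "))
  cellFeatures[pairs$cell_line, , drop = FALSE]
}

# Core training engine shared by trainModel / fineTune / the DEUP uncertainty
# head. loss = "mse" or list(grad = function(yhat, y, n), value = function(yhat, y)).
.fitModel <- function(model, Xa, Xb, C, y, config, loss = "mse",
                      valFraction = 0.2, seed = NULL) {
  n <- length(y)
  if (n == 0) stop("empty dataset")
  if (is.null(seed)) seed <- config@seed
  if (identical(loss, "mse")) {
    # train against standardized targets so the optimisation is well scaled
    # regardless of the x100 synergy units; the affine transform is stored on
    # the model and inverted at prediction time. A fine-tuned model keeps the
    # transform it was pretrained with so its weights stay aligned.
    if (model@trained) {
      oc <- model@outputCenter; os <- model@outputScale
    } else {
      oc <- mean(y); os <- stats::sd(y)
      if (!is.finite(os) || os == 0) os <- 1
    }
    y <- (y - oc) / os
    lossGrad <- function(yhat, y, n) 2 * (yhat - y) / n
    lossValue <- function(yhat, y) mean((yhat - y)^2)
  } else {
    oc <- 0; os <- 1
    lossGrad <- loss$grad; lossValue <- loss$value
  }
  params <- model@params
  state <- .adamInit(params)
  idx <- .withSeed(.substream(seed, "val_split"), sample.int(n))
  nVal <- max(if (n >= 5) 1L else 0L, floor(valFraction * n))
  valIdx <- idx[seq_len(nVal)]
  trainIdx <- if (nVal > 0) idx[-seq_len(nVal)] else idx
  subRows <- function(M, i) if (is.null(M)) NULL else M[i, , drop = FALSE]
  evalLoss <- function(params, i) {
    fw <- .modelForward(params, subRows(Xa, i), subRows(Xb, i), subRows(C, i))
    lossValue(fw$yhat, y[i])
  }
  best <- list(params = params, val = Inf, epoch = 0L)
  trainTrace <- valTrace <- numeric(0)
  wait <- 0L
  epochsRun <- 0L
  .withSeed(.substream(seed, "train_shuffle"), {
    for (epoch in seq_len(config@maxEpochs)) {
      epochsRun <- epoch
      ord <- sample(trainIdx)
      starts <- seq(1, length(ord), by = config@batchSize)
      epochLoss <- 0
      for (s in starts) {
        bIdx <- ord[s:min(s + config@batchSize - 1, length(ord))]
        fw <- .modelForward(params, subRows(Xa, bIdx), subRows(Xb, bIdx),
                            subRows(C, bIdx))
        lv <- lossValue(fw$yhat, y[bIdx])
        if (!is.finite(lv)) stop("non-finite training loss at epoch ", epoch)
        epochLoss <- epochLoss + lv * length(bIdx)
        grads <- .modelBackward(params, fw, lossGrad(fw$yhat, y[bIdx], length(bIdx)))
        upd <- .adamStep(params, grads, state, config@learningRate,
                         config@weightDecay)
        params <- upd$params; state <- upd$state
      }
      trainTrace <- c(trainTrace, epochLoss / length(ord))
      valLoss <- if (nVal > 0) evalLoss(params, valIdx) else trainTrace[epoch]
      valTrace <- c(valTrace, valLoss)
      if (valLoss < best$val - 1e-12) {
        best <- list(params = params, val = valLoss, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config@patience) break
      }
    }
  })
  model@params <- best$params
  model@trained <- TRUE
  model@outputCenter <- oc
  model@outputScale <- os
  # report validation MSE on the original target scale; custom-criterion fits
  # (which may be negative, e.g. a log-likelihood) report NA here and keep
  # their trace in valLossTrace
  bestVal <- if (identical(loss, "mse")) best$val * os^2 else NA_real_
  report <- new("TrainReport", epochsRun = epochsRun,
                bestValidationMse = bestVal,
                trainLossTrace = trainTrace, valLossTrace = valTrace)
  list(model = model, report = report)
}

#' Train the synergy regression model
#'
#' Minimises mean squared error on an internal 80/20 train/validation split
#' with Adam, stopping when the validation MSE has not improved for
#' \code{patience} epochs and restoring the best-validation weights.
#'
#' @param data data.frame with columns drug_a, drug_b, synergy and optionally
#'   cell_line.
#' @param drugFeatures a [DrugFeatureMatrix-class] covering all drugs in
#'   \code{data}.
#' @param config a [SynergyModelConfig-class].
#' @param cellFeatures optional matrix of cell-line features (rownames = cell
#'   lines); enables FiLM conditioning.
#' @param seed overrides \code{config@seed} (initialization, split, shuffling).
#' @param model optionally, an existing [SynergyModel-class] whose weights are
#'   the starting point (fine-tuning); a fresh model is initialised otherwise.
#' @param valFraction validation fraction of the internal split.
#' @return list with \code{model} ([SynergyModel-class]) and \code{report}
#'   ([TrainReport-class]).
#' @export
trainModel <- function(data, drugFeatures, config = synergyModelConfig(),
                       cellFeatures = NULL, seed = NULL, model = NULL,
                       valFraction = 0.2) {
  if (nrow(data) == 0) stop("empty dataset")
  .assertColumns(data, c("drug_a", "drug_b", "synergy"), "training data")
  X <- .pairFeatureRows(data, drugFeatures)
  C <- .cellFeatureRows(data, cellFeatures)
  cellDim <- if (is.null(C)) 0L else ncol(C)
  if (is.null(model)) {
    model <- initSynergyModel(config, ncol(featureMatrix(drugFeatures)),
                              cellDim, seed = seed)
  }
  .fitModel(model, X$Xa, X$Xb, C, data$synergy, config, loss = "mse",
            valFraction = valFraction, seed = seed)
}

#' Predict synergy for drug pairs
#'
#' Deterministic given the model weights, and invariant to the order of the
#' two drugs in each pair (every bilinear slice is symmetrised at evaluation).
#'
#' @param model a trained [SynergyModel-class].
#' @param pairs data.frame with columns drug_a, drug_b (and cell_line when the
#'   model is conditioned).
#' @inheritParams trainModel
#' @return numeric vector of predicted synergy scores (x100 scale).
#' @export
predictSynergy <- function(model, pairs, drugFeatures, cellFeatures = NULL) {
  if (nrow(pairs) == 0) return(numeric(0))
  X <- .pairFeatureRows(pairs, drugFeatures)
  C <- .cellFeatureRows(pairs, cellFeatures)
  model@outputCenter + model@outputScale *
    .modelForward(model@params, X$Xa, X$Xb, C)$yhat
}

#' Encode a drug feature row into its embedding
#'
#' @param model a [SynergyModel-class].
#' @param x drug feature vector of length l_D.
#' @param cell optional cell feature vector (FiLM conditioning).
#' @return embedding vector of length k_D.
#' @export
encodeDrug <- function(model, x, cell = NULL) {
  if (length(x) != model@inputDim) {
    stop("feature length ", length(x), " does not match model input dim ",
         model@inputDim)
  }
  C <- if (!is.null(cell)) matrix(cell, nrow = 1) else NULL
  as.numeric(.mlpForward(model@params$enc, matrix(x, nrow = 1), C)$out)
}

#' Combine two drug embeddings into a synergy prediction
#'
#' Computes \eqn{z_i = e_1' B_i e_2} for every symmetrised bilinear slice
#' \eqn{B_i = (W_i + W_i')/2} and maps z through the combination head.
#' Swapping \code{e1} and \code{e2} yields an identical prediction.
#'
#' @param model a [SynergyModel-class].
#' @param e1,e2 embedding vectors of length k_D.
#' @param cell optional cell feature vector.
#' @return predicted synergy (scalar, x100 scale).
#' @export
combinePair <- function(model, e1, e2, cell = NULL) {
  kD <- model@config@drugEmbeddingDim
  if (length(e1) != kD || length(e2) != kD) {
    stop("embedding length mismatch: expected ", kD)
  }
  C <- if (!is.null(cell)) matrix(cell, nrow = 1) else NULL
  bl <- .bilinearForward(model@params$bil$W, matrix(e1, nrow = 1),
                         matrix(e2, nrow = 1))
  model@outputCenter + model@outputScale *
    as.numeric(.mlpForward(model@params$head, bl$Z, C)$out)
}

#' Feature-wise linear modulation of hidden activations
#'
#' FiLM applies a learned affine transform \eqn{\gamma \odot h + \beta} to the
#' activations of a layer, after the affine layer and before the nonlinearity;
#' here \eqn{\gamma} and \eqn{\beta} are functions of the cell-line features.
#'
#' @param hidden activation vector.
#' @param gamma,beta scale and shift vectors of the same width.
#' @return modulated activation vector.
#' @export
filmModulate <- function(hidden, gamma, beta) {
  if (length(gamma) != length(hidden) || length(beta) != length(hidden)) {
    stop("FiLM width mismatch: hidden has ", length(hidden), " units")
  }
  gamma * hidden + beta
}

# --- DeepSynergy-style baseline ----------------------------------------------

#' Concatenation MLP baseline
#'
#' A plain feed-forward baseline: the two drug feature rows (and cell features,
#' when given) are concatenated and passed through an MLP with input dropout
#' 0.2 and layer dropout 0.5. Inputs are standardized to mean 0 / sd 1
#' (zero-variance columns are guarded and map to 0) and tanh-normalized. The
#' final prediction averages the predictions on (d1, d2) and (d2, d1), making
#' the baseline order-invariant by construction.
#'
#' @inheritParams trainModel
#' @param hiddenDims hidden layer widths (the reference configuration uses
#'   \code{c(8182, 4096)}; scale down for small studies).
#' @param inputDropout,layerDropout dropout probabilities used in training.
#' @return list with \code{model} (opaque baseline object) and \code{report}.
#' @export
deepSynergyBaseline <- function(data, drugFeatures, config = synergyModelConfig(),
                                cellFeatures = NULL, hiddenDims = c(8182, 4096),
                                inputDropout = 0.2, layerDropout = 0.5,
                                seed = NULL) {
  if (nrow(data) == 0) stop("empty dataset")
  if (is.null(seed)) seed <- config@seed
  X <- .pairFeatureRows(data, drugFeatures)
  C <- .cellFeatureRows(data, cellFeatures)
  buildInput <- function(Xa, Xb, C) cbind(Xa, Xb, C)
  # train on both drug orderings
  Xtr <- rbind(buildInput(X$Xa, X$Xb, C), buildInput(X$Xb, X$Xa, C))
  y <- rep(data$synergy, 2)
  yCenter <- mean(y); yScale <- stats::sd(y)
  if (!is.finite(yScale) || yScale == 0) yScale <- 1
  y <- (y - yCenter) / yScale
  center <- colMeans(Xtr)
  scale <- apply(Xtr, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1  # zero-variance guard
  normalize <- function(M) tanh(sweep(sweep(M, 2, center), 2, scale, `/`))
  Xn <- normalize(Xtr)
  mlp <- .withSeed(.substream(seed, "deepsynergy_init"), {
    .mlpInit(c(ncol(Xn), hiddenDims, 1))
  })
  dropout <- list(input = inputDropout, layer = layerDropout)
  n <- length(y)
  state <- .adamInit(mlp)
  idx <- .withSeed(.substream(seed, "ds_val_split"), sample.int(n))
  nVal <- max(1L, floor(0.2 * n))
  valIdx <- idx[seq_len(nVal)]; trainIdx <- idx[-seq_len(nVal)]
  best <- list(mlp = mlp, val = Inf)
  wait <- 0L; epochsRun <- 0L
  trainTrace <- valTrace <- numeric(0)
  .withSeed(.substream(seed, "ds_train"), {
    for (epoch in seq_len(config@maxEpochs)) {
      epochsRun <- epoch
      ord <- sample(trainIdx)
      starts <- seq(1, length(ord), by = config@batchSize)
      epochLoss <- 0
      for (s in starts) {
        bIdx <- ord[s:min(s + config@batchSize - 1, length(ord))]
        fw <- .mlpForward(mlp, Xn[bIdx, , drop = FALSE], dropout = dropout,
                          training = TRUE)
        resid <- as.numeric(fw$out) - y[bIdx]
        lv <- mean(resid^2)
        if (!is.finite(lv)) stop("non-finite training loss at epoch ", epoch)
        epochLoss <- epochLoss + lv * length(bIdx)
        bk <- .mlpBackward(mlp, fw$cache, matrix(2 * resid / length(bIdx), ncol = 1))
        upd <- .adamStep(mlp, bk$grads, state, config@learningRate, config@weightDecay)
        mlp <- upd$params; state <- upd$state
      }
      trainTrace <- c(trainTrace, epochLoss / length(ord))
      valPred <- as.numeric(.mlpForward(mlp, Xn[valIdx, , drop = FALSE])$out)
      valLoss <- mean((valPred - y[valIdx])^2)
      valTrace <- c(valTrace, valLoss)
      if (valLoss < best$val - 1e-12) {
        best <- list(mlp = mlp, val = valLoss); wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config@patience) break
      }
    }
  })
  model <- structure(list(mlp = best$mlp, center = center, scale = scale,
                          yCenter = yCenter, yScale = yScale),
                     class = "deepSynergyModel")
  report <- new("TrainReport", epochsRun = epochsRun,
                bestValidationMse = best$val * yScale^2,
                trainLossTrace = trainTrace, valLossTrace = valTrace)
  list(model = model, report = report)
}

#' @rdname deepSynergyBaseline
#' @param model a fitted baseline from \code{deepSynergyBaseline}.
#' @param pairs data.frame with drug_a, drug_b (and cell_line when used).
#' @export
predictDeepSynergy <- function(model, pairs, drugFeatures, cellFeatures = NULL) {
  if (nrow(pairs) == 0) return(numeric(0))
  X <- .pairFeatureRows(pairs, drugFeatures)
  C <- .cellFeatureRows(pairs, cellFeatures)
  normalize <- function(M) {
    tanh(sweep(sweep(M, 2, model$center), 2, model$scale, `/`))
  }
  p1 <- as.numeric(.mlpForward(model$mlp, normalize(cbind(X$Xa, X$Xb, C)))$out)
  p2 <- as.numeric(.mlpForward(model$mlp, normalize(cbind(X$Xb, X$Xa, C)))$out)
  model$yCenter + model$yScale * (p1 + p2) / 2
}
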