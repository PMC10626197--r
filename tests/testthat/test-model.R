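test_that("drug encoder produces embeddings of the configured dimension", {
  cfg <- synergyModelConfig()  # reference configuration
  m <- initSynergyModel(cfg, inputDim = 64)
  x <- withr::with_seed(1, stats::runif(64))
  e <- encodeDrug(m, x)
  expect_length(e, 128)
  expect_identical(e, encodeDrug(m, x))  # deterministic
  # zero weights and biases give a zero embedding (ReLU fixes 0)
  m0 <- m
  m0@params$enc <- rapply(m0@params$enc, function(w) w * 0, how = "replace")
  expect_equal(encodeDrug(m0, x), rep(0, 128))
  expect_error(encodeDrug(m, x[1:10]), "input dim")
})

test_that("bilinear combination is symmetric and reduces to hand arithmetic", {
  cfg <- tinyConfig(drugEmbeddingDim = 2, bilinearDim = 1,
                    combinationHiddenDims = 1)
  m <- initSynergyModel(cfg, inputDim = 4)
  # identity slice and identity head: z1 = e1' I e2
  m@params$bil$W[[1]] <- diag(2)
  m@params$head$W[[1]] <- matrix(1); m@params$head$b[[1]] <- 0
  m@params$head$W[[2]] <- matrix(1); m@params$head$b[[2]] <- 0
  expect_equal(combinePair(m, c(1, 2), c(3, 4)), 11)  # 1*3 + 2*4
  # symmetry for arbitrary weights
  m2 <- initSynergyModel(tinyConfig(seed = 5), inputDim = 8)
  e1 <- withr::with_seed(2, stats::rnorm(4))
  e2 <- withr::with_seed(3, stats::rnorm(4))
  expect_equal(combinePair(m2, e1, e2), combinePair(m2, e2, e1),
               tolerance = 1e-6)
  # zero first embedding collapses z to 0 whatever the partner is
  expect_equal(combinePair(m2, rep(0, 4), e1), combinePair(m2, rep(0, 4), e2))
  expect_error(combinePair(m2, e1[1:2], e2), "length mismatch")
})

test_that("FiLM is an elementwise affine transform of the activations", {
  h <- c(3, 4)
  expect_equal(filmModulate(h, gamma = c(1, 1), beta = c(0, 0)), h)
  expect_equal(filmModulate(h, gamma = c(0, 0), beta = c(5, -5)), c(5, -5))
  expect_equal(filmModulate(h, gamma = c(2, 0.5), beta = c(1, -1)), c(7, 1))
  expect_error(filmModulate(h, gamma = c(1, 1, 1), beta = c(0, 0)), "width")
})

test_that("neutral FiLM conditioning agrees exactly with the unconditioned model", {
  lib <- toyLibrary(n = 8, bits = 16)
  feats <- assembleDrugFeatures(lib)
  cells <- diag(2); rownames(cells) <- c("CL1", "CL2")
  cfg <- tinyConfig(seed = 4)
  m <- initSynergyModel(cfg, inputDim = ncol(featureMatrix(feats)), cellDim = 2)
  pairs <- data.frame(drug_a = drugIds(lib)[1:4], drug_b = drugIds(lib)[5:8],
                      cell_line = "CL1")
  # FiLM maps initialise at zero (gamma = 1, beta = 0)
  withCell <- predictSynergy(m, pairs, feats, cellFeatures = cells)
  noCell <- predictSynergy(m, pairs[, 1:2], feats)
  expect_equal(withCell, noCell)
})

test_that("predictions are permutation invariant and batching transparent", {
  lib <- smallStudy(seed = 7, nDrugs = 30)@library
  feats <- assembleDrugFeatures(lib)
  m <- initSynergyModel(tinyConfig(seed = 2), ncol(featureMatrix(feats)))
  ids <- drugIds(lib)
  pairs <- withr::with_seed(11, data.frame(
    drug_a = sample(ids, 1000, replace = TRUE),
    drug_b = sample(ids, 1000, replace = TRUE)))
  fwd <- predictSynergy(m, pairs, feats)
  rev <- predictSynergy(m, pairs[, c("drug_b", "drug_a")] |>
                          stats::setNames(c("drug_a", "drug_b")), feats)
  expect_lt(max(abs(fwd - rev)), 1e-6)
  # batch evaluation equals one-by-one evaluation
  sub <- pairs[1:20, ]
  oneByOne <- vapply(seq_len(20), function(i) {
    predictSynergy(m, sub[i, ], feats)
  }, numeric(1))
  expect_lt(max(abs(predictSynergy(m, sub, feats) - oneByOne)), 1e-6)
  expect_identical(predictSynergy(m, pairs[0, ], feats), numeric(0))
  expect_error(predictSynergy(m, data.frame(drug_a = "nope", drug_b = ids[1]),
                              feats), "nope")
})

test_that("training fits a constant target and respects the epoch budget", {
  lib <- toyLibrary(n = 8, bits = 16)
  feats <- assembleDrugFeatures(lib)
  d <- withr::with_seed(5, data.frame(
    drug_a = sample(drugIds(lib), 60, replace = TRUE),
    drug_b = sample(drugIds(lib), 60, replace = TRUE),
    synergy = 5))
  fit <- trainModel(d, feats, tinyConfig(maxEpochs = 50, patience = 50))
  expect_lt(fit$report@bestValidationMse, 1e-2)
  expect_lte(fit$report@epochsRun, 50)
  expect_error(trainModel(d[0, ], feats, tinyConfig()), "empty")
})

test_that("conflicting duplicate targets bound the achievable MSE from below", {
  lib <- toyLibrary(n = 4, bits = 8)
  feats <- assembleDrugFeatures(lib)
  y <- 10
  d <- data.frame(drug_a = "drug1", drug_b = "drug2",
                  synergy = rep(c(y, -y), 20))
  fit <- trainModel(d, feats, tinyConfig(maxEpochs = 40, patience = 40))
  pred <- predictSynergy(fit$model, d, feats)
  # identical inputs force one prediction p; MSE = y^2 + p^2 >= y^2
  expect_gte(mean((d$synergy - pred)^2), y^2 - 1e-6)
})

test_that("training loss decreases on an easy target at a small learning rate", {
  lib <- toyLibrary(n = 10, bits = 16)
  feats <- assembleDrugFeatures(lib)
  proj <- withr::with_seed(6, stats::rnorm(ncol(featureMatrix(feats))))
  latent <- as.numeric(featureMatrix(feats) %*% proj)
  names(latent) <- drugIds(lib)
  d <- withr::with_seed(7, data.frame(
    drug_a = sample(drugIds(lib), 80, replace = TRUE),
    drug_b = sample(drugIds(lib), 80, replace = TRUE)))
  d$synergy <- latent[d$drug_a] + latent[d$drug_b]
  fit <- trainModel(d, feats,
                    tinyConfig(learningRate = 5e-4, batchSize = 80,
                               maxEpochs = 60, patience = 60),
                    valFraction = 0.1)
  tr <- fit$report@trainLossTrace
  expect_lt(tr[length(tr)], tr[1])
  expect_lt(max(diff(tr)), 0.05 * tr[1])  # no substantial rebound
})

test_that("the trained model beats the mean-only predictor on synthetic data", {
  study <- smallStudy(seed = 31, nReplicates = 3)
  obs <- meanObserved(study)
  recs <- data.frame(drug_a = obs$drug_a, drug_b = obs$drug_b,
                     synergy = obs$synergy, true = study@truth$synergy)
  sp <- makeTaskSplit(recs, "default", seed = 31)
  feats <- assembleDrugFeatures(study@library)
  fit <- trainModel(rbind(sp$train, sp$validation), feats, learnConfig(seed = 31))
  pr <- predictSynergy(fit$model, sp$test, feats)
  expect_gt(regressionMetrics(sp$test$true, pr)$r2, 0)
})

test_that("the concatenation-MLP baseline is order invariant and deterministic", {
  lib <- toyLibrary(n = 8, bits = 12)
  feats <- assembleDrugFeatures(lib)
  d <- withr::with_seed(8, data.frame(
    drug_a = sample(drugIds(lib), 50, replace = TRUE),
    drug_b = sample(drugIds(lib), 50, replace = TRUE),
    synergy = stats::rnorm(50, 0, 5)))
  fit <- deepSynergyBaseline(d, feats, tinyConfig(maxEpochs = 10, patience = 10),
                             hiddenDims = c(16, 8))
  pairs <- data.frame(drug_a = drugIds(lib)[1:3], drug_b = drugIds(lib)[4:6])
  swapped <- stats::setNames(pairs[, 2:1], c("drug_a", "drug_b"))
  p1 <- predictDeepSynergy(fit$model, pairs, feats)
  expect_identical(p1, predictDeepSynergy(fit$model, swapped, feats))
  # dropout is disabled at evaluation: repeated predictions identical
  expect_identical(p1, predictDeepSynergy(fit$model, pairs, feats))
})

test_that("zero-variance feature columns survive baseline standardization", {
  lib <- toyLibrary(n = 6, bits = 8)
  fp <- fingerprints(lib)
  fp[, 1] <- 1  # constant column
  lib2 <- drugLibrary(drugIds(lib), fingerprints = fp)
  feats <- assembleDrugFeatures(lib2, useOnehot = FALSE)
  d <- withr::with_seed(9, data.frame(
    drug_a = sample(drugIds(lib2), 30, replace = TRUE),
    drug_b = sample(drugIds(lib2), 30, replace = TRUE),
    synergy = stats::rnorm(30)))
  fit <- deepSynergyBaseline(d, feats, tinyConfig(maxEpochs = 5, patience = 5),
                             hiddenDims = c(8))
  p <- predictDeepSynergy(fit$model, d[1:5, ], feats)
  expect_true(all(is.finite(p)))
})
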