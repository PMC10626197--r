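mkRecords <- function(nDrugs = 20, seed = 1) {
  ids <- sprintf("r%02d", seq_len(nDrugs))
  idx <- which(upper.tri(matrix(0, nDrugs, nDrugs)), arr.ind = TRUE)
  withr::with_seed(seed, data.frame(
    drug_a = ids[idx[, 1]], drug_b = ids[idx[, 2]],
    synergy = stats::rnorm(nrow(idx), 0, 10)))
}

test_that("the default split gives exact 70/20/10 sizes and partitions records", {
  recs <- mkRecords()[1:100, ]
  sp <- makeTaskSplit(recs, "default", seed = 4)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$validation), 20)
  expect_equal(nrow(sp$test), 10)
  key <- function(df) paste(df$drug_a, df$drug_b)
  all3 <- c(key(sp$train), key(sp$validation), key(sp$test))
  expect_setequal(all3, key(recs))
  expect_false(anyDuplicated(all3) > 0)
  # seed-reproducible
  sp2 <- makeTaskSplit(recs, "default", seed = 4)
  expect_identical(sp, sp2)
})

test_that("unseen-drug splits hold out drugs as defined", {
  recs <- mkRecords(nDrugs = 25, seed = 2)
  one <- makeTaskSplit(recs, "one_unseen_drug", seed = 3)
  held <- one$heldOutDrugs
  expect_equal(length(held), round(0.3 * 25))
  trainDrugs <- unique(c(one$train$drug_a, one$train$drug_b,
                         one$validation$drug_a, one$validation$drug_b))
  expect_length(intersect(trainDrugs, held), 0)
  # every test pair has exactly one held-out drug
  nHeld <- (one$test$drug_a %in% held) + (one$test$drug_b %in% held)
  expect_true(all(nHeld == 1))
  # seen-seen pairs split 80/20
  nSeen <- nrow(one$train) + nrow(one$validation)
  expect_equal(nrow(one$train) / nSeen, 0.8, tolerance = 0.02)

  two <- makeTaskSplit(recs, "two_unseen_drugs", seed = 3)
  nHeld2 <- (two$test$drug_a %in% two$heldOutDrugs) +
    (two$test$drug_b %in% two$heldOutDrugs)
  expect_true(all(nHeld2 == 2))
  testDrugs <- unique(c(two$test$drug_a, two$test$drug_b))
  trainDrugs2 <- unique(c(two$train$drug_a, two$train$drug_b,
                          two$validation$drug_a, two$validation$drug_b))
  expect_length(intersect(testDrugs, trainDrugs2), 0)
  # shuffled-labels task flags the feature permutation
  expect_true(makeTaskSplit(recs, "shuffled_labels", seed = 1)$shuffleFeatures)
  expect_error(makeTaskSplit(recs[0, ], "one_unseen_drug", seed = 1), "non-empty")
})

test_that("regression metrics behave on perfect, null and reversed predictors", {
  y <- withr::with_seed(5, stats::rnorm(50))
  m <- regressionMetrics(y, y, sigma = rep(2, 50))
  expect_equal(m$r2, 1)
  expect_equal(m$spearman, 1)
  expect_equal(m$weighted_explained_variance, 1)
  m0 <- suppressWarnings(regressionMetrics(y, rep(mean(y), 50)))
  expect_equal(m0$r2, 0)
  expect_equal(regressionMetrics(y - mean(y), -(y - mean(y)))$spearman, -1)
  expect_warning(mz <- regressionMetrics(rep(1, 10), y[1:10]), "zero variance")
  expect_true(is.na(mz$r2))
  expect_error(regressionMetrics(y, y[1:10]), "equal length")
  # weighted EV down-weights badly predicted high-uncertainty points
  yhat <- y; yhat[1] <- y[1] + 10
  sig <- rep(1, 50); sig[1] <- 100
  unw <- regressionMetrics(y, yhat, sigma = rep(1, 50))
  wtd <- regressionMetrics(y, yhat, sigma = sig)
  expect_gt(wtd$weighted_explained_variance,
            unw$weighted_explained_variance)
})

test_that("reversed CDF and enrichment follow their counting definitions", {
  v <- c(0, 10, 20)
  expect_equal(reversedCdf(v, 10), 2 / 3)
  expect_equal(reversedCdf(v, -5), 1)
  expect_equal(reversedCdf(v, 21), 0)
  th <- seq(-5, 25, by = 5)
  expect_true(all(diff(reversedCdf(v, th)) <= 0))
  expect_error(reversedCdf(numeric(0), 1), "non-empty")
  # self-enrichment is identically 1
  expect_equal(enrichmentRatio(v, v, th[th <= 20]), rep(1, sum(th <= 20)))
  # strategy all above s*, random half above -> ratio 2
  expect_equal(enrichmentRatio(c(10, 12), c(5, 15), 8), 2)
  # random density zero -> undefined point
  expect_true(is.na(enrichmentRatio(c(10), c(1), 5)))
})

test_that("discovery curves are monotone and match the hypergeometric rate", {
  s <- local({
    nDrugs <- 15
    ids <- sprintf("d%02d", seq_len(nDrugs))
    idx <- which(upper.tri(matrix(0, nDrugs, nDrugs)), arr.ind = TRUE)
    pool <- data.frame(drug_a = ids[idx[, 1]], drug_b = ids[idx[, 2]])
    truth <- withr::with_seed(3, stats::rnorm(nrow(pool)))
    lib <- toyLibrary(n = nDrugs, bits = 8, seed = 3)
    f <- featureMatrix(assembleDrugFeatures(lib)); rownames(f) <- ids
    feats <- new("DrugFeatureMatrix", features = f, fpBits = 8L,
                 useFingerprint = TRUE, useOnehot = TRUE)
    lookup <- stats::setNames(truth, paste(pool$drug_a, pool$drug_b))
    list(pool = pool, truth = truth, feats = feats,
         oracle = function(p) lookup[paste(p$drug_a, p$drug_b)])
  })
  top <- s$pool[order(-s$truth)[1:10], ]
  # a trajectory querying the whole pool ends at fraction 1, monotonically
  trAll <- runSmo(s$pool, s$oracle, s$feats, acquisitionSpec("brute_force"),
                  batchConstraints(batchSize = 50), tinyConfig(),
                  initSize = 30, nRounds = 10, seed = 2)
  curve <- discoveryRateCurve(trAll, top)
  expect_true(all(diff(curve$fraction) >= 0))
  expect_equal(curve$fraction[nrow(curve)], 1)
  expect_error(discoveryRateCurve(trAll, top[0, ]), "empty")
  # round-0 expectation: init of 30 from 105 pairs finds 30/105 of the top set
  f0 <- vapply(1:150, function(seed) {
    tr <- runSmo(s$pool, s$oracle, s$feats, acquisitionSpec("brute_force"),
                 batchConstraints(batchSize = 5), tinyConfig(),
                 initSize = 30, nRounds = 0, seed = seed)
    discoveryRateCurve(tr, top)$fraction[1]
  }, numeric(1))
  expect_equal(mean(f0), 30 / nrow(s$pool), tolerance = 0.15)
})

test_that("the noise-derived bound is exact at zero noise and decays with eta", {
  y <- withr::with_seed(6, stats::rnorm(200, 0, 10))
  expect_identical(noiseUpperBound(y, 0, "r2"), 1)
  expect_identical(noiseUpperBound(y, 0, "spearman"), 1)
  etas <- c(2, 5, 10, 20)
  bounds <- vapply(etas, function(e) noiseUpperBound(y, e, "r2", 100, seed = 8),
                   numeric(1))
  expect_true(all(diff(bounds) < 0.02))  # non-increasing within MC error
  boundsS <- vapply(etas, function(e) {
    noiseUpperBound(y, e, "spearman", 100, seed = 8)
  }, numeric(1))
  expect_true(all(diff(boundsS) < 0.02))
  # pure-noise limit: Spearman bound collapses to 0
  expect_lt(abs(noiseUpperBound(y, 1e6, "spearman", 100, seed = 9)), 0.05)
  expect_error(noiseUpperBound(rep(1, 10), 1), "degenerate")
})

test_that("synergy CSV round trip canonicalises pair order", {
  recs <- data.frame(drug_a = c("z", "a"), drug_b = c("a", "b"),
                     cell_line = "CL1", synergy = c(10, 20), study = "s1")
  path <- withr::local_tempfile(fileext = ".csv")
  writeSynergyCsv(recs, path)
  back <- readSynergyCsv(path)
  expect_equal(back$drug_a, c("a", "a"))
  expect_equal(back$drug_b, c("z", "b"))
  expect_equal(back$synergy, c(10, 20))
})
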