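test_that("Bliss excess matches direct evaluation of the independence formula", {
  mk <- function(I1, I2, I12) {
    doseResponseBlock("a", "b", "CL1", c(0, 1), c(0, 1),
                      matrix(c(0, I1, I2, I12), 2, 2))
  }
  # exact independence: V12 = V1 * V2
  expect_equal(as.numeric(blissExcessMatrix(mk(0.5, 0.5, 0.75))), 0)
  # direct arithmetic: 0.8 - 0.2 - 0.3 + 0.06 = 0.36 -> 36 on the x100 scale
  expect_equal(as.numeric(blissExcessMatrix(mk(0.2, 0.3, 0.8))), 36)
  # one agent already fully inhibits
  expect_equal(as.numeric(blissExcessMatrix(mk(1, 0, 1))), 0)
})

test_that("Bliss excess is zero on any exact independence surface", {
  for (s in 1:20) {
    I1 <- withr::with_seed(s, sort(stats::runif(4, 0, 0.9)))
    I2 <- withr::with_seed(s + 100, sort(stats::runif(5, 0, 0.9)))
    b <- blockFromCurves(I1, I2, excess = 0)
    expect_lt(max(abs(blissExcessMatrix(b))), 1e-9)
  }
})

test_that("replicate aggregation modes are both available and agree when noiseless", {
  b <- blockFromCurves(c(0.2, 0.5), c(0.1, 0.6), excess = 0.1, nRep = 3)
  before <- blissExcessMatrix(b, "before")
  after <- blissExcessMatrix(b, "after")
  expect_equal(before, after)
  # with heterogeneous replicates, 'after' equals the mean of per-replicate scores
  b2 <- blockFromCurves(c(0.2, 0.5), c(0.1, 0.6), excess = 0.1, nRep = 3,
                        noiseSd = 0.05, seed = 9)
  perRep <- lapply(1:3, function(r) {
    blissExcessMatrix(doseResponseBlock("a", "b", "CL1", b2@concA, b2@concB,
                                        b2@inhibition[r, , , drop = FALSE]))
  })
  expect_equal(blissExcessMatrix(b2, "after"), Reduce(`+`, perRep) / 3)
})

test_that("missing single-agent margins and NA cells raise informative errors", {
  noZero <- doseResponseBlock("a", "b", "CL1", c(1, 2), c(1, 2),
                              matrix(0.5, 2, 2))
  expect_error(blissExcessMatrix(noZero), "single-agent")
  inh <- matrix(c(0, 0.2, 0.3, NA), 2, 2)
  bad <- doseResponseBlock("a", "b", "CL1", c(0, 1), c(0, 1), inh)
  expect_error(blissExcessMatrix(bad), "NaN/NA")
})

test_that("pooling returns max or mean over nonzero-dose cells", {
  expect_equal(poolSynergy(matrix(0, 5, 5), "max"), 0)
  m <- matrix(c(0, 36, -10), 1)
  expect_equal(poolSynergy(m, "max"), 36)
  expect_equal(poolSynergy(m, "mean"), 26 / 3)
  expect_error(poolSynergy(matrix(numeric(0), 0, 0)), "empty")
  # max pooling never falls below mean pooling
  for (s in 1:10) {
    m <- withr::with_seed(s, matrix(stats::rnorm(12), 3))
    expect_gte(poolSynergy(m, "max"), poolSynergy(m, "mean"))
  }
})

test_that("plate normalization anchors DMSO at inhibition 0 and DOX at 1", {
  conc <- c(0, 1, 3)
  raw <- matrix(80, 3, 3)  # equal to the DMSO control everywhere
  b <- normalizeViabilityPlate(raw, doxWells = 5, dmsoWells = 80,
                               "a", "b", "CL1", conc, conc)
  expect_true(all(b@inhibition == 0))
  rawDox <- matrix(5, 3, 3)  # at the DOX anchor everywhere
  b2 <- normalizeViabilityPlate(rawDox, 5, 80, "a", "b", "CL1", conc, conc)
  expect_true(all(b2@inhibition == 1))
  rawBelow <- matrix(-10, 3, 3)  # below the total-kill anchor -> capped
  b3 <- normalizeViabilityPlate(rawBelow, 5, 80, "a", "b", "CL1", conc, conc)
  expect_true(all(b3@inhibition == 1))
  expect_error(normalizeViabilityPlate(raw, numeric(0), 80, "a", "b", "CL1",
                                       conc, conc), "DOX")
  expect_error(normalizeViabilityPlate(raw, 5, NULL, "a", "b", "CL1",
                                       conc, conc), "DMSO")
})

test_that("plate normalization is idempotent on already-normalized data", {
  conc <- c(0, 1, 3, 9)
  raw <- withr::with_seed(3, matrix(stats::runif(16, 10, 90), 4))
  raw[1, 1] <- 90
  b1 <- normalizeViabilityPlate(raw, doxWells = 10, dmsoWells = 90,
                                "a", "b", "CL1", conc, conc)
  # re-express as viability on the normalized 0-100 scale and normalize again
  v <- 100 * (1 - b1@inhibition[1, , ])
  b2 <- normalizeViabilityPlate(v, doxWells = 0, dmsoWells = 100,
                                "a", "b", "CL1", conc, conc)
  expect_equal(b2@inhibition, b1@inhibition)
  expect_true(all(b1@inhibition >= 0 & b1@inhibition <= 1))
})

test_that("QC filters reject flat, small and extreme blocks and are idempotent", {
  flat <- doseResponseBlock("a", "b", "CL1", c(0, 1, 2, 3), c(0, 1, 2, 3),
                            matrix(0.5, 4, 4))
  small <- doseResponseBlock("c", "d", "CL1", c(0, 1), c(0, 1),
                             matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2))
  good <- doseResponseBlock("e", "f", "CL1", c(0, 1, 2, 3), c(0, 1, 2, 3),
                            matrix(rep(c(0.3, 0.7), 8), 4, 4))
  hot <- matrix(1, 4, 4); hot[1, 1:4] <- 0.84  # mean 0.96, sd > 0.05
  extreme <- doseResponseBlock("g", "h", "CL1", c(0, 1, 2, 3), c(0, 1, 2, 3), hot)
  res <- qcFilterBlocks(list(flat, small, good, extreme))
  expect_length(res$retained, 1)
  expect_identical(res$retained[[1]]@drugA, "e")
  expect_equal(unname(res$report),
               c(1L, 1L, 1L))  # one rejection per rule a/b/c
  # idempotent: re-filtering the retained set rejects nothing
  res2 <- qcFilterBlocks(res$retained)
  expect_length(res2$retained, 1)
  expect_equal(sum(res2$report), 0L)
  # empty input
  empty <- qcFilterBlocks(list())
  expect_length(empty$retained, 0)
})

test_that("replicate-noise estimation averages per-triplet sample deviations", {
  recs <- data.frame(
    drug_a = c("a", "a", "b", "b"),
    drug_b = c("x", "x", "y", "y"),
    cell_line = "CL1",
    synergy = c(10, 10, 0, 2))
  est1 <- estimateReplicateNoise(recs[1:2, ])
  expect_equal(noiseLevel(est1), 0)
  est2 <- estimateReplicateNoise(recs[3:4, ])
  expect_equal(noiseLevel(est2), sqrt(2))  # sample (n-1) convention
  est <- estimateReplicateNoise(recs)
  expect_equal(noiseLevel(est), mean(c(0, sqrt(2))))
  expect_equal(est@nTriplets, 2L)
  # mean of per-triplet sds 1 and 3 is 2
  recs2 <- data.frame(
    drug_a = "a", drug_b = c("x", "x", "y", "y"), cell_line = "CL1",
    synergy = c(0, sqrt(2) * 1, 0, sqrt(2) * 3))
  expect_equal(noiseLevel(estimateReplicateNoise(recs2)), 2)
  expect_error(estimateReplicateNoise(recs[c(1, 3), ]), "replicated")
})

test_that("long-format CSV round-trips dose-response blocks", {
  b <- blockFromCurves(c(0.2, 0.5, 0.8), c(0.1, 0.4), excess = 0.05, nRep = 2,
                       noiseSd = 0.02, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDoseResponseCsv(list(b), path)
  back <- readDoseResponseCsv(path)
  expect_length(back, 1)
  expect_equal(back[[1]]@inhibition, b@inhibition, tolerance = 1e-12)
  expect_equal(back[[1]]@concA, b@concA)
  expect_equal(poolSynergy(blissExcessMatrix(back[[1]])),
               poolSynergy(blissExcessMatrix(b)))
})
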