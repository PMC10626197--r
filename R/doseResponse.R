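#' Construct a dose-response block
#'
#' @param drugA,drugB drug identifiers.
#' @param cellLine cell line identifier.
#' @param concA,concB strictly increasing concentration vectors (uM); include
#'   0 as the first entry when the block carries its single-agent row/column.
#' @param inhibition fractional growth inhibition in \[0, 1\]: either a matrix
#'   of dimension \code{length(concA) x length(concB)} (single replicate) or a
#'   3-d array \code{n_rep x length(concA) x length(concB)}.
#' @return a [DoseResponseBlock-class].
#' @examples
#' b <- doseResponseBlock("a", "b", "MCF7", c(0, 1), c(0, 1),
#'                        matrix(c(0, .2, .3, .8), 2, 2))
#' blissExcessMatrix(b)
#' @export
doseResponseBlock <- function(drugA, drugB, cellLine, concA, concB, inhibition) {
  if (is.matrix(inhibition)) {
    inhibition <- array(inhibition, dim = c(1L, dim(inhibition)))
  }
  new("DoseResponseBlock", drugA = as.character(drugA), drugB = as.character(drugB),
      cellLine = as.character(cellLine), concA = as.numeric(concA),
      concB = as.numeric(concB), inhibition = inhibition)
}

# Average replicates on the inhibition scale -> single matrix.
.meanInhibition <- function(block) {
  apply(block@inhibition, c(2, 3), mean)
}

.blissExcess <- function(I12, I1, I2) {
  # s(c1,c2) = I12 - I1 - I2 + I1*I2, fractional units
  sweep(sweep(I12, 1, I1, `-`), 2, I2, `-`) + outer(I1, I2)
}

#' Elementwise Bliss excess over the nonzero-dose grid
#'
#' Under the Bliss independence null, the combined viability equals the
#' product of the single-agent viabilities; the excess
#' \deqn{s(c_1,c_2) = I(c_1,c_2) - I(c_1) - I(c_2) + I(c_1) I(c_2)}
#' measures the departure from it. The single-agent responses \eqn{I(c_1)},
#' \eqn{I(c_2)} are read from the zero-dose column/row of the block.
#' Arithmetic is carried out in fractional units and the result reported on
#' the x100 percentage scale. Zero-dose rows/columns are excluded from the
#' output (the excess there is 0 by construction under exact normalization).
#'
#' @param block a [DoseResponseBlock-class] whose first concentration of each
#'   drug is 0 (the single-agent margins).
#' @param aggregateReplicates \code{"before"} (default) averages replicate
#'   inhibition before computing the excess; \code{"after"} scores each
#'   replicate separately and averages the resulting excess matrices.
#' @return numeric matrix of Bliss excess scores (x100), one row per nonzero
#'   concentration of drug A and one column per nonzero concentration of
#'   drug B.
#' @export
blissExcessMatrix <- function(block, aggregateReplicates = c("before", "after")) {
  aggregateReplicates <- match.arg(aggregateReplicates)
  stopifnot(is(block, "DoseResponseBlock"))
  if (anyNA(block@inhibition)) {
    idx <- which(is.na(block@inhibition), arr.ind = TRUE)
    stop("NaN/NA inhibition at (replicate, row, col): ",
         paste(apply(idx, 1, paste, collapse = ","), collapse = "; "))
  }
  zA <- which(block@concA == 0)
  zB <- which(block@concB == 0)
  if (length(zA) != 1) {
    stop("missing single-agent column for drug ", block@drugB,
         ": block has no zero-dose entry in concA")
  }
  if (length(zB) != 1) {
    stop("missing single-agent row for drug ", block@drugA,
         ": block has no zero-dose entry in concB")
  }
  scoreOne <- function(I) {
    I1 <- I[, zB]   # single-agent response of drug A across its doses
    I2 <- I[zA, ]   # single-agent response of drug B
    s <- .blissExcess(I, I1, I2)
    s[-zA, -zB, drop = FALSE]
  }
  if (aggregateReplicates == "before") {
    s <- scoreOne(.meanInhibition(block))
  } else {
    nRep <- dim(block@inhibition)[1]
    mats <- lapply(seq_len(nRep), function(r) scoreOne(block@inhibition[r, , ]))
    s <- Reduce(`+`, mats) / nRep
  }
  out <- s * 100
  dimnames(out) <- list(block@concA[-zA], block@concB[-zB])
  out
}

#' Pool an elementwise Bliss excess matrix into a global synergy score
#'
#' Max pooling takes the largest excess over the dose grid, which is less
#' sensitive to the chosen dose interval than the arithmetic mean (most pairs
#' synergize only in a specific dose window); mean pooling is provided as the
#' common alternative.
#'
#' @param excess Bliss excess matrix from [blissExcessMatrix()].
#' @param pooling \code{"max"} (default) or \code{"mean"}.
#' @return a single pooled synergy score (x100 scale).
#' @export
poolSynergy <- function(excess, pooling = c("max", "mean")) {
  pooling <- match.arg(pooling)
  if (length(excess) == 0) stop("cannot pool an empty Bliss excess matrix")
  if (pooling == "max") max(excess) else mean(excess)
}

#' Score a dose-response block end to end
#'
#' Convenience wrapper: Bliss excess then pooling.
#' @inheritParams blissExcessMatrix
#' @inheritParams poolSynergy
#' @return one-row data.frame (drug_a, drug_b, cell_line, synergy, pooling)
#'   with the drug pair in canonical sorted order.
#' @export
scoreBlock <- function(block, pooling = c("max", "mean"),
                       aggregateReplicates = c("before", "after")) {
  pooling <- match.arg(pooling)
  s <- poolSynergy(blissExcessMatrix(block, aggregateReplicates), pooling)
  p <- .canonicalPair(block@drugA, block@drugB)
  data.frame(drug_a = p$a, drug_b = p$b, cell_line = block@cellLine,
             synergy = s, pooling = pooling, stringsAsFactors = FALSE)
}

#' Normalize a raw viability plate into a dose-response block
#'
#' Anchors the viability scale per the screening convention: 0% viability is
#' the highest-concentration doxorubicin (total-kill) well of each replicate,
#' 100% is the (0, 0) DMSO control of the combination; values are capped and
#' linearly scaled to \[0, 100\] and converted to fractional inhibition
#' \eqn{I = 1 - V/100}.
#'
#' @param rawViability array (\code{n_rep x nA x nB}) or matrix of raw
#'   viability percentages for the combination grid.
#' @param doxWells numeric vector, one per replicate: raw viability of the
#'   highest-concentration doxorubicin positive control.
#' @param dmsoWells numeric vector, one per replicate: raw viability of the
#'   (0, 0) DMSO control for this combination.
#' @param drugA,drugB,cellLine,concA,concB metadata for the resulting block.
#' @return a normalized [DoseResponseBlock-class].
#' @export
normalizeViabilityPlate <- function(rawViability, doxWells, dmsoWells,
                                    drugA, drugB, cellLine, concA, concB) {
  if (is.matrix(rawViability)) {
    rawViability <- array(rawViability, dim = c(1L, dim(rawViability)))
  }
  nRep <- dim(rawViability)[1]
  if (is.null(doxWells) || length(doxWells) == 0) {
    stop("missing control wells: DOX (total-kill) positive control")
  }
  if (is.null(dmsoWells) || length(dmsoWells) == 0) {
    stop("missing control wells: DMSO (0,0) negative control")
  }
  doxWells <- rep_len(doxWells, nRep)
  dmsoWells <- rep_len(dmsoWells, nRep)
  norm <- rawViability
  for (r in seq_len(nRep)) {
    span <- dmsoWells[r] - doxWells[r]
    if (!is.finite(span) || span <= 0) {
      stop("degenerate controls in replicate ", r,
           ": DMSO anchor must exceed DOX anchor")
    }
    v <- (rawViability[r, , ] - doxWells[r]) / span * 100
    v <- pmin(pmax(v, 0), 100)  # cap and scale between 0 and 100
    norm[r, , ] <- 1 - v / 100
  }
  doseResponseBlock(drugA, drugB, cellLine, concA, concB, norm)
}

#' Quality-control filtering of dose-response blocks
#'
#' Applies the screening QC rules: (a) drop blocks with inhibition standard
#' deviation <= 0.05 (flat, likely erroneous), (b) drop blocks smaller than
#' 3 x 3, (c) drop blocks with extreme mean inhibition outside (0.05, 0.95).
#' Filtering is idempotent.
#'
#' @param blocks list of [DoseResponseBlock-class] objects.
#' @return list with \code{retained} (sub-list of blocks) and \code{report},
#'   a named integer vector of rejection counts keyed by rule
#'   (\code{low_variance}, \code{too_small}, \code{extreme_inhibition}).
#' @export
qcFilterBlocks <- function(blocks) {
  report <- c(low_variance = 0L, too_small = 0L, extreme_inhibition = 0L)
  keep <- logical(length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    vals <- as.numeric(b@inhibition)
    d <- dim(b@inhibition)
    if (stats::sd(vals) <= 0.05) {
      report["low_variance"] <- report["low_variance"] + 1L
    } else if (d[2] < 3 || d[3] < 3) {
      report["too_small"] <- report["too_small"] + 1L
    } else {
      m <- mean(vals)
      if (m <= 0.05 || m >= 0.95) {
        report["extreme_inhibition"] <- report["extreme_inhibition"] + 1L
      } else {
        keep[i] <- TRUE
      }
    }
  }
  list(retained = blocks[keep], report = report)
}

#' Estimate replicate noise from repeated synergy measurements
#'
#' Groups records by (drug_a, drug_b, cell_line), computes the sample
#' standard deviation of the pooled synergy within each replicated triplet,
#' and averages across triplets to give the mean noise level eta_bar.
#'
#' @param records data.frame with columns drug_a, drug_b, cell_line, synergy;
#'   replicated triplets appear as multiple rows.
#' @return a [NoiseEstimate-class].
#' @export
estimateReplicateNoise <- function(records) {
  .assertColumns(records, c("drug_a", "drug_b", "cell_line", "synergy"),
                 "synergy record table")
  key <- paste(.pairKey(records$drug_a, records$drug_b), records$cell_line)
  counts <- table(key)
  replicated <- names(counts)[counts >= 2]
  if (length(replicated) == 0) {
    stop("no replicated (drug_a, drug_b, cell_line) triplet found")
  }
  sds <- vapply(replicated, function(k) {
    stats::sd(records$synergy[key == k])
  }, numeric(1))
  new("NoiseEstimate", etaBar = mean(sds), nTriplets = length(replicated))
}

#' Read / write long-format dose-response CSV
#'
#' Long format columns: drug_a, drug_b, cell_line, conc_a, conc_b, replicate,
#' inhibition (fractional units); missing values as empty fields.
#'
#' @param path CSV file path.
#' @return \code{readDoseResponseCsv}: a list of [DoseResponseBlock-class]
#'   objects, one per (drug_a, drug_b, cell_line).
#' @export
readDoseResponseCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assertColumns(df, c("drug_a", "drug_b", "cell_line", "conc_a", "conc_b",
                       "replicate", "inhibition"), "dose-response CSV")
  key <- paste(df$drug_a, df$drug_b, df$cell_line, sep = "\r")
  lapply(split(df, key), function(g) {
    cA <- sort(unique(g$conc_a)); cB <- sort(unique(g$conc_b))
    reps <- sort(unique(g$replicate))
    arr <- array(NA_real_, dim = c(length(reps), length(cA), length(cB)))
    arr[cbind(match(g$replicate, reps), match(g$conc_a, cA), match(g$conc_b, cB))] <-
      g$inhibition
    doseResponseBlock(g$drug_a[1], g$drug_b[1], g$cell_line[1], cA, cB, arr)
  })
}

#' @rdname readDoseResponseCsv
#' @param blocks list of [DoseResponseBlock-class] objects to write.
#' @export
writeDoseResponseCsv <- function(blocks, path) {
  rows <- lapply(blocks, function(b) {
    d <- dim(b@inhibition)
    idx <- expand.grid(r = seq_len(d[1]), i = seq_len(d[2]), j = seq_len(d[3]))
    data.frame(drug_a = b@drugA, drug_b = b@drugB, cell_line = b@cellLine,
               conc_a = b@concA[idx$i], conc_b = b@concB[idx$j],
               replicate = idx$r,
               inhibition = b@inhibition[as.matrix(idx)],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
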