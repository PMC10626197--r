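#' Parameters for a synthetic synergy landscape
#'
#' The generator emulates the statistical structure of large combination
#' screens: most pair scores sit in a Gaussian background around zero while a
#' small set of mechanism pairs carries large planted effects drawn from a
#' location-scale exponential tail, giving the heavy-tailed, near-zero-mode
#' distribution the pipeline assumes. Drugs carry latent mechanisms that are
#' correlated with their pseudo-fingerprints, so structure is informative
#' about synergy.
#'
#' @param nDrugs number of drugs in the library.
#' @param nMechanisms number of latent mechanisms (balanced assignment).
#' @param fpBits pseudo-fingerprint length.
#' @param fpDensity expected set-bit fraction of a mechanism base pattern.
#' @param bitFlipProb per-bit flip probability per drug.
#' @param plantedMechPairs number of mechanism pairs with planted synergy;
#'   must stay small enough that at most 10\% of drug pairs are planted.
#' @param effectLocation,effectScale planted effects are
#'   \code{effectLocation + Exp(1/effectScale)} (x100 synergy scale).
#' @param mechanismSd standard deviation of the mechanism-pair-level
#'   background component; this is the structure a model can learn from
#'   fingerprints, mirroring mechanism-driven synergy in real screens.
#' @param backgroundSd pair-level jitter around the mechanism-pair component
#'   (unlearnable spread).
#' @param eta observation noise standard deviation (x100 scale).
#' @param seed study seed; all randomness flows from it via named substreams.
#' @return a [LandscapeParams-class].
#' @export
landscapeParams <- function(nDrugs = 60, nMechanisms = 10, fpBits = 1024,
                            fpDensity = 0.15, bitFlipProb = 0.05,
                            plantedMechPairs = 3, effectLocation = 40,
                            effectScale = 15, mechanismSd = 4,
                            backgroundSd = 3, eta = 5, seed = 1) {
  new("LandscapeParams", nDrugs = nDrugs, nMechanisms = nMechanisms,
      fpBits = fpBits, fpDensity = fpDensity, bitFlipProb = bitFlipProb,
      plantedMechPairs = plantedMechPairs, effectLocation = effectLocation,
      effectScale = effectScale, mechanismSd = mechanismSd,
      backgroundSd = backgroundSd, eta = eta, seed = seed)
}

#' Generate a synthetic drug library with mechanism-correlated fingerprints
#'
#' Each drug is assigned a latent mechanism (balanced across the library).
#' Its pseudo-fingerprint is the mechanism's deterministic base bit pattern
#' with seeded per-bit flips, so drugs sharing a mechanism have higher
#' expected Tanimoto similarity than drugs of different mechanisms — the
#' structure/mechanism correlation that fingerprint-based generalization
#' relies on.
#'
#' @param params a [LandscapeParams-class].
#' @return a [DrugLibrary-class] with ids \code{D001, D002, ...}.
#' @export
generateDrugLibrary <- function(params) {
  n <- params@nDrugs
  nMech <- params@nMechanisms
  if (nMech > n) stop("n_mechanisms exceeds n_drugs")
  ids <- sprintf("D%03d", seq_len(n))
  mech <- .withSeed(.substream(params@seed, "library_mechanisms"),
                    sample(rep_len(seq_len(nMech), n)))
  # deterministic mechanism base patterns: seeded only by (seed, mechanism)
  basePattern <- function(m) {
    .withSeed(.substream(params@seed, paste0("mech_pattern_", m)),
              stats::rbinom(params@fpBits, 1, params@fpDensity))
  }
  bases <- lapply(seq_len(nMech), basePattern)
  fp <- .withSeed(.substream(params@seed, "library_bitflips"), {
    t(vapply(seq_len(n), function(i) {
      base <- bases[[mech[i]]]
      flips <- stats::rbinom(params@fpBits, 1, params@bitFlipProb)
      as.integer(xor(base == 1, flips == 1))
    }, integer(params@fpBits)))
  })
  rownames(fp) <- ids
  new("DrugLibrary", ids = ids, smiles = rep(NA_character_, n),
      fingerprints = fp, mechanism = as.integer(mech))
}

# Seeded choice of which mechanism pairs carry planted effects, and their
# effect sizes (location-scale exponential tail).
.synergyLookup <- function(params) {
  nMech <- params@nMechanisms
  mechPairs <- which(upper.tri(matrix(0, nMech, nMech), diag = TRUE),
                     arr.ind = TRUE)
  .withSeed(.substream(params@seed, "landscape_lookup"), {
    if (params@plantedMechPairs == 0) return(NULL)
    pick <- sample.int(nrow(mechPairs), params@plantedMechPairs)
    data.frame(m1 = mechPairs[pick, 1], m2 = mechPairs[pick, 2],
               effect = params@effectLocation +
                 stats::rexp(length(pick), rate = 1 / params@effectScale))
  })
}

#' Generate the true synergy landscape over all drug pairs
#'
#' Pair score = planted effect when the pair's mechanism pair is in the
#' synergy lookup, else a mechanism-pair base effect Gaussian(0, mechanismSd)
#' plus pair-level jitter Gaussian(0, backgroundSd). Symmetric in pair order;
#' with a non-empty lookup the score distribution has a heavy positive tail
#' (positive excess kurtosis).
#'
#' @param library a [DrugLibrary-class] from [generateDrugLibrary()].
#' @param params the matching [LandscapeParams-class].
#' @return data.frame with columns drug_a, drug_b, synergy, planted
#'   (canonical pair order, one row per unordered pair).
#' @export
generateSynergyLandscape <- function(library, params) {
  n <- length(library@ids)
  if (n == 0) stop("empty drug library")
  lookup <- .synergyLookup(params)
  pairIdx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m1 <- library@mechanism[pairIdx[, 1]]
  m2 <- library@mechanism[pairIdx[, 2]]
  lo <- pmin(m1, m2); hi <- pmax(m1, m2)
  effect <- rep(NA_real_, nrow(pairIdx))
  if (!is.null(lookup)) {
    key <- paste(lo, hi)
    lkey <- paste(pmin(lookup$m1, lookup$m2), pmax(lookup$m1, lookup$m2))
    hit <- match(key, lkey)
    effect <- lookup$effect[hit]
  }
  # mechanism-pair base effects: the learnable component of the background
  nMech <- params@nMechanisms
  mechBase <- .withSeed(.substream(params@seed, "landscape_mechanism"), {
    matrix(stats::rnorm(nMech * nMech, 0, params@mechanismSd), nMech, nMech)
  })
  mechBase[lower.tri(mechBase)] <- t(mechBase)[lower.tri(mechBase)]
  synergy <- .withSeed(.substream(params@seed, "landscape_background"), {
    bg <- mechBase[cbind(lo, hi)] +
      stats::rnorm(nrow(pairIdx), 0, params@backgroundSd)
    ifelse(is.na(effect), bg, effect)
  })
  p <- .canonicalPair(library@ids[pairIdx[, 1]], library@ids[pairIdx[, 2]])
  data.frame(drug_a = p$a, drug_b = p$b, synergy = synergy,
             planted = !is.na(effect), stringsAsFactors = FALSE)
}

#' Corrupt a true synergy table with observation noise
#'
#' observed = true + iid Gaussian(0, eta^2), per replicate. eta = 0
#' reproduces the truth exactly.
#'
#' @param truth data.frame with drug_a, drug_b, synergy.
#' @param eta noise standard deviation.
#' @param seed noise seed.
#' @param nReplicates replicate measurements per pair.
#' @return data.frame with columns drug_a, drug_b, replicate, synergy (and a
#'   true_synergy column retaining the noiseless value).
#' @export
generateObservations <- function(truth, eta, seed = 1, nReplicates = 1) {
  if (eta < 0) stop("eta must be >= 0")
  reps <- truth[rep(seq_len(nrow(truth)), each = nReplicates), , drop = FALSE]
  reps$replicate <- rep(seq_len(nReplicates), nrow(truth))
  reps$true_synergy <- reps$synergy
  noise <- .withSeed(.substream(seed, "observation_noise"),
                     stats::rnorm(nrow(reps), 0, eta))
  reps$synergy <- reps$true_synergy + noise
  rownames(reps) <- NULL
  reps
}

# Four-parameter sigmoidal single-agent inhibition curve, zero at dose 0.
.hillCurve <- function(conc, ec50, slope, imax) {
  ifelse(conc <= 0, 0, imax / (1 + (ec50 / conc)^slope))
}

#' Generate 6x6 dose-response blocks realizing a synergy table
#'
#' Builds, for each pair, a dose grid of serial 1:3 dilutions (5
#' concentrations plus a zero dose), sigmoidal single-agent inhibition
#' curves, and a combination surface equal to the Bliss-independent surface
#' plus a planted excess scaled so that the max-pooled Bliss score of the
#' noiseless block equals the pair's true synergy. Positive synergies are
#' planted as a localized bump (Gaussian spatial decay around a seeded dose
#' cell, reflecting that synergy typically occurs in a specific dose window)
#' on a weak-single-agent background; non-positive scores are planted as a
#' uniform excess on a potent-single-agent background, since a localized
#' deficit cannot lower the grid maximum. Replicate noise is Gaussian on the
#' inhibition scale with standard deviation \code{eta/100}.
#'
#' @param library a [DrugLibrary-class].
#' @param truth synergy table from [generateSynergyLandscape()] (subset rows
#'   to generate fewer blocks).
#' @param gridSize dose grid size including the zero dose (default 6).
#' @param eta observation noise on the x100 synergy scale.
#' @param nReplicates replicates per block.
#' @param seed generation seed.
#' @param cellLine cell line label stamped on the blocks.
#' @return list of [DoseResponseBlock-class]; each carries the planted pooled
#'   synergy as attribute \code{"planted_synergy"}.
#' @export
generateDoseResponseBlocks <- function(library, truth, gridSize = 6, eta = 0,
                                       nReplicates = 1, seed = 1,
                                       cellLine = "SYN1") {
  if (gridSize < 2) stop("grid must be at least 2x2")
  nDose <- gridSize - 1L  # nonzero doses
  drawCurve <- function(drugSeed, potent) {
    .withSeed(drugSeed, {
      cTop <- 10^stats::runif(1, -1, 1)
      conc <- c(0, cTop / 3^rev(seq_len(nDose) - 1))
      ec50 <- if (potent) {
        conc[2] * stats::runif(1, 0.1, 1)      # saturating already at low dose
      } else {
        cTop * 10^stats::runif(1, -0.5, 0.5)   # active only near the top doses
      }
      list(conc = conc,
           ec50 = ec50,
           slope = stats::runif(1, 1, 2),
           imax = if (potent) stats::runif(1, 0.6, 0.95)
                  else stats::runif(1, 0.4, 0.9))
    })
  }
  blocks <- vector("list", nrow(truth))
  for (r in seq_len(nrow(truth))) {
    a <- truth$drug_a[r]; b <- truth$drug_b[r]
    s <- truth$synergy[r] / 100
    pairSeed <- .substream(seed, paste0("block_", a, "_", b))
    potent <- s <= 0
    curveA <- drawCurve(.substream(pairSeed, paste0("curve_", a)), potent)
    curveB <- drawCurve(.substream(pairSeed, paste0("curve_", b)), potent)
    IA <- .hillCurve(curveA$conc, curveA$ec50, curveA$slope, curveA$imax)
    IB <- .hillCurve(curveB$conc, curveB$ec50, curveB$slope, curveB$imax)
    indep <- outer(IA, IB, function(x, y) x + y - x * y)
    excess <- matrix(0, gridSize, gridSize)
    nz <- seq.int(2L, gridSize)
    if (s > 0) {
      # localized bump: peak exactly s at a seeded cell where it fits
      room <- 1 - indep[nz, nz]
      eligible <- which(room >= s + 1e-9, arr.ind = TRUE)
      if (nrow(eligible) == 0) {
        eligible <- which(room == max(room), arr.ind = TRUE)
      }
      # prefer interior cells of the nonzero grid when available
      interior <- eligible[eligible[, 1] > 1 & eligible[, 1] < length(nz) &
                           eligible[, 2] > 1 & eligible[, 2] < length(nz), ,
                           drop = FALSE]
      if (nrow(interior) > 0) eligible <- interior
      pick <- .withSeed(.substream(pairSeed, "bump_cell"),
                        eligible[sample.int(nrow(eligible), 1), ])
      di <- outer(seq_along(nz), seq_along(nz), function(i, j) {
        (i - pick[1])^2 + (j - pick[2])^2
      })
      bump <- s * exp(-di / (2 * 1.0^2))
      # never exceed the headroom of any cell (peak cell is exact by choice)
      bump <- pmin(bump, 1 - indep[nz, nz])
      excess[nz, nz] <- bump
    } else if (s < 0) {
      # uniform excess: every cell supports it on the potent background
      excess[nz, nz] <- pmax(s, -indep[nz, nz])
    }
    surface <- pmin(pmax(indep + excess, 0), 1)
    inh <- array(rep(surface, each = nReplicates),
                 dim = c(nReplicates, gridSize, gridSize))
    if (eta > 0) {
      noise <- .withSeed(.substream(pairSeed, "replicate_noise"),
                         array(stats::rnorm(length(inh), 0, eta / 100),
                               dim = dim(inh)))
      inh <- pmin(pmax(inh + noise, 0), 1)
    }
    blk <- doseResponseBlock(a, b, cellLine, curveA$conc, curveB$conc, inh)
    attr(blk, "planted_synergy") <- truth$synergy[r]
    blocks[[r]] <- blk
  }
  blocks
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: library, true landscape and noisy observations in one
#' object.
#'
#' @param params a [LandscapeParams-class].
#' @param nReplicates replicates in the observed table.
#' @return a [SyntheticStudy-class].
#' @export
syntheticStudy <- function(params = landscapeParams(), nReplicates = 1) {
  lib <- generateDrugLibrary(params)
  truth <- generateSynergyLandscape(lib, params)
  observed <- generateObservations(truth, params@eta,
                                   seed = .substream(params@seed, "observations"),
                                   nReplicates = nReplicates)
  new("SyntheticStudy", library = lib, truth = truth, observed = observed,
      params = params)
}
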