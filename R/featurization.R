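#' Construct a drug library
#'
#' @param ids unique drug identifiers.
#' @param smiles optional SMILES strings (NA allowed); when supplied and
#'   \code{fingerprints} is NULL, circular fingerprints are computed from the
#'   structures.
#' @param fingerprints optional 0/1 matrix (one row per drug), e.g.
#'   generator-supplied pseudo-fingerprints for drugs without structures.
#' @param mechanism optional integer latent-mechanism labels.
#' @param nBits,radius fingerprint settings used when computing from SMILES.
#' @return a [DrugLibrary-class].
#' @export
drugLibrary <- function(ids, smiles = NULL, fingerprints = NULL,
                        mechanism = NULL, nBits = 1024, radius = 2) {
  ids <- as.character(ids)
  n <- length(ids)
  if (is.null(smiles)) smiles <- rep(NA_character_, n)
  if (is.null(fingerprints)) {
    fingerprints <- t(vapply(smiles, function(s) {
      computeFingerprint(s, radius = radius, nBits = nBits)
    }, numeric(nBits)))
  }
  fingerprints <- as.matrix(fingerprints)
  rownames(fingerprints) <- ids
  if (is.null(mechanism)) mechanism <- rep(NA_integer_, n)
  new("DrugLibrary", ids = ids, smiles = as.character(smiles),
      fingerprints = fingerprints, mechanism = as.integer(mechanism))
}

#' Read a drug table CSV (drug_id, smiles)
#'
#' @param path CSV path with columns drug_id and smiles.
#' @inheritParams drugLibrary
#' @export
readDrugTable <- function(path, nBits = 1024, radius = 2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assertColumns(df, c("drug_id", "smiles"), "drug table")
  drugLibrary(df$drug_id, df$smiles, nBits = nBits, radius = radius)
}

# --- circular fingerprint -----------------------------------------------------

# Parse a SMILES into atom elements / bond table via ChemmineR.
.parseSmiles <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("unparseable SMILES string: ", smiles, call. = FALSE)
  )
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(numeric(0), 0, 3)
  } else {
    cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
  }
  list(elements = elements, bonds = bonds)
}

#' Circular (Morgan-style) hashed fingerprint from a SMILES string
#'
#' Computes a fixed-length binary fingerprint by iteratively hashing each
#' atom's bonded neighbourhood out to the given radius and folding the
#' resulting substructure identifiers into \code{nBits} bits. Deterministic:
#' the same structure always yields the same vector.
#'
#' @param smiles structure string.
#' @param radius neighbourhood radius (default 2).
#' @param nBits fingerprint length (default 1024).
#' @return integer 0/1 vector of length \code{nBits}.
#' @export
computeFingerprint <- function(smiles, radius = 2, nBits = 1024) {
  if (is.na(smiles) || !nzchar(smiles)) {
    stop("unparseable SMILES string: ", deparse(smiles))
  }
  mol <- .parseSmiles(smiles)
  nAtoms <- length(mol$elements)
  bonds <- mol$bonds
  neighbours <- vector("list", nAtoms)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]; o <- bonds[r, 3]
      neighbours[[i]] <- rbind(neighbours[[i]], c(j, o))
      neighbours[[j]] <- rbind(neighbours[[j]], c(i, o))
    }
  }
  degree <- vapply(neighbours, function(nb) if (is.null(nb)) 0L else nrow(nb), integer(1))
  bondSum <- vapply(neighbours, function(nb) if (is.null(nb)) 0 else sum(nb[, 2]), numeric(1))
  # radius-0 invariants: element, degree, total bond order
  ids <- vapply(seq_len(nAtoms), function(i) {
    .hash32(paste(mol$elements[i], degree[i], bondSum[i], sep = ":"))
  }, integer(1))
  allIds <- ids
  if (nAtoms > 0) {
    for (r in seq_len(radius)) {
      ids <- vapply(seq_len(nAtoms), function(i) {
        nb <- neighbours[[i]]
        env <- if (is.null(nb)) character(0) else {
          sort(paste(nb[, 2], ids[nb[, 1]], sep = "-"))
        }
        .hash32(paste(c(r, ids[i], env), collapse = "|"))
      }, integer(1))
      allIds <- c(allIds, ids)
    }
  }
  fp <- integer(nBits)
  fp[unique(allIds %% nBits) + 1L] <- 1L
  fp
}

#' Tanimoto similarity between two binary fingerprints
#'
#' Intersection over union of the set bits; defined as 1 when both vectors
#' are all-zero.
#'
#' @param fp1,fp2 equal-length 0/1 vectors.
#' @return similarity in \[0, 1\].
#' @export
tanimotoSimilarity <- function(fp1, fp2) {
  if (length(fp1) != length(fp2)) {
    stop("fingerprint length mismatch: ", length(fp1), " vs ", length(fp2))
  }
  fp1 <- fp1 != 0; fp2 <- fp2 != 0
  u <- sum(fp1 | fp2)
  if (u == 0) return(1)
  sum(fp1 & fp2) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param X 0/1 matrix, fingerprints in rows.
#' @return symmetric similarity matrix.
#' @export
tanimotoMatrix <- function(X) {
  X <- (X != 0) * 1
  inter <- X %*% t(X)
  counts <- rowSums(X)
  uni <- outer(counts, counts, `+`) - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  dimnames(sim) <- list(rownames(X), rownames(X))
  sim
}

#' Assemble the drug feature matrix
#'
#' Concatenates the fingerprint block and the one-hot identity block. A
#' disabled block is zero-filled so the total dimension never changes, which
#' keeps model capacity comparable across feature-importance experiments.
#'
#' @param library a [DrugLibrary-class].
#' @param useFingerprint,useOnehot block flags; at least one must be TRUE.
#' @return a [DrugFeatureMatrix-class].
#' @export
assembleDrugFeatures <- function(library, useFingerprint = TRUE, useOnehot = TRUE) {
  if (!useFingerprint && !useOnehot) {
    stop("at least one of useFingerprint/useOnehot must be TRUE (no signal otherwise)")
  }
  n <- length(library@ids)
  fp <- library@fingerprints
  fpBlock <- if (useFingerprint) fp else matrix(0, n, ncol(fp))
  ohBlock <- if (useOnehot) diag(n) else matrix(0, n, n)
  features <- cbind(fpBlock, ohBlock)
  rownames(features) <- library@ids
  colnames(features) <- c(paste0("fp", seq_len(ncol(fp))), paste0("oh_", library@ids))
  new("DrugFeatureMatrix", features = features, fpBits = ncol(fp),
      useFingerprint = useFingerprint, useOnehot = useOnehot)
}

#' Randomly permute drug feature rows (shuffled-labels / gradual randomization)
#'
#' A seeded random subset of \code{ceiling(fraction * n)} drugs has its whole
#' feature rows permuted among themselves, so each affected drug is
#' represented by another affected drug's features (fixed points allowed).
#' \code{fraction = 0} is the identity; \code{fraction = 1} permutes all rows.
#'
#' @param X a [DrugFeatureMatrix-class].
#' @param fraction proportion of drugs to involve, in \[0, 1\].
#' @param seed integer seed.
#' @return a [DrugFeatureMatrix-class] with permuted rows (rownames keep the
#'   original drug order, so drug i is now *represented by* other features).
#' @export
randomizeFeatures <- function(X, fraction, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  feats <- X@features
  n <- nrow(feats)
  m <- ceiling(fraction * n)
  if (m >= 2) {
    .withSeed(.substream(seed, "randomize_features"), {
      subset <- sample.int(n, m)
      perm <- sample(subset)
      feats[subset, ] <- feats[perm, , drop = FALSE]
    })
  }
  initialize(X, features = feats)
}

# Seeded k-medoids++ initialization over a distance matrix.
.kmedoidsPlusPlusInit <- function(D, k, seed) {
  n <- nrow(D)
  .withSeed(.substream(seed, "kmedoids_init"), {
    medoids <- sample.int(n, 1)
    while (length(medoids) < k) {
      dmin <- apply(D[, medoids, drop = FALSE], 1, min)
      w <- dmin^2
      if (sum(w) <= 0) {
        cand <- setdiff(seq_len(n), medoids)
        medoids <- c(medoids, cand[sample.int(length(cand), 1)])
      } else {
        medoids <- c(medoids, sample.int(n, 1, prob = w / sum(w)))
      }
      medoids <- unique(medoids)
    }
  })
  medoids
}

#' k-medoids library design over Tanimoto distance
#'
#' Clusters a candidate library with k-medoids (seeded k-medoids++
#' initialization, PAM swap refinement) on the Tanimoto distance
#' \eqn{1 - similarity} between fingerprints, and returns one representative
#' medoid per cluster. Used to condense a large compound collection into a
#' diverse search-space panel.
#'
#' @param library a [DrugLibrary-class] of candidates.
#' @param k number of clusters (representatives).
#' @param seed integer seed for the initialization.
#' @return list with \code{medoids} (drug ids), \code{assignment} (cluster
#'   index per drug), \code{objective} (summed within-cluster distance) and
#'   \code{distance} (the distance matrix, for the replacement hook).
#' @seealso [nearestAnalogue()] for the availability-replacement rule.
#' @export
clusterLibraryMedoids <- function(library, k = 54, seed = 1) {
  n <- length(library@ids)
  if (n < k) stop("need at least k = ", k, " candidates, got ", n)
  D <- 1 - tanimotoMatrix(library@fingerprints)
  if (k == n) {
    return(list(medoids = library@ids, assignment = stats::setNames(seq_len(n), library@ids),
                objective = 0, distance = D))
  }
  init <- .kmedoidsPlusPlusInit(D, k, seed)
  fit <- cluster::pam(stats::as.dist(D), k = k, medoids = init, diss = TRUE)
  assignment <- stats::setNames(fit$clustering, library@ids)
  medoidIdx <- as.integer(fit$id.med)
  objective <- sum(vapply(seq_len(n), function(i) {
    D[i, medoidIdx[assignment[i]]]
  }, numeric(1)))
  list(medoids = library@ids[medoidIdx], assignment = assignment,
       objective = objective, distance = D)
}

#' Nearest same-cluster analogue of a medoid
#'
#' Availability-replacement rule for the library design: when a selected
#' representative cannot be sourced, swap it for the most Tanimoto-similar
#' drug in the same cluster.
#'
#' @param clustering result of [clusterLibraryMedoids()].
#' @param medoid drug id of the representative to replace.
#' @return drug id of the nearest analogue.
#' @export
nearestAnalogue <- function(clustering, medoid) {
  ids <- names(clustering$assignment)
  if (!medoid %in% ids) stop("unknown medoid: ", medoid)
  cl <- clustering$assignment[medoid]
  others <- ids[clustering$assignment == cl & ids != medoid]
  if (length(others) == 0) stop("cluster of ", medoid, " has no other member")
  d <- clustering$distance[medoid, others]
  others[which.min(d)]
}
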