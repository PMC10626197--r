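# Internal helpers shared across modules.

# Deterministic 31-bit polynomial string hash (modular arithmetic in doubles,
# exact below 2^53). Used for substream seeds and fingerprint bit folding.
.hash32 <- function(key) {
  bytes <- utf8ToInt(key)
  h <- 5381
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483629
  }
  as.integer(h)
}

# Derive a named RNG substream seed from a study seed. Keeps every source of
# randomness traceable to one integer while decoupling the streams.
.substream <- function(seed, name) {
  as.integer((as.numeric(seed) * 48271 + .hash32(name)) %% 2147483647)
}

# Evaluate expr with a local, seeded RNG state; the caller's state is restored.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Canonical sorted order for a drug pair; vectorised.
.canonicalPair <- function(a, b) {
  swap <- as.character(a) > as.character(b)
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

.pairKey <- function(a, b) {
  p <- .canonicalPair(a, b)
  paste(p$a, p$b, sep = "\r")
}

.assertColumns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}
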