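# Internal helpers shared across modules.

# Evaluate `fun()` under a temporary RNG state seeded with `seed`.
# seed = NULL uses (and advances) the caller's RNG stream.
withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  fun()
}

# Derive a deterministic child seed from a master seed, keeping it inside
# the 32-bit integer range.
childSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

logsumexp <- function(m) {
  # rowwise log-sum-exp of a matrix
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# split a comma-separated annotation field into a character vector
splitCommaField <- function(x) {
  x <- as.character(x)
  out <- strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ",", fixed = TRUE)
  lapply(out, function(v) if (length(v) == 1L && is.na(v)) character(0) else trimws(v))
}

joinCommaField <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ","), character(1))
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

fmtCount <- function(k, n) {
  sprintf("%d/%d (%.1f%%)", k, n, 100 * k / n)
}
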