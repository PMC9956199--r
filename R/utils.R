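#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number, got %s", deparse(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(code)
}

# Deterministic sub-seed for a named pipeline stage: hashing keeps the
# streams of independent stages (key generation, encryption, training, ...)
# decoupled, so disabling one stage cannot shift another's randomness.
#' @noRd
derive_seed <- function(master_seed, tag) {
  h <- sha256_hex(paste0("phecare:", format(master_seed, scientific = FALSE),
                         ":", tag))
  as.integer(strtoi(substr(h, 1L, 7L), base = 16L))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' @noRd
is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x < 1
}

# Decimal string rendering of doubles that survives a write/read roundtrip
# exactly: 15 significant digits when that reparses to the same double,
# 17 otherwise.
#' @noRd
format_full_precision <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}

#' @noRd
now_ms <- function() as.numeric(Sys.time()) * 1000
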