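# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit child seed from a master seed by a fixed counter scheme.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 7919 + 104729 * as.numeric(counter)) %% 2147483647)
}

# Runs of TRUE in a logical vector as a two-column matrix of start/end indices
# (inclusive). Zero-row matrix when no run exists.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Close FALSE gaps of at most `max_gap` samples that are flanked by TRUE runs.
close_gaps <- function(x, max_gap) {
  if (max_gap < 1L || !any(x)) return(x)
  r <- rle(x)
  n <- length(r$values)
  if (n > 2L) {
    inner <- 2:(n - 1L)
    fill <- inner[!r$values[inner] & r$lengths[inner] <= max_gap]
    r$values[fill] <- TRUE
  }
  inverse.rle(r)
}

# Drop TRUE runs shorter than `min_len` samples.
drop_short_runs <- function(x, min_len) {
  if (min_len <= 1L || !any(x)) return(x)
  r <- rle(x)
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
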