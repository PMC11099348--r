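# Internal helpers shared across modules.

# Evaluate `code` under a temporarily-seeded RNG, restoring the caller's
# RNG state afterwards. Every stochastic operation in the package routes
# through this so that a single integer seed fixes all output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# seed + op-specific offset, kept inside 32-bit integer range
op_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x == round(x)
}

# Equal-occupancy bin assignment by rank; ties broken by stable input
# order so repeated values land deterministically.
occupancy_bins <- function(x, n_bins) {
  n <- length(x)
  if (n_bins > n) stopf("more bins (%d) than observations (%d)", n_bins, n)
  ord <- order(x, seq_along(x))
  sizes <- diff(floor(seq(0, n, length.out = n_bins + 1L)))
  bin <- integer(n)
  bin[ord] <- rep.int(seq_len(n_bins), sizes)
  bin
}
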