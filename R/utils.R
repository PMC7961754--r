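# shared internal helpers

# derive a child seed from a master seed and an index, kept < 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + index * 104729) %% 2147483647L)
}

# draw from N(mean, sd) truncated at +/- 3 sd (rejection; sd = 0 allowed)
rnorm_trunc3 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > 3 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 3 * sd
  }
  x
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

warnf <- function(fmt, ...) warn(sprintf(fmt, ...))

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# first index of x at/after `from` where condition vector is TRUE, NA if none
first_true <- function(cond, from = 1L) {
  idx <- which(cond)
  idx <- idx[idx >= from]
  if (length(idx) == 0L) NA_integer_ else idx[[1L]]
}
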