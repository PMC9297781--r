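# Internal helpers shared across modules.

# Run `expr` under a fixed seed when one is given, otherwise use the ambient
# RNG stream (so outer seeded contexts stay reproducible).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s, got %s",
                  name, format(min), deparse(substitute(x))))
  }
  invisible(x)
}

# Draw `n` fragment lengths from a histogram (counts over `lengths`).
# With replacement this is a single multinomial draw over the histogram
# cells; without replacement it is a draw from the expanded multiset.
# Returns the drawn counts aligned with `lengths`.
draw_counts <- function(counts, n, replace = TRUE) {
  stopifnot(n >= 1)
  k <- length(counts)
  total <- sum(counts)
  if (total == 0) abort("cannot sample from an empty pool")
  if (replace) {
    as.vector(rmultinom(1L, n, prob = counts / total))
  } else {
    if (n > total) {
      abort(sprintf("cannot draw %d fragments without replacement from a pool of %d", n, total))
    }
    idx <- sample.int(total, n)
    tabulate(findInterval(idx, cumsum(counts) - counts + 1L), nbins = k)
  }
}
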