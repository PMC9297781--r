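#' cfDNA fragment pools
#'
#' A fragment pool is the multiset of cfDNA fragment lengths observed for one
#' sample, stored without information loss as a `length -> count` histogram:
#' a tibble with integer columns `length` (bp, >= 1) and `count` (>= 0),
#' plus `sample_id` and `source_label` attributes. All scoring operations
#' work on this histogram representation, so pools of hundreds of millions
#' of fragments stay small in memory.
#'
#' @param lengths Integer vector of fragment lengths (bp), one entry per
#'   fragment. Ignored when `counts` is given.
#' @param counts Optional data frame with `length` and `count` columns (a
#'   pre-tabulated histogram); repeated lengths are summed.
#' @param sample_id Sample identifier.
#' @param source Provenance label, one of `"tumour_reference"`,
#'   `"nonmalignant"`, `"patient_preop"`, `"patient_postop"`.
#'
#' @return A `fragment_pool` tibble with columns `length` and `count`.
#' @examples
#' fragment_pool(c(167, 167, 334, 140), sample_id = "s1")
#' @export
fragment_pool <- function(lengths = NULL, counts = NULL,
                          sample_id = "sample",
                          source = c("nonmalignant", "tumour_reference",
                                     "patient_preop", "patient_postop")) {
  source <- match.arg(source)
  if (is.null(counts)) {
    if (is.null(lengths)) lengths <- integer(0)
    if (length(lengths) > 0 && any(lengths < 1 | lengths != round(lengths))) {
      abort("fragment lengths must be positive integers")
    }
    tab <- table(as.integer(lengths))
    counts <- tibble::tibble(length = as.integer(names(tab)),
                             count = as.integer(tab))
  } else {
    counts <- tibble::as_tibble(counts)[, c("length", "count")]
    if (any(counts$count < 0) || any(counts$length < 1) ||
        any(counts$length != round(counts$length))) {
      abort("histogram must have integer lengths >= 1 and counts >= 0")
    }
    len <- as.integer(counts$length)
    cnt <- as.integer(counts$count)
    if (anyDuplicated(len)) {
      agg <- rowsum(cnt, len)
      len <- as.integer(rownames(agg))
      cnt <- as.integer(agg[, 1])
    }
    keep <- cnt > 0
    ord <- order(len[keep])
    counts <- tibble::tibble(length = len[keep][ord], count = cnt[keep][ord])
  }
  new_fragment_pool(counts, sample_id, source)
}

new_fragment_pool <- function(counts, sample_id, source) {
  out <- tibble::new_tibble(counts, sample_id = sample_id,
                            source_label = source,
                            class = "fragment_pool")
  out
}

#' @export
print.fragment_pool <- function(x, ...) {
  cat(sprintf("<fragment_pool> sample '%s' (%s): %s fragments, %d distinct lengths\n",
              attr(x, "sample_id"), attr(x, "source_label"),
              format(pool_size(x), big.mark = ","), nrow(x)))
  NextMethod()
}

#' Total number of fragments in a pool
#'
#' @param pool A [fragment_pool()].
#' @return Total fragment count (numeric, O(1) from the histogram).
#' @export
pool_size <- function(pool) sum(as.numeric(pool$count))

#' Merge fragment pools into one histogram
#'
#' @param ... Fragment pools (or plain `length`/`count` tibbles).
#' @param sample_id,source Attributes for the merged pool.
#' @return A [fragment_pool()] whose histogram is the sum of the inputs.
#' @export
pool_merge <- function(..., sample_id = "merged", source = "nonmalignant") {
  tabs <- lapply(list(...), function(p) tibble::as_tibble(p)[, c("length", "count")])
  fragment_pool(counts = dplyr::bind_rows(tabs), sample_id = sample_id,
                source = source)
}

#' Draw fragment lengths from a pool
#'
#' Draws `n` lengths (with replacement by default) and returns the drawn
#' histogram; used by the score-table bootstrap and FS sampling.
#'
#' @param pool A [fragment_pool()].
#' @param n Number of fragments to draw.
#' @param replace Sample with replacement (default) or without.
#' @return Tibble with `length` and `count` of the draw (rows with count 0
#'   dropped).
#' @export
pool_draw <- function(pool, n, replace = TRUE) {
  if (nrow(pool) == 0) abort("cannot sample from an empty pool")
  drawn <- draw_counts(pool$count, n, replace = replace)
  keep <- drawn > 0
  tibble::tibble(length = pool$length[keep], count = drawn[keep])
}
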