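# Fragment-length score reference: the per-length log2 density-ratio score
# s(L) contrasting tumour-derived against non-malignant cfDNA fragments.

new_fs_table <- function(tbl, meta) {
  tibble::new_tibble(tbl, meta = meta, class = "fs_table")
}

fs_table_meta <- function(table) attr(table, "meta")

#' @export
print.fs_table <- function(x, ...) {
  m <- fs_table_meta(x)
  cat(sprintf("<fs_table> s(L) over 1..%s bp (n_boot=%s, n_sample=%s, cap=%s, min_count=%s)\n",
              m$length_cap %||% max(x$length), m$n_boot %||% "?",
              m$n_sample %||% "?", m$cap %||% "?", m$min_count %||% "?"))
  NextMethod()
}

#' Empirical fragment-length density
#'
#' The probability of each fragment length in a sample: `count(L) / n`.
#' Sums to one over the observed support.
#'
#' @param sample A [fragment_pool()], a `length`/`count` tibble, or an
#'   integer vector of lengths.
#' @param support Optional integer vector of lengths over which to report
#'   the density (zero where unobserved). Defaults to the observed lengths.
#' @return Tibble with `length` and `density`.
#' @examples
#' empirical_density(c(167, 167, 334, 140))
#' @export
empirical_density <- function(sample, support = NULL) {
  pool <- if (inherits(sample, "data.frame")) {
    tibble::as_tibble(sample)[, c("length", "count")]
  } else {
    tibble::as_tibble(fragment_pool(sample))[, c("length", "count")]
  }
  n <- sum(pool$count)
  if (n == 0) abort("empirical_density() needs a non-empty sample")
  dens <- dplyr::mutate(pool, density = .data$count / n)[, c("length", "density")]
  if (!is.null(support)) {
    dens <- tibble::tibble(length = as.integer(support)) |>
      dplyr::left_join(dens, by = "length") |>
      dplyr::mutate(density = dplyr::coalesce(.data$density, 0))
  }
  dens
}

# Counts over the fixed support 1:length_cap for a pool; lengths above the
# cap are dropped (they carry score 0 anyway).
counts_on_support <- function(pool, length_cap) {
  out <- numeric(length_cap)
  keep <- pool$length <= length_cap
  out[pool$length[keep]] <- pool$count[keep]
  out
}

#' One bootstrap iteration of the per-length score
#'
#' Draws `n_sample` fragments from the tumour and the non-malignant pool,
#' forms the per-length empirical densities, and scores each length as
#' `log2(d_tumour / d_nonmalignant)`, clipped to `[-cap, +cap]` (a length
#' absent from one draw but present in the other scores at the cap).
#' Lengths whose combined sampled count is `min_count` or fewer score 0.
#'
#' @param tumour_pool,nontumour_pool [fragment_pool()]s (non-empty).
#' @param n_sample Fragments drawn from each pool per iteration.
#' @param cap Score clip value.
#' @param min_count Combined-count threshold at or below which a length
#'   scores 0.
#' @param length_cap Support upper bound (bp).
#' @param replace Draw with replacement (bootstrap, default) or without.
#' @return Numeric vector `s[1..length_cap]` of iteration scores.
#' @export
bootstrap_iteration_scores <- function(tumour_pool, nontumour_pool,
                                       n_sample = 10000, cap = 5,
                                       min_count = 20, length_cap = 600,
                                       replace = TRUE) {
  if (n_sample <= 0) abort("n_sample must be positive")
  if (nrow(tumour_pool) == 0 || nrow(nontumour_pool) == 0) {
    abort("both fragment pools must be non-empty")
  }
  iteration_scores(counts_on_support(tumour_pool, length_cap),
                   counts_on_support(nontumour_pool, length_cap),
                   n_sample, cap, min_count, length_cap, replace)
}

# Hot path: one iteration given pool histograms aligned on 1:length_cap.
iteration_scores <- function(tum_counts, non_counts, n_sample, cap,
                             min_count, length_cap, replace) {
  ct <- draw_counts(tum_counts, n_sample, replace = replace)
  cn <- draw_counts(non_counts, n_sample, replace = replace)
  score <- numeric(length_cap)
  active <- (ct + cn) > min_count
  only_t <- active & cn == 0
  only_n <- active & ct == 0
  both <- active & ct > 0 & cn > 0
  score[only_t] <- cap
  score[only_n] <- -cap
  score[both] <- pmin(pmax(log2(ct[both] / cn[both]), -cap), cap)
  score
}

#' Build a fragmentation score table
#'
#' The per-length score s(L) is the mean (optionally median) of
#' [bootstrap_iteration_scores()] over `n_boot` iterations; bootstrapping
#' smooths sampling noise in sparse length bins. The defaults are the
#' method's standard build: 1000 iterations of 10,000 fragments per pool,
#' scores clipped at +/-5, lengths with 20 or fewer combined sampled reads
#' zeroed.
#'
#' @inheritParams bootstrap_iteration_scores
#' @param n_boot Number of bootstrap iterations.
#' @param aggregate `"mean"` (default) or `"median"` across iterations.
#' @param seed Optional integer; the build is deterministic given the seed
#'   (one RNG stream, iterations consume it sequentially).
#' @return An `fs_table`: tibble with `length` (1..`length_cap`) and
#'   `score`, with build metadata attached.
#' @examples
#' tum <- fragment_pool(sample(130:160, 500, replace = TRUE))
#' ctl <- fragment_pool(sample(150:190, 500, replace = TRUE))
#' tab <- build_score_table(tum, ctl, n_boot = 10, n_sample = 200, seed = 1)
#' @export
build_score_table <- function(tumour_pool, nontumour_pool, n_boot = 1000,
                              n_sample = 10000, cap = 5, min_count = 20,
                              length_cap = 600,
                              aggregate = c("mean", "median"),
                              replace = TRUE, seed = NULL) {
  aggregate <- match.arg(aggregate)
  if (n_boot < 1) abort("n_boot must be >= 1")
  if (n_sample <= 0) abort("n_sample must be positive")
  if (nrow(tumour_pool) == 0 || nrow(nontumour_pool) == 0) {
    abort("both fragment pools must be non-empty")
  }
  tum_counts <- counts_on_support(tumour_pool, length_cap)
  non_counts <- counts_on_support(nontumour_pool, length_cap)
  scores <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(i) {
      iteration_scores(tum_counts, non_counts, n_sample, cap, min_count,
                       length_cap, replace)
    }, numeric(length_cap))
  })
  s <- if (aggregate == "mean") rowMeans(scores) else
    apply(scores, 1, stats::median)
  meta <- list(n_boot = n_boot, n_sample = n_sample, cap = cap,
               min_count = min_count, length_cap = length_cap,
               aggregate = aggregate, replace = replace,
               seed = seed,
               n_tumour = pool_size(tumour_pool),
               n_nontumour = pool_size(nontumour_pool),
               table_id = paste(n_boot, n_sample, cap, min_count, length_cap,
                                aggregate, seed %||% "NULL",
                                format(sum(s * seq_along(s)), digits = 17),
                                sep = "_"))
  new_fs_table(tibble::tibble(length = seq_len(length_cap), score = s), meta)
}

#' Look up per-fragment scores
#'
#' @param table An `fs_table`.
#' @param lengths Integer fragment lengths.
#' @return Numeric scores; lengths outside the table's support score 0.
#' @export
score_lookup <- function(table, lengths) {
  s <- numeric(length(lengths))
  ok <- lengths >= 1 & lengths <= nrow(table)
  s[ok] <- table$score[lengths[ok]]
  s
}
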