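# Patient-level (FS) and variant-level (VFS) fragmentation scores.

#' Patient-level fragmentation score (FS)
#'
#' Samples `n_sample` fragments (with replacement by default) from a
#' patient's fragment pool and reports the mean per-fragment score — the
#' "mean fragmentation score per million fragments" at the default
#' `n_sample = 1e6`. With-replacement sampling is used even when the pool
#' is larger than `n_sample`, so behaviour is uniform across pool sizes.
#'
#' @param pool A non-empty [fragment_pool()].
#' @param table An `fs_table` from [build_score_table()].
#' @param n_sample Number of fragments sampled (default one million).
#' @param replace Sample with replacement (default).
#' @param seed Optional seed; the FS is deterministic given pool, table and
#'   seed.
#' @return One-row tibble: `sample_id`, `fs`, `n_sampled`.
#' @export
patient_fs <- function(pool, table, n_sample = 1e6, replace = TRUE,
                       seed = NULL) {
  if (nrow(pool) == 0) abort("patient_fs() needs a non-empty pool")
  assert_scalar_number(n_sample, "n_sample", min = 1)
  drawn <- with_seed_if(seed, pool_draw(pool, n_sample, replace = replace))
  fs <- sum(drawn$count * score_lookup(table, drawn$length)) / n_sample
  tibble::tibble(sample_id = attr(pool, "sample_id") %||% "sample",
                 fs = fs, n_sampled = as.integer(n_sample))
}

#' Exact expectation of the patient FS
#'
#' The closed form `sum_L p_pool(L) * s(L)` that [patient_fs()] estimates
#' by sampling; used for unbiasedness checks and fast exact scoring.
#'
#' @inheritParams patient_fs
#' @return A single number.
#' @export
patient_fs_expected <- function(pool, table) {
  if (nrow(pool) == 0) abort("patient_fs_expected() needs a non-empty pool")
  sum(pool$count * score_lookup(table, pool$length)) / pool_size(pool)
}

#' FS positivity threshold from non-malignant controls
#'
#' Mean plus two sample standard deviations of the control FS values.
#'
#' @param control_fs Numeric FS values of at least two non-malignant
#'   control samples.
#' @return The threshold (a single number).
#' @examples
#' fs_threshold(c(-0.7, -0.6, -0.65)) # -0.55
#' @export
fs_threshold <- function(control_fs) {
  if (length(control_fs) < 2) abort("fs_threshold() needs >= 2 control FS values")
  mean(control_fs) + 2 * sd(control_fs)
}

#' FS-based MRD call
#'
#' Positive iff `fs` is strictly greater than the threshold.
#'
#' @param fs Numeric FS value(s).
#' @param threshold Threshold from [fs_threshold()].
#' @return Logical vector.
#' @export
fs_call <- function(fs, threshold) fs > threshold

#' Variant-level fragmentation score (VFS)
#'
#' Averages the per-fragment score over all fragments supporting each
#' variant. Pre- and postoperative supporting fragments of the same variant
#' are pooled (analysed collectively) so more fragments contribute per
#' variant. Variants with no supporting fragments get `NA` VFS.
#'
#' @param support Supporting-fragment tibble (`patient_id`, `compartment`,
#'   `chrom`, `pos`, `ref`, `alt`, `fragment_length`), one row per
#'   alt-supporting fragment.
#' @param table An `fs_table`.
#' @return Tibble with one row per variant: key columns, `vfs`, `n_reads`.
#' @export
variant_fs <- function(support, table) {
  support <- tibble::as_tibble(support)
  support |>
    dplyr::mutate(.s = score_lookup(table, .data$fragment_length)) |>
    dplyr::summarise(vfs = mean(.s), n_reads = dplyr::n(),
                     .by = c("patient_id", "chrom", "pos", "ref", "alt"))
}

# Per-(table, n) threshold cache; keyed on table id + draw parameters.
.vfs_cache <- new.env(parent = emptyenv())

#' Read-count-dependent VFS null thresholds
#'
#' For each read count `n`, draws `n` fragments from the pooled
#' non-malignant fragment pool `n_iter` times, computes the VFS of each
#' draw, and sets the threshold to the mean plus two standard deviations of
#' those null VFS values. Thresholds are cached per (score table, n,
#' n_iter, seed).
#'
#' @param nonmalignant_pool Pooled control [fragment_pool()].
#' @param table An `fs_table`.
#' @param n_reads Integer vector of read counts to compute thresholds for.
#' @param n_iter Null draws per read count (default 1000).
#' @param seed Optional seed.
#' @return Tibble with `n_reads` and `threshold`.
#' @export
vfs_null_thresholds <- function(nonmalignant_pool, table, n_reads,
                                n_iter = 1000, seed = NULL) {
  if (n_iter < 2) abort("n_iter must be >= 2")
  if (any(n_reads < 1)) abort("n_reads must be >= 1")
  n_reads <- as.integer(n_reads)
  meta <- fs_table_meta(table)
  key0 <- paste(meta$table_id %||% "anon", n_iter, seed %||% "NULL",
                pool_size(nonmalignant_pool),
                sum(nonmalignant_pool$length *
                      as.numeric(nonmalignant_pool$count)), sep = "|")
  thr <- vapply(n_reads, function(n) {
    key <- paste(key0, n, sep = "|")
    if (!is.null(.vfs_cache[[key]])) return(.vfs_cache[[key]])
    val <- with_seed_if(if (is.null(seed)) NULL else seed + n, {
      draws <- sample(score_lookup(table, nonmalignant_pool$length),
                      n * n_iter, replace = TRUE,
                      prob = nonmalignant_pool$count)
      m <- matrix(draws, nrow = n)
      v <- colMeans(m)
      mean(v) + 2 * sd(v)
    })
    .vfs_cache[[key]] <- val
    val
  }, numeric(1))
  tibble::tibble(n_reads = n_reads, threshold = thr)
}

#' Classify variants as tumour- or blood-derived by VFS
#'
#' Variants with fewer than `min_reads` supporting fragments are
#' `indeterminate`; otherwise `tumour` if the VFS strictly exceeds the
#' read-count-matched non-malignant null threshold, else `blood`. The
#' default `min_reads = 8` is the cut-off at which the +1/-1/0 performance
#' score of the classifier is maximised.
#'
#' @param vfs_tbl Output of [variant_fs()].
#' @param nonmalignant_pool Pooled control [fragment_pool()].
#' @param table An `fs_table`.
#' @param min_reads Minimum supporting reads for a determinate call.
#' @param n_iter,seed Passed to [vfs_null_thresholds()].
#' @return `vfs_tbl` with `threshold` and `classification`
#'   (`tumour`/`blood`/`indeterminate`) columns added.
#' @export
classify_variants <- function(vfs_tbl, nonmalignant_pool, table,
                              min_reads = 8, n_iter = 1000, seed = NULL) {
  vfs_tbl <- tibble::as_tibble(vfs_tbl)
  det <- !is.na(vfs_tbl$n_reads) & vfs_tbl$n_reads >= min_reads
  thr <- rep(NA_real_, nrow(vfs_tbl))
  if (any(det)) {
    lut <- vfs_null_thresholds(nonmalignant_pool, table,
                               sort(unique(vfs_tbl$n_reads[det])),
                               n_iter = n_iter, seed = seed)
    thr[det] <- lut$threshold[match(vfs_tbl$n_reads[det], lut$n_reads)]
  }
  cls <- dplyr::case_when(
    !det ~ "indeterminate",
    vfs_tbl$vfs > thr ~ "tumour",
    .default = "blood")
  dplyr::mutate(vfs_tbl, threshold = thr, classification = cls)
}

#' Performance score of a VFS classification
#'
#' +1 per correctly classified variant, -1 per misclassified variant, 0 per
#' indeterminate variant.
#'
#' @param classification Character vector in
#'   `{"tumour","blood","indeterminate"}`.
#' @param truth Character vector in `{"tumour","blood"}`, same length.
#' @return Integer score.
#' @export
vfs_performance_score <- function(classification, truth) {
  if (length(classification) != length(truth)) {
    abort("classification and truth must have the same length")
  }
  sum(dplyr::case_when(
    classification == "indeterminate" ~ 0L,
    classification == truth ~ 1L,
    .default = -1L))
}
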