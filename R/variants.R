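# Compartment-based variant classification and the tumour-informed
# variant-tracking MRD caller with grid-search cut-off optimisation.

#' Classify baseline variants by compartment pattern
#'
#' Applies the compartment rules per patient and variant: a variant
#' detected (pipeline-called) in the blood cell pellet (BCP) is `germline`
#' if also detected in tumour tissue, otherwise `chip` (clonal
#' haematopoiesis); a non-BCP variant detected in tissue or preoperative
#' plasma is `trackable`; a variant seen only in postoperative plasma is
#' `uninformative`. Germline and CHIP variants are excluded from all
#' downstream MRD analysis; only trackable variants are traced
#' postoperatively.
#'
#' "Detected" means `pipeline_called = TRUE` in that compartment — the
#' lowered read cut-offs apply only to postoperative tracking of variants
#' already informed at baseline.
#'
#' @param variants Variant observation tibble (see [read_variant_table()]),
#'   one or many patients.
#' @return Tibble with one row per (patient, variant): key columns and
#'   `label` in `{"germline","chip","trackable","uninformative"}`.
#' @export
classify_baseline_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  variants |>
    dplyr::summarise(
      in_bcp = any(.data$compartment == "bcp" & .data$pipeline_called),
      in_tissue = any(.data$compartment == "tissue" & .data$pipeline_called),
      in_preop = any(.data$compartment == "preop_plasma" & .data$pipeline_called),
      .by = c("patient_id", "chrom", "pos", "ref", "alt")) |>
    dplyr::mutate(label = dplyr::case_when(
      .data$in_bcp & .data$in_tissue ~ "germline",
      .data$in_bcp ~ "chip",
      .data$in_tissue | .data$in_preop ~ "trackable",
      .default = "uninformative")) |>
    dplyr::select(!dplyr::all_of(c("in_bcp", "in_tissue", "in_preop")))
}

#' Count trackable variants detected in postoperative plasma
#'
#' A trackable variant counts as detected when its postoperative alt read
#' count reaches the lowered cut-off `read_cutoff`, or when the upstream
#' pipeline already called it there (a pipeline call outranks the raw-read
#' threshold).
#'
#' @param variants Variant observation tibble for one or more patients.
#' @param read_cutoff Minimum postoperative alt reads `r >= 1`.
#' @param classes Optional precomputed [classify_baseline_variants()]
#'   output (recomputed otherwise).
#' @param count_pipeline_calls Count pipeline-called postoperative variants
#'   regardless of `read_cutoff` (default TRUE).
#' @return Tibble with `patient_id` and `n_detected` (patients with no
#'   trackable variants get 0).
#' @export
count_detected_variants <- function(variants, read_cutoff, classes = NULL,
                                    count_pipeline_calls = TRUE) {
  if (read_cutoff < 1) abort("read_cutoff must be >= 1")
  variants <- tibble::as_tibble(variants)
  classes <- classes %||% classify_baseline_variants(variants)
  key <- c("patient_id", "chrom", "pos", "ref", "alt")
  postop <- variants |>
    dplyr::filter(.data$compartment == "postop_plasma") |>
    dplyr::inner_join(dplyr::filter(classes, .data$label == "trackable")[key],
                      by = key)
  hits <- postop |>
    dplyr::filter(.data$alt_reads >= read_cutoff |
                    (count_pipeline_calls & .data$pipeline_called)) |>
    dplyr::summarise(n_detected = dplyr::n(), .by = "patient_id")
  tibble::tibble(patient_id = unique(variants$patient_id)) |>
    dplyr::left_join(hits, by = "patient_id") |>
    dplyr::mutate(n_detected = as.integer(dplyr::coalesce(.data$n_detected, 0L)))
}

#' Variant-tracking MRD call
#'
#' MRD-positive iff at least `min_variants` baseline-informed variants are
#' detected in the postoperative plasma.
#'
#' @param n_detected Integer count(s) of detected trackable variants.
#' @param min_variants Minimum number of detected variants `k >= 1`.
#' @return Logical vector.
#' @export
variant_mrd_call <- function(n_detected, min_variants) {
  if (any(min_variants < 1)) abort("min_variants must be >= 1")
  n_detected >= min_variants
}

#' Grid-search optimisation of variant-tracking cut-offs
#'
#' Exhaustively evaluates the read cut-off `r` (1-8) crossed with the
#' minimum detected-variant count `k` (1-6) and returns the pair with the
#' highest concordance (accuracy, `(TP+TN)/N`) with recurrence status.
#' Ties are broken deterministically: highest accuracy, then larger `r`
#' (stricter per-read evidence, minimising false positives), then smaller
#' `k` (never demanding more concordant variants than the training data
#' requires, which preserves sensitivity for held-out patients with few
#' trackable variants).
#'
#' @param variants Variant observation tibble for the training patients.
#' @param metadata Cohort metadata with `patient_id` and `recurrence`.
#' @param read_cutoffs,min_variants Grid ranges (defaults 1:8 and 1:6).
#' @param count_pipeline_calls Passed to [count_detected_variants()].
#' @return List of class `mrd_cutoffs`: `read_cutoff`, `min_variants`,
#'   `accuracy`, and the full `grid` tibble.
#' @export
optimize_cutoffs <- function(variants, metadata, read_cutoffs = 1:8,
                             min_variants = 1:6,
                             count_pipeline_calls = TRUE) {
  metadata <- tibble::as_tibble(metadata)
  if (length(unique(metadata$recurrence)) < 2) {
    warn("all training patients share one recurrence label; returning default cut-offs (r=1, k=1)")
    return(structure(list(read_cutoff = 1L, min_variants = 1L,
                          accuracy = NA_real_, grid = tibble::tibble()),
                     class = "mrd_cutoffs"))
  }
  classes <- classify_baseline_variants(variants)
  counts <- purrr::map(read_cutoffs, function(r) {
    count_detected_variants(variants, r, classes = classes,
                            count_pipeline_calls = count_pipeline_calls) |>
      dplyr::mutate(read_cutoff = as.integer(r))
  }) |> purrr::list_rbind() |>
    tidyr::complete(patient_id = metadata$patient_id,
                    read_cutoff = as.integer(read_cutoffs),
                    fill = list(n_detected = 0L))
  grid <- tidyr::expand_grid(read_cutoff = as.integer(read_cutoffs),
                             min_variants = as.integer(min_variants)) |>
    dplyr::inner_join(counts, by = "read_cutoff",
                      relationship = "many-to-many") |>
    dplyr::inner_join(metadata[, c("patient_id", "recurrence")],
                      by = "patient_id") |>
    dplyr::mutate(call = .data$n_detected >= .data$min_variants) |>
    dplyr::summarise(accuracy = mean(.data$call == .data$recurrence),
                     .by = c("read_cutoff", "min_variants"))
  best <- grid |>
    dplyr::arrange(dplyr::desc(.data$accuracy), dplyr::desc(.data$read_cutoff),
                   .data$min_variants) |>
    dplyr::slice(1)
  structure(list(read_cutoff = best$read_cutoff,
                 min_variants = best$min_variants,
                 accuracy = best$accuracy, grid = grid),
            class = "mrd_cutoffs")
}

#' @export
print.mrd_cutoffs <- function(x, ...) {
  cat(sprintf("<mrd_cutoffs> read_cutoff r=%d, min_variants k=%d (training concordance %.3f)\n",
              x$read_cutoff, x$min_variants, x$accuracy))
  invisible(x)
}
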