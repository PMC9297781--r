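# Shared fixtures, built in code at test time.

tumour_prof <- fragment_profile("tumour")
nontumour_prof <- fragment_profile("nontumour")

# A small score table contrasting the two default profiles; cached per run.
small_score_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tum <- sample_fragment_pool(tumour_prof, 2e4, seed = 101,
                                  source = "tumour_reference")
      non <- sample_fragment_pool(nontumour_prof, 2e5, seed = 102)
      tab <<- build_score_table(tum, non, n_boot = 50, n_sample = 5000,
                                seed = 103)
    }
    tab
  }
})

# A reduced synthetic cohort for unit tests: 12 patients, 5 recurrent.
small_cohort_config <- function(...) {
  cohort_config(n_patients = 12, n_recurrent = 5, n_controls = 5,
                control_pool_size = 5e4, patient_pool_size = 5e4,
                n_trackable_range = c(3, 8), n_chip_range = c(1, 4),
                n_germline_range = c(1, 3), mean_depth = 2000, ...)
}

small_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- sample_cohort(small_cohort_config(), seed = 2024)
    co
  }
})

# Hand-built variant observation rows.
variant_row <- function(patient_id, compartment, pos, alt_reads,
                        pipeline_called = alt_reads >= 5, depth = 1000,
                        chrom = "chr1", ref = "A", alt = "T") {
  tibble::tibble(patient_id = patient_id, compartment = compartment,
                 chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 alt_reads = as.integer(alt_reads),
                 depth = as.integer(depth),
                 pipeline_called = pipeline_called)
}

# A cohort engineered so that exactly one grid point is perfect:
# recurrent patients have two trackable variants at 3 postop reads each,
# non-recurrent have two at 2 reads plus one at 3 reads.
engineered_cohort <- function() {
  rows <- purrr::map(1:12, function(i) {
    id <- sprintf("E%02d", i)
    rec <- i <= 6
    alt <- if (rec) c(3L, 3L, 0L) else c(2L, 2L, 3L)
    purrr::map(1:3, function(v) {
      dplyr::bind_rows(
        variant_row(id, "tissue", v * 10, 300),
        variant_row(id, "postop_plasma", v * 10, alt[v],
                    pipeline_called = FALSE))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  meta <- tibble::tibble(patient_id = sprintf("E%02d", 1:12),
                         recurrence = rep(c(TRUE, FALSE), each = 6))
  list(variants = rows, metadata = meta)
}

# A cross-validation result object built by hand (for majority-rule tests).
fake_cv <- function(combined, n_repeats = 20) {
  structure(list(
    counts = tibble::tibble(
      patient_id = sprintf("P%02d", seq_along(combined)),
      combined = as.integer(combined), fs_only = as.integer(combined),
      variant_only = as.integer(combined),
      n_predictions = n_repeats),
    calls = tibble::tibble(), fits = tibble::tibble(),
    n_repeats = n_repeats, n_folds = 10), class = "mrd_cv")
}
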