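# Compartment classification and the variant-tracking MRD caller.

test_that("compartment patterns map to germline/CHIP/trackable/uninformative", {
  obs <- dplyr::bind_rows(
    variant_row("P1", "bcp", 10, 400),           # + tissue -> germline
    variant_row("P1", "tissue", 10, 300),
    variant_row("P1", "preop_plasma", 10, 200),
    variant_row("P1", "bcp", 20, 100),           # BCP only -> chip
    variant_row("P1", "preop_plasma", 20, 50),
    variant_row("P1", "tissue", 30, 250),        # tissue -> trackable
    variant_row("P1", "preop_plasma", 40, 60),   # preop -> trackable
    variant_row("P1", "postop_plasma", 50, 30))  # postop only -> uninformative
  cls <- classify_baseline_variants(obs)
  lab <- setNames(cls$label, cls$pos)
  expect_equal(lab[["10"]], "germline")
  expect_equal(lab[["20"]], "chip")
  expect_equal(lab[["30"]], "trackable")
  expect_equal(lab[["40"]], "trackable")
  expect_equal(lab[["50"]], "uninformative")
})

test_that("a BCP-detected variant never reaches the trackable set", {
  co <- small_cohort()
  cls <- classify_baseline_variants(co$variants)
  bcp_detected <- co$variants |>
    dplyr::filter(compartment == "bcp", pipeline_called) |>
    dplyr::distinct(patient_id, chrom, pos, ref, alt)
  joined <- dplyr::inner_join(
    cls, bcp_detected, by = c("patient_id", "chrom", "pos", "ref", "alt"))
  expect_true(all(joined$label %in% c("germline", "chip")))
  expect_true(all(cls$label %in% c("germline", "chip", "trackable",
                                   "uninformative")))
})

test_that("detected-variant counts honour the read cut-off and pipeline rescue", {
  obs <- dplyr::bind_rows(
    # four trackable variants (tissue-informed), postop alt reads 0,1,3,8
    purrr::map(1:4, function(i) variant_row("P1", "tissue", i * 10, 300)),
    variant_row("P1", "postop_plasma", 10, 0, pipeline_called = FALSE),
    variant_row("P1", "postop_plasma", 20, 1, pipeline_called = FALSE),
    variant_row("P1", "postop_plasma", 30, 3, pipeline_called = FALSE),
    variant_row("P1", "postop_plasma", 40, 8, pipeline_called = FALSE))
  expect_equal(count_detected_variants(obs, 2)$n_detected, 2L)
  expect_equal(count_detected_variants(obs, 1)$n_detected, 3L)
  expect_equal(count_detected_variants(obs, 8)$n_detected, 1L)

  # counts are non-increasing in the cut-off
  counts <- vapply(1:8, function(r) count_detected_variants(obs, r)$n_detected,
                   integer(1))
  expect_true(all(diff(counts) <= 0))

  # a pipeline-called postop variant counts regardless of the raw cut-off
  obs2 <- dplyr::bind_rows(
    variant_row("P2", "tissue", 100, 300),
    variant_row("P2", "postop_plasma", 100, 2, pipeline_called = TRUE))
  expect_equal(count_detected_variants(obs2, 8)$n_detected, 1L)
  expect_equal(count_detected_variants(obs2, 8,
                                       count_pipeline_calls = FALSE)$n_detected,
               0L)
  expect_error(count_detected_variants(obs, 0), ">= 1")
})

test_that("counts match generator truth on a synthetic patient", {
  co <- small_cohort()
  pid <- co$metadata$patient_id[1]
  obs <- dplyr::filter(co$variants, patient_id == pid)
  truth <- dplyr::filter(co$truth$variants, patient_id == pid,
                         origin == "tumour")
  postop <- dplyr::semi_join(
    dplyr::filter(obs, compartment == "postop_plasma"), truth,
    by = c("patient_id", "chrom", "pos", "ref", "alt"))
  for (r in c(1L, 5L, 20L)) {
    expect_equal(count_detected_variants(obs, r)$n_detected,
                 sum(postop$alt_reads >= r | postop$pipeline_called))
  }
})

test_that("the MRD call thresholds on the detected-variant count", {
  expect_false(any(variant_mrd_call(0L, 1:6)))
  expect_true(variant_mrd_call(3L, 3))
  expect_false(variant_mrd_call(2L, 3))
  expect_error(variant_mrd_call(2L, 0), ">= 1")
})

test_that("grid search returns the unique perfect cut-off pair (r=3, k=2)", {
  eng <- engineered_cohort()
  opt <- optimize_cutoffs(eng$variants, eng$metadata)
  expect_equal(opt$read_cutoff, 3L)
  expect_equal(opt$min_variants, 2L)
  expect_equal(opt$accuracy, 1)
  # only one perfect grid point
  expect_equal(sum(opt$grid$accuracy == 1), 1L)
})

test_that("grid search is an argmax over the exhaustively enumerated grid", {
  co <- small_cohort()
  opt <- optimize_cutoffs(co$variants, co$metadata)
  # independent brute-force enumeration
  cls <- classify_baseline_variants(co$variants)
  trackable <- cls[cls$label == "trackable", ]
  brute <- expand.grid(r = 1:8, k = 1:6)
  brute$acc <- mapply(function(r, k) {
    calls <- vapply(co$metadata$patient_id, function(pid) {
      keys <- trackable[trackable$patient_id == pid, ]
      po <- merge(as.data.frame(co$variants[
        co$variants$compartment == "postop_plasma", ]), as.data.frame(keys))
      sum(po$alt_reads >= r | po$pipeline_called) >= k
    }, logical(1))
    mean(calls == co$metadata$recurrence)
  }, brute$r, brute$k)
  expect_equal(opt$accuracy, max(brute$acc))
  expect_true(all(opt$accuracy >= opt$grid$accuracy))
  expect_equal(nrow(opt$grid), 48L)
})

test_that("full grid ties break to largest r, smallest k, and degenerate labels warn", {
  # no variants at all: every grid point has the same accuracy
  meta <- tibble::tibble(patient_id = c("A", "B"),
                         recurrence = c(FALSE, TRUE))
  empty <- variant_row("A", "tissue", 10, 300)[0, ]
  opt <- optimize_cutoffs(empty, meta)
  expect_equal(opt$read_cutoff, 8L)
  expect_equal(opt$min_variants, 1L)

  meta1 <- tibble::tibble(patient_id = c("A", "B"),
                          recurrence = c(TRUE, TRUE))
  expect_warning(opt1 <- optimize_cutoffs(empty, meta1), "default")
  expect_equal(opt1$read_cutoff, 1L)
  expect_equal(opt1$min_variants, 1L)
})
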