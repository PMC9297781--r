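# Combined model fitting, cross-validation, majority calls, evaluation.

cv_small <- local({
  cv <- NULL
  function() {
    if (is.null(cv)) {
      cv <<- run_ttfcv(small_cohort(), n_repeats = 3, n_folds = 4,
                       n_boot = 30, fs_n_sample = 1e5, seed = 99)
    }
    cv
  }
})

test_that("fitting rebuilds the reference and threshold from training data only", {
  co <- small_cohort()
  fit <- fit_mrd_model(co, n_boot = 30, fs_n_sample = 1e5, seed = 5)
  expect_s3_class(fit$table, "fs_table")
  expect_equal(fit$fs_threshold, fs_threshold(fit$control_fs))
  expect_true(fit$logic %in% c("AND", "OR"))
  expect_true(all(fit$tumour_pool_patients %in% fit$train_ids))
  # chosen logic attains the max of the two training accuracies
  expect_equal(unname(fit$training_accuracy[fit$logic]),
               max(fit$training_accuracy[c("AND", "OR")]))
  # AND is chosen on ties (or when strictly better)
  if (fit$training_accuracy["AND"] >= fit$training_accuracy["OR"]) {
    expect_equal(fit$logic, "AND")
  }
})

test_that("prediction combines the two calls under the fitted logic", {
  co <- small_cohort()
  fit <- fit_mrd_model(co, n_boot = 30, fs_n_sample = 1e5, seed = 6)
  pred <- predict(fit, co, seed = 7)
  expect_equal(pred$mrd_call,
               if (fit$logic == "AND") pred$fs_call & pred$variant_call
               else pred$fs_call | pred$variant_call)
  or_fit <- fit
  or_fit$logic <- "OR"
  pred_or <- predict(or_fit, co, seed = 7)
  expect_equal(pred_or$mrd_call, pred_or$fs_call | pred_or$variant_call)
  # (TRUE, FALSE) -> FALSE under AND, TRUE under OR
  mixed <- pred$fs_call & !pred$variant_call
  if (any(mixed)) {
    and_fit <- fit
    and_fit$logic <- "AND"
    expect_false(any(predict(and_fit, co, seed = 7)$mrd_call[mixed]))
    expect_true(all(pred_or$mrd_call[mixed]))
  }
  expect_error(cohort_pool(co, "nonexistent", "postop"), "no postop")
})

test_that("cross-validation predicts each patient once per repeat in 3-4 patient folds", {
  cv <- cv_small()
  expect_true(all(cv$counts$n_predictions == 3))
  per_repeat <- dplyr::count(cv$calls, repeat_idx, patient_id)
  expect_true(all(per_repeat$n == 1))
  fold_sizes <- vapply(cv$fits$test_ids, length, integer(1))
  expect_true(all(fold_sizes == 3))  # N = 12 over 4 folds
  expect_equal(nrow(cv$fits), 3 * 4)
})

test_that("held-out patients never feed the fold's tumour reference", {
  cv <- cv_small()
  leaks <- purrr::map2_int(cv$fits$tumour_pool_patients, cv$fits$test_ids,
                           ~ length(intersect(.x, .y)))
  expect_true(all(leaks == 0))
})

test_that("cross-validation is reproducible for a fixed seed", {
  co <- small_cohort()
  cv2 <- run_ttfcv(co, n_repeats = 1, n_folds = 4, n_boot = 10,
                   fs_n_sample = 1e4, seed = 123)
  cv3 <- run_ttfcv(co, n_repeats = 1, n_folds = 4, n_boot = 10,
                   fs_n_sample = 1e4, seed = 123)
  expect_equal(cv2$counts, cv3$counts)
  expect_equal(cv2$calls$fs, cv3$calls$fs)
  expect_error(run_ttfcv(co, n_folds = 40, seed = 1), "cannot exceed")
})

test_that("stratified folds balance recurrence labels and still cover every patient", {
  co <- small_cohort()
  cv <- run_ttfcv(co, n_repeats = 2, n_folds = 4, n_boot = 10,
                  fs_n_sample = 1e4, stratify = TRUE, seed = 55)
  expect_true(all(cv$counts$n_predictions == 2))
  rec <- setNames(co$metadata$recurrence, co$metadata$patient_id)
  n_rec_per_fold <- vapply(cv$fits$test_ids,
                           function(ids) sum(rec[ids]), numeric(1))
  # 5 recurrent over 4 folds: every fold holds 1 or 2 recurrent patients
  expect_true(all(n_rec_per_fold %in% c(1, 2)))
  fold_sizes <- vapply(cv$fits$test_ids, length, integer(1))
  expect_true(all(fold_sizes == 3))
})

test_that("the majority rule switches at more than half the repeats", {
  cv <- fake_cv(c(11L, 10L, 0L, 20L), n_repeats = 20)
  mc <- majority_call(cv)
  expect_equal(mc$mrd_call, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(majority_call(cv, min_positive = 15)$mrd_call,
               c(FALSE, FALSE, FALSE, TRUE))
})

test_that("FS shuffling permutes pools bijectively and leaves variants untouched", {
  co <- small_cohort()
  sh <- shuffle_fs_control(co, seed = 31)
  perm <- attr(sh, "fs_permutation")
  expect_setequal(unname(perm), co$metadata$patient_id)
  expect_equal(sort(names(perm)), sort(co$metadata$patient_id))
  expect_identical(sh$variants, co$variants)
  expect_identical(sh$support, co$support)
  # pools moved with the permutation
  pid <- co$metadata$patient_id[1]
  expect_equal(
    tibble::as_tibble(cohort_pool(sh, unname(perm[pid]), "postop")),
    tibble::as_tibble(cohort_pool(co, pid, "postop")))
  sh2 <- shuffle_fs_control(co, seed = 31)
  expect_identical(attr(sh2, "fs_permutation"), perm)
})

test_that("evaluation reproduces hand-computed confusion metrics", {
  n <- 36
  meta <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:n),
    recurrence = rep(c(TRUE, FALSE), c(14, 22)),
    followup_months = c(runif(14, 5, 20), runif(22, 18, 36)))
  # TP = 9, FN = 5, FP = 4, TN = 18
  calls <- tibble::tibble(
    patient_id = meta$patient_id,
    mrd_call = c(rep(TRUE, 9), rep(FALSE, 5), rep(TRUE, 4), rep(FALSE, 18)))
  ev <- evaluate_mrd(calls, meta)
  expect_equal(unname(ev$confusion), c(9, 4, 18, 5))
  g <- glance(ev)
  expect_equal(g$accuracy, 27 / 36)
  expect_equal(g$npv, 18 / 23)
  expect_equal(g$sensitivity, 9 / 14)
  expect_equal(g$specificity, 18 / 22)
  expect_true(all(tidy(ev)$conf_low <= tidy(ev)$estimate &
                    tidy(ev)$estimate <= tidy(ev)$conf_high))
  expect_true(is.finite(ev$logrank$p_value))

  # perfect calls
  ev2 <- evaluate_mrd(
    tibble::tibble(patient_id = meta$patient_id,
                   mrd_call = meta$recurrence), meta)
  expect_equal(glance(ev2)$accuracy, 1)
  expect_equal(glance(ev2)$npv, 1)
})

test_that("log-rank is ~1 for identical survival groups and NA for one group", {
  meta <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:20),
    recurrence = rep(c(TRUE, FALSE), 10),
    followup_months = rep(c(10, 30), 10))
  calls <- tibble::tibble(patient_id = meta$patient_id,
                          mrd_call = rep(c(TRUE, FALSE), each = 10))
  # both predicted groups contain the same survival experience
  ev <- evaluate_mrd(calls, meta)
  expect_gt(ev$logrank$p_value, 0.9)

  one <- tibble::tibble(patient_id = meta$patient_id, mrd_call = FALSE)
  ev1 <- evaluate_mrd(one, meta)
  expect_true(is.na(ev1$logrank$p_value))
  expect_match(ev1$logrank$note, "one predicted group")
  expect_null(ev1$survfit)
})

test_that("FS group-comparison utilities return sane statistics", {
  x <- c(-0.47, -0.54, -0.37, -0.5, -0.41)
  y <- c(-0.67, -0.7, -0.56, -0.66, -0.6)
  w <- compare_fs_groups(x, y)
  expect_equal(w$test, "wilcoxon rank-sum")
  expect_lt(w$p_value, 0.05)
  p <- compare_fs_groups(x, y, paired = TRUE)
  expect_equal(p$test, "paired t-test")
  expect_true(is.finite(p$statistic))
})
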