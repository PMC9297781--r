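# Combined FS + variant-tracking MRD classifier, its 20x repeated 10-fold
# cross-validation with per-fold reference rebuilding, majority-vote final
# calls, and the evaluation statistics.

tumour_reference_pool <- function(cohort, patient_ids) {
  classes <- classify_baseline_variants(
    dplyr::filter(cohort$variants, .data$patient_id %in% patient_ids))
  key <- c("patient_id", "chrom", "pos", "ref", "alt")
  lens <- cohort$support |>
    dplyr::filter(.data$patient_id %in% patient_ids,
                  .data$compartment %in% c("preop_plasma", "postop_plasma")) |>
    dplyr::inner_join(dplyr::filter(classes, .data$label == "trackable")[key],
                      by = key)
  if (nrow(lens) == 0) {
    abort("no tumour-tagged fragments (trackable-variant supporting reads) in the training set")
  }
  pool <- fragment_pool(lens$fragment_length, sample_id = "tumour_reference",
                        source = "tumour_reference")
  attr(pool, "patient_ids") <- sort(unique(lens$patient_id))
  pool
}

#' Fit the combined FS + variant MRD model
#'
#' Rebuilds the fragment-score reference from the training patients'
#' tumour-tagged fragments only (the supporting reads of their trackable
#' variants), recomputes all control FS values and the FS threshold,
#' optimises the variant-tracking cut-offs on the training data, and
#' selects the combination logic — both calls required (AND) or one
#' sufficient (OR) — that maximises training accuracy (ties go to AND, the
#' specificity-first choice).
#'
#' @param cohort An `mrd_cohort`.
#' @param train_ids Patient ids to train on (default: all).
#' @param n_boot Bootstrap iterations for the per-fit score table (default
#'   100, the cross-validation setting; use 1000 for a final model).
#' @param fs_n_sample Fragments sampled per FS (default one million).
#' @param n_sample,cap,min_count,length_cap Score-table build parameters
#'   (see [build_score_table()]).
#' @param seed Optional seed for the whole fit.
#' @return An `mrd_model`: score table, control FS values, FS threshold,
#'   cut-offs, logic, and training calls.
#' @export
fit_mrd_model <- function(cohort, train_ids = NULL, n_boot = 100,
                          fs_n_sample = 1e6, n_sample = 10000, cap = 5,
                          min_count = 20, length_cap = 600, seed = NULL) {
  train_ids <- train_ids %||% cohort$metadata$patient_id
  meta <- dplyr::filter(cohort$metadata, .data$patient_id %in% train_ids)
  if (length(unique(meta$recurrence)) < 2) {
    warn("training set has a single recurrence label; cut-offs fall back to defaults")
  }
  with_seed_if(seed, {
    tumour_pool <- tumour_reference_pool(cohort, train_ids)
    nontumour_pool <- control_pools(cohort, merged = TRUE)
    table <- build_score_table(tumour_pool, nontumour_pool, n_boot = n_boot,
                               n_sample = n_sample, cap = cap,
                               min_count = min_count,
                               length_cap = length_cap)
    ctl_fs <- vapply(control_pools(cohort),
                     function(p) patient_fs(p, table, fs_n_sample)$fs,
                     numeric(1))
    threshold <- fs_threshold(ctl_fs)
    train_vars <- dplyr::filter(cohort$variants,
                                .data$patient_id %in% train_ids)
    cutoffs <- optimize_cutoffs(train_vars, meta)
    train_fs <- vapply(meta$patient_id, function(id) {
      patient_fs(cohort_pool(cohort, id, "postop"), table, fs_n_sample)$fs
    }, numeric(1))
    fs_calls <- fs_call(train_fs, threshold)
    det <- count_detected_variants(train_vars, cutoffs$read_cutoff)
    n_det <- det$n_detected[match(meta$patient_id, det$patient_id)]
    n_det[is.na(n_det)] <- 0L
    var_calls <- variant_mrd_call(n_det, cutoffs$min_variants)
    acc_and <- mean((fs_calls & var_calls) == meta$recurrence)
    acc_or <- mean((fs_calls | var_calls) == meta$recurrence)
    logic <- if (acc_and >= acc_or) "AND" else "OR"
    training <- tibble::tibble(patient_id = meta$patient_id,
                               fs = unname(train_fs),
                               fs_call = unname(fs_calls),
                               variant_call = unname(var_calls),
                               recurrence = meta$recurrence)
    structure(list(
      table = table, control_fs = unname(ctl_fs), fs_threshold = threshold,
      cutoffs = cutoffs, logic = logic,
      training = training,
      training_accuracy = c(AND = acc_and, OR = acc_or,
                            fs_only = mean(fs_calls == meta$recurrence),
                            variant_only = mean(var_calls == meta$recurrence)),
      fs_n_sample = fs_n_sample,
      train_ids = sort(train_ids),
      tumour_pool_patients = attr(tumour_pool, "patient_ids")),
      class = "mrd_model")
  })
}

#' @export
print.mrd_model <- function(x, ...) {
  cat(sprintf("<mrd_model> logic %s, FS threshold %.4f, r=%d, k=%d (trained on %d patients)\n",
              x$logic, x$fs_threshold, x$cutoffs$read_cutoff,
              x$cutoffs$min_variants, length(x$train_ids)))
  invisible(x)
}

combine_calls <- function(fs_calls, var_calls, logic) {
  if (logic == "AND") fs_calls & var_calls else fs_calls | var_calls
}

#' Predict MRD status for patients with a fitted model
#'
#' Computes each patient's postoperative FS against the fitted score table
#' and threshold, the detected trackable-variant count against the fitted
#' cut-offs, and combines the two calls under the fitted logic.
#'
#' @param object An `mrd_model` from [fit_mrd_model()].
#' @param cohort An `mrd_cohort` holding the patients' postoperative pools
#'   and variant tables.
#' @param patient_ids Patients to predict (default: all in `cohort`).
#' @param seed Optional seed for the FS sampling.
#' @param ... Unused.
#' @return Tibble: `patient_id`, `fs`, `fs_call`, `n_detected`,
#'   `variant_call`, `mrd_call`.
#' @export
predict.mrd_model <- function(object, cohort,
                              patient_ids = cohort$metadata$patient_id,
                              seed = NULL, ...) {
  with_seed_if(seed, {
    fs <- vapply(patient_ids, function(id) {
      patient_fs(cohort_pool(cohort, id, "postop"), object$table,
                 object$fs_n_sample)$fs
    }, numeric(1))
    vars <- dplyr::filter(cohort$variants, .data$patient_id %in% patient_ids)
    counts <- count_detected_variants(vars, object$cutoffs$read_cutoff)
    n_det <- counts$n_detected[match(patient_ids, counts$patient_id)]
    n_det[is.na(n_det)] <- 0L
    fs_calls <- unname(fs_call(fs, object$fs_threshold))
    var_calls <- variant_mrd_call(n_det, object$cutoffs$min_variants)
    tibble::tibble(patient_id = patient_ids, fs = unname(fs),
                   fs_call = fs_calls, n_detected = n_det,
                   variant_call = var_calls,
                   mrd_call = combine_calls(fs_calls, var_calls,
                                            object$logic))
  })
}

make_folds <- function(ids, n_folds, strata = NULL) {
  n <- length(ids)
  if (n_folds > n) abort("n_folds cannot exceed the number of patients")
  if (is.null(strata)) {
    sizes <- rep(n %/% n_folds, n_folds)
    extra <- n %% n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    return(split(sample(ids), rep(seq_len(n_folds), sizes)))
  }
  # stratified: deal each stratum's shuffled members round-robin onto a
  # shuffled fold order, keeping label balance and near-equal sizes
  assign <- integer(n)
  offset <- sample.int(n_folds, 1L) - 1L
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    assign[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
    offset <- offset + length(idx)
  }
  split(ids, assign)
}

#' Repeated k-fold cross-validation of the combined MRD model
#'
#' The standard evaluation scheme: per repeat, patients are randomly
#' partitioned into `n_folds` folds of near-equal size (3 or 4 patients at
#' N = 36); each fold is held out once while the model — score table,
#' control FS, FS threshold, variant cut-offs, and AND/OR logic — is
#' refitted from scratch on the remaining folds and applied to the held-out
#' patients. Positive predictions are counted per patient across the
#' `n_repeats` repeats, separately for the combined call and the FS-only /
#' variant-only channels.
#'
#' @param cohort An `mrd_cohort`.
#' @param n_repeats,n_folds Cross-validation scheme (defaults 20 and 10).
#' @param n_boot Bootstrap iterations per per-fold score-table rebuild
#'   (default 100).
#' @param fs_n_sample Fragments per FS evaluation.
#' @param stratify Balance recurrence labels across folds (default FALSE:
#'   plain random partitions).
#' @param seed Seed for the whole procedure (one stream; partitions and
#'   fold fits consume it sequentially).
#' @return An `mrd_cv`: `counts` (per patient, positive counts per
#'   modality), `calls` (per repeat x patient), `fits` (per repeat x fold
#'   fitted parameters and an audit of which patients fed the score
#'   table), `n_repeats`, `n_folds`.
#' @export
run_ttfcv <- function(cohort, n_repeats = 20, n_folds = 10, n_boot = 100,
                      fs_n_sample = 1e6, stratify = FALSE, seed = NULL) {
  ids <- cohort$metadata$patient_id
  strata <- if (stratify) cohort$metadata$recurrence else NULL
  with_seed_if(seed, {
    reps <- purrr::map(seq_len(n_repeats), function(r) {
      folds <- make_folds(ids, n_folds, strata = strata)
      purrr::imap(folds, function(test_ids, fold_name) {
        fit <- fit_mrd_model(cohort, train_ids = setdiff(ids, test_ids),
                             n_boot = n_boot, fs_n_sample = fs_n_sample)
        pred <- predict(fit, cohort, patient_ids = test_ids)
        list(
          calls = dplyr::mutate(pred, repeat_idx = r,
                                fold = as.integer(fold_name)),
          fit = tibble::tibble(
            repeat_idx = r, fold = as.integer(fold_name),
            fs_threshold = fit$fs_threshold,
            read_cutoff = fit$cutoffs$read_cutoff,
            min_variants = fit$cutoffs$min_variants,
            logic = fit$logic,
            test_ids = list(sort(test_ids)),
            tumour_pool_patients = list(fit$tumour_pool_patients)))
      })
    })
    flat <- purrr::list_flatten(reps)
    calls <- purrr::list_rbind(purrr::map(flat, "calls"))
    fits <- purrr::list_rbind(purrr::map(flat, "fit"))
    counts <- calls |>
      dplyr::summarise(
        combined = sum(.data$mrd_call),
        fs_only = sum(.data$fs_call),
        variant_only = sum(.data$variant_call),
        n_predictions = dplyr::n(), .by = "patient_id") |>
      dplyr::arrange(.data$patient_id)
    structure(list(counts = counts, calls = calls, fits = fits,
                   n_repeats = n_repeats, n_folds = n_folds),
              class = "mrd_cv")
  })
}

#' @export
print.mrd_cv <- function(x, ...) {
  cat(sprintf("<mrd_cv> %d repeats x %d folds, %d patients\n",
              x$n_repeats, x$n_folds, nrow(x$counts)))
  invisible(x)
}

#' Majority-vote final MRD calls from cross-validation
#'
#' A patient is called positive when predicted positive in more than half
#' of the repeats — at least 11 of 20 under the default scheme.
#'
#' @param cv An `mrd_cv` from [run_ttfcv()].
#' @param modality `"combined"` (default), `"fs_only"` or `"variant_only"`.
#' @param min_positive Votes required for a positive call (default
#'   `floor(n_repeats / 2) + 1`).
#' @return Tibble: `patient_id`, `positive_count`, `mrd_call`.
#' @export
majority_call <- function(cv, modality = c("combined", "fs_only",
                                           "variant_only"),
                          min_positive = NULL) {
  modality <- match.arg(modality)
  min_positive <- min_positive %||% (cv$n_repeats %/% 2 + 1L)
  tibble::tibble(patient_id = cv$counts$patient_id,
                 positive_count = cv$counts[[modality]],
                 mrd_call = cv$counts[[modality]] >= min_positive)
}

#' Negative-control cohort with permuted patient FS
#'
#' Reassigns each patient's postoperative fragment pool (hence their FS) to
#' a uniformly random other patient, leaving all variant data untouched —
#' the randomised-FS negative control. Preoperative pools are permuted with
#' the same assignment so the patient's fragment data stay internally
#' consistent.
#'
#' @param cohort An `mrd_cohort` with at least two patients.
#' @param seed Optional seed.
#' @return A new `mrd_cohort`; the permutation used is stored in attribute
#'   `fs_permutation`.
#' @export
shuffle_fs_control <- function(cohort, seed = NULL) {
  ids <- cohort$metadata$patient_id
  if (length(ids) < 2) abort("need >= 2 patients to shuffle FS")
  with_seed_if(seed, {
    perm <- sample(ids)
    map <- setNames(perm, ids)
    pools <- dplyr::mutate(cohort$pools,
                           patient_id = unname(map[.data$patient_id]))
    out <- new_mrd_cohort(cohort$metadata, pools, cohort$variants,
                          cohort$support, cohort$controls, cohort$truth,
                          cohort$config)
    attr(out, "fs_permutation") <- map
    out
  })
}

#' Evaluate MRD calls against recurrence and survival
#'
#' Confusion-matrix metrics (accuracy, sensitivity, specificity, NPV, PPV)
#' with exact Clopper-Pearson 95% confidence intervals, a two-group
#' log-rank test (recurrence as event, follow-up as time), and the
#' Kaplan-Meier fit per predicted group.
#'
#' @param calls Tibble with `patient_id` and `mrd_call` (e.g. from
#'   [majority_call()]).
#' @param metadata Cohort metadata with `patient_id`, `recurrence`,
#'   `followup_months`.
#' @return An `mrd_evaluation`: `confusion`, `metrics` (tibble with
#'   estimate and CI per metric), `logrank` (chisq, df, p_value), and
#'   `survfit` (the Kaplan-Meier object, `NULL` when all patients fall in
#'   one predicted group).
#' @export
evaluate_mrd <- function(calls, metadata) {
  df <- dplyr::inner_join(tibble::as_tibble(calls),
                          tibble::as_tibble(metadata), by = "patient_id")
  if (nrow(df) == 0) abort("no overlapping patients between calls and metadata")
  tp <- sum(df$mrd_call & df$recurrence)
  fp <- sum(df$mrd_call & !df$recurrence)
  tn <- sum(!df$mrd_call & !df$recurrence)
  fn <- sum(!df$mrd_call & df$recurrence)
  ci <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(x / n, stats::binom.test(x, n)$conf.int)
  }
  metrics <- tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "npv", "ppv"),
    numerator = c(tp + tn, tp, tn, tn, tp),
    denominator = c(nrow(df), tp + fn, tn + fp, tn + fn, tp + fp))
  est <- t(mapply(ci, metrics$numerator, metrics$denominator))
  metrics$estimate <- est[, 1]
  metrics$conf_low <- est[, 2]
  metrics$conf_high <- est[, 3]
  one_group <- length(unique(df$mrd_call)) < 2
  logrank <- if (one_group) {
    list(chisq = NA_real_, df = NA_integer_, p_value = NA_real_,
         note = "all patients in one predicted group; log-rank undefined")
  } else {
    sd <- survival::survdiff(
      survival::Surv(followup_months, recurrence) ~ mrd_call, data = df)
    list(chisq = unname(sd$chisq), df = length(sd$n) - 1L,
         p_value = unname(1 - pchisq(sd$chisq, length(sd$n) - 1L)))
  }
  km <- if (one_group) NULL else {
    survival::survfit(
      survival::Surv(followup_months, recurrence) ~ mrd_call, data = df)
  }
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = metrics, logrank = logrank, survfit = km,
                 data = df),
            class = "mrd_evaluation")
}

#' @export
print.mrd_evaluation <- function(x, ...) {
  cat(sprintf("<mrd_evaluation> TP=%d FP=%d TN=%d FN=%d | accuracy %.3f, NPV %.3f | log-rank p=%s\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"],
              x$metrics$estimate[x$metrics$metric == "accuracy"],
              x$metrics$estimate[x$metrics$metric == "npv"],
              format.pval(x$logrank$p_value, digits = 3)))
  invisible(x)
}

#' Group comparison utilities for FS distributions
#'
#' Thin wrappers for the standard cohort comparisons: Wilcoxon rank-sum
#' for independent groups (e.g. patients vs controls) and the paired
#' t-test for paired samples (e.g. pre- vs postoperative FS).
#'
#' @param x,y Numeric FS vectors.
#' @param paired Use the paired t-test instead of the Wilcoxon rank-sum.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `median_x`,
#'   `median_y`.
#' @export
compare_fs_groups <- function(x, y, paired = FALSE) {
  ht <- if (paired) stats::t.test(x, y, paired = TRUE) else
    stats::wilcox.test(x, y)
  tibble::tibble(test = if (paired) "paired t-test" else "wilcoxon rank-sum",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 median_x = stats::median(x), median_y = stats::median(y))
}
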