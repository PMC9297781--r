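# broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a fragmentation score table
#'
#' @param x An `fs_table`.
#' @param ... Unused.
#' @return Tibble with `length` and `score`.
#' @export
tidy.fs_table <- function(x, ...) {
  tibble::tibble(length = x$length, score = x$score)
}

#' @rdname tidy.fs_table
#' @export
glance.fs_table <- function(x, ...) {
  m <- fs_table_meta(x)
  tibble::tibble(n_boot = m$n_boot, n_sample = m$n_sample, cap = m$cap,
                 min_count = m$min_count, length_cap = m$length_cap,
                 n_tumour = m$n_tumour %||% NA_real_,
                 n_nontumour = m$n_nontumour %||% NA_real_,
                 max_abs_score = max(abs(x$score)))
}

#' Tidy a fitted MRD model
#'
#' @param x An `mrd_model`.
#' @param ... Unused.
#' @return One row per fitted parameter.
#' @export
tidy.mrd_model <- function(x, ...) {
  tibble::tibble(
    parameter = c("fs_threshold", "read_cutoff", "min_variants", "logic"),
    value = c(format(x$fs_threshold), x$cutoffs$read_cutoff,
              x$cutoffs$min_variants, x$logic))
}

#' @rdname tidy.mrd_model
#' @export
glance.mrd_model <- function(x, ...) {
  tibble::tibble(logic = x$logic, fs_threshold = x$fs_threshold,
                 read_cutoff = x$cutoffs$read_cutoff,
                 min_variants = x$cutoffs$min_variants,
                 training_accuracy = unname(x$training_accuracy[x$logic]),
                 n_train = length(x$train_ids))
}

#' Tidy cross-validation results
#'
#' @param x An `mrd_cv`.
#' @param ... Unused.
#' @return Per-patient positive counts per modality with the majority
#'   combined call.
#' @export
tidy.mrd_cv <- function(x, ...) {
  dplyr::mutate(x$counts,
                mrd_call = .data$combined >= (x$n_repeats %/% 2 + 1L))
}

#' @rdname tidy.mrd_cv
#' @export
glance.mrd_cv <- function(x, ...) {
  tibble::tibble(n_repeats = x$n_repeats, n_folds = x$n_folds,
                 n_patients = nrow(x$counts),
                 n_fits = nrow(x$fits))
}

#' Tidy an MRD evaluation
#'
#' @param x An `mrd_evaluation`.
#' @param ... Unused.
#' @return The metrics tibble (estimate with Clopper-Pearson CI per
#'   metric).
#' @export
tidy.mrd_evaluation <- function(x, ...) x$metrics

#' @rdname tidy.mrd_evaluation
#' @export
glance.mrd_evaluation <- function(x, ...) {
  g <- function(m) x$metrics$estimate[x$metrics$metric == m]
  tibble::tibble(accuracy = g("accuracy"), sensitivity = g("sensitivity"),
                 specificity = g("specificity"), npv = g("npv"),
                 logrank_chisq = x$logrank$chisq,
                 logrank_p = x$logrank$p_value,
                 TP = x$confusion[["TP"]], FP = x$confusion[["FP"]],
                 TN = x$confusion[["TN"]], FN = x$confusion[["FN"]])
}

#' Tidy a benefit simulation
#'
#' @param x A `benefit_sim`.
#' @param ... Unused.
#' @return The per-group summary tibble.
#' @export
tidy.benefit_sim <- function(x, ...) x$summary

#' @rdname tidy.benefit_sim
#' @export
glance.benefit_sim <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter, benefit_rate = x$benefit_rate)
}
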