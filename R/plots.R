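# ggplot2 autoplot() methods for the package's result types.

#' Plot a fragmentation score table
#'
#' Per-fragment score against fragment length; positive scores mark
#' lengths enriched in tumour-derived cfDNA.
#'
#' @param object An `fs_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_table <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$length, .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "#C0392B") +
    ggplot2::labs(x = "Fragment length (bp)",
                  y = "Per-fragment score (log2 tumour / non-tumour density)") +
    ggplot2::theme_minimal()
}

#' Plot fragment-length densities of one or more pools
#'
#' @param ... Named [fragment_pool()]s.
#' @param max_length Truncate the x axis (default 600 bp).
#' @return A ggplot of the empirical densities.
#' @export
plot_fragment_densities <- function(..., max_length = 600) {
  pools <- list(...)
  nm <- names(pools) %||% paste0("pool", seq_along(pools))
  df <- purrr::imap(pools, function(p, label) {
    dplyr::mutate(empirical_density(p), pool = label)
  }) |> purrr::list_rbind() |>
    dplyr::filter(.data$length <= max_length)
  ggplot2::ggplot(df, ggplot2::aes(.data$length, .data$density,
                                   colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Fragment length (bp)", y = "Density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation positive counts per patient
#'
#' @param object An `mrd_cv`.
#' @param metadata Optional metadata to colour patients by recurrence.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrd_cv <- function(object, metadata = NULL, ...) {
  df <- tidy(object)
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, tibble::as_tibble(metadata)[
      , c("patient_id", "recurrence")], by = "patient_id")
  } else {
    df$recurrence <- NA
  }
  ggplot2::ggplot(df, ggplot2::aes(
    stats::reorder(.data$patient_id, .data$combined), .data$combined,
    fill = .data$recurrence)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$n_repeats %/% 2 + 1,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = sprintf("Positive predictions (of %d repeats)",
                              object$n_repeats),
                  fill = "Recurrence") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of an MRD evaluation
#'
#' @param object An `mrd_evaluation` with a fitted survival object.
#' @param ... Unused.
#' @return A ggplot of the per-group Kaplan-Meier step functions.
#' @export
autoplot.mrd_evaluation <- function(object, ...) {
  if (is.null(object$survfit)) {
    abort("no survival fit available (all patients in one predicted group)")
  }
  sf <- summary(object$survfit, censored = TRUE)
  df <- tibble::tibble(time = sf$time, surv = sf$surv,
                       group = as.character(sf$strata))
  start <- dplyr::distinct(df, .data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  df <- dplyr::bind_rows(start, df) |> dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Follow-up (months)", y = "Recurrence-free fraction",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %s",
                                     format.pval(object$logrank$p_value,
                                                 digits = 2))) +
    ggplot2::theme_minimal()
}

#' Plot the benefit-simulation distributions
#'
#' @param object A `benefit_sim`.
#' @param ... Unused.
#' @return A ggplot of the per-group benefit-fraction distributions.
#' @export
autoplot.benefit_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$iterations,
                            dplyr::all_of(c("positive", "negative")),
                            names_to = "group", values_to = "benefit") |>
    dplyr::filter(!is.na(.data$benefit))
  ggplot2::ggplot(df, ggplot2::aes(.data$benefit, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.6,
                            position = "identity") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "Benefit of adjuvant chemotherapy",
                  y = "Iterations", fill = "Predicted group") +
    ggplot2::theme_minimal()
}
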