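# Broom-style accessors and ggplot2 autoplot methods for the result types.

#' @exportS3Method generics::tidy
tidy.threshold_curve <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.threshold_curve <- function(x, ...) {
  tibble::tibble(auc_rcc = x$auc_rcc, auc_riu = x$auc_riu, auc_ua = x$auc_ua,
                 n_records = x$n_records)
}

#' @exportS3Method ggplot2::autoplot
autoplot.threshold_curve <- function(object, ...) {
  long <- tidyr_pivot(object$curve)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     color = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = expression(I[T]), y = NULL, color = NULL,
                  title = "Certainty-threshold metrics",
                  subtitle = sprintf("AUC: Rcc %.3f, Riu %.3f, UA %.3f",
                                     object$auc_rcc, object$auc_riu,
                                     object$auc_ua)) +
    ggplot2::theme_minimal()
}

# Minimal long-format reshape (avoids a tidyr dependency for one call).
tidyr_pivot <- function(curve) {
  dplyr::bind_rows(
    tibble::tibble(threshold = curve$threshold, measure = "Rcc",
                   value = curve$rcc),
    tibble::tibble(threshold = curve$threshold, measure = "Riu",
                   value = curve$riu),
    tibble::tibble(threshold = curve$threshold, measure = "UA",
                   value = curve$ua))
}

#' @exportS3Method generics::tidy
tidy.deferral_curve <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.deferral_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_records = x$n_records)
}

#' @exportS3Method ggplot2::autoplot
autoplot.deferral_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 100 * .data$fraction,
                               y = .data$misclassified_pct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "% of cases decided by the ensemble",
                  y = "% misclassified",
                  title = "Deferral analysis",
                  subtitle = sprintf("AUC %.3f (lower is better)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot example records of a signal batch
#'
#' @param batch A [signal_batch()].
#' @param records Indices of records to show (default first 4).
#' @param channel Channel to plot.
#' @return A ggplot object, faceted by record.
#' @export
plot_records <- function(batch, records = seq_len(min(4L, n_records(batch))),
                         channel = 1L) {
  t_len <- dim(batch$signals)[3L]
  tt <- (seq_len(t_len) - 1) / batch$sampling_rate
  dfs <- lapply(records, function(i) {
    lbl <- batch$labels[i]
    cls <- if (!is.null(batch$class_names)) batch$class_names[lbl + 1L]
           else as.character(lbl)
    tibble::tibble(record = sprintf("%s (%s)", batch$record_ids[i], cls),
                   time = tt, value = batch$signals[i, channel, ])
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~record, ncol = 1L) +
    ggplot2::labs(x = "time [s]", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
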