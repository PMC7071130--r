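# ggplot2 diagnostics.

#' @importFrom ggplot2 .data
NULL

#' Plot mean MLA lead weights
#'
#' @param w Named 12-vector of lead weights (from [lead_weights()] or
#'   `mla_cv$mean_lead_weights`).
#' @return A ggplot object: one bar per lead in canonical order.
#' @export
plot_lead_weights <- function(w) {
  df <- data.frame(lead = factor(names(w), levels = ecg_leads()),
                   weight = as.numeric(w))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lead, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "mean lead weight (alpha1)") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param model A trained `mla_model` (uses `model$history`).
#' @return A ggplot object of training loss (and validation accuracy when
#'   recorded) per epoch.
#' @export
plot_history <- function(model) {
  h <- model$history
  stopifnot(!is.null(h))
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$train_loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
  p
}

#' Plot one 12-lead record
#'
#' @param record An `ecg_record`.
#' @param seconds Time span to show from the start of the record.
#' @return A ggplot object, one facet per lead.
#' @export
plot_record <- function(record, seconds = 5) {
  n <- min(ncol(record$signals), round(seconds * record$fs))
  df <- data.frame(
    t = rep((seq_len(n) - 1) / record$fs, each = 12),
    lead = factor(rep(record$lead_names, n), levels = ecg_leads()),
    mV = as.numeric(record$signals[, seq_len(n)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "mV", title = record$record_id) +
    ggplot2::theme_minimal()
}
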