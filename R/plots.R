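#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted model over the data
#'
#' One panel per patient: measured activities with +/- 1 sigma error bars
#' and the fitted curve evaluated on a dense grid out to twice the last
#' sample time (the range the shape gate inspects).
#'
#' @param object A `pbms_fit`.
#' @param log_y Plot activity on a log scale (curves that hit zero are
#'   clipped by ggplot2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbms_fit <- function(object, log_y = FALSE, ...) {
  model <- get_model(object$model_id)
  curves <- dplyr::bind_rows(lapply(unique(object$data$patient_id), function(id) {
    d <- object$data[object$data$patient_id == id, ]
    grid <- seq(0, 2 * max(d$time_h), length.out = 200)
    tibble::tibble(
      patient_id = id, time_h = grid,
      fitted = model$eval_fn(patient_param_vector(object, id),
                             object$decay$lambda_phys, grid))
  }))
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$activity_pct_ia)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$activity_pct_ia - .data$sigma,
                   ymax = .data$activity_pct_ia + .data$sigma),
      width = 0, colour = "grey40") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~patient_id, scales = "free") +
    ggplot2::labs(x = "Time post-injection (h)", y = "Activity (%IA)",
                  title = sprintf("Model %s (%s fit)", object$model_id, object$mode))
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot Akaike weights of a selection run
#'
#' Bar chart of the Akaike weights over the goodness-of-fit-passing models;
#' excluded models appear with zero weight and are annotated with their
#' exclusion reason in the tooltip-friendly `excluded_reason` column.
#'
#' @param object A `pbms_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbms_selection <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  tab$weight <- ifelse(is.na(tab$weight), 0, tab$weight)
  tab$model_id <- factor(tab$model_id, levels = names(model_catalog()))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$model_id, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Akaike weight",
                  title = sprintf("%s model selection", attr(object, "mode"))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("patient_id" %in% names(tab)) p <- p + ggplot2::facet_wrap(~patient_id)
  p
}

#' Plot jackknife weight stability
#'
#' @param object A `pbms_jackknife`.
#' @param ... Unused.
#' @return A ggplot object: per-model leave-one-out weights (points) with
#'   the median highlighted.
#' @export
autoplot.pbms_jackknife <- function(object, ...) {
  reps <- object$replicates
  reps$model_id <- factor(reps$model_id, levels = names(model_catalog()))
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$model_id, y = .data$weight)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = stats::median, geom = "point",
                          colour = "firebrick", size = 2.5) +
    ggplot2::labs(x = NULL, y = "Leave-one-out Akaike weight",
                  title = "Jackknife stability of model selection") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
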