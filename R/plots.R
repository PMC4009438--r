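#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated or loaded recording
#'
#' Motor-channel EEG (C3/C4) and channel-mean HbO on one time axis, with the
#' task blocks shaded.
#'
#' @param object A `bci_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bci_recording
#' @export
autoplot.bci_recording <- function(object, ...) {
  eeg <- tidyr::pivot_longer(object$eeg[c("time", "C3", "C4")],
                             c("C3", "C4"),
                             names_to = "channel", values_to = "value")
  eeg$panel <- paste0("EEG ", eeg$channel, " (uV)")
  sched <- object$schedule[object$schedule$trial_type != "rest", ]
  p <- ggplot2::ggplot(eeg, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_rect(
      data = tibble::tibble(xmin = sched$onset,
                            xmax = sched$onset + sched$duration,
                            trial_type = sched$trial_type),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$trial_type),
      alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "task") +
    ggplot2::theme_minimal()
  p
}

#' Plot a hemoglobin series
#'
#' Channel-mean HbO and HbR concentration changes over time.
#'
#' @param object A [new_hemo()] series.
#' @param channels Channel subset to average (default all 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bci_hemo
#' @export
autoplot.bci_hemo <- function(object, channels = 1:12, ...) {
  df <- tibble::tibble(
    time = object$time,
    HbO = rowMeans(hemo_matrix(object, "hbo")[, channels, drop = FALSE]),
    HbR = rowMeans(hemo_matrix(object, "hbr")[, channels, drop = FALSE])
  )
  df <- tidyr::pivot_longer(df, c("HbO", "HbR"),
                            names_to = "species", values_to = "conc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$conc,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "c (uM)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a decoded command stream
#'
#' Decoded command per frame (points) over the intended command (line).
#'
#' @param object A `bci_decode` from [decode_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bci_decode
#' @export
autoplot.bci_decode <- function(object, ...) {
  fr <- object$frames
  fr$command <- factor(fr$command, levels = commands)
  fr$truth <- factor(fr$truth, levels = commands)
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$truth, group = 1),
                       colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$command,
                                     colour = .data$command == .data$truth),
                        size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "#d95f02"),
                                 labels = c(`TRUE` = "correct",
                                            `FALSE` = "wrong")) +
    ggplot2::labs(x = "time (s)", y = "command", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
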