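#' Plot the context-block structure of a schedule
#'
#' Trials coloured by context along session time, with stop-relevant trials
#' marked, making the 13-18-trial context runs visible.
#'
#' @param object A `stop_schedule` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stop_schedule <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$onset_s / 60, y = .data$context,
                               colour = factor(.data$context))) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$stop_relevant), size = 1) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "session time (min)", y = "context",
                  colour = "context", shape = "stop-relevant") +
    ggplot2::theme_minimal()
}

#' Plot per-context staircase trajectories
#'
#' Stop-signal delay of every deviant trial over the session, one line per
#' context: the asymmetric 1-up/1-down tracking converging toward its
#' equilibrium delay.
#'
#' @param records Behavioural records from [simulate_session()].
#' @return A ggplot object.
#' @export
plot_staircase <- function(records) {
  d <- records[!is.na(records$soa_ms), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$soa_ms,
                                  colour = factor(.data$context))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "trial", y = "stop-signal delay (ms)",
                  colour = "context") +
    ggplot2::theme_minimal()
}

#' Heatmap of trial-averaged ERSP values
#'
#' Time-frequency dB map averaged over trials for one channel.
#'
#' @param object An `ersp_db` object from [baseline_normalize()].
#' @param channel Channel label (default: first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ersp_db <- function(object, channel = object$channels[1], ...) {
  ci <- match(channel, object$channels)
  if (is.na(ci)) abort_input(paste("no such channel:", channel))
  m <- apply(object$db[, ci, , , drop = FALSE], c(3, 4), mean)
  d <- tidyr::expand_grid(f = object$freqs, t = object$times)
  d$db <- as.vector(m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$f, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)", fill = "dB",
                  title = channel) +
    ggplot2::theme_minimal()
}

#' Plot design-matrix regressors over scan time
#'
#' @param object An `fmri_design`.
#' @param kinds Column kinds to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fmri_design <- function(object, kinds = c("event", "modulator"), ...) {
  keep <- object$columns$name[object$columns$kind %in% kinds]
  d <- tibble(scan = rep(seq_len(object$n_scans), length(keep)),
              regressor = rep(keep, each = object$n_scans),
              value = as.vector(object$X[, keep]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scan * object$tr, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~regressor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "regressor value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
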