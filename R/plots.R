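# Pseudo-log time transform used throughout the figures: linear up to
# 1 ps, logarithmic beyond, mirroring the usual presentation of
# pump-probe series that span femtoseconds to nanoseconds.
.linlog_time <- function(t, breakpoint = 1) {
  ifelse(t <= breakpoint, t / breakpoint, 1 + log10(pmax(t, breakpoint) / breakpoint))
}

#' Plot refined parameter trajectories
#'
#' One panel per refined parameter against a linear-to-1-ps /
#' logarithmic-beyond time axis.
#'
#' @param object A `txs_refinement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot txs_refinement
#' @export
autoplot.txs_refinement <- function(object, ...) {
  df <- tidy(object)
  df$tt <- .linlog_time(df$t)
  brk <- c(0, 0.5, 1, 1 + log10(10), 1 + log10(100))
  lab <- c("0", "0.5", "1", "10", "100")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tt, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = brk, labels = lab) +
    ggplot2::labs(x = "time (ps, linear to 1 ps then log)", y = NULL,
                  title = paste("Refined parameters,", object$solvent)) +
    ggplot2::theme_minimal()
}

#' Plot a difference-scattering dataset
#'
#' q-t false-colour maps of the isotropic and anisotropic components.
#'
#' @param object An `aniso_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aniso_dataset
#' @export
autoplot.aniso_dataset <- function(object, ...) {
  df <- tidy(object)
  df <- tidyr::pivot_longer(df, c("dS0", "dS2"), names_to = "component",
                            values_to = "dS")
  df$tt <- .linlog_time(df$t)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tt, y = .data$q, fill = .data$dS)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "time (ps, linear to 1 ps then log)",
                  y = "q (1/Angstrom)",
                  title = paste("Difference scattering,", object$solvent)) +
    ggplot2::theme_minimal()
}

#' Plot the geminate-pair decay fit
#'
#' @param object A `gp_decay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gp_decay_fit
#' @export
autoplot.gp_decay_fit <- function(object, ...) {
  df <- tibble::tibble(t = object$t, data = object$data, fitted = object$fitted)
  df$tt <- .linlog_time(df$t)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tt)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$data), shape = 4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "time (ps, linear to 1 ps then log)",
                  y = "geminate-pair amplitude",
                  subtitle = sprintf("tau1 = %.2g ps, tau2 = %.2g ps",
                                     object$tau1, object$tau2)) +
    ggplot2::theme_minimal()
}

#' Data-versus-model panels at selected timepoints
#'
#' Overlays the measured (or simulated) isotropic and anisotropic
#' difference curves with the model evaluated at the refined parameters.
#'
#' @param dataset An `aniso_dataset`.
#' @param refinement A `txs_refinement` on the same dataset.
#' @param ctx The [forward_context()] used for the refinement.
#' @param times Timepoints (ps); the nearest available delays are shown.
#' @return A ggplot object.
#' @export
plot_fit_panels <- function(dataset, refinement, ctx, times = c(0.2, 0.5, 1, 10, 100)) {
  pp <- dplyr::arrange(refinement$params, t)
  rows <- lapply(times, function(tv) {
    k <- which.min(abs(dataset$t - tv))
    i <- which.min(abs(pp$t - dataset$t[k]))
    x <- as.numeric(pp[i, .param_names]); names(x) <- .param_names
    tibble::tibble(
      t_label = sprintf("t = %.3g ps", dataset$t[k]),
      q = rep(dataset$q, 2),
      component = rep(c("dS0", "dS2"), each = length(dataset$q)),
      data = c(dataset$dS0[, k], dataset$dS2[, k]),
      model = c(.model_iso_curve(x, ctx), .model_aniso_curve(x, ctx)))
  })
  df <- dplyr::bind_rows(rows)
  df$t_label <- factor(df$t_label, levels = unique(df$t_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$data), size = 0.4,
                        colour = "firebrick", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model)) +
    ggplot2::facet_grid(component ~ t_label, scales = "free_y") +
    ggplot2::labs(x = "q (1/Angstrom)", y = "difference scattering (e.u.)") +
    ggplot2::theme_minimal()
}
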