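# ggplot2 views of the result types.

#' Woods plot of summed uptake differences
#'
#' One horizontal segment per peptide spanning its residue range at its
#' summed uptake difference, with the summed-SD error bar at the center
#' residue; peptides passing the three-gate significance filter are red.
#'
#' @param object An `hdx_woods` table (see [woods_summary()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hdx_woods <- function(object, ...) {
  df <- as_tibble(object)
  states <- attr(object, "states")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center_residue,
                                   y = .data$sum_delta_d,
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sum_delta_d - .data$sum_sd,
                                        ymax = .data$sum_delta_d + .data$sum_sd),
                           width = 0, linewidth = 0.3) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$sum_delta_d),
                          linewidth = 1.2) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey35", `TRUE` = "red"),
                                 name = "significant") +
    ggplot2::facet_wrap(ggplot2::vars(.data$protein), scales = "free_x") +
    ggplot2::labs(x = "center residue",
                  y = expression(paste(Sigma, Delta, "D (Da)")),
                  title = if (!is.null(states))
                    paste0(states["b"], " - ", states["a"]) else NULL) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.hdx_woods
#' @param comparison An `hdx_comparison`.
#' @export
plot_woods <- function(comparison, ...) autoplot(woods_summary(comparison), ...)

#' Dose-response curve with the fitted one-site model
#'
#' @param object An `hdx_binding_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hdx_binding_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration,
                                        y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "response") +
    ggplot2::theme_bw()
  if (isTRUE(object$converged)) {
    grid <- tibble(concentration = exp(seq(log(max(min(df$concentration), 1e-3)),
                                           log(max(df$concentration)),
                                           length.out = 200)))
    grid$response <- predict(object, grid)
    p <- p +
      ggplot2::geom_line(data = grid, colour = "red") +
      ggplot2::labs(subtitle = sprintf("kd = %.3g +/- %.2g nM", object$kd,
                                       object$kd_se))
  }
  p
}

#' Per-residue interface buried-area profile
#'
#' @param object An `hdx_interface` from [buried_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hdx_interface <- function(object, ...) {
  df <- object$per_residue
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$bsa,
                                   fill = .data$bsa > object$bsa_threshold)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$bsa_threshold, linetype = 2,
                        colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chain), scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "red"),
                               name = paste0("BSA > ", object$bsa_threshold,
                                             " Å²")) +
    ggplot2::labs(x = "residue", y = "buried area (Å²)") +
    ggplot2::theme_bw()
}
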