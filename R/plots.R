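#' Plot a normalized viewpoint profile
#'
#' Signal per retained fragment against position on the viewpoint
#' chromosome, with the viewpoint marked.
#'
#' @param profile A `fourc_profile`.
#' @param window Plot radius around the viewpoint, bp (default the
#'   normalization radius).
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, window = NULL) {
  vp <- attr(profile, "viewpoint")
  window <- window %||% vp$norm_radius
  cis <- profile[profile$chrom == vp$chrom &
                   abs(profile$midpoint - vp$centre) <= window, ]
  ggplot2::ggplot(cis, ggplot2::aes(x = (.data$midpoint - vp$centre) / 1e6,
                                    y = .data$signal)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Distance from viewpoint (Mb)",
                  y = "Normalized 4C signal",
                  title = sprintf("Viewpoint %s:%s", vp$chrom,
                                  format(vp$centre, scientific = FALSE))) +
    ggplot2::theme_minimal()
}

#' Plot a fitted 4C model over its profile
#'
#' Shows the per-fragment signal, the fitted background decay, the full
#' model curve and the significant interaction peaks.
#'
#' @param object A `fourc_fit`.
#' @param window Plot radius around the viewpoint, bp.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fourc_fit <- function(object, window = NULL, ...) {
  vp <- object$viewpoint
  window <- window %||% vp$norm_radius
  cis <- object$profile[object$profile$chrom == vp$chrom &
                          abs(object$profile$midpoint - vp$centre) <= window, ]
  grid <- seq(vp$centre - window, vp$centre + window, length.out = 2000)
  curves <- tibble(
    x = rep((grid - vp$centre) / 1e6, 2),
    y = c(predict(object$background, abs(grid - vp$centre)),
          evaluate_model(object, grid)),
    component = rep(c("background", "full model"), each = length(grid))
  )
  sig <- object$peaks[object$peaks$significant, ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = cis,
                        ggplot2::aes(x = (.data$midpoint - vp$centre) / 1e6,
                                     y = .data$signal),
                        size = 0.4, alpha = 0.3) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$component),
                       linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40")
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble(x = (sig$centre - vp$centre) / 1e6,
                    y = evaluate_model(object, sig$centre)),
      ggplot2::aes(x = .data$x, y = .data$y),
      shape = 25, fill = "red", colour = "red", size = 2)
  }
  p + ggplot2::labs(x = "Distance from viewpoint (Mb)",
                    y = "Normalized 4C signal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
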