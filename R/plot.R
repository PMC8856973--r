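#' Plot a concentration curve against the line of perfect equality
#'
#' Draws the concentration curve (solid) and the 45-degree line of perfect
#' equality (dashed), with the cumulative risk-factor percentage on the X
#' axis and the cumulative wealth percentage on the Y axis, and the
#' concentration index in the caption. The figure is written both as SVG and
#' as PNG next to each other.
#'
#' @param curve A `concentration_curve`.
#' @param summary Optional `curve_summary` used for the caption.
#' @param path Output path; the extension (if any) is replaced by `.svg` and
#'   `.png`.
#' @param title Plot title.
#' @return Invisibly, a character vector of the two files written.
#' @export
plot_concentration <- function(curve, summary = NULL, path,
                               title = "Concentration curve") {
  stopifnot(inherits(curve, "concentration_curve"))
  base <- sub("\\.(svg|png)$", "", path)
  dir <- dirname(base)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  caption <- if (!is.null(summary)) {
    sprintf("concentration index %+.4f (mode %s, n = %s)",
            summary$concentration_index, summary$mode, format(summary$n))
  } else {
    sprintf("concentration index %+.4f", concentration_index(curve))
  }
  eq <- data.frame(p = c(0, 100), L = c(0, 100))
  gg <- ggplot2::ggplot(as.data.frame(curve), ggplot2::aes(x = p, y = L)) +
    ggplot2::geom_line(data = eq, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_point(colour = "#2166ac", size = 1.4) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100), expand = FALSE) +
    ggplot2::labs(x = "cumulative % risk factor",
                  y = "cumulative % wealth quintiles",
                  title = title, caption = caption) +
    ggplot2::theme_classic(base_size = 11)
  files <- paste0(base, c(".svg", ".png"))
  grDevices::svg(files[1L], width = 6, height = 6)
  print(gg)
  grDevices::dev.off()
  grDevices::png(files[2L], width = 1200, height = 1200, res = 200)
  print(gg)
  grDevices::dev.off()
  invisible(files)
}
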