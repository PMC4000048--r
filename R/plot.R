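# 2D simplex graph of FcLM support, in the style of likelihood-mapping
# figures: an equilateral triangle with one dot per quartet and the three
# topologies at the corners.

#' Plot FcLM results in the 2-simplex
#'
#' @param fclm an \code{fclm_result} (or its \code{results} data.frame with
#'   columns x, y).
#' @param labels corner labels for T1, T2, T3.
#' @param show_percent annotate corners with argmax percentages.
#' @param pch,cex,col point style.
#' @param main plot title.
#' @return invisibly, the plotted coordinates.
#' @export
plot_simplex <- function(fclm, labels = c("T1 (12|34)", "T2 (13|24)",
                                          "T3 (14|23)"),
                         show_percent = TRUE, pch = 16, cex = 0.5,
                         col = grDevices::rgb(0.1, 0.3, 0.7, 0.5),
                         main = "Four-cluster likelihood mapping") {
  res <- if (inherits(fclm, "fclm_result")) fclm$results else fclm
  h <- sqrt(3) / 2
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.12, 1.12), ylim = c(-0.12, h + 0.12),
                        asp = 1)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, h), border = "grey30")
  graphics::points(res$x, res$y, pch = pch, cex = cex, col = col)
  lab <- labels
  if (show_percent && inherits(fclm, "fclm_result")) {
    pc <- fclm$summary$argmax$percent[1:3]
    lab <- sprintf("%s\n%.1f%%", labels, pc)
  }
  graphics::text(c(0, 1, 0.5), c(-0.02, -0.02, h + 0.02), lab,
                 pos = c(1, 1, 3), cex = 0.8)
  graphics::title(main = main)
  invisible(res[, c("x", "y")])
}
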