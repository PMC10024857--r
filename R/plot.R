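#' Plot a proximity profile
#'
#' Two panels in the style of distance-interval summaries: per-bin cell
#' counts by phenotype, and the stacked relative percentage of phenotypes
#' at each distance interval.
#'
#' @param x a `proximity_profile`.
#' @param which `"counts"`, `"percent"`, or `"both"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.proximity_profile <- function(x, which = c("both", "counts", "percent"),
                                   ...) {
  which <- match.arg(which)
  cols <- grDevices::hcl.colors(ncol(x$counts), "Dark 3")
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (which == "both") graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  if (which %in% c("both", "counts")) {
    graphics::barplot(t(x$counts), beside = TRUE, col = cols, las = 2,
                      ylab = "cells", main = sprintf("counts near %s",
                                                     as.character(x$pathology_kind)),
                      ...)
    graphics::legend("topleft", legend = colnames(x$counts), fill = cols,
                     bty = "n", cex = 0.7)
  }
  if (which %in% c("both", "percent")) {
    pct <- x$row_pct
    pct[is.na(pct)] <- 0
    graphics::barplot(t(pct), col = cols, las = 2,
                      ylab = "% of cells in bin",
                      main = "relative phenotype percentage", ...)
  }
  invisible(x)
}

#' Plot a residual-stain tile map
#'
#' Grey-scale heat map of per-tile residual percentages, exposing
#' spatially non-uniform blocking.
#'
#' @param x a `qc_record`.
#' @param ... passed to [graphics::image()].
#' @export
plot.qc_record <- function(x, ...) {
  m <- x$tile_map
  m[is.na(m)] <- 0
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  axes = FALSE,
                  main = sprintf("%s residual %% per tile", x$marker), ...)
  invisible(x)
}
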