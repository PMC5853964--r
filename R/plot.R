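#' Plot normalized coverage per chromosome
#'
#' One panel per chromosome: raw per-bin normalized values (points), the
#' moving average used for presentation (line), the low-coverage cutoff
#' (dashed), and any deletion calls (shaded).
#'
#' @param x a `normalized_coverage` object.
#' @param calls optional `deletion_calls` for the same line.
#' @param low_fraction cutoff drawn as a dashed line (default 0.1).
#' @param window moving-average window in bins (default 4).
#' @param chroms chromosomes to draw (default all).
#' @param ... ignored.
#' @export
plot.normalized_coverage <- function(x, calls = NULL, low_fraction = 0.1,
                                     window = 4L, chroms = NULL, ...) {
  b <- x$bins
  if (is.null(chroms)) chroms <- unique(b$chrom)
  nc <- ceiling(sqrt(length(chroms)))
  nr <- ceiling(length(chroms) / nc)
  op <- par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.5, 0.5, 0))
  on.exit(par(op))
  for (ch in chroms) {
    bb <- b[b$chrom == ch, , drop = FALSE]
    bb <- bb[order(bb$start), , drop = FALSE]
    mid <- (bb$start + bb$end) / 2 / 1e6
    ymax <- max(2, min(3, max(bb$value, na.rm = TRUE)))
    plot.new()
    plot.window(xlim = range(mid), ylim = c(0, ymax))
    axis(1); axis(2)
    title(main = ch, xlab = "position (Mb)", ylab = "normalized coverage")
    if (!is.null(calls)) {
      cc <- calls[calls$chrom == ch, , drop = FALSE]
      if (nrow(cc))
        rect(cc$start / 1e6, 0, cc$end / 1e6, ymax, col = gray(0.9), border = NA)
    }
    points(mid, pmin(bb$value, ymax), pch = 16, cex = 0.3, col = gray(0.4))
    if (nrow(bb) >= window) {
      ma <- moving_average(bb$value, window)
      lines(mid[seq_along(ma)], pmin(ma, ymax), col = "steelblue")
    }
    abline(h = low_fraction, lty = 2, col = "red3")
  }
  invisible(x)
}
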