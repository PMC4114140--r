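#' Genome-wide log2-ratio plot of a single-cell profile
#'
#' Probes along a concatenated genome axis, alternating colour per
#' chromosome, with the detection thresholds drawn at +/- `threshold`.
#'
#' @param x A `ratio_profile`.
#' @param threshold Detection threshold drawn as dashed lines.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ratio_profile <- function(x, threshold = 0.3, ...) {
  chroms <- unique(x$chrom)
  offs <- setNames(cumsum(c(0, head(tapply(x$end, x$chrom, max)[chroms], -1))),
                   chroms)
  pos <- (x$start + x$end) / 2 + offs[x$chrom]
  col <- ifelse(match(x$chrom, chroms) %% 2 == 0, "grey55", "grey25")
  graphics::plot(pos, x$log2ratio, pch = 16, cex = 0.4, col = col,
                 xlab = "genome position", ylab = "log2 ratio",
                 main = sprintf("cell %s (%s)", attr(x, "cell_id"),
                                attr(x, "phase")), xaxt = "n", ...)
  graphics::abline(h = c(-threshold, threshold), lty = 2, col = "red")
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
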