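# Base-graphics rendering of single-case CNV plots and cohort summary plots.

# Lay bins out on a single genome axis; returns cumulative offsets per
# chromosome actually present.
genome_layout <- function(chroms) {
  gi <- genome_info()
  gi <- gi[gi$chrom %in% chroms, , drop = FALSE]
  gi$offset <- cumsum(c(0, gi$length[-nrow(gi)]))
  gi
}

#' Render a single-case CNV plot
#'
#' Genome-ordered scatter of bin log2 values (green above baseline, red
#' below), the fitted baseline as a horizontal line, segment means as dark
#' blue steps, chromosome boundaries as solid and p/q arm boundaries as
#' dotted separators, and highlight-gene labels.
#'
#' @param profile A baselined [bin_profile()].
#' @param segments Optional [segment_profile()] output to overlay.
#' @param events Optional [call_events()] output (amplified/deleted genes are
#'   labelled).
#' @param path Output PNG path; when `NULL`, draws on the current device.
#' @param genes Highlight-gene table (default bundled list).
#' @param ylim Y-axis range (default `c(-2, 2)`).
#' @param width,height,res PNG device parameters.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_cnv_profile <- function(profile, segments = NULL, events = NULL,
                             path = NULL, genes = highlight_genes(),
                             ylim = c(-2, 2), width = 1400, height = 500,
                             res = 96) {
  stopifnot(inherits(profile, "bin_profile"))
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height, res = res)
    on.exit(grDevices::dev.off())
  }
  b <- profile$bins
  v <- rel_values(profile)
  lay <- genome_layout(unique(as.character(b$chrom)))
  off <- stats::setNames(lay$offset, lay$chrom)
  x <- off[as.character(b$chrom)] + (b$start + b$end) / 2
  graphics::par(mar = c(3, 4, 2, 1))
  graphics::plot(x, pmin(pmax(v, ylim[1]), ylim[2]),
                 pch = 16, cex = 0.4,
                 col = ifelse(v >= 0, "forestgreen", "firebrick"),
                 xlab = "", ylab = "log2 ratio (baseline-relative)",
                 xaxt = "n", ylim = ylim,
                 main = profile$sample_id)
  graphics::abline(h = 0, col = "grey40")
  graphics::abline(v = c(lay$offset, sum(lay$length) + lay$offset[1]),
                   col = "grey70")
  graphics::abline(v = lay$offset + lay$p_end, col = "grey80", lty = 3)
  graphics::axis(1, at = lay$offset + lay$length / 2, labels = lay$chrom,
                 tick = FALSE, cex.axis = 0.7)
  if (!is.null(segments) && nrow(segments) > 0) {
    s <- as.data.frame(segments)
    so <- off[as.character(s$chrom)]
    graphics::segments(so + s$start, pmin(pmax(s$mean_log2, ylim[1]), ylim[2]),
                       so + s$end, pmin(pmax(s$mean_log2, ylim[1]), ylim[2]),
                       col = "navy", lwd = 2.5)
  }
  if (!is.null(genes) && nrow(genes) > 0) {
    g <- genes[genes$chrom %in% lay$chrom, , drop = FALSE]
    gx <- off[as.character(g$chrom)] + (g$start + g$end) / 2
    graphics::points(gx, rep(ylim[2] * 0.92, nrow(g)), pch = 1, col = "blue",
                     cex = 0.6)
    graphics::text(gx, rep(ylim[2] * 0.97, nrow(g)), g$symbol, col = "blue",
                   cex = 0.45, srt = 90, adj = 0, xpd = NA)
  }
  invisible(path)
}

#' Render a cohort summary CNV plot
#'
#' Mirrored bar plot of per-bin alteration frequencies: gains drawn upward,
#' losses downward, both in percent of samples, with chromosome separators.
#' Unlike a single-case plot the y axis is a frequency, not a signal
#' amplitude: a single-copy gain and a high-level amplification count the
#' same.
#'
#' @param freq A [summarize_cohort()] result.
#' @param path Output PNG path; when `NULL`, draws on the current device.
#' @param width,height,res PNG device parameters.
#' @param main Plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_cohort_summary <- function(freq, path = NULL, width = 1400, height = 500,
                                res = 96, main = NULL) {
  stopifnot(inherits(freq, "cohort_frequency"))
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height, res = res)
    on.exit(grDevices::dev.off())
  }
  b <- freq$bins
  lay <- genome_layout(unique(as.character(b$chrom)))
  off <- stats::setNames(lay$offset, lay$chrom)
  x0 <- off[as.character(b$chrom)] + b$start
  x1 <- off[as.character(b$chrom)] + b$end
  if (is.null(main)) main <- sprintf("cohort summary (n = %d)", freq$n_samples)
  graphics::par(mar = c(3, 4, 2, 1))
  graphics::plot(NA, xlim = c(0, sum(lay$length)), ylim = c(-100, 100),
                 xlab = "", ylab = "% of samples (gain up / loss down)",
                 xaxt = "n", main = main)
  graphics::rect(x0, 0, x1, b$gain_pct, col = "forestgreen", border = NA)
  graphics::rect(x0, -b$loss_pct, x1, 0, col = "firebrick", border = NA)
  graphics::abline(h = 0, col = "grey40")
  graphics::abline(v = c(lay$offset, sum(lay$length)), col = "grey70")
  graphics::axis(1, at = lay$offset + lay$length / 2, labels = lay$chrom,
                 tick = FALSE, cex.axis = 0.7)
  invisible(path)
}
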