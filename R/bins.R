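# Genomic binning: partition each chromosome's probes into contiguous
# equal-probe runs, allocating the genome-wide bin budget proportionally.

#' Build genomic bins from a probe manifest
#'
#' Partitions the non-excluded probes of each chromosome into contiguous runs
#' so that the genome-wide bin count equals `target_bins` whenever the probe
#' supply allows. The budget is allocated across chromosomes proportionally to
#' their probe counts (largest-remainder rounding), capped so every bin keeps
#' at least `min_probes` probes; within a chromosome probes are split into
#' near-equal runs. No bin crosses a chromosome boundary. Chromosome Y is
#' excluded by default; X is binned but marked as a sex chromosome.
#'
#' @param manifest A [probe_manifest()].
#' @param target_bins Genome-wide bin target (default 8000).
#' @param min_probes Minimum probes per bin (default 15).
#' @param include_x,include_y Include the X (default `TRUE`) / Y (default
#'   `FALSE`) chromosome.
#' @param small_chrom What to do with a chromosome holding fewer than
#'   `min_probes` probes: `"single"` (one bin, default) or `"skip"`.
#' @return A `genomic_bins` data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `probe_count`, `sex_chrom`, and an attribute
#'   `probe_bin`: for each manifest row, the bin index it belongs to (`NA`
#'   for excluded or unbinned probes).
#' @export
build_bins <- function(manifest, target_bins = 8000, min_probes = 15,
                       include_x = TRUE, include_y = FALSE,
                       small_chrom = c("single", "skip")) {
  stopifnot(inherits(manifest, "probe_manifest"))
  small_chrom <- match.arg(small_chrom)
  if (target_bins < 1 || min_probes < 1) stop("target_bins and min_probes must be >= 1")

  drop_chrom <- character(0)
  if (!include_x) drop_chrom <- c(drop_chrom, "X")
  if (!include_y) drop_chrom <- c(drop_chrom, "Y")
  usable <- !manifest$excluded & !(as.character(manifest$chrom) %in% drop_chrom)

  empty <- data.frame(chrom = factor(character(0), levels = chrom_levels()),
                      start = numeric(0), end = numeric(0),
                      probe_count = integer(0), sex_chrom = logical(0))
  if (!any(usable)) {
    attr(empty, "probe_bin") <- rep(NA_integer_, nrow(manifest))
    class(empty) <- c("genomic_bins", "data.frame")
    return(empty)
  }

  counts <- table(droplevels(manifest$chrom[usable]))
  chroms <- names(counts)
  p <- as.integer(counts)

  small <- p < min_probes
  if (small_chrom == "skip" && any(small)) {
    chroms <- chroms[!small]; p <- p[!small]; small <- small[!small]
  }
  n_bins <- integer(length(p))
  n_bins[small] <- 1L

  big <- which(!small)
  if (length(big) > 0) {
    budget <- max(target_bins - sum(small), length(big))
    cap <- pmax(1L, p[big] %/% min_probes)
    quota <- budget * p[big] / sum(p[big])
    alloc <- pmin(cap, pmax(1L, floor(quota)))
    # distribute the remaining budget by largest fractional remainder
    leftover <- budget - sum(alloc)
    while (leftover > 0) {
      room <- which(alloc < cap)
      if (length(room) == 0) break
      pick <- room[which.max(quota[room] - alloc[room])]
      alloc[pick] <- alloc[pick] + 1L
      leftover <- leftover - 1L
    }
    while (leftover < 0) {
      shrinkable <- which(alloc > 1L)
      if (length(shrinkable) == 0) break
      pick <- shrinkable[which.min(quota[shrinkable] - alloc[shrinkable])]
      alloc[pick] <- alloc[pick] - 1L
      leftover <- leftover + 1L
    }
    n_bins[big] <- alloc
  }

  probe_bin <- rep(NA_integer_, nrow(manifest))
  rows <- vector("list", sum(n_bins))
  bin_i <- 0L
  for (ci in seq_along(chroms)) {
    cidx <- which(usable & as.character(manifest$chrom) == chroms[ci])
    nb <- n_bins[ci]
    cuts <- round(seq(0, length(cidx), length.out = nb + 1))
    for (b in seq_len(nb)) {
      member <- cidx[(cuts[b] + 1):cuts[b + 1]]
      bin_i <- bin_i + 1L
      probe_bin[member] <- bin_i
      rows[[bin_i]] <- data.frame(
        chrom = chroms[ci],
        start = manifest$pos[member[1]],
        end = manifest$pos[member[length(member)]] + 1,
        probe_count = length(member),
        stringsAsFactors = FALSE
      )
    }
  }
  bins <- do.call(rbind, rows)
  bins$chrom <- factor(bins$chrom, levels = chrom_levels())
  bins$sex_chrom <- as.character(bins$chrom) %in% c("X", "Y")
  rownames(bins) <- NULL
  attr(bins, "probe_bin") <- probe_bin
  class(bins) <- c("genomic_bins", "data.frame")
  bins
}

#' @export
print.genomic_bins <- function(x, ...) {
  cat(sprintf("genomic_bins: %d bins on %d chromosomes (min probes/bin: %s)\n",
              nrow(x), length(unique(as.character(x$chrom))),
              if (nrow(x)) min(x$probe_count) else "-"))
  invisible(x)
}
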