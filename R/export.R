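# Track exports: IGV-format bin track, SEG-format segments, event tables.

#' Export a binned profile as an IGV track
#'
#' Writes the tab-separated IGV format: a header line
#' `Chromosome Start End Feature <sample>` followed by one row per bin with
#' its log2 value (raw, not baseline-subtracted — the baseline can be drawn
#' as a track line). Rows are grouped and ordered by chromosome; a `chr`
#' prefix is added for viewer compatibility.
#'
#' @param profile A [bin_profile()].
#' @param path Output path (conventionally `.igv`).
#' @return `path`, invisibly.
#' @export
export_igv <- function(profile, path) {
  stopifnot(inherits(profile, "bin_profile"))
  b <- profile$bins
  d <- data.frame(
    Chromosome = paste0("chr", as.character(b$chrom)),
    Start = format(b$start, scientific = FALSE, trim = TRUE),
    End = format(b$end, scientific = FALSE, trim = TRUE),
    Feature = sprintf("bin_%05d", seq_len(nrow(b))),
    value = sprintf("%.6f", b$log2),
    stringsAsFactors = FALSE
  )
  names(d)[5] <- profile$sample_id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = "\t"), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back an exported IGV track
#'
#' @param path Path written by [export_igv()].
#' @return Data.frame with `chrom`, `start`, `end`, `feature`, `value`,
#'   and the sample id as attribute `sample_id`.
#' @export
read_igv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- data.frame(chrom = sub("^chr", "", d[[1]]), start = as.numeric(d[[2]]),
                    end = as.numeric(d[[3]]), feature = d[[4]],
                    value = as.numeric(d[[5]]), stringsAsFactors = FALSE)
  attr(out, "sample_id") <- names(d)[5]
  out
}

#' Export segments in SEG format
#'
#' Standard SEG columns: sample, chromosome, start, end, number of marks
#' (bins) and segment mean (baseline-relative log2).
#'
#' @param segments [segment_profile()] output.
#' @param path Output path (conventionally `.seg`).
#' @param sample_id Sample identifier; defaults to the one attached to the
#'   segments.
#' @return `path`, invisibly.
#' @export
export_seg <- function(segments, path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- attr(segments, "sample_id")
  if (is.null(sample_id)) sample_id <- "sample"
  s <- as.data.frame(segments)
  d <- data.frame(
    ID = sample_id,
    chrom = paste0("chr", as.character(s$chrom)),
    loc.start = format(s$start, scientific = FALSE, trim = TRUE),
    loc.end = format(s$end, scientific = FALSE, trim = TRUE),
    num.mark = s$n_bins,
    seg.mean = sprintf("%.6f", s$mean_log2),
    stringsAsFactors = FALSE
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a called-event table
#'
#' @param events [call_events()] output.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  d <- as.data.frame(events)
  d$chrom <- as.character(d$chrom)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
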