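# Cohort-level gain/loss frequency summaries over shared bin boundaries.

#' Summarize gain/loss frequencies across a cohort of profiles
#'
#' For every bin, counts the fraction of samples whose baseline-relative bin
#' value exceeds `+threshold` (gain) or falls below `-threshold` (loss) and
#' reports both as percentages. Amplitude is deliberately ignored: a
#' high-level amplification and a single-copy gain contribute identically.
#' Bins missing in a sample (NA) are excluded from that sample's denominator
#' at that bin.
#'
#' @param profiles List of baselined [bin_profile()]s sharing identical bin
#'   boundaries.
#' @param threshold Log2 magnitude counted as changed (default 0.15).
#' @return A `cohort_frequency`: list with `bins` (bin table plus `gain_pct`,
#'   `loss_pct`, `n_eff`) and `n_samples`.
#' @export
summarize_cohort <- function(profiles, threshold = 0.15) {
  if (length(profiles) < 1) stop("empty cohort")
  if (!all(vapply(profiles, inherits, TRUE, "bin_profile"))) {
    stop("profiles must be bin_profile objects")
  }
  if (any(vapply(profiles, function(p) is.na(p$baseline), TRUE))) {
    stop("all profiles must be baselined; run fit_baseline()")
  }
  key <- function(p) p$bins[, c("chrom", "start", "end")]
  ref <- key(profiles[[1]])
  for (p in profiles[-1]) {
    k <- key(p)
    if (nrow(k) != nrow(ref) ||
        !isTRUE(all.equal(k, ref, check.attributes = FALSE))) {
      stop("mismatched bin boundaries across cohort profiles")
    }
  }
  vals <- vapply(profiles, rel_values, numeric(nrow(ref)))
  n_eff <- rowSums(!is.na(vals))
  gain <- rowSums(vals >= threshold, na.rm = TRUE)
  loss <- rowSums(vals <= -threshold, na.rm = TRUE)
  b <- profiles[[1]]$bins[, c("chrom", "start", "end", "probe_count")]
  b$gain_pct <- ifelse(n_eff > 0, 100 * gain / n_eff, NA_real_)
  b$loss_pct <- ifelse(n_eff > 0, 100 * loss / n_eff, NA_real_)
  b$n_eff <- n_eff
  structure(list(bins = b, n_samples = length(profiles),
                 threshold = threshold),
            class = "cohort_frequency")
}

#' @export
print.cohort_frequency <- function(x, ...) {
  cat(sprintf(
    "cohort_frequency: %d samples, %d bins, call threshold +/-%.2f log2\n",
    x$n_samples, nrow(x$bins), x$threshold))
  invisible(x)
}

#' Write a cohort frequency table
#'
#' Tab-separated columns: `chrom`, `start`, `end`, `gain_pct`, `loss_pct`,
#' `n` (effective sample count per bin).
#'
#' @param freq A [summarize_cohort()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_frequency <- function(freq, path) {
  stopifnot(inherits(freq, "cohort_frequency"))
  d <- data.frame(chrom = as.character(freq$bins$chrom),
                  start = freq$bins$start, end = freq$bins$end,
                  gain_pct = freq$bins$gain_pct, loss_pct = freq$bins$loss_pct,
                  n = freq$bins$n_eff, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort frequency table back
#'
#' @param path Path written by [write_cohort_frequency()].
#' @return Data.frame with the table's columns.
#' @export
read_cohort_frequency <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
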