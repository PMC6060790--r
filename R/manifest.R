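# Probe manifest: the anchor shared by samples, reference panels and bins.

#' Construct a probe manifest
#'
#' A probe manifest maps array probes to genomic coordinates. All downstream
#' objects (intensities, reference panels, bins) are aligned to the manifest
#' row order, which is genome order: chromosome 1–22, X, Y, then position.
#' Coordinates are 0-based.
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param chrom Chromosome labels (`"1"`–`"22"`, `"X"`, `"Y"`; a `"chr"`
#'   prefix is tolerated).
#' @param pos Non-negative base-pair positions (0-based).
#' @param excluded Logical QC-exclusion flag per probe (default all `FALSE`).
#' @param affinity,meth_fraction Optional per-probe simulation attributes
#'   carried by synthetic manifests (see [simulate_manifest()]); real
#'   manifests omit them.
#' @return A `probe_manifest`: a data.frame sorted in genome order with
#'   columns `probe_id`, `chrom` (ordered factor), `pos`, `excluded`.
#' @seealso [read_manifest()], [simulate_manifest()]
#' @export
probe_manifest <- function(probe_id, chrom, pos, excluded = FALSE,
                           affinity = NULL, meth_fraction = NULL) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) stop("probe_ids must be unique")
  pos <- as.numeric(pos)
  if (any(!is.finite(pos)) || any(pos < 0)) stop("positions must be finite and non-negative")
  n <- length(probe_id)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  chrom <- as_chrom(chrom)
  stopifnot(length(chrom) == n, length(pos) == n)
  excluded <- rep_len(as.logical(excluded), n)
  m <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                  excluded = excluded, stringsAsFactors = FALSE)
  if (!is.null(affinity)) m$affinity <- rep_len(as.numeric(affinity), n)
  if (!is.null(meth_fraction)) m$meth_fraction <- rep_len(as.numeric(meth_fraction), n)
  ord <- order(as.integer(m$chrom), m$pos)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("probe_manifest", "data.frame")
  m
}

#' Read a probe manifest from a tab-separated file
#'
#' Expected columns: `probe_id`, `chrom`, `pos` and optionally `excluded`,
#' `affinity`, `meth_fraction`. Rows are re-sorted into genome order on load.
#'
#' @param path Path to a TSV file with a header line.
#' @return A [probe_manifest()].
#' @export
read_manifest <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(d))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  probe_manifest(d$probe_id, d$chrom, d$pos,
                 excluded = if ("excluded" %in% names(d)) d$excluded else FALSE,
                 affinity = d$affinity, meth_fraction = d$meth_fraction)
}

#' Write a probe manifest to a tab-separated file
#'
#' @param manifest A [probe_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "probe_manifest"))
  d <- as.data.frame(manifest)
  d$chrom <- as.character(d$chrom)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mark probes as excluded
#'
#' Applies a user-supplied exclusion list (e.g. cross-reactive or
#' SNP-overlapping probes) to the manifest QC flag. Excluded probes are
#' dropped from ratio formation and binning but retained in the manifest.
#'
#' @param manifest A [probe_manifest()].
#' @param probe_ids Probe identifiers to flag.
#' @return The manifest with updated `excluded` column.
#' @export
exclude_probes <- function(manifest, probe_ids) {
  stopifnot(inherits(manifest, "probe_manifest"))
  manifest$excluded <- manifest$excluded | manifest$probe_id %in% probe_ids
  manifest
}

#' @export
print.probe_manifest <- function(x, ...) {
  cat(sprintf("probe_manifest: %d probes on %d chromosomes (%d excluded)\n",
              nrow(x), length(unique(x$chrom[!is.na(x$chrom)])), sum(x$excluded)))
  invisible(x)
}
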