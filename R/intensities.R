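# Sample intensities, beta values, combined intensity and the flat-genome
# reference panel.

#' Construct per-sample probe intensities
#'
#' Holds the methylated and unmethylated channel intensities for one sample,
#' aligned to a probe manifest. Both channels must be finite and non-negative.
#'
#' @param sample_id Sample identifier.
#' @param probe_id Probe identifiers (must be a subset of the manifest when
#'   validated against one).
#' @param meth,unmeth Numeric intensity vectors, one value per probe.
#' @param reported_sex One of `"male"`, `"female"`, `"unknown"` — the sex on
#'   the request form, used by the sex-concordance QC step.
#' @return A `sample_intensities` object.
#' @export
sample_intensities <- function(sample_id, probe_id, meth, unmeth,
                               reported_sex = "unknown") {
  meth <- as.numeric(meth); unmeth <- as.numeric(unmeth)
  if (any(!is.finite(meth)) || any(!is.finite(unmeth))) {
    stop("intensities must be finite")
  }
  if (any(meth < 0) || any(unmeth < 0)) stop("intensities must be non-negative")
  probe_id <- as.character(probe_id)
  stopifnot(length(meth) == length(probe_id), length(unmeth) == length(probe_id))
  reported_sex <- match.arg(reported_sex, c("male", "female", "unknown"))
  structure(list(sample_id = as.character(sample_id), probe_id = probe_id,
                 meth = meth, unmeth = unmeth, reported_sex = reported_sex),
            class = "sample_intensities")
}

#' @export
print.sample_intensities <- function(x, ...) {
  cat(sprintf("sample_intensities: %s (%d probes, reported sex: %s)\n",
              x$sample_id, length(x$probe_id), x$reported_sex))
  invisible(x)
}

# Align a sample to the manifest row order; errors on probes missing from the
# manifest, returns NA for manifest probes the sample lacks.
align_to_manifest <- function(sample, manifest) {
  stopifnot(inherits(sample, "sample_intensities"),
            inherits(manifest, "probe_manifest"))
  idx <- match(sample$probe_id, manifest$probe_id)
  if (anyNA(idx)) {
    stop(sprintf("sample %s has %d probes absent from the manifest",
                 sample$sample_id, sum(is.na(idx))))
  }
  back <- match(manifest$probe_id, sample$probe_id)
  list(meth = sample$meth[back], unmeth = sample$unmeth[back])
}

#' Beta value from channel intensities
#'
#' The methylation fraction at a probe: `meth / (meth + unmeth + offset)`.
#' The offset stabilises low-intensity probes; with the platform-conventional
#' default of 100 the value lies in `[0, 1)`.
#'
#' @param meth,unmeth Non-negative intensities (vectorised).
#' @param offset Small positive constant added to the denominator
#'   (default 100; may be set to 0 when exact ratios are wanted).
#' @return Beta values in `[0, 1]`.
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  if (offset < 0) stop("offset must be >= 0")
  meth / (meth + unmeth + offset)
}

#' Combined copy-number intensity
#'
#' The methylated and unmethylated signals are added per probe; the sum is
#' proportional to the local DNA amount and is the quantity ratioed against
#' the flat-genome reference for CNV calling.
#'
#' @param sample A [sample_intensities()] object.
#' @return Numeric vector, `meth + unmeth` in the sample's probe order.
#' @export
combined_intensity <- function(sample) {
  stopifnot(inherits(sample, "sample_intensities"))
  sample$meth + sample$unmeth
}

#' Build a flat-genome reference panel
#'
#' Aggregates the combined intensities of copy-number-neutral reference
#' samples into a per-probe reference signal. Probes whose reference falls
#' below `floor` are flagged excluded (they cannot support a stable ratio);
#' manifest-level exclusions are carried over.
#'
#' @param samples List of at least 3 [sample_intensities()] sharing the
#'   manifest.
#' @param manifest The [probe_manifest()].
#' @param aggregator `"median"` (default, robust) or `"mean"`.
#' @param floor Minimum admissible reference intensity (default 50).
#' @return A `reference_panel`: list with `reference` (per-probe aggregate in
#'   manifest order), `excluded` (logical per probe), `n_samples`,
#'   `aggregator`.
#' @export
build_reference <- function(samples, manifest, aggregator = c("median", "mean"),
                            floor = 50) {
  aggregator <- match.arg(aggregator)
  if (length(samples) < 3) stop("insufficient reference panel: need >= 3 samples")
  stopifnot(inherits(manifest, "probe_manifest"))
  mat <- vapply(samples, function(s) {
    a <- align_to_manifest(s, manifest)
    a$meth + a$unmeth
  }, numeric(nrow(manifest)))
  agg <- if (aggregator == "median") {
    apply(mat, 1, stats::median)
  } else {
    rowMeans(mat)
  }
  excluded <- manifest$excluded | !is.finite(agg) | agg < floor
  structure(list(reference = agg, excluded = excluded,
                 n_samples = length(samples), aggregator = aggregator,
                 floor = floor),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d samples, %d probes (%d excluded), %s aggregation\n",
              x$n_samples, length(x$reference), sum(x$excluded), x$aggregator))
  invisible(x)
}

#' Read intensities from a wide two-column-per-sample table
#'
#' The table has a `probe_id` column and, per sample, columns
#' `<sample>_meth` and `<sample>_unmeth`.
#'
#' @param path TSV path.
#' @param reported_sex Optional named vector, sample id to reported sex.
#' @return Named list of [sample_intensities()].
#' @export
read_intensity_table <- function(path, reported_sex = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"probe_id" %in% names(d)) stop("intensity table needs a probe_id column")
  mcols <- grep("_meth$", names(d), value = TRUE)
  ids <- sub("_meth$", "", mcols)
  out <- lapply(ids, function(id) {
    um <- paste0(id, "_unmeth")
    if (!um %in% names(d)) stop("missing column ", um)
    rs <- if (!is.null(reported_sex) && id %in% names(reported_sex)) {
      reported_sex[[id]]
    } else "unknown"
    sample_intensities(id, d$probe_id, d[[paste0(id, "_meth")]], d[[um]],
                       reported_sex = rs)
  })
  names(out) <- ids
  out
}

#' Write intensities to a wide two-column-per-sample table
#'
#' @param samples List of [sample_intensities()] sharing one probe set.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(samples, path) {
  stopifnot(length(samples) >= 1)
  ids <- vapply(samples, `[[`, "", "sample_id")
  d <- data.frame(probe_id = samples[[1]]$probe_id, stringsAsFactors = FALSE)
  for (s in samples) {
    if (!identical(s$probe_id, d$probe_id)) stop("samples must share probe order")
    d[[paste0(s$sample_id, "_meth")]] <- s$meth
    d[[paste0(s$sample_id, "_unmeth")]] <- s$unmeth
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
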