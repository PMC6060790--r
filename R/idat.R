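#' IDAT ingestion boundary
#'
#' The package does not decode binary IDAT files itself; raw scanner output is
#' expected to be converted upstream. This adapter accepts any `reader`
#' function that maps an IDAT basename (the path without the `_Grn.idat` /
#' `_Red.idat` suffix) to a data.frame with columns `probe_id`, `meth`,
#' `unmeth`, and wraps the result as [sample_intensities()].
#'
#' @param basename IDAT basename handed to `reader`.
#' @param reader Function `(basename) -> data.frame(probe_id, meth, unmeth)`.
#' @param sample_id Sample identifier (defaults to the basename's file part).
#' @param reported_sex Reported sex for QC (see [sample_intensities()]).
#' @return A [sample_intensities()] object.
#' @export
read_idat_pair <- function(basename, reader, sample_id = base::basename(basename),
                           reported_sex = "unknown") {
  if (missing(reader) || !is.function(reader)) {
    stop("IDAT decoding is delegated: supply a reader function ",
         "(basename -> data.frame(probe_id, meth, unmeth))")
  }
  d <- reader(basename)
  need <- c("probe_id", "meth", "unmeth")
  if (!is.data.frame(d) || !all(need %in% names(d))) {
    stop("IDAT reader must return a data.frame with columns: ",
         paste(need, collapse = ", "))
  }
  sample_intensities(sample_id, d$probe_id, d$meth, d$unmeth,
                     reported_sex = reported_sex)
}
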