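#' @keywords internal
"_PACKAGE"

# hg19 chromosome lengths and p-arm boundaries (centromere start, approximate).
# Used for proportional probe placement by the simulator, arm annotation of
# events and the p/q separators in CNV plots.
.HG19 <- data.frame(
  chrom = c(as.character(1:22), "X", "Y"),
  length = c(
    249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
    159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
    115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
    59128983, 63025520, 48129895, 51304566, 155270560, 59373566
  ),
  p_end = c(
    121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
    58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
    16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
    24681782, 26369569, 11288129, 13000000, 58632012, 10104553
  ),
  stringsAsFactors = FALSE
)

#' Canonical chromosome ordering
#'
#' Chromosome labels used throughout the package: `"1"`–`"22"`, `"X"`, `"Y"`
#' (no `"chr"` prefix internally; exported IGV/SEG tracks add it).
#'
#' @return Character vector of the 24 chromosome labels in genome order.
#' @export
chrom_levels <- function() .HG19$chrom

#' Genome layout table
#'
#' @return A data.frame with one row per chromosome: `chrom`, `length` (bp,
#'   hg19) and `p_end` (approximate end of the p arm, bp).
#' @export
genome_info <- function() .HG19

# Coerce chromosome labels to the canonical ordered factor, accepting an
# optional "chr" prefix. Unknown labels raise an error.
as_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  bad <- setdiff(unique(x), .HG19$chrom)
  if (length(bad) > 0) {
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = .HG19$chrom)
}

# Ordering helper: genome order by (chromosome, position).
genome_order <- function(chrom, pos) order(as.integer(as_chrom(chrom)), pos)
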