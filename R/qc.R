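# Batch quality control: sex concordance, CNV noise scoring, cross-
# contamination scanning, expectation consistency, reanalysis flagging.

#' Predict sample sex from sex-chromosome intensities
#'
#' Compares the median combined intensity on X and on Y with the autosomal
#' median. Two X copies put the X ratio near 1 with no Y signal (female); one
#' X and one Y put the X ratio near 0.5 with clear Y signal (male). The
#' germline sex chromosomes are not diluted by tumor purity, so the call is
#' robust in low-purity samples. Anything in between — or missing
#' sex-chromosome probes — yields `"undetermined"`.
#'
#' @param sample A [sample_intensities()].
#' @param manifest The [probe_manifest()].
#' @param x_mid X/autosome ratio separating one from two X copies
#'   (default 0.75).
#' @param y_min Y/autosome ratio above which a Y chromosome is considered
#'   present (default 0.2); below `y_absent` (default 0.1) it is considered
#'   absent, between the two the call is undetermined.
#' @param y_absent See `y_min`.
#' @return List with `predicted_sex` (`"male"`, `"female"`,
#'   `"undetermined"`), `x_ratio`, `y_ratio`, and `concordant` (`TRUE`/
#'   `FALSE`/`NA` against the sample's `reported_sex`).
#' @export
predict_sex <- function(sample, manifest, x_mid = 0.75, y_min = 0.2,
                        y_absent = 0.1) {
  a <- align_to_manifest(sample, manifest)
  comb <- a$meth + a$unmeth
  ch <- as.character(manifest$chrom)
  keep <- !manifest$excluded & !is.na(comb)
  auto <- stats::median(comb[keep & !(ch %in% c("X", "Y"))])
  xi <- comb[keep & ch == "X"]; yi <- comb[keep & ch == "Y"]
  if (length(xi) < 100 || !is.finite(auto) || auto <= 0) {
    res <- "undetermined"; rx <- NA_real_; ry <- NA_real_
  } else {
    rx <- stats::median(xi) / auto
    ry <- if (length(yi) > 0) stats::median(yi) / auto else 0
    res <- if (ry >= y_min && rx <= x_mid) {
      "male"
    } else if (ry <= y_absent && rx > x_mid) {
      "female"
    } else {
      "undetermined"
    }
  }
  conc <- if (sample$reported_sex == "unknown" || res == "undetermined") {
    NA
  } else {
    identical(res, sample$reported_sex)
  }
  list(predicted_sex = res, x_ratio = rx, y_ratio = ry, concordant = conc)
}

#' CNV noise score of a binned profile
#'
#' The median absolute difference between consecutive within-chromosome bin
#' log2 values. Being derivative-based it is insensitive to the profile's
#' level and to genuine copy-number steps (steps occupy a sparse set of bin
#' junctions, so the median ignores them); for i.i.d. Gaussian bin noise with
#' standard deviation `sigma` the score converges to
#' `qnorm(0.75) * sqrt(2) * sigma ~= 0.954 * sigma`. There is no community-
#' standard numeric noise metric for these plots — plots are conventionally
#' judged by eye — so this metric and its default grade cutoffs are this
#' package's operational definition.
#'
#' @param profile A [bin_profile()] with at least 2 usable bins on some
#'   chromosome.
#' @return Scalar noise score (log2 units).
#' @seealso [grade_noise()]
#' @export
noise_score <- function(profile) {
  stopifnot(inherits(profile, "bin_profile"))
  b <- profile$bins
  diffs <- unlist(lapply(split(b$log2, b$chrom), function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2) abs(diff(x)) else numeric(0)
  }), use.names = FALSE)
  if (length(diffs) == 0) {
    stop("noise score needs at least 2 usable bins on some chromosome")
  }
  stats::median(diffs)
}

#' Grade a noise score
#'
#' @param score [noise_score()] value.
#' @param crisp Upper bound of the crisp grade (default 0.1).
#' @param unusable Lower bound of the unusable grade (default 0.3); CNV
#'   information should not be extracted from unusable profiles and
#'   reanalysis is recommended.
#' @return `"crisp"`, `"elevated"` or `"unusable"`.
#' @export
grade_noise <- function(score, crisp = 0.1, unusable = 0.3) {
  if (!is.finite(score) || score < 0) stop("invalid noise score")
  if (score < crisp) "crisp" else if (score > unusable) "unusable" else "elevated"
}

#' Scan a batch for cross-contamination via shared amplified regions
#'
#' Contamination of one array preparation by DNA from another becomes visible
#' through the donor's amplifications: their massive copy number makes them
#' surface in the recipient as focal gains or amplifications at the identical
#' loci even at minimal contamination fractions, while the donor's ordinary
#' gains and losses stay invisible. For every sample carrying at least one
#' amplification, every other batch member is scanned for an amplification or
#' focal gain whose interval reciprocally overlaps at least `min_overlap` of
#' both events; pairs sharing one or more regions are flagged.
#'
#' @param batch Named list of [call_events()] tables, one per sample.
#' @param min_overlap Reciprocal-overlap fraction counting two events as the
#'   identical region (default 0.5).
#' @return Data.frame with one row per flagged unordered pair: `sample_a`
#'   (the amplification carrier), `sample_b`, `n_shared`, `regions`
#'   (semicolon-joined `chrom:start-end`). Empty for batches of size < 2.
#' @export
contamination_scan <- function(batch, min_overlap = 0.5) {
  empty <- data.frame(sample_a = character(0), sample_b = character(0),
                      n_shared = integer(0), regions = character(0),
                      stringsAsFactors = FALSE)
  if (length(batch) < 2) return(empty)
  ids <- names(batch)
  if (is.null(ids)) stop("batch must be a named list of event tables")
  amp_of <- lapply(batch, function(ev) {
    ev <- as.data.frame(ev)
    ev[ev$kind == "amplification", , drop = FALSE]
  })
  recip_of <- lapply(batch, function(ev) {
    ev <- as.data.frame(ev)
    ev[ev$kind == "amplification" |
         (ev$kind == "gain" & isTRUE_vec(ev$focal)), , drop = FALSE]
  })
  out <- list()
  seen <- character(0)
  for (i in seq_along(ids)) {
    amps <- amp_of[[i]]
    if (nrow(amps) == 0) next
    for (j in seq_along(ids)) {
      if (i == j) next
      pair_key <- paste(sort(c(ids[i], ids[j])), collapse = "\r")
      if (pair_key %in% seen) next
      cand <- recip_of[[j]]
      if (nrow(cand) == 0) next
      shared <- character(0)
      for (k in seq_len(nrow(amps))) {
        ov <- as.character(cand$chrom) == as.character(amps$chrom[k]) &
          cand$start < amps$end[k] & cand$end > amps$start[k]
        if (any(ov)) {
          inter <- pmin(cand$end[ov], amps$end[k]) - pmax(cand$start[ov], amps$start[k])
          frac <- pmin(inter / (amps$end[k] - amps$start[k]),
                       inter / (cand$end[ov] - cand$start[ov]))
          if (any(frac >= min_overlap)) {
            shared <- c(shared, sprintf("%s:%d-%d", amps$chrom[k],
                                        as.integer(amps$start[k]),
                                        as.integer(amps$end[k])))
          }
        }
      }
      if (length(shared) > 0) {
        seen <- c(seen, pair_key)
        out[[length(out) + 1]] <- data.frame(
          sample_a = ids[i], sample_b = ids[j],
          n_shared = length(shared),
          regions = paste(shared, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Check batch decisions against expected diagnoses
#'
#' Flags samples whose top methylation class differs from the expected class
#' supplied with the batch; when every expectation in a batch of four or more
#' mismatches, a batch-level warning suggests a systematic error such as an
#' array loaded in reverse order.
#'
#' @param decisions List of [decide()] reports.
#' @param expected Named character vector: sample id to expected top class.
#'   Samples without an expectation are skipped.
#' @return Data.frame of mismatches (`sample_id`, `expected`, `observed`)
#'   with attribute `batch_warning` (`TRUE` when all checked samples in a
#'   batch of >= 4 mismatch).
#' @export
consistency_check <- function(decisions, expected) {
  ids <- vapply(decisions, `[[`, "", "sample_id")
  obs <- vapply(decisions, `[[`, "", "top_class")
  checked <- ids[ids %in% names(expected)]
  mis <- checked[expected[checked] != obs[match(checked, ids)]]
  out <- data.frame(sample_id = mis,
                    expected = unname(expected[mis]),
                    observed = obs[match(mis, ids)],
                    stringsAsFactors = FALSE)
  attr(out, "batch_warning") <-
    length(checked) >= 4 && length(mis) == length(checked)
  out
}

#' Run the batch quality-control workflow
#'
#' Applies the standard per-run QC steps to a batch: sex prediction and
#' concordance with the reported sex, noise scoring and grading of each CNV
#' profile, and the cross-contamination scan over called events. An unusable
#' noise grade, a sex mismatch, or a contamination flag each set
#' `reanalysis_recommended`; contamination flags are advisory (the usability
#' of lightly contaminated data is a case-by-case decision).
#'
#' @param samples Named list of [sample_intensities()].
#' @param profiles Named list of baselined [bin_profile()]s (same names).
#' @param events Named list of [call_events()] tables (same names).
#' @param manifest The shared manifest.
#' @param noise_crisp,noise_unusable Grade cutoffs, see [grade_noise()].
#' @return A `qc_report`: list with `samples` (per-sample data.frame:
#'   `sample_id`, `reported_sex`, `predicted_sex`, `sex_concordant`,
#'   `noise_score`, `noise_grade`, `contamination_partners`,
#'   `reanalysis_recommended`) and `contamination` (the scan table).
#' @export
run_batch_qc <- function(samples, profiles, events, manifest,
                         noise_crisp = 0.1, noise_unusable = 0.3) {
  ids <- names(samples)
  stopifnot(!is.null(ids), identical(ids, names(profiles)),
            identical(ids, names(events)))
  contam <- contamination_scan(events)
  rows <- lapply(ids, function(id) {
    sx <- predict_sex(samples[[id]], manifest)
    ns <- noise_score(profiles[[id]])
    grade <- grade_noise(ns, crisp = noise_crisp, unusable = noise_unusable)
    partners <- unique(c(contam$sample_b[contam$sample_a == id],
                         contam$sample_a[contam$sample_b == id]))
    data.frame(
      sample_id = id,
      reported_sex = samples[[id]]$reported_sex,
      predicted_sex = sx$predicted_sex,
      sex_concordant = if (is.na(sx$concordant)) NA else sx$concordant,
      noise_score = ns,
      noise_grade = grade,
      contamination_partners = paste(partners, collapse = ","),
      reanalysis_recommended = grade == "unusable" ||
        isFALSE(sx$concordant) || length(partners) > 0,
      stringsAsFactors = FALSE)
  })
  structure(list(samples = do.call(rbind, rows), contamination = contam),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  d <- x$samples
  cat(sprintf("qc_report: %d samples, %d flagged for reanalysis, %d contamination pair(s)\n",
              nrow(d), sum(d$reanalysis_recommended), nrow(x$contamination)))
  invisible(x)
}

#' Write the per-sample QC table
#'
#' @param report A [run_batch_qc()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  utils::write.table(report$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
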