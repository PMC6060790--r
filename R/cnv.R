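# Single-sample CNV calling: probe log2 ratios, binned profile, minimal-MAD
# baseline, recursive binary segmentation, focal-event calling.

#' Per-probe copy-number log2 ratio against a reference panel
#'
#' The sample's combined (methylated + unmethylated) intensities are scaled so
#' that their genome-wide median over usable probes equals the reference
#' median, then `log2(sample / reference)` is taken per probe. The median
#' matching removes the arbitrary overall intensity scale; the copy-number
#' neutral level is established later by the minimal-MAD baseline.
#'
#' @param sample A [sample_intensities()].
#' @param panel A [build_reference()] panel.
#' @param manifest The shared [probe_manifest()].
#' @param scaling `"median-match"` (default) or `"quantile"`, which matches
#'   the deciles of the combined-intensity distribution instead of the median
#'   alone.
#' @param clamp Symmetric bound applied to the ratios (default 4 log2 units),
#'   containing the unbounded negative ratios of homozygous deletions.
#' @return Numeric vector of log2 ratios in manifest order; `NA` at excluded
#'   probes.
#' @export
probe_log2 <- function(sample, panel, manifest,
                       scaling = c("median-match", "quantile"), clamp = 4) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(panel, "reference_panel"))
  a <- align_to_manifest(sample, manifest)
  comb <- a$meth + a$unmeth
  use <- !panel$excluded & !is.na(comb)
  if (any(use & panel$reference <= 0)) {
    stop("zero or negative reference at a non-excluded probe; raise the reference floor")
  }
  if (!any(use)) stop("no usable probes shared between sample and panel")
  out <- rep(NA_real_, nrow(manifest))
  if (scaling == "median-match") {
    f <- stats::median(panel$reference[use]) / stats::median(comb[use])
    scaled <- comb * f
  } else {
    qs <- seq(0.1, 0.9, by = 0.1)
    f <- stats::approxfun(stats::quantile(comb[use], qs),
                          stats::quantile(panel$reference[use], qs),
                          rule = 2)
    scaled <- f(comb)
  }
  lr <- log2(scaled[use] / panel$reference[use])
  out[use] <- pmin(pmax(lr, -clamp), clamp)
  out
}

#' Aggregate probe log2 ratios into a binned profile
#'
#' Each bin's value is the median of its member probes' log2 ratios — the
#' colored dots of a single-case CNV plot. The baseline is unset until
#' [fit_baseline()] is applied.
#'
#' @param log2_ratios Per-probe log2 ratios in manifest order
#'   (from [probe_log2()]).
#' @param bins [build_bins()] output for the same manifest.
#' @param sample_id Sample identifier attached to the profile.
#' @return A `bin_profile`: list with `sample_id`, `bins` (the bin table plus
#'   a `log2` column), and `baseline` (`NA` until fitted).
#' @export
bin_profile <- function(log2_ratios, bins, sample_id = "sample") {
  stopifnot(inherits(bins, "genomic_bins"))
  pb <- attr(bins, "probe_bin")
  if (length(log2_ratios) != length(pb)) {
    stop("log2_ratios must be aligned to the manifest the bins were built from")
  }
  vals <- rep(NA_real_, nrow(bins))
  ok <- !is.na(pb) & !is.na(log2_ratios)
  if (any(ok)) {
    med <- tapply(log2_ratios[ok], pb[ok], stats::median)
    vals[as.integer(names(med))] <- as.numeric(med)
  }
  b <- as.data.frame(bins)
  b$log2 <- vals
  structure(list(sample_id = sample_id, bins = b, baseline = NA_real_),
            class = "bin_profile")
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("bin_profile: %s (%d bins, baseline %s)\n", x$sample_id,
              nrow(x$bins),
              if (is.na(x$baseline)) "unset" else sprintf("%.4f", x$baseline)))
  invisible(x)
}

# Baseline-relative bin values.
rel_values <- function(profile) {
  stopifnot(inherits(profile, "bin_profile"))
  b <- if (is.na(profile$baseline)) 0 else profile$baseline
  profile$bins$log2 - b
}

#' Minimal-MAD baseline of a binned profile
#'
#' Methylation arrays carry no allele-frequency information, so the
#' copy-number-neutral level is taken as the shift `b` minimizing the median
#' absolute deviation `median(|log2 - b|)` over all bins — the line closest to
#' the predominant copy-number state. A grid search over the value range at
#' `step` resolution is used. For even bin counts the lower middle order
#' statistic serves as the median: the averaged form has flat tie plateaus
#' wider than the grid step, whereas the lower form has a generically unique
#' minimizer, keeping the fit translation-equivariant. Remaining exact ties
#' are broken toward the smallest `|b|` (the "most of the genome is neutral"
#' reading).
#'
#' @param profile A [bin_profile()] (>= 10 non-missing bins, unless the
#'   profile is degenerate).
#' @param step Grid resolution in log2 units (default 0.001).
#' @return The profile with `baseline` set.
#' @seealso [fit_baseline_value()] for the scalar search on a bare vector.
#' @export
fit_baseline <- function(profile, step = 0.001) {
  stopifnot(inherits(profile, "bin_profile"))
  profile$baseline <- fit_baseline_value(profile$bins$log2, step = step)
  profile
}

#' @rdname fit_baseline
#' @param values Numeric vector of bin log2 values (`NA` dropped).
#' @export
fit_baseline_value <- function(values, step = 0.001) {
  x <- values[!is.na(values)]
  if (length(x) == 0) stop("no bin values to fit a baseline to")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  if (length(x) < 10) {
    warning("fewer than 10 bins; baseline fit may be unstable")
  }
  grid <- unique(c(seq(rng[1], rng[2], by = step), rng[2]))
  k <- ceiling(length(x) / 2)
  mads <- vapply(grid, function(b) sort(abs(x - b), partial = k)[k], numeric(1))
  best <- mads <= min(mads) + 1e-9
  cand <- grid[best]
  cand[which.min(abs(cand))]
}

# Circular scan: the maximal two-sample t statistic comparing a candidate
# interior segment x[(i+1)..j] against the rest of the sequence, maximized
# over all (i, j). The two-boundary ("circular") form lets a short embedded
# segment — e.g. a focal amplification — be cut out in a single test, which a
# single-cut statistic cannot do. Returns list(stat, i, j); stat is -Inf when
# no admissible candidate exists.
best_segment <- function(x, min_width = 1L) {
  n <- length(x)
  best <- list(stat = -Inf, i = NA_integer_, j = NA_integer_)
  if (n < 2L || n < min_width + 1L) return(best)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x * x))
  S <- cs[n + 1]; S2 <- cs2[n + 1]
  df <- max(n - 2L, 1L)
  for (L in seq.int(min_width, n - 1L)) {
    n_out <- n - L
    starts <- 0:(n - L)                       # segment covers (i+1)..(i+L)
    sum_in <- cs[starts + L + 1] - cs[starts + 1]
    ss_in <- cs2[starts + L + 1] - cs2[starts + 1] - sum_in^2 / L
    m_in <- sum_in / L
    m_out <- (S - sum_in) / n_out
    ss_out <- (S2 - (cs2[starts + L + 1] - cs2[starts + 1])) -
      (S - sum_in)^2 / n_out
    sp <- sqrt(pmax(ss_in + ss_out, 0) / df)
    se <- sp * sqrt(1 / L + 1 / n_out)
    t <- abs(m_in - m_out) / se
    zero <- se == 0
    if (any(zero)) t[zero] <- ifelse(abs(m_in - m_out)[zero] > 0, Inf, 0)
    k <- which.max(t)
    if (length(k) == 1 && t[k] > best$stat) {
      best <- list(stat = t[k], i = starts[k], j = starts[k] + L)
    }
  }
  best
}

# Permutation p-value for the best segment of x; uses the caller's RNG.
# Stops early once enough exceedances accrue that p cannot fall below alpha.
segment_p_value <- function(x, obs, n_perm, min_width, alpha = 1) {
  if (is.infinite(obs)) return(if (obs > 0) 0 else 1)
  give_up <- floor(alpha * (n_perm + 1))   # ge > give_up - 1 means p > alpha
  ge <- 0L
  for (i in seq_len(n_perm)) {
    s <- best_segment(sample(x), min_width)$stat
    if (s >= obs) {
      ge <- ge + 1L
      if (ge + 1L > give_up) return((1 + ge) / (n_perm + 1))
    }
  }
  (1 + ge) / (n_perm + 1)
}

# Recursive segmentation of one chromosome's bin values; returns cut
# positions 0 = c0 < c1 < ... < ck = n delimiting segments.
#
# A candidate segment is accepted through either of two routes, both at
# level alpha:
#  * a z bound: the mean shift standardized by a robust noise estimate
#    (median absolute consecutive difference, insensitive to the shift
#    itself) exceeds the Bonferroni-corrected Gaussian critical value over
#    all candidate segments. This decides overwhelming changes immediately
#    and, unlike the permutation route, can isolate a 1-2-bin focal
#    amplification: a permutation reassembles such a pair adjacently with
#    probability ~2/n, putting alpha out of reach on short chromosomes.
#  * the permutation test: the max statistic of the observed sequence
#    against its value on permuted sequences.
segment_sequence <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < min_width + 1L) return(c(0L, n))
  bs <- best_segment(x, min_width)
  if (!is.finite(bs$stat) || bs$stat <= 0) return(c(0L, n))
  accept <- FALSE
  if (n >= 8) {
    sigma <- stats::median(abs(diff(x))) / (stats::qnorm(0.75) * sqrt(2))
    if (sigma > 0) {
      L <- bs$j - bs$i
      seg_idx <- (bs$i + 1):bs$j
      z <- abs(mean(x[seg_idx]) - mean(x[-seg_idx])) /
        (sigma * sqrt(1 / L + 1 / (n - L)))
      z_crit <- stats::qnorm(1 - alpha / (2 * n * (n - 1) / 2))
      accept <- is.finite(z) && z >= z_crit
    }
  }
  if (!accept) {
    p <- segment_p_value(x, bs$stat, n_perm, min_width, alpha = alpha)
    accept <- p <= alpha
  }
  if (!accept) return(c(0L, n))
  cuts <- c(0L)
  pieces <- list(c(0L, bs$i), c(bs$i, bs$j), c(bs$j, n))
  for (pc in pieces) {
    len <- pc[2] - pc[1]
    if (len == 0L) next
    sub <- segment_sequence(x[(pc[1] + 1):pc[2]], alpha, n_perm, min_width)
    cuts <- c(cuts, pc[1] + sub[-1])
  }
  unique(cuts)
}

#' Segment a baselined profile into piecewise-constant copy-number levels
#'
#' Per chromosome, recursive binary splitting with a circular scan: the
#' candidate interior segment maximizing the two-sample t statistic against
#' the rest of the chromosome is accepted when significant at `alpha` —
#' immediately, when its mean shift standardized by a robust noise estimate
#' clears a Bonferroni-corrected Gaussian bound, or otherwise by a
#' permutation test on the maximum statistic — and the resulting pieces are
#' segmented recursively. Flat input yields one segment per chromosome.
#' Segment means are unweighted means of member-bin values,
#' baseline-relative.
#'
#' @param profile A baselined [bin_profile()].
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_perm Number of permutations per test (default 200).
#' @param min_width Minimum segment width in bins (default 1, so single-bin
#'   focal amplifications can be isolated).
#' @return A `cn_segments` data.frame: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_log2` (baseline-relative).
#' @export
segment_profile <- function(profile, alpha = 0.01, n_perm = 200, min_width = 1L) {
  stopifnot(inherits(profile, "bin_profile"))
  if (is.na(profile$baseline)) {
    stop("profile has no baseline; run fit_baseline() first")
  }
  b <- profile$bins
  v <- rel_values(profile)
  out <- list()
  for (ch in unique(as.character(b$chrom))) {
    idx <- which(as.character(b$chrom) == ch & !is.na(v))
    if (length(idx) == 0) next
    x <- v[idx]
    cuts <- segment_sequence(x, alpha, n_perm, min_width)
    for (s in seq_len(length(cuts) - 1)) {
      member <- idx[(cuts[s] + 1):cuts[s + 1]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start = b$start[member[1]],
        end = b$end[member[length(member)]],
        n_bins = length(member),
        mean_log2 = mean(x[(cuts[s] + 1):cuts[s + 1]]),
        stringsAsFactors = FALSE
      )
    }
  }
  seg <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_bins = integer(0), mean_log2 = numeric(0))
  }
  seg$chrom <- factor(seg$chrom, levels = chrom_levels())
  seg <- seg[order(as.integer(seg$chrom), seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  attr(seg, "sample_id") <- profile$sample_id
  class(seg) <- c("cn_segments", "data.frame")
  seg
}

#' Call copy-number events from segments
#'
#' Classifies baseline-relative segments: short high-amplitude segments are
#' focal amplifications (`mean >= amp_threshold`) or homozygous deletions
#' (`mean <= -amp_threshold`); everything else beyond `call_threshold` is a
#' gain or loss (numerical/arm-scale changes, or focal low-level gains when
#' short). Events overlapping a highlight gene carry the gene symbol(s).
#'
#' @param segments [segment_profile()] output.
#' @param amp_threshold Log2 bound for amplification / homozygous deletion
#'   relative to baseline (default 0.4).
#' @param call_threshold Log2 bound for any gain/loss call (default 0.15).
#' @param focal_cap Maximum length in bp of a focal event (default 10 Mb);
#'   high-amplitude segments longer than this are reported as gain/loss.
#' @param genes Highlight-gene table (`chrom`, `start`, `end`, `symbol`), by
#'   default the bundled 29-gene CNS list (see [highlight_genes()]). A bare
#'   character vector is rejected: coordinates are required.
#' @return A `focal_events` data.frame: `chrom`, `start`, `end`, `length`,
#'   `n_bins`, `mean_log2`, `kind` (amplification / homozygous_deletion /
#'   gain / loss), `focal` (length <= cap), `gene` (comma-joined symbols or
#'   `NA`).
#' @export
call_events <- function(segments, amp_threshold = 0.4, call_threshold = 0.15,
                        focal_cap = 10e6, genes = highlight_genes()) {
  stopifnot(inherits(segments, "cn_segments") || is.data.frame(segments))
  if (is.character(genes)) {
    stop("missing gene coordinates for: ", paste(genes, collapse = ", "),
         " (supply a table with chrom, start, end, symbol)")
  }
  if (!is.null(genes)) {
    need <- c("chrom", "start", "end", "symbol")
    if (!all(need %in% names(genes))) {
      stop("gene table must have columns: ", paste(need, collapse = ", "))
    }
  }
  s <- as.data.frame(segments)
  s$length <- s$end - s$start
  hit <- abs(s$mean_log2) >= call_threshold
  ev <- s[hit, , drop = FALSE]
  if (nrow(ev) > 0) {
    ev$focal <- ev$length <= focal_cap
    high <- abs(ev$mean_log2) >= amp_threshold
    ev$kind <- ifelse(high & ev$focal & ev$mean_log2 > 0, "amplification",
               ifelse(high & ev$focal, "homozygous_deletion",
               ifelse(ev$mean_log2 > 0, "gain", "loss")))
    ev$gene <- NA_character_
    if (!is.null(genes) && nrow(genes) > 0) {
      gch <- sub("^chr", "", as.character(genes$chrom))
      for (i in seq_len(nrow(ev))) {
        ov <- gch == as.character(ev$chrom[i]) &
          genes$start < ev$end[i] & genes$end > ev$start[i]
        if (any(ov)) ev$gene[i] <- paste(genes$symbol[ov], collapse = ",")
      }
    }
  } else {
    ev$focal <- logical(0); ev$kind <- character(0); ev$gene <- character(0)
  }
  rownames(ev) <- NULL
  attr(ev, "sample_id") <- attr(segments, "sample_id")
  class(ev) <- c("focal_events", "data.frame")
  ev
}

#' Bundled highlight-gene regions
#'
#' The 29 CNS-tumor-relevant gene regions highlighted by default on CNV plots
#' and used to annotate called events (approximate hg19 coordinates, bundled
#' as a reconstruction of the commonly highlighted set: EGFR, CDKN2A/B, MYC,
#' MYCN, CDK4/6, MDM2/4, PDGFRA, PTEN, RB1, TP53, NF1/2, SMARCB1, BRAF, TERT
#' and others).
#'
#' @param path Optional path to a user-supplied BED-like TSV
#'   (`chrom`, `start`, `end`, `symbol`).
#' @return Data.frame with columns `chrom`, `start`, `end`, `symbol`.
#' @export
highlight_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "highlight_genes_hg19.tsv",
                        package = "methylDx", mustWork = TRUE)
  }
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "symbol")
  if (!all(need %in% names(g))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  g$chrom <- sub("^chr", "", as.character(g$chrom))
  g
}

#' Run the full single-sample CNV pipeline
#'
#' Convenience wrapper: [probe_log2()] -> [bin_profile()] -> [fit_baseline()]
#' -> [segment_profile()] -> [call_events()].
#'
#' @param sample A [sample_intensities()].
#' @param panel A [build_reference()] panel.
#' @param manifest The shared manifest.
#' @param bins Prebuilt [build_bins()] (built with defaults when `NULL`).
#' @param ... Passed to [segment_profile()] and [call_events()] (matched by
#'   name: `alpha`, `n_perm`, `min_width`, `amp_threshold`, `call_threshold`,
#'   `focal_cap`, `genes`).
#' @return List with `profile`, `segments`, `events`.
#' @export
cnv_pipeline <- function(sample, panel, manifest, bins = NULL, ...) {
  dots <- list(...)
  pick <- function(f) dots[intersect(names(dots), names(formals(f)))]
  if (is.null(bins)) bins <- build_bins(manifest)
  lr <- probe_log2(sample, panel, manifest)
  prof <- fit_baseline(bin_profile(lr, bins, sample_id = sample$sample_id))
  seg <- do.call(segment_profile, c(list(prof), pick(segment_profile)))
  ev <- do.call(call_events, c(list(seg), pick(call_events)))
  list(profile = prof, segments = seg, events = ev)
}
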