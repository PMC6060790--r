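# Synthetic data: manifests, flat-genome reference panels, tumors with known
# copy-number truth / purity / sex, contamination mixtures, score vectors.
# All generators are deterministic under a fixed seed.

#' Simulate a probe manifest
#'
#' A down-scaled genome: probes are spread over chromosomes 1–22, X and Y
#' proportionally to hg19 chromosome lengths, evenly spaced within each
#' chromosome. Each probe carries two fixed properties drawn once with the
#' manifest: a multiplicative `affinity` (log-normal, capturing probe-to-
#' probe intensity differences) and a `meth_fraction` (bimodal Beta mixture,
#' the probe's methylation level splitting the combined signal into the two
#' channels). The `"test"` scale (~30,000 probes) runs full pipelines in
#' seconds with ~800 bins; the `"full"` scale (~450,000 probes) matches a
#' genome-wide array and supports the default 8000-bin configuration.
#'
#' @param scale `"test"` (default) or `"full"`; alternatively set `n_probes`
#'   directly.
#' @param n_probes Total probe count (overrides `scale`).
#' @param seed Integer seed; the manifest is bit-identical for a given seed.
#' @param affinity_sd Log-scale standard deviation of probe affinity
#'   (default 0.3).
#' @return A [probe_manifest()] with `affinity` and `meth_fraction` columns.
#' @export
simulate_manifest <- function(scale = c("test", "full"), n_probes = NULL,
                              seed = 1, affinity_sd = 0.3) {
  scale <- match.arg(scale)
  if (is.null(n_probes)) n_probes <- if (scale == "full") 450000L else 30000L
  if (n_probes < 1000) stop("n_probes must be >= 1000")
  set.seed(seed)
  gi <- genome_info()
  alloc <- round(n_probes * gi$length / sum(gi$length))
  alloc[alloc < 10] <- 10L
  chrom <- rep(gi$chrom, alloc)
  pos <- unlist(lapply(seq_len(nrow(gi)), function(i) {
    round(seq(1e4, gi$length[i] - 1e4, length.out = alloc[i]))
  }), use.names = FALSE)
  n <- length(chrom)
  affinity <- exp(stats::rnorm(n, 0, affinity_sd))
  # bimodal methylation landscape: mostly unmethylated CpG islands plus a
  # methylated compartment
  comp <- stats::runif(n) < 0.4
  meth_fraction <- ifelse(comp, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
  probe_manifest(sprintf("cg%08d", seq_len(n)), chrom, pos,
                 affinity = affinity, meth_fraction = meth_fraction)
}

#' Define a copy-number ground truth
#'
#' The truth states the tumor's absolute integer copy number on a set of
#' non-overlapping genomic segments (elsewhere the genome is neutral), the
#' germline sex, and the tumor purity. The observed copy number at a locus is
#' the purity-weighted mixture of the tumor copy number and the germline
#' state: `purity * cn + (1 - purity) * germline`.
#'
#' @param segments Data.frame with columns `chrom`, `start`, `end`, `cn`
#'   (non-negative integers); may be empty for a flat genome.
#' @param sex `"male"` or `"female"` (germline; sets the X/Y baseline).
#' @param purity Tumor-cell fraction in `(0, 1]`.
#' @return A `cn_truth` object.
#' @export
cn_truth <- function(segments = NULL, sex = c("female", "male"), purity = 1) {
  sex <- match.arg(sex)
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), cn = numeric(0))
  } else {
    need <- c("chrom", "start", "end", "cn")
    if (!all(need %in% names(segments))) {
      stop("truth segments need columns: ", paste(need, collapse = ", "))
    }
    segments$chrom <- as.character(as_chrom(segments$chrom))
    if (any(segments$cn < 0) || any(segments$cn != round(segments$cn))) {
      stop("truth copy numbers must be non-negative integers")
    }
    if (any(segments$end <= segments$start)) stop("truth segments must have end > start")
    sp <- split(segments, segments$chrom)
    for (s in sp) {
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
        stop("overlapping truth segments on chromosome ", s$chrom[1])
      }
    }
  }
  structure(list(segments = segments, sex = sex, purity = purity),
            class = "cn_truth")
}

#' Write / read a copy-number truth file
#'
#' BED-like TSV (`chrom`, `start`, `end`, `cn`) with `#sex=` and `#purity=`
#' header comments, for comparison harnesses.
#'
#' @param truth A [cn_truth()].
#' @param path File path.
#' @return `path` invisibly; `read_truth` returns a [cn_truth()].
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "cn_truth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sex=%s", truth$sex),
               sprintf("#purity=%g", truth$purity),
               paste(c("chrom", "start", "end", "cn"), collapse = "\t")), con)
  if (nrow(truth$segments) > 0) {
    utils::write.table(truth$segments[, c("chrom", "start", "end", "cn")], con,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  hdr <- readLines(path, n = 10)
  sex <- sub("^#sex=", "", grep("^#sex=", hdr, value = TRUE)[1])
  purity <- as.numeric(sub("^#purity=", "", grep("^#purity=", hdr, value = TRUE)[1]))
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cn_truth(if (nrow(d)) d else NULL, sex = sex, purity = purity)
}

# Germline copy number per probe for a given sex.
germline_cn <- function(manifest, sex) {
  ch <- as.character(manifest$chrom)
  g <- rep(2, nrow(manifest))
  if (sex == "male") {
    g[ch == "X"] <- 1; g[ch == "Y"] <- 1
  } else {
    g[ch == "Y"] <- 0
  }
  g
}

# Expected combined intensity per probe (before noise), on the scale where a
# neutral diploid autosome equals `scale * affinity`.
expected_combined <- function(manifest, truth, scale, bg_frac) {
  g <- germline_cn(manifest, truth$sex)
  cn <- g
  seg <- truth$segments
  ch <- as.character(manifest$chrom)
  for (i in seq_len(nrow(seg))) {
    hit <- ch == seg$chrom[i] & manifest$pos >= seg$start[i] &
      manifest$pos < seg$end[i]
    cn[hit] <- seg$cn[i]
  }
  observed <- truth$purity * cn + (1 - truth$purity) * g
  aff <- if ("affinity" %in% names(manifest)) manifest$affinity else 1
  scale * aff * (observed / 2 + bg_frac)
}

# Split a combined intensity into channels and wrap as sample_intensities.
make_sample <- function(manifest, combined, sample_id, reported_sex) {
  mf <- if ("meth_fraction" %in% names(manifest)) {
    manifest$meth_fraction
  } else 0.5
  sample_intensities(sample_id, manifest$probe_id,
                     meth = combined * mf, unmeth = combined * (1 - mf),
                     reported_sex = reported_sex)
}

#' Simulate a flat-genome reference panel
#'
#' Copy-number-neutral samples: per probe the combined intensity is the
#' diploid level times the probe affinity, with multiplicative log-normal
#' noise (`2^N(0, noise_sd)` on the log2 scale). The channel split follows
#' the probe's fixed methylation fraction, so with `noise_sd = 0` all panel
#' members are identical.
#'
#' @param n Number of reference samples (>= 3).
#' @param manifest A [simulate_manifest()] manifest.
#' @param scale Diploid combined-intensity level (default 5000).
#' @param noise_sd Per-probe log2 noise standard deviation (default 0.1).
#' @param seed Integer seed.
#' @param sex Germline sex of the reference donors (default `"female"`).
#' @param bg_frac Background signal as a fraction of the diploid level
#'   (default 0.01); keeps zero-copy loci finite.
#' @return List of [sample_intensities()].
#' @export
simulate_reference_panel <- function(n, manifest, scale = 5000, noise_sd = 0.1,
                                     seed = 1, sex = "female", bg_frac = 0.01) {
  if (n < 3) stop("a reference panel needs n >= 3 samples")
  set.seed(seed)
  flat <- cn_truth(NULL, sex = sex, purity = 1)
  base <- expected_combined(manifest, flat, scale, bg_frac)
  lapply(seq_len(n), function(i) {
    noisy <- base * 2^stats::rnorm(nrow(manifest), 0, noise_sd)
    make_sample(manifest, noisy, sprintf("ref_%02d", i), sex)
  })
}

#' Simulate a tumor sample with known copy-number truth
#'
#' Per probe in a truth segment of copy number `n` at purity `p`, the
#' expected combined intensity is proportional to
#' `(p * n + (1 - p) * 2) / 2` (on autosomes), so the recovered log2 ratio of
#' the segment is `log2((p * n + (1 - p) * 2) / 2)`; elsewhere the genome is
#' neutral. Multiplicative log-normal probe noise as in
#' [simulate_reference_panel()].
#'
#' @param manifest A [simulate_manifest()] manifest.
#' @param truth A [cn_truth()].
#' @param scale,noise_sd,bg_frac As in [simulate_reference_panel()].
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @param reported_sex Sex written on the request form (defaults to the
#'   truth's germline sex; set differently to simulate a mix-up).
#' @return A [sample_intensities()].
#' @export
simulate_tumor <- function(manifest, truth, scale = 5000, noise_sd = 0.1,
                           seed = 1, sample_id = "tumor",
                           reported_sex = truth$sex, bg_frac = 0.01) {
  stopifnot(inherits(truth, "cn_truth"))
  set.seed(seed)
  base <- expected_combined(manifest, truth, scale, bg_frac)
  noisy <- base * 2^stats::rnorm(nrow(manifest), 0, noise_sd)
  make_sample(manifest, noisy, sample_id, reported_sex)
}

#' Simulate cross-sample contamination
#'
#' A convex per-probe mixture of two samples' channel intensities:
#' `(1 - f) * recipient + f * donor`, applied to the methylated and
#' unmethylated channels separately so the channel split stays proportional.
#' With a donor amplification of copy number `n`, the mixture carries a focal
#' gain of `log2(((1 - f) * 2 + f * n) / 2)` — large amplifications surface
#' even at small `f`, ordinary gains do not.
#'
#' @param recipient,donor [sample_intensities()] on the same probe set.
#' @param fraction Contamination fraction `f` in `(0, 0.5]`.
#' @param sample_id Identifier of the mixture (default: recipient's id).
#' @return A [sample_intensities()].
#' @export
simulate_contamination <- function(recipient, donor, fraction,
                                   sample_id = recipient$sample_id) {
  stopifnot(inherits(recipient, "sample_intensities"),
            inherits(donor, "sample_intensities"))
  if (!(fraction > 0 && fraction <= 0.5)) stop("fraction must be in (0, 0.5]")
  if (!identical(recipient$probe_id, donor$probe_id)) {
    stop("recipient and donor must share the same manifest probe order")
  }
  sample_intensities(
    sample_id, recipient$probe_id,
    meth = (1 - fraction) * recipient$meth + fraction * donor$meth,
    unmeth = (1 - fraction) * recipient$unmeth + fraction * donor$unmeth,
    reported_sex = recipient$reported_sex)
}

#' Simulate a calibrated score vector
#'
#' Assigns `top_mass` to the target class — or, when the target is a family,
#' splits it across the family members (first member dominant by default, or
#' per `member_weights`) — and distributes the remainder over all other
#' classes by a symmetric Dirichlet draw. The result sums to 1 within 1e-9.
#'
#' @param schema A [class_schema()].
#' @param target A class name or family name from the schema.
#' @param top_mass Probability mass on the target, in `(0, 1]` (default 0.9).
#' @param concentration Dirichlet concentration of the remainder (default 1;
#'   smaller spreads the mass over fewer classes).
#' @param member_weights Optional weights over family members (same order as
#'   the schema lists them) used to split `top_mass`; default puts weight 4
#'   on the first member and 1 on the rest.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return A [score_vector()].
#' @export
simulate_scores <- function(schema, target, top_mass = 0.9, concentration = 1,
                            member_weights = NULL, seed = 1,
                            sample_id = "synthetic") {
  stopifnot(inherits(schema, "class_schema"))
  if (!(top_mass > 0 && top_mass <= 1)) stop("top_mass must be in (0, 1]")
  set.seed(seed)
  cls <- schema$classes$class
  s <- stats::setNames(rep(0, length(cls)), cls)
  if (target %in% names(schema$families)) {
    members <- schema$families[[target]]
    w <- if (is.null(member_weights)) c(4, rep(1, length(members) - 1)) else member_weights
    if (length(w) != length(members) || any(w < 0) || sum(w) == 0) {
      stop("member_weights must be non-negative, one per family member")
    }
    s[members] <- top_mass * w / sum(w)
    rest <- setdiff(cls, members)
  } else if (target %in% cls) {
    s[target] <- top_mass
    rest <- setdiff(cls, target)
  } else {
    stop("unknown target: ", target)
  }
  if (top_mass < 1 && length(rest) > 0) {
    g <- stats::rgamma(length(rest), shape = concentration)
    if (sum(g) == 0) g <- rep(1, length(rest))
    s[rest] <- (1 - top_mass) * g / sum(g)
  }
  score_vector(s, schema, sample_id = sample_id)
}
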