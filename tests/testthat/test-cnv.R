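# CNV core: ratios, bin medians, minimal-MAD baseline, segmentation, events.

test_that("probe_log2 recovers identity, doublings and the per-probe quotient", {
  m <- tiny_manifest("1", seq(1e5, 1e7, length.out = 200))
  mk <- function(id, comb) sample_intensities(id, m$probe_id, comb * 0.4, comb * 0.6)
  ref_comb <- rep(1000, 200)
  panel <- build_reference(list(mk("r1", ref_comb), mk("r2", ref_comb),
                                mk("r3", ref_comb)), m)

  expect_equal(probe_log2(mk("same", ref_comb), panel, m), rep(0, 200))

  # doubling one probe: +1 after median-match scaling (median unaffected)
  comb <- ref_comb; comb[7] <- 2000
  lr <- probe_log2(mk("dbl", comb), panel, m)
  expect_equal(lr[7], 1)
  expect_equal(median(lr), 0)

  # random intensities against the loop-based quotient oracle
  set.seed(21)
  rc <- runif(200, 500, 2000)
  s <- mk("rand", rc)
  f <- median(panel$reference) / median(rc)
  looped <- vapply(1:200, function(i) log2(rc[i] * f / panel$reference[i]),
                   numeric(1))
  expect_equal(probe_log2(s, panel, m), looped)
})

test_that("bin medians match a sort-and-pick oracle", {
  m <- tiny_manifest("1", seq(1e5, 1e6, length.out = 9))
  bins <- build_bins(m, target_bins = 3, min_probes = 3)
  vals <- c(0.1, 0.2, 0.9, 0, 0, 0, -1, 2, 0.5)
  prof <- bin_profile(vals, bins)
  expect_equal(prof$bins$log2[1], 0.2)   # median of {0.1, 0.2, 0.9}
  expect_equal(prof$bins$log2[2], 0)
  oracle <- vapply(1:3, function(b) {
    x <- sort(vals[(3 * b - 2):(3 * b)]); x[2]
  }, numeric(1))
  expect_equal(prof$bins$log2, oracle)

  expect_equal(bin_profile(rep(0, 9), bins)$bins$log2, rep(0, 3))
})

test_that("grid-search baseline equals the exhaustive oracle", {
  expect_equal(fit_baseline_value(rep(0.3, 20)), 0.3)
  expect_equal(suppressWarnings(fit_baseline_value(c(0, 0, 0, 1, 1), step = 0.001)),
               0)

  set.seed(31)
  for (i in 1:25) {
    x <- round(rnorm(50, sd = 0.5) + sample(c(0, 0.6), 50, replace = TRUE), 3)
    expect_equal(fit_baseline_value(x), oracle_baseline(x))
  }
})

test_that("no grid candidate beats the returned baseline (minimal-MAD optimality)", {
  low_median <- function(d) sort(d)[ceiling(length(d) / 2)]
  set.seed(32)
  for (i in 1:10) {
    x <- rnorm(30, sd = 0.4)
    b <- fit_baseline_value(x, step = 0.01)
    grid <- seq(min(x), max(x), by = 0.01)
    mads <- vapply(grid, function(g) low_median(abs(x - g)), numeric(1))
    expect_lte(low_median(abs(x - b)), min(mads) + 1e-9)
  }
})

test_that("baseline is translation-equivariant and calls are unchanged", {
  set.seed(33)
  vals <- rnorm(60, 0, 0.05)
  vals[20:30] <- vals[20:30] + 1
  prof <- fit_baseline(values_as_profile(vals))
  shifted <- fit_baseline(values_as_profile(vals + 0.7))
  expect_equal(shifted$baseline, prof$baseline + 0.7, tolerance = 0.002)

  set.seed(34); seg1 <- segment_profile(prof)
  set.seed(34); seg2 <- segment_profile(shifted)
  expect_equal(seg1$mean_log2, seg2$mean_log2, tolerance = 0.002)
  expect_equal(seg1$start, seg2$start)
})

test_that("a simulated step is recovered within two bins", {
  set.seed(41)
  for (r in 1:5) {
    x <- c(rnorm(100, 0, 0.1), rnorm(100, 1, 0.1))
    prof <- fit_baseline(values_as_profile(x))
    seg <- segment_profile(prof)
    expect_equal(nrow(seg), 2)
    # breakpoint at bin 100 (0-based end of first segment)
    expect_lte(abs(seg$end[1] - 100), 2)
  }
})

test_that("pure noise yields no split in at least 95% of replicates", {
  set.seed(42)
  n_rep <- 40
  no_split <- 0
  for (r in seq_len(n_rep)) {
    x <- rnorm(200, 0, 0.1)
    prof <- fit_baseline(values_as_profile(x))
    if (nrow(segment_profile(prof, alpha = 0.01)) == 1) no_split <- no_split + 1
  }
  expect_gte(no_split / n_rep, 0.95)
})

test_that("segment means conserve the unweighted mean of member bins", {
  set.seed(43)
  x <- c(rnorm(50, 0, 0.05), rnorm(30, 0.8, 0.05), rnorm(40, -0.5, 0.05))
  prof <- fit_baseline(values_as_profile(x))
  seg <- segment_profile(prof)
  v <- prof$bins$log2 - prof$baseline
  # reconstruct each segment's member bins from its coordinates (unit bins)
  for (i in seq_len(nrow(seg))) {
    member <- v[(seg$start[i] + 1):seg$end[i]]
    expect_equal(seg$mean_log2[i], mean(member))
    expect_equal(seg$n_bins[i], length(member))
  }
  expect_equal(sum(seg$n_bins), length(x))
})

test_that("event calling separates amplification, deletion and arm-scale changes", {
  seg <- data.frame(
    chrom = c("7", "9", "1", "2", "3"),
    start = c(55e6, 21.9e6, 0, 0, 0),
    end = c(57e6, 22.1e6, 120e6, 120e6, 120e6),
    n_bins = c(2, 1, 30, 30, 30),
    mean_log2 = c(1.5, -1.2, 0.25, -0.3, 0.05))
  class(seg) <- c("cn_segments", "data.frame")
  ev <- call_events(seg)
  expect_equal(nrow(ev), 4)
  amp <- ev[ev$kind == "amplification", ]
  expect_equal(as.character(amp$chrom), "7")
  expect_equal(amp$gene, "EGFR")
  del <- ev[ev$kind == "homozygous_deletion", ]
  expect_equal(del$gene, "CDKN2A/B")
  expect_setequal(ev$kind[ev$n_bins == 30], c("gain", "loss"))
  # long high-amplitude segments are numerical changes, not focal events
  seg$mean_log2[3] <- 0.9
  ev2 <- call_events(seg)
  expect_equal(ev2$kind[as.character(ev2$chrom) == "1"], "gain")
})

test_that("a flat genome produces no events and bad gene input errors", {
  seg <- data.frame(chrom = "1", start = 0, end = 1e8, n_bins = 25,
                    mean_log2 = 0.01)
  class(seg) <- c("cn_segments", "data.frame")
  expect_equal(nrow(call_events(seg)), 0)
  expect_error(call_events(seg, genes = c("EGFR", "MYCN")),
               "missing gene coordinates")
})

test_that("purity dilutes segment means by the closed-form mixture", {
  m <- fx_manifest()
  bins <- fx_bins()
  panel <- fx_panel()
  means <- vapply(c(1.0, 0.7, 0.4), function(p) {
    truth <- cn_truth(data.frame(chrom = "5", start = 1, end = 180e6, cn = 4),
                      sex = "female", purity = p)
    tum <- simulate_tumor(m, truth, seed = 140 + round(100 * p))
    res <- cnv_pipeline(tum, panel, m, bins = bins)
    s5 <- res$segments[as.character(res$segments$chrom) == "5", ]
    s5$mean_log2[which.max(s5$n_bins)]
  }, numeric(1))
  expected <- log2((c(1.0, 0.7, 0.4) * 4 + (1 - c(1.0, 0.7, 0.4)) * 2) / 2)
  expect_equal(means, expected, tolerance = 0.05)
  expect_true(all(diff(abs(means)) < 0))   # lower purity, smaller amplitude
})
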