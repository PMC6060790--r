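# Synthetic-data generator: determinism, closed-form recoveries, mixtures.

test_that("generators are bit-identical under a fixed seed", {
  m1 <- simulate_manifest("test", seed = 7)
  m2 <- simulate_manifest("test", seed = 7)
  expect_identical(m1, m2)
  p1 <- simulate_reference_panel(3, m1, seed = 8)
  p2 <- simulate_reference_panel(3, m1, seed = 8)
  expect_identical(p1, p2)
  t1 <- simulate_tumor(m1, cn_truth(NULL), seed = 9)
  t2 <- simulate_tumor(m1, cn_truth(NULL), seed = 9)
  expect_identical(t1, t2)
  s1 <- simulate_scores(fx_schema(), "MNG", seed = 10)
  s2 <- simulate_scores(fx_schema(), "MNG", seed = 10)
  expect_identical(s1$scores, s2$scores)
})

test_that("a noiseless panel is identical up to the deterministic channel split", {
  m <- fx_manifest()
  p <- simulate_reference_panel(3, m, noise_sd = 0, seed = 11)
  expect_equal(p[[1]]$meth, p[[2]]$meth)
  expect_equal(p[[1]]$unmeth, p[[3]]$unmeth)
  # channel split follows the manifest's per-probe methylation fraction
  beta <- p[[1]]$meth / (p[[1]]$meth + p[[1]]$unmeth)
  expect_equal(beta, m$meth_fraction, tolerance = 1e-12)
})

test_that("panel members ratio to ~zero against their own panel", {
  m <- fx_manifest()
  samples <- fx_panel_samples()
  panel <- fx_panel()
  lr <- probe_log2(samples[[1]], panel, m)
  # unbiased per probe; residual scatter bounded by the probe noise level
  expect_lt(abs(mean(lr, na.rm = TRUE)), 0.05)
  expect_lt(mean(abs(lr), na.rm = TRUE), 2 * 0.1)
})

test_that("tumor segments recover the purity-mixture closed form", {
  m <- fx_manifest()
  bins <- fx_bins()
  panel <- fx_panel()
  # n = 4 at purity 1 -> log2 2.0; n = 4 at purity 0.5 -> log2(3/2)
  for (case in list(list(p = 1, exp = 1), list(p = 0.5, exp = log2(1.5)))) {
    truth <- cn_truth(data.frame(chrom = "8", start = 1, end = 146e6, cn = 4),
                      sex = "female", purity = case$p)
    tum <- simulate_tumor(m, truth, seed = 12 + round(10 * case$p))
    res <- cnv_pipeline(tum, panel, m, bins = bins)
    s8 <- res$segments[as.character(res$segments$chrom) == "8", ]
    expect_equal(s8$mean_log2[which.max(s8$n_bins)], case$exp,
                 tolerance = 0.05)
  }
})

test_that("a noiseless homozygous deletion drops to the clamp floor", {
  m <- fx_manifest()
  panel <- build_reference(simulate_reference_panel(3, m, noise_sd = 0,
                                                    seed = 13), m)
  truth <- cn_truth(data.frame(chrom = "9", start = 19e6, end = 27e6, cn = 0),
                    sex = "female", purity = 1)
  tum <- simulate_tumor(m, truth, noise_sd = 0, seed = 14)
  lr <- probe_log2(tum, panel, m, clamp = 4)
  ch9 <- as.character(m$chrom) == "9" & m$pos >= 19e6 & m$pos < 27e6
  # background-only signal (~log2(0.01)) sits below the clamp, so every
  # probe lands exactly on the configured floor
  expect_equal(lr[ch9], rep(-4, sum(ch9)))
  wide <- probe_log2(tum, panel, m, clamp = 8)
  expect_true(all(wide[ch9] < -6))
})

test_that("contamination mixes channels convexly and vanishes as f -> 0", {
  m <- fx_manifest()
  rec <- simulate_tumor(m, cn_truth(NULL), seed = 15, sample_id = "rec")
  don <- simulate_tumor(m, cn_truth(NULL), seed = 16, sample_id = "don")
  mix <- simulate_contamination(rec, don, 0.25)
  expect_equal(mix$meth, 0.75 * rec$meth + 0.25 * don$meth)
  expect_equal(mix$unmeth, 0.75 * rec$unmeth + 0.25 * don$unmeth)
  tiny <- simulate_contamination(rec, don, 1e-9)
  expect_equal(tiny$meth, rec$meth, tolerance = 1e-6)
  expect_error(simulate_contamination(rec, don, 0.7), "fraction")
})

test_that("only the donor's amplification surfaces in a 5% mixture", {
  m <- fx_manifest()
  bins <- fx_bins()
  panel <- fx_panel()
  # donor: 50-fold amplification (cn 100) at an EGFR-like locus plus an
  # ordinary single-copy gain of 1q
  donor_truth <- cn_truth(data.frame(
    chrom = c("7", "1"), start = c(54e6, 125e6), end = c(60e6, 249e6),
    cn = c(100, 3)), sex = "female", purity = 1)
  don <- simulate_tumor(m, donor_truth, seed = 17, sample_id = "don")
  rec <- simulate_tumor(m, cn_truth(NULL), seed = 18, sample_id = "rec")
  mix <- simulate_contamination(rec, don, 0.05, sample_id = "mix")
  res <- cnv_pipeline(mix, panel, m, bins = bins)

  # probe-level check of the closed-form mixture amplitudes
  lr <- probe_log2(mix, panel, m)
  ch <- as.character(m$chrom)
  amp_probes <- ch == "7" & m$pos >= 54.5e6 & m$pos < 59.5e6
  expected_amp <- log2((0.95 * 2 + 0.05 * 100) / 2)   # ~1.8
  expect_equal(mean(lr[amp_probes]), expected_amp, tolerance = 0.1)

  arm_probes <- ch == "1" & m$pos >= 126e6
  expected_arm <- log2((0.95 * 2 + 0.05 * 3) / 2)     # ~0.035, invisible
  expect_lt(abs(mean(lr[arm_probes]) - expected_arm), 0.03)
  expect_lt(mean(lr[arm_probes]), 0.15)  # stays below the call threshold
  ev <- res$events
  expect_false(any(as.character(ev$chrom) == "1"))
  expect_true(any(as.character(ev$chrom) == "7" &
                    ev$kind %in% c("amplification", "gain")))
})

test_that("score simulation hits its target mass and normalizes", {
  sc <- fx_schema()
  v <- simulate_scores(sc, "ETMR", top_mass = 1.0, seed = 19)
  expect_equal(unname(v$scores[["ETMR"]]), 1)
  expect_equal(sum(v$scores), 1, tolerance = 1e-9)

  fam <- simulate_scores(sc, "Plexus tumor", top_mass = 0.88, seed = 20)
  fs <- family_scores(fam, sc)
  expect_equal(unname(fs[["Plexus tumor"]]), 0.88, tolerance = 1e-9)
  expect_equal(sum(fam$scores), 1, tolerance = 1e-9)
  expect_error(simulate_scores(sc, "NOT A CLASS"), "unknown target")
})

test_that("overlapping truth segments are rejected", {
  expect_error(
    cn_truth(data.frame(chrom = c("1", "1"), start = c(0, 5e6),
                        end = c(10e6, 15e6), cn = c(3, 4))),
    "overlapping")
  expect_error(cn_truth(NULL, purity = 0), "purity")
})

test_that("truth files round-trip", {
  tr <- cn_truth(data.frame(chrom = "7", start = 1e6, end = 9e6, cn = 5),
                 sex = "male", purity = 0.65)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(tr, path)
  back <- read_truth(path)
  expect_equal(back$sex, "male")
  expect_equal(back$purity, 0.65)
  expect_equal(back$segments$cn, 5)
})
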