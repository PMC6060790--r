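# Batch QC: sex prediction, noise scoring, contamination scan, consistency.

test_that("sex is predicted from X/Y intensity ratios and checked for concordance", {
  m <- fx_manifest()
  female <- simulate_tumor(m, cn_truth(NULL, sex = "female"), seed = 91,
                           sample_id = "f1")
  male <- simulate_tumor(m, cn_truth(NULL, sex = "male"), seed = 92,
                         sample_id = "m1")
  expect_equal(predict_sex(female, m)$predicted_sex, "female")
  expect_equal(predict_sex(male, m)$predicted_sex, "male")

  # reported male, predicted female: discordant
  swapped <- simulate_tumor(m, cn_truth(NULL, sex = "female"), seed = 93,
                            sample_id = "s1", reported_sex = "male")
  expect_false(predict_sex(swapped, m)$concordant)

  # prediction survives purity dilution of an aberrant genome
  truth <- cn_truth(data.frame(chrom = "7", start = 1, end = 159e6, cn = 4),
                    sex = "male", purity = 0.4)
  diluted <- simulate_tumor(m, truth, seed = 94, sample_id = "d1")
  expect_equal(predict_sex(diluted, m)$predicted_sex, "male")
})

test_that("a sample without Y probes and intermediate X ratio is undetermined", {
  m <- fx_manifest()
  s <- simulate_tumor(m, cn_truth(NULL, sex = "female"), seed = 95)
  comb <- combined_intensity(s)
  ch <- as.character(m$chrom)
  # force X to an ambiguous level between one and two copies, drop Y signal
  comb[ch == "X"] <- comb[ch == "X"] * 0.65
  comb[ch == "Y"] <- 0
  amb <- sample_intensities("amb", s$probe_id, comb / 2, comb / 2)
  expect_equal(predict_sex(amb, m, x_mid = 0.75)$predicted_sex, "undetermined")
})

test_that("noise score is zero on flat profiles and tracks the Monte-Carlo value", {
  expect_equal(noise_score(values_as_profile(rep(0.2, 100))), 0)
  expect_error(noise_score(values_as_profile(0.1)), "at least 2")

  # i.i.d. Gaussian bin noise: median |diff| of N(0, 2 sigma^2)
  set.seed(96)
  sigma <- 0.2
  score <- noise_score(values_as_profile(rnorm(5000, 0, sigma)))
  expect_equal(score, 0.6745 * sigma * sqrt(2), tolerance = 0.1)

  scores <- vapply(c(0.05, 0.2, 0.5), function(s) {
    noise_score(values_as_profile(rnorm(2000, 0, s)))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("noise score ignores level shifts and sparse true steps", {
  set.seed(97)
  x <- rnorm(1000, 0, 0.1)
  base <- noise_score(values_as_profile(x))
  expect_equal(noise_score(values_as_profile(x + 5)), base)
  # a handful of true copy-number steps (< 5% of junctions) barely move it
  stepped <- x + rep(c(0, 0.6, 0, -0.6, 0), each = 200)
  expect_equal(noise_score(values_as_profile(stepped)), base, tolerance = 0.02)
})

test_that("noise grades map onto the configured cutoffs", {
  expect_equal(grade_noise(0.05), "crisp")
  expect_equal(grade_noise(0.2), "elevated")
  expect_equal(grade_noise(0.4), "unusable")
  expect_error(grade_noise(-1), "invalid")
})

mk_events <- function(df) {
  if (is.null(df)) {
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), n_bins = integer(0),
                     mean_log2 = numeric(0), length = numeric(0),
                     focal = logical(0), kind = character(0),
                     gene = character(0))
  }
  class(df) <- c("focal_events", "data.frame")
  df
}

amp_row <- function(chrom, start, end, kind = "amplification", log2 = 2) {
  data.frame(chrom = chrom, start = start, end = end, n_bins = 2,
             mean_log2 = log2, length = end - start, focal = TRUE,
             kind = kind, gene = NA_character_, stringsAsFactors = FALSE)
}

test_that("contamination scan flags shared amplified regions symmetrically", {
  donor <- mk_events(rbind(amp_row("7", 55e6, 58e6),
                           amp_row("2", 15e6, 17e6),
                           amp_row("12", 68e6, 70e6)))
  recip <- mk_events(rbind(amp_row("7", 55e6, 58e6, kind = "gain", log2 = 0.3),
                           amp_row("2", 15e6, 17e6, kind = "gain", log2 = 0.25),
                           amp_row("12", 68e6, 70e6, kind = "gain", log2 = 0.3)))
  clean <- mk_events(NULL)
  res <- contamination_scan(list(donor = donor, recip = recip, clean = clean))
  expect_equal(nrow(res), 1)
  expect_equal(res$n_shared, 3)
  expect_setequal(c(res$sample_a, res$sample_b), c("donor", "recip"))

  # scanning from the other direction finds the same pair once
  res2 <- contamination_scan(list(recip = recip, donor = donor, clean = clean))
  expect_equal(nrow(res2), 1)
  expect_equal(res2$n_shared, 3)
})

test_that("amplifications on different chromosomes or a lone sample do not flag", {
  a <- mk_events(amp_row("7", 55e6, 58e6))
  b <- mk_events(amp_row("9", 21e6, 23e6))
  expect_equal(nrow(contamination_scan(list(a = a, b = b))), 0)
  expect_equal(nrow(contamination_scan(list(a = a))), 0)
  # overlap below the reciprocal threshold does not count
  c_ <- mk_events(amp_row("7", 57.9e6, 70e6, kind = "gain"))
  expect_equal(nrow(contamination_scan(list(a = a, c = c_))), 0)
})

test_that("consistency check lists mismatches and spots systematic errors", {
  mk_dec <- function(id, top) {
    structure(list(sample_id = id, top_class = top), class = "decision_report")
  }
  decs <- lapply(1:8, function(i) mk_dec(paste0("s", i), "A IDH"))
  expected <- setNames(rep("A IDH", 8), paste0("s", 1:8))
  expect_equal(nrow(consistency_check(decs, expected)), 0)

  expected["s3"] <- "MNG"
  one <- consistency_check(decs, expected)
  expect_equal(one$sample_id, "s3")
  expect_false(attr(one, "batch_warning"))

  all_wrong <- setNames(rep("MNG", 8), paste0("s", 1:8))
  res <- consistency_check(decs, all_wrong)
  expect_equal(nrow(res), 8)
  expect_true(attr(res, "batch_warning"))
})

test_that("the batch QC report combines all checks and forces reanalysis", {
  m <- fx_manifest()
  bins <- fx_bins()
  panel <- fx_panel()
  s1 <- simulate_tumor(m, cn_truth(NULL, sex = "female"), seed = 98,
                       sample_id = "ok")
  # bisulfite-failure-like dispersion: very large per-probe noise
  s2 <- simulate_tumor(m, cn_truth(NULL, sex = "female"), noise_sd = 1.8,
                       seed = 99, sample_id = "noisy")
  samples <- list(ok = s1, noisy = s2)
  profs <- lapply(samples, function(s) {
    fit_baseline(bin_profile(probe_log2(s, panel, m), bins, s$sample_id))
  })
  evs <- lapply(samples, function(s) mk_events(NULL))
  rep_ <- run_batch_qc(samples, profs, evs, m)
  d <- rep_$samples
  expect_equal(d$noise_grade[d$sample_id == "ok"], "crisp")
  expect_equal(d$noise_grade[d$sample_id == "noisy"], "unusable")
  expect_true(d$reanalysis_recommended[d$sample_id == "noisy"])
  expect_false(d$reanalysis_recommended[d$sample_id == "ok"])
})
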