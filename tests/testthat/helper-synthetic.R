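# Shared synthetic fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (!exists(key, envir = .fx)) assign(key, make(), envir = .fx)
  get(key, envir = .fx)
}

fx_manifest <- function() memo("manifest", function() {
  simulate_manifest("test", seed = 101)
})

fx_bins <- function() memo("bins", function() {
  build_bins(fx_manifest(), target_bins = 800, min_probes = 15)
})

fx_panel_samples <- function() memo("panel_samples", function() {
  simulate_reference_panel(5, fx_manifest(), seed = 102)
})

fx_panel <- function() memo("panel", function() {
  build_reference(fx_panel_samples(), fx_manifest())
})

fx_schema <- function() memo("schema", function() read_class_schema())

# A tiny handmade manifest for exact, enumerable cases: one or two
# chromosomes, a handful of probes at given positions.
tiny_manifest <- function(chrom, pos, ...) {
  probe_manifest(sprintf("p%03d", seq_along(pos)), chrom, pos, ...)
}

# Wrap a bare numeric vector as a one-chromosome bin profile (unit bins),
# for operations that only look at bin values.
values_as_profile <- function(values, chrom = "1", baseline = 0) {
  n <- length(values)
  b <- data.frame(chrom = factor(rep(chrom, n), levels = chrom_levels()),
                  start = seq_len(n) - 1, end = seq_len(n),
                  probe_count = 1L, sex_chrom = FALSE, log2 = values)
  structure(list(sample_id = "vec", bins = b, baseline = baseline),
            class = "bin_profile")
}

# Independent oracle for the minimal-MAD baseline: exhaustive loop over the
# same grid and deviation-median contract (lower middle order statistic),
# kept free of the package's search code.
oracle_baseline <- function(values, step = 0.001) {
  x <- values[!is.na(values)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  grid <- unique(c(seq(rng[1], rng[2], by = step), rng[2]))
  mads <- numeric(length(grid))
  for (i in seq_along(grid)) {
    devs <- sort(abs(x - grid[i]))
    mads[i] <- devs[ceiling(length(devs) / 2)]
  }
  cand <- grid[mads <= min(mads) + 1e-9]
  cand[which.min(abs(cand))]
}
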