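test_that("GC correction is a near-no-op without bias and removes real bias", {
  build <- default_build()
  bins <- simulate_gc_content(make_bins(build, 1e6), seed = 15)
  gt <- tumor_genotype()
  # bias-free: corrected within 1% median absolute relative difference
  p0 <- simulate_bin_counts(gt, sim_config(0, total_reads = 6430000,
                                           seed = 16), bins)
  c0 <- gc_correct(p0)
  rel <- abs(c0$counts - p0$counts) / p0$counts
  expect_lt(median(rel[!c0$excluded]), 0.01)
  # quadratic bias: post-correction GC correlation collapses
  pb <- simulate_bin_counts(gt, sim_config(0, total_reads = 6430000,
                                           gc_bias_coeffs = c(2, -10),
                                           seed = 17), bins)
  expect_gt(abs(cor(pb$counts, bins$gc_fraction)), 0.3)
  cb <- gc_correct(pb)
  use <- !cb$excluded
  expect_lt(abs(cor(cb$counts[use], bins$gc_fraction[use])), 0.05)
  # deterministic
  cb2 <- gc_correct(pb)
  expect_identical(cb$counts, cb2$counts)
  # missing GC coverage is an error
  p0$bins$gc_fraction[seq_len(ceiling(0.15 * nrow(bins)))] <- NA
  expect_error(gc_correct(p0), "90%")
})

test_that("log2 ratios are zero against an identical control and exclude dead bins", {
  build <- chr8_build()
  bins <- make_bins(build, 1e6)
  p <- simulate_bin_counts(tumor_genotype(),
                           sim_config(0, total_reads = 1e6, seed = 20), bins)
  lp <- log2_ratio(p, list(p))
  expect_true(all(abs(lp$log2) < 1e-12))
  # zero control median -> excluded with reason
  ctrl <- p
  ctrl$counts[5] <- 0
  lp2 <- log2_ratio(p, list(ctrl))
  expect_true(is.na(lp2$log2[5]))
  expect_equal(lp2$excluded_reason[5], "zero-control")
  # bin set mismatch
  other <- simulate_bin_counts(tumor_genotype(),
                               sim_config(0, total_reads = 1e5, seed = 2),
                               make_bins(toy_build(), 1e4))
  expect_error(log2_ratio(p, list(other)), "same bin set")
  expect_error(log2_ratio(p, list()), "empty")
})

test_that("a control scored against a panel containing it is centred at zero", {
  build <- chr8_build()
  bins <- make_bins(build, 1e6)
  panel <- simulate_control_cohort(6, sim_config(0, total_reads = 2e6,
                                                 seed = 30), bins)
  lp <- log2_ratio(panel[[1]], panel)
  expect_lt(abs(median(lp$log2, na.rm = TRUE)), 0.02)
})

test_that("noise-free log2 ratios follow the forward admixture formula", {
  build <- chr8_build()
  bins <- make_bins(build, 1e6)
  gene_bin <- which(bins$start == 38e6)
  gt16 <- tumor_genotype(list(cna_event("8", 38e6, 39e6, 16)))
  lp <- noise_free_profile(gt16, 0.05, bins)
  expect_equal(lp$log2[gene_bin], log2(1 - 0.05 + 0.05 * 8),
               tolerance = 1e-12)
  expect_equal(lp$log2[gene_bin], 0.433, tolerance = 1e-3)
  gt7 <- tumor_genotype(list(cna_event("8", 38e6, 39e6, 7)))
  lp7 <- noise_free_profile(gt7, 0.0035, bins)
  expect_equal(lp7$log2[gene_bin], 0.0126, tolerance = 5e-3)
})

test_that("segmentation: flat profiles give one balanced segment per chromosome", {
  build <- toy_build()
  bins <- make_bins(build, 5000)
  lp <- structure(list(sample_id = "flat", bins = bins,
                       log2 = rep(0, nrow(bins)),
                       excluded_reason = rep(NA_character_, nrow(bins))),
                  class = "log2_profile")
  segs <- segment_profile(lp)
  expect_equal(nrow(segs), 2)
  expect_true(all(segs$label == "balanced"))
  expect_equal(segs$n_bins, as.vector(table(bins$chrom)[unique(bins$chrom)]))
})

test_that("a noiseless step yields exactly one breakpoint at the step", {
  b <- genome_build(data.frame(chrom = "c", length = 1e6, centromere = 5e5))
  bins <- make_bins(b, 1e4)  # 100 bins
  lp <- structure(list(sample_id = "step", bins = bins,
                       log2 = c(rep(0, 50), rep(0.5, 50)),
                       excluded_reason = rep(NA_character_, 100)),
                  class = "log2_profile")
  segs <- segment_profile(lp)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end[1], 50 * 1e4)
  expect_equal(segs$mean_log2, c(0, 0.5))
  expect_equal(segs$label, c("balanced", "gain"))
})

test_that("segment means reconstruct the profile mean (bin-weighted)", {
  build <- chr8_build()
  bins <- make_bins(build, 1e6)
  gt <- default_tumor_genotype(default_build(), focal_amp = TRUE)
  p <- simulate_bin_counts(gt, sim_config(0.2, total_reads = 2e6, seed = 44),
                           bins)
  panel <- simulate_control_cohort(5, sim_config(0, total_reads = 2e6,
                                                 seed = 45), bins)
  lp <- log2_ratio(p, panel)
  segs <- segment_profile(lp)
  expect_equal(sum(segs$mean_log2 * segs$n_bins) / sum(segs$n_bins),
               mean(lp$log2, na.rm = TRUE), tolerance = 1e-10)
})

test_that("arm-level breakpoints are recovered within 2 bins despite a focal spike", {
  build <- chr8_build()
  bins <- make_bins(build, 1e6)
  gt <- tumor_genotype(list(
    cna_event("8", 45338887, 146364022, 4),   # two-copy 8q gain
    cna_event("8", 38e6, 39e6, 16)))          # focal amplicon
  hits <- vapply(1:25, function(i) {
    panel <- simulate_control_cohort(
      10, sim_config(0, total_reads = 6430000, seed = 5000 + 100 * i),
      bins)
    p <- simulate_bin_counts(gt, sim_config(0.2, total_reads = 6430000,
                                            seed = 60 + i), bins)
    segs <- segment_profile(log2_ratio(p, panel))
    internal <- segs$start[segs$start > 0]
    any(abs(internal - 45338887) <= 2e6)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("focal amplification calling applies level, arm-delta and focality", {
  build <- chr8_build()
  bins <- make_bins(build, 1e6)
  arms <- make_arms(default_build())
  gr <- gene_region("FGFR1")
  flat <- noise_free_profile(tumor_genotype(), 0, bins)
  fsegs <- segment_profile(flat)
  expect_false(call_focal_amplification(flat, fsegs, gr, arms)$called)
  # focal c = 16 at tf = 0.05: log2 0.433 over a flat arm -> called
  gt16 <- tumor_genotype(list(cna_event("8", 38e6, 39e6, 16)))
  lp <- noise_free_profile(gt16, 0.05, bins)
  fc <- call_focal_amplification(lp, segment_profile(lp), gr, arms)
  expect_true(fc$called)
  expect_equal(fc$event_length, 1e6)
  # whole-arm gain only at tf = 0.3: high level but fails the arm delta
  gt_arm <- tumor_genotype(list(cna_event("8", 0, 45338887, 3)))
  lp_arm <- noise_free_profile(gt_arm, 0.3, bins)
  fca <- call_focal_amplification(lp_arm, segment_profile(lp_arm), gr, arms)
  expect_false(fca$called)
  expect_true(fca$criteria$pass_level)
  expect_false(fca$criteria$pass_delta)
  # gene off the build
  expect_error(call_focal_amplification(
    flat, fsegs, list(gene = "g", chrom = "99", start = 1, end = 2), arms),
    "no bins")
})
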