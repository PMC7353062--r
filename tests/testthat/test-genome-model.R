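test_that("arm construction splits at the centromere and flags acrocentrics", {
  build <- default_build()
  arms <- make_arms(build)
  expect_equal(nrow(arms), 48)  # 2 arms x 24 chromosomes
  expect_setequal(arms$arm_id[arms$acrocentric_short],
                  c("13p", "14p", "15p", "21p", "22p"))

  toy <- genome_build(data.frame(chrom = "c", length = 100, centromere = 40))
  ta <- make_arms(toy, acrocentric = character(0))
  expect_equal(ta$start, c(0, 40))
  expect_equal(ta$end, c(40, 100))
})

test_that("invalid builds are rejected", {
  expect_error(genome_build(data.frame(chrom = c("a", "a"),
                                       length = c(10, 10),
                                       centromere = c(5, 5))),
               "unique")
  expect_error(genome_build(data.frame(chrom = "a", length = 100,
                                       centromere = 100)),
               "strictly inside")
  expect_error(genome_build(data.frame(chrom = "a", length = 0,
                                       centromere = 0)), "positive")
  expect_error(genome_build(data.frame(chrom = "a", length = 100,
                                       centromere = NA)), "missing")
})

test_that("bins tile each chromosome half-open, short terminal bin allowed", {
  toy <- genome_build(data.frame(chrom = "c", length = 2500000,
                                 centromere = 1200000))
  bins <- make_bins(toy, 1e6)
  expect_equal(bins$start, c(0, 1e6, 2e6))
  expect_equal(bins$end, c(1e6, 2e6, 2.5e6))
  expect_error(make_bins(toy, 0), "positive")

  build <- default_build()
  b <- make_bins(build, 1e6)
  chr <- build$chromosomes
  expect_equal(nrow(b), sum(ceiling(chr$length / 1e6)))
  # exhaustive, non-overlapping tiling per chromosome
  for (ch in c("1", "13", "X")) {
    bb <- b[b$chrom == ch, ]
    expect_equal(bb$start[-1], bb$end[-nrow(bb)])
    expect_equal(bb$start[1], 0)
    expect_equal(bb$end[nrow(bb)], chr$length[chr$chrom == ch])
  }
})

test_that("the FGFR1 locus falls in the chr8 38-39 Mb bin", {
  bins <- make_bins(default_build(), 1e6)
  gr <- gene_region("FGFR1")
  idx <- plasmaCNV:::overlapping_regions(bins, gr$chrom, gr$start, gr$end)
  expect_length(idx, 1)
  expect_equal(bins$chrom[idx], "8")
  expect_equal(bins$start[idx], 38e6)
  expect_equal(bins$end[idx], 39e6)
})

test_that("read counting respects mapq, flags, and region assignment", {
  build <- toy_build()
  bins <- make_bins(build, 10000)
  reads <- data.frame(
    qname = c("r1", "r2", "r3", "r4", "r5"),
    flag = c(0L, 0L, 0L, 256L, 1024L),   # r4 secondary, r5 duplicate
    chrom = c("tc1", "tc1", "tc2", "tc2", "tc2"),
    pos1 = c(101L, 15001L, 25001L, 25001L, 30001L),
    mapq = c(60L, 10L, 60L, 60L, 60L))   # r2 fails mapq > 15
  bam <- write_test_bam(reads, build)
  prof <- count_reads(bam, bins, min_mapq = 15)
  expect_s3_class(prof, "bin_counts")
  expect_equal(prof$total_reads, 2)
  expect_equal(sum(prof$counts), 2)
  expect_equal(prof$counts[bins$chrom == "tc1" & bins$start == 0], 1)
  expect_equal(prof$counts[bins$chrom == "tc2" & bins$start == 20000], 1)

  arms <- make_arms(build, acrocentric = character(0))
  pa <- count_reads(bam, arms, min_mapq = 15)
  expect_equal(unname(pa$counts[c("tc1p", "tc2q")]), c(1, 1))
  expect_equal(sum(pa$counts), 2)
})

test_that("read counting is invariant to input read order and handles empties", {
  build <- toy_build()
  bins <- make_bins(build, 10000)
  reads <- data.frame(qname = paste0("r", 1:4), flag = 0L,
                      chrom = c("tc1", "tc2", "tc1", "tc2"),
                      pos1 = c(500L, 100L, 90001L, 49000L), mapq = 60L)
  b1 <- write_test_bam(reads, build)
  b2 <- write_test_bam(reads[c(3, 1, 4, 2), ], build)
  expect_equal(count_reads(b1, bins)$counts, count_reads(b2, bins)$counts)

  empty <- write_test_bam(reads[0, ], build)
  pe <- count_reads(empty, bins)
  expect_equal(sum(pe$counts), 0)
  expect_equal(pe$total_reads, 0)
})

test_that("reads on contigs absent from the build are a validation error", {
  build <- toy_build()
  other <- genome_build(data.frame(chrom = "weird", length = 1e5,
                                   centromere = 5e4))
  reads <- data.frame(qname = "r1", flag = 0L, chrom = "weird",
                      pos1 = 100L, mapq = 60L)
  bam <- write_test_bam(reads, other)
  expect_error(count_reads(bam, make_bins(build, 1e4)), "weird")
})

test_that("count tables round-trip and reject bad input", {
  build <- toy_build()
  bins <- make_bins(build, 10000)
  prof <- bin_count_profile("s1", bins, seq_len(nrow(bins)))
  path <- tempfile(fileext = ".tsv")
  write_count_table(prof, path)
  back <- read_count_table(path, bins)
  expect_length(back, 1)
  expect_equal(back$s1$counts, prof$counts)
  expect_equal(back$s1$total_reads, prof$total_reads)

  arms <- make_arms(build, acrocentric = character(0))
  pa <- arm_count_profile("a1", setNames(c(5, 0, 2, 9), arms$arm_id))
  write_count_table(pa, path)
  back_a <- read_count_table(path, arms)
  expect_equal(back_a$a1$counts, pa$counts)

  tab <- read.delim(path)
  tab$count[1] <- -5
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_table(path, arms), "nonnegative")

  tab$count[1] <- 5
  tab$arm[1] <- "nosuch"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_table(path, arms), "unknown arms")
})

test_that("profile constructors enforce their invariants", {
  expect_error(arm_count_profile("s", setNames(c(-1, 2), c("1p", "1q"))),
               "nonnegative")
  expect_error(arm_count_profile("s", setNames(c(1, 2), c("1p", "1q")),
                                 total_reads = 1), ">=")
  bins <- make_bins(toy_build(), 10000)
  expect_error(bin_count_profile("s", bins, 1:3), "nrow")
})
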