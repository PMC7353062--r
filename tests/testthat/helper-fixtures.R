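# shared in-code fixtures; everything is generated, nothing is stored

toy_build <- function() {
  genome_build(data.frame(chrom = c("tc1", "tc2"),
                          length = c(100000, 50000),
                          centromere = c(40000, 20000)),
               name = "toy")
}

# single-chromosome build (chr8 of the bundled genome) for fast sWGS sims
chr8_build <- function() {
  chr <- default_build()$chromosomes
  genome_build(chr[chr$chrom == "8", ], name = "chr8-only")
}

# noise-free log2 profile for a genotype at tumor fraction tf
noise_free_profile <- function(genotype, tf, bins, sample_id = "nf") {
  structure(list(sample_id = sample_id, bins = bins,
                 log2 = log2(plasmaCNV:::weighted_relative_coverage(
                   genotype, tf, bins)),
                 excluded_reason = rep(NA_character_, nrow(bins))),
            class = "log2_profile")
}

# write a small SAM and convert to an indexed BAM; reads is a data.frame
# with qname, flag, chrom, pos1 (1-based), mapq
write_test_bam <- function(reads, build) {
  chr <- build$chromosomes
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chr$chrom, chr$length))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t50M\t*\t0\t0\t*\t*",
                  reads$qname, reads$flag, reads$chrom, reads$pos1,
                  reads$mapq)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, body), sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
}

expect_silent_warning_free <- function(expr) {
  expect_warning(expr, regexp = NA)
}
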