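#' Per-arm read-count profile
#'
#' @param sample_id sample label.
#' @param counts named nonnegative vector, one element per arm, named by
#'   `arm_id` (e.g. `"1p"`).
#' @param total_reads total passing reads for the sample; must be at least
#'   the sum of the arm counts (reads in unlisted regions may be dropped).
#' @return Object of class `arm_counts`.
#' @export
arm_count_profile <- function(sample_id, counts, total_reads = sum(counts)) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("`counts` must be named by arm_id")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("arm counts must be finite and nonnegative")
  if (total_reads < sum(counts))
    stop("total_reads must be >= sum of arm counts")
  structure(list(sample_id = as.character(sample_id), counts = counts,
                 total_reads = total_reads),
            class = "arm_counts")
}

#' Per-bin read-count profile
#'
#' @param sample_id sample label.
#' @param bins bin table from [make_bins()] (the profile keeps a copy so
#'   that downstream stages can locate bins).
#' @param counts nonnegative vector parallel to `bins`.
#' @param total_reads total passing reads (defaults to `sum(counts)`).
#' @return Object of class `bin_counts` with fields `excluded` (logical)
#'   and `excluded_reason` maintained by the GC-correction stage.
#' @export
bin_count_profile <- function(sample_id, bins, counts,
                              total_reads = sum(counts)) {
  if (nrow(bins) != length(counts))
    stop("length(counts) must equal nrow(bins)")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("bin counts must be finite and nonnegative")
  structure(list(sample_id = as.character(sample_id), bins = bins,
                 counts = as.numeric(counts), total_reads = total_reads,
                 excluded = rep(FALSE, length(counts)),
                 excluded_reason = rep(NA_character_, length(counts))),
            class = "bin_counts")
}

#' @export
print.arm_counts <- function(x, ...) {
  cat("<arm_counts>", x$sample_id, "-", length(x$counts), "arms,",
      format(x$total_reads, big.mark = ","), "reads\n")
  invisible(x)
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("<bin_counts>", x$sample_id, "-", nrow(x$bins), "bins,",
      format(round(x$total_reads), big.mark = ","), "reads",
      if (any(x$excluded)) paste0("(", sum(x$excluded), " excluded)"),
      "\n")
  invisible(x)
}

#' Count aligned reads per chromosome arm or genomic bin
#'
#' Each primary, non-duplicate, non-supplementary alignment with mapping
#' quality strictly above `min_mapq` is assigned to the region containing
#' its leftmost aligned base. `total_reads` is the number of passing reads.
#'
#' @param bam path to a BAM file.
#' @param regions arm table from [make_arms()] or bin table from
#'   [make_bins()]; arms are recognised by the presence of an `arm_id`
#'   column.
#' @param min_mapq mapping-quality cutoff; reads with `mapq > min_mapq`
#'   are counted (default 15).
#' @param sample_id sample label (defaults to the BAM basename).
#' @return An `arm_counts` or `bin_counts` profile.
#' @export
count_reads <- function(bam, regions, min_mapq = 15,
                        sample_id = sub("\\.bam$", "", basename(bam))) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "mapq"))
  aln <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                  error = function(e)
                    stop("failed to read alignments from ", bam, ": ",
                         conditionMessage(e)))
  keep <- !is.na(aln$mapq) & aln$mapq > min_mapq & !is.na(aln$pos)
  rname <- as.character(aln$rname)[keep]
  pos0 <- aln$pos[keep] - 1L   # BAM is 1-based; internal 0-based
  unknown <- setdiff(unique(rname), unique(regions$chrom))
  if (length(unknown))
    stop("alignment contigs absent from the build: ",
         paste(unknown, collapse = ", "))
  n_regions <- nrow(regions)
  counts <- numeric(n_regions)
  for (ch in unique(rname)) {
    idx <- which(regions$chrom == ch)
    reg <- regions[idx, ]
    p <- pos0[rname == ch]
    slot <- findInterval(p, reg$start)
    ok <- slot >= 1 & p < reg$end[pmax(slot, 1)]
    tab <- tabulate(slot[ok], nbins = nrow(reg))
    counts[idx] <- counts[idx] + tab
  }
  if ("arm_id" %in% names(regions)) {
    arm_count_profile(sample_id, setNames(counts, regions$arm_id),
                      total_reads = sum(keep))
  } else {
    bin_count_profile(sample_id, regions, counts, total_reads = sum(keep))
  }
}

#' Write count profiles to a TSV table
#'
#' Arm profiles are written with columns `sample_id`, `arm`, `count`,
#' `total_reads`; bin profiles with `sample_id`, `chrom`, `start`, `end`,
#' `count`, `total_reads` (BED-style half-open coordinates). Multiple
#' profiles are stacked in one file.
#'
#' @param profiles a single profile or a list of profiles of one kind.
#' @param path output TSV path.
#' @export
write_count_table <- function(profiles, path) {
  if (inherits(profiles, c("arm_counts", "bin_counts")))
    profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (inherits(p, "arm_counts")) {
      data.frame(sample_id = p$sample_id, arm = names(p$counts),
                 count = unname(p$counts), total_reads = p$total_reads,
                 stringsAsFactors = FALSE)
    } else if (inherits(p, "bin_counts")) {
      data.frame(sample_id = p$sample_id, chrom = p$bins$chrom,
                 start = p$bins$start, end = p$bins$end,
                 count = p$counts, total_reads = p$total_reads,
                 stringsAsFactors = FALSE)
    } else stop("unsupported profile class")
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read count profiles from a TSV table
#'
#' The table schema (arm vs bin) is detected from the header. Counts must
#' be nonnegative and every region must belong to `regions`.
#'
#' @param path TSV written by [write_count_table()] (or equivalent).
#' @param regions the arm or bin table the counts are keyed by.
#' @return Named list of profiles, one per `sample_id`, in file order.
#' @export
read_count_table <- function(path, regions) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"count" %in% names(tab) || !"sample_id" %in% names(tab))
    stop("count table must have `sample_id` and `count` columns")
  if (any(!is.finite(tab$count) | tab$count < 0))
    stop("counts must be finite and nonnegative")
  by_arm <- "arm" %in% names(tab)
  if (!by_arm && !all(c("chrom", "start", "end") %in% names(tab)))
    stop("count table must have either an `arm` column or ",
         "`chrom`/`start`/`end` columns")
  samples <- unique(tab$sample_id)
  out <- lapply(samples, function(s) {
    rows <- tab[tab$sample_id == s, ]
    total <- if ("total_reads" %in% names(rows)) rows$total_reads[1]
             else sum(rows$count)
    if (by_arm) {
      unknown <- setdiff(rows$arm, regions$arm_id)
      if (length(unknown))
        stop("unknown arms in count table: ", paste(unknown, collapse = ", "))
      counts <- setNames(rep(0, nrow(regions)), regions$arm_id)
      counts[rows$arm] <- rows$count
      arm_count_profile(s, counts, total_reads = total)
    } else {
      key <- paste(regions$chrom, regions$start, regions$end)
      rkey <- paste(rows$chrom, rows$start, rows$end)
      unknown <- setdiff(rkey, key)
      if (length(unknown))
        stop("unknown bins in count table: ",
             paste(utils::head(unknown, 5), collapse = "; "))
      counts <- numeric(nrow(regions))
      counts[match(rkey, key)] <- rows$count
      bin_count_profile(s, regions, counts, total_reads = total)
    }
  })
  setNames(out, samples)
}
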