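#' Construct a genome build
#'
#' A genome build is the coordinate scaffold shared by all stages: an
#' ordered set of chromosomes with their lengths and a single centromere
#' position splitting each chromosome into a p and a q arm. Coordinates
#' are 0-based half-open throughout the package.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`,
#'   `centromere` (base pairs; centromere strictly inside the chromosome).
#' @param name label for the build.
#' @return An object of class `genome_build`.
#' @seealso [default_build()], [make_arms()], [make_bins()]
#' @export
genome_build <- function(chromosomes, name = "custom") {
  if (!is.data.frame(chromosomes))
    stop("`chromosomes` must be a data.frame")
  req <- c("chrom", "length", "centromere")
  missing_cols <- setdiff(req, names(chromosomes))
  if (length(missing_cols))
    stop("chromosome table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  chromosomes <- chromosomes[, req]
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("chromosome names must be unique")
  if (any(!is.finite(chromosomes$length) | chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  if (any(is.na(chromosomes$centromere)))
    stop("centromere position missing for: ",
         paste(chromosomes$chrom[is.na(chromosomes$centromere)],
               collapse = ", "))
  inside <- chromosomes$centromere > 0 &
    chromosomes$centromere < chromosomes$length
  if (!all(inside))
    stop("centromere must lie strictly inside (0, length) for: ",
         paste(chromosomes$chrom[!inside], collapse = ", "))
  structure(list(name = name, chromosomes = chromosomes),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build>", x$name, "-", nrow(x$chromosomes),
      "chromosomes,", format(sum(x$chromosomes$length), big.mark = ","),
      "bp\n")
  invisible(x)
}

#' Read a genome build from a TSV file
#'
#' @param path TSV with header `chrom`, `length`, `centromere`.
#' @inheritParams genome_build
#' @export
read_genome_build <- function(path, name = basename(path)) {
  genome_build(read.delim(path, stringsAsFactors = FALSE), name = name)
}

#' The bundled hg19-like genome build
#'
#' Chromosomes 1-22, X and Y with hg19 lengths and centromere positions
#' taken as the midpoint of the hg19 centromeric gap.
#' @return A `genome_build`.
#' @export
default_build <- function() {
  read_genome_build(
    system.file("extdata", "hg19_chromosomes.tsv", package = "plasmaCNV"),
    name = "hg19-like")
}

#' Split a build into chromosome arms
#'
#' Each chromosome yields a p arm `[0, centromere)` and a q arm
#' `[centromere, length)`. The short arms of the acrocentric chromosomes
#' (13, 14, 15, 21, 22 in the default build) carry essentially no uniquely
#' alignable LINE-1 signal and are flagged so that downstream z-score
#' stages can drop them.
#'
#' @param build a `genome_build`.
#' @param acrocentric chromosome names whose p arm is flagged
#'   `acrocentric_short`.
#' @return data.frame with columns `chrom`, `arm`, `start`, `end`,
#'   `arm_id`, `acrocentric_short`, ordered by chromosome then arm.
#' @export
make_arms <- function(build, acrocentric = c("13", "14", "15", "21", "22")) {
  stopifnot(inherits(build, "genome_build"))
  chr <- build$chromosomes
  arms <- rbind(
    data.frame(chrom = chr$chrom, arm = "p", start = 0,
               end = chr$centromere, stringsAsFactors = FALSE),
    data.frame(chrom = chr$chrom, arm = "q", start = chr$centromere,
               end = chr$length, stringsAsFactors = FALSE))
  arms <- arms[order(match(arms$chrom, chr$chrom), arms$arm), ]
  rownames(arms) <- NULL
  arms$arm_id <- paste0(arms$chrom, arms$arm)
  arms$acrocentric_short <- arms$chrom %in% acrocentric & arms$arm == "p"
  arms
}

#' Tile a build into fixed-size bins
#'
#' Half-open bins of `bin_size` bp tile every chromosome; the terminal bin
#' of each chromosome may be shorter. `gc_fraction` is initialised to `NA`
#' and can be filled from an annotation or by [simulate_gc_content()].
#'
#' @param build a `genome_build`.
#' @param bin_size bin width in bp (default 1 Mb, the working resolution
#'   of shallow WGS copy-number profiling).
#' @return data.frame with columns `chrom`, `start`, `end`, `gc_fraction`.
#' @export
make_bins <- function(build, bin_size = 1e6) {
  stopifnot(inherits(build, "genome_build"))
  if (!is.numeric(bin_size) || length(bin_size) != 1 ||
      !is.finite(bin_size) || bin_size <= 0)
    stop("`bin_size` must be a single positive number")
  chr <- build$chromosomes
  pieces <- lapply(seq_len(nrow(chr)), function(i) {
    starts <- seq(0, chr$length[i] - 1, by = bin_size)
    data.frame(chrom = chr$chrom[i], start = starts,
               end = pmin(starts + bin_size, chr$length[i]),
               gc_fraction = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Bundled gene annotation
#'
#' @param path TSV with header `gene`, `chrom`, `start`, `end` (default:
#'   the bundled hg19-like annotation carrying the FGFR1 locus at 8p11-12).
#' @return data.frame of gene regions.
#' @export
read_gene_annotation <- function(path = system.file(
    "extdata", "genes_hg19.tsv", package = "plasmaCNV")) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "start", "end")
  if (!all(req %in% names(ann)))
    stop("gene annotation must have columns: ", paste(req, collapse = ", "))
  ann$chrom <- as.character(ann$chrom)
  ann
}

#' Look up a gene region
#'
#' @param gene gene symbol (default `"FGFR1"`).
#' @param annotation data.frame as returned by [read_gene_annotation()].
#' @return One-row data.frame with `gene`, `chrom`, `start`, `end`.
#' @export
gene_region <- function(gene = "FGFR1", annotation = read_gene_annotation()) {
  hit <- annotation[annotation$gene == gene, , drop = FALSE]
  if (nrow(hit) != 1)
    stop("gene not found in annotation: ", gene)
  rownames(hit) <- NULL
  hit
}

# indices of bins/regions overlapping [start, end) on chrom
overlapping_regions <- function(regions, chrom, start, end) {
  which(regions$chrom == chrom & regions$start < end & regions$end > start)
}
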