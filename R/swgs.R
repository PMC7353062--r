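#' GC-bias correction of bin counts
#'
#' Fits a smooth count-vs-GC curve by loess over the usable GC range and
#' rescales each bin by `median(count) / fitted(gc)`. Bins with missing
#' GC or GC outside `gc_range` are excluded from both the fit and the
#' downstream profile and flagged with a reason.
#'
#' @param profile a `bin_counts` profile whose bins carry `gc_fraction`
#'   for at least 90% of bins.
#' @param span loess span (default 0.3).
#' @param gc_range usable GC interval (default `[0.3, 0.6]`).
#' @return The profile with corrected (non-integer) counts and updated
#'   `excluded` / `excluded_reason` fields.
#' @export
gc_correct <- function(profile, span = 0.3, gc_range = c(0.3, 0.6)) {
  gc <- profile$bins$gc_fraction
  if (mean(!is.na(gc)) < 0.9)
    stop("gc_fraction present for < 90% of bins; cannot GC-correct")
  out_of_range <- !is.na(gc) & (gc < gc_range[1] | gc > gc_range[2])
  excl <- is.na(gc) | out_of_range
  reason <- ifelse(is.na(gc), "no-gc",
                   ifelse(out_of_range, "gc-outlier", NA_character_))
  use <- !excl
  fit <- loess(count ~ gc, data = data.frame(count = profile$counts[use],
                                             gc = gc[use]),
               span = span, degree = 2)
  fitted <- predict(fit, newdata = data.frame(gc = gc[use]))
  bad_fit <- !is.finite(fitted) | fitted <= 0
  corrected <- profile$counts
  corrected[use][!bad_fit] <- profile$counts[use][!bad_fit] *
    median(profile$counts[use]) / fitted[!bad_fit]
  if (any(bad_fit)) {
    idx <- which(use)[bad_fit]
    excl[idx] <- TRUE
    reason[idx] <- "gc-fit"
  }
  profile$counts <- corrected
  profile$excluded <- profile$excluded | excl
  profile$excluded_reason <- ifelse(is.na(profile$excluded_reason),
                                    reason, profile$excluded_reason)
  profile
}

#' Log2 ratio of a sample against a control panel
#'
#' Per-bin fractions of the sample are divided by the median per-bin
#' fraction over the control panel and log2-transformed:
#' `r_i = log2((s_i / sum s) / median_c(c_i / sum c))`. Bins excluded in
#' the sample, or with a zero/undefined control median, are set to `NA`
#' with a reason.
#'
#' @param sample a `bin_counts` profile (typically GC-corrected).
#' @param panel list of >= 1 control `bin_counts` profiles on the same
#'   bin set.
#' @return Object of class `log2_profile`: list with `sample_id`, `bins`,
#'   `log2` (NA where excluded), `excluded_reason`.
#' @export
log2_ratio <- function(sample, panel) {
  if (inherits(panel, "bin_counts")) panel <- list(panel)
  if (!length(panel)) stop("control panel is empty")
  nb <- nrow(sample$bins)
  for (p in panel) {
    if (nrow(p$bins) != nb ||
        !all(p$bins$chrom == sample$bins$chrom) ||
        !all(p$bins$start == sample$bins$start))
      stop("panel profile ", p$sample_id,
           " is not on the same bin set as the sample")
  }
  cfrac <- vapply(panel, function(p) {
    f <- p$counts
    f[p$excluded] <- NA
    f / sum(f, na.rm = TRUE)
  }, numeric(nb))
  cmed <- apply(cfrac, 1, median, na.rm = TRUE)
  s <- sample$counts
  s[sample$excluded] <- NA
  sfrac <- s / sum(s, na.rm = TRUE)
  r <- log2(sfrac / cmed)
  reason <- sample$excluded_reason
  zero_ctrl <- (!is.finite(cmed) | cmed <= 0) & !sample$excluded
  reason[zero_ctrl] <- "zero-control"
  r[!is.finite(r)] <- NA
  structure(list(sample_id = sample$sample_id, bins = sample$bins,
                 log2 = r, excluded_reason = reason),
            class = "log2_profile")
}

#' @export
print.log2_profile <- function(x, ...) {
  cat("<log2_profile>", x$sample_id, "-", sum(!is.na(x$log2)), "of",
      length(x$log2), "bins; median",
      round(median(x$log2, na.rm = TRUE), 3), "\n")
  invisible(x)
}

# clip single-bin excursions toward a running median (window 5) so that
# breakpoint detection is not dominated by focal outliers; no-op when the
# residual MAD is zero (noise-free profiles)
winsorize_outliers <- function(x, window = 5, k = 2.5) {
  n <- length(x)
  if (n < window) return(x)
  m <- stats::runmed(x, window, endrule = "median")
  r <- x - m
  sigma <- stats::mad(r)
  if (sigma == 0) return(x)
  m + pmin(pmax(r, -k * sigma), k * sigma)
}

# local refinement sweep: shift each accepted breakpoint within a small
# window to the position minimizing the SSE of the two adjacent segments
refine_breaks <- function(x, breaks, min_bins, window = 3) {
  if (!length(breaks)) return(breaks)
  bounds <- c(0, breaks, length(x))
  for (j in seq_along(breaks)) {
    lo <- bounds[j] + 1
    hi <- bounds[j + 2]
    cand <- (bounds[j + 1] - window):(bounds[j + 1] + window)
    cand <- cand[cand >= lo + min_bins - 1 & cand <= hi - min_bins]
    if (length(cand) < 2) next
    sse <- vapply(cand, function(k) {
      a <- x[lo:k]
      b <- x[(k + 1):hi]
      sum((a - mean(a))^2) + sum((b - mean(b))^2)
    }, numeric(1))
    bounds[j + 1] <- cand[which.min(sse)]
  }
  bounds[-c(1, length(bounds))]
}

# best single split of x by two-sample pooled-variance t statistic;
# returns NULL or list(k = left size, p = p-value)
best_split <- function(x, min_bins) {
  n <- length(x)
  if (n < 2 * min_bins) return(NULL)
  cs <- cumsum(x)
  css <- cumsum(x^2)
  k <- min_bins:(n - min_bins)
  n1 <- k
  n2 <- n - k
  m1 <- cs[k] / n1
  m2 <- (cs[n] - cs[k]) / n2
  ss <- pmax(css[k] - n1 * m1^2, 0) + pmax(css[n] - css[k] - n2 * m2^2, 0)
  se <- sqrt(ss / (n - 2) * (1 / n1 + 1 / n2))
  tt <- abs(m1 - m2) / se
  tt[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 0, Inf)
  i <- which.max(tt)
  list(k = k[i], p = 2 * pt(-tt[i], df = n - 2))
}

#' Segment a log2-ratio profile by recursive binary splitting
#'
#' At each step the breakpoint maximizing the two-sample t statistic
#' between the left and right bin means is placed; the split is accepted
#' if its p-value is below `alpha` and both sides retain at least
#' `min_bins` bins, then both sides are segmented recursively. Segments
#' are labelled `gain` / `loss` / `balanced` by their mean log2 ratio.
#'
#' @param profile a `log2_profile`.
#' Single-bin outliers (e.g. focal amplicons) would otherwise inflate the
#' within-segment variance and mask genuine arm-level breakpoints, so
#' breakpoint detection runs on values winsorized toward a running median
#' (`smooth = TRUE`); segment means are always computed on the raw
#' values, so the reported profile is unbiased.
#'
#' @param alpha split acceptance level (default 1e-4).
#' @param min_bins minimum bins per segment (default 3).
#' @param gain_threshold,loss_threshold mean-log2 label cutoffs
#'   (defaults +0.1 / -0.1).
#' @param smooth winsorize outliers before breakpoint detection
#'   (default TRUE; automatically skipped for noise-free profiles).
#' @return data.frame of segments: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_log2`, `label`, ordered and non-overlapping within chromosome.
#' @export
segment_profile <- function(profile, alpha = 1e-4, min_bins = 3,
                            gain_threshold = 0.1, loss_threshold = -0.1,
                            smooth = TRUE) {
  segs <- list()
  for (ch in unique(profile$bins$chrom)) {
    on_ch <- which(profile$bins$chrom == ch & !is.na(profile$log2))
    if (!length(on_ch)) {
      warning("chromosome ", ch, " has no usable bins; skipped")
      next
    }
    x_raw <- profile$log2[on_ch]
    x <- if (smooth) winsorize_outliers(x_raw) else x_raw
    breaks <- integer(0)
    recurse <- function(lo, hi) {
      sp <- best_split(x[lo:hi], min_bins)
      if (is.null(sp) || sp$p >= alpha) return(invisible())
      cut <- lo + sp$k - 1
      breaks <<- c(breaks, cut)
      recurse(lo, cut)
      recurse(cut + 1, hi)
    }
    recurse(1, length(x))
    breaks <- refine_breaks(x, sort(unique(breaks)), min_bins)
    bounds <- sort(unique(c(0, breaks, length(x))))
    for (j in seq_len(length(bounds) - 1)) {
      idx <- on_ch[(bounds[j] + 1):bounds[j + 1]]
      m <- mean(profile$log2[idx])
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = profile$bins$start[idx[1]],
        end = profile$bins$end[idx[length(idx)]],
        n_bins = length(idx), mean_log2 = m,
        label = if (m >= gain_threshold) "gain"
                else if (m <= loss_threshold) "loss" else "balanced",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Call focal amplification of a target gene
#'
#' Three configurable criteria, all of which must hold:
#' the mean log2 ratio of the bins overlapping the gene is at least
#' `min_log2`; it exceeds the median log2 ratio of the chromosome arm
#' carrying the gene by at least `min_delta` (so whole-arm gains alone do
#' not fire); and the event is focal — the contiguous run of bins around
#' the gene that stay at least `min_delta` above the arm median spans at
#' most `max_len` bp. (The run, not the covering segment, measures
#' focality: a 1-Mb amplicon can never form its own segment under the
#' segmenter's minimum-segment-size rule.) Default thresholds of 0.1 are
#' matched to the gain/loss labelling scale and admit high-amplitude
#' amplifications down to tumor fractions below 1%.
#'
#' @param profile a `log2_profile`.
#' @param segments segment table from [segment_profile()].
#' @param region one-row data.frame or list with `chrom`, `start`, `end`
#'   (e.g. [gene_region()]); a `gene` field is carried into the call.
#' @param arms arm table locating the carrying arm (default: arms of the
#'   bundled build).
#' @param min_log2 minimum gene-bin mean log2 ratio (default 0.1).
#' @param min_delta minimum excess over the arm median (default 0.1).
#' @param max_len maximum length of the elevated run in bp (default
#'   20 Mb).
#' @return Object of class `focal_call`: `gene`, `gene_log2`,
#'   `arm_median`, `event_length` (elevated run), `segment_length`
#'   (covering segment, informational), `called`, and a `criteria`
#'   record of thresholds and per-criterion outcomes.
#' @export
call_focal_amplification <- function(profile, segments, region,
                                     arms = make_arms(default_build()),
                                     min_log2 = 0.1, min_delta = 0.1,
                                     max_len = 20e6) {
  gene_bins <- overlapping_regions(profile$bins, region$chrom,
                                   region$start, region$end)
  if (!length(gene_bins))
    stop("gene region overlaps no bins of this profile (wrong build?)")
  gene_log2 <- mean(profile$log2[gene_bins], na.rm = TRUE)
  if (!is.finite(gene_log2))
    stop("all bins overlapping the gene region are excluded")
  mid <- (region$start + region$end) / 2
  arm <- arms[arms$chrom == region$chrom & arms$start <= mid &
                arms$end > mid, ]
  if (nrow(arm) != 1)
    stop("gene region is not on any arm of the supplied build")
  arm_bins <- overlapping_regions(profile$bins, arm$chrom, arm$start,
                                  arm$end)
  arm_median <- median(profile$log2[arm_bins], na.rm = TRUE)
  seg <- segments[segments$chrom == region$chrom & segments$start <= mid &
                    segments$end > mid, ]
  seg_len <- if (nrow(seg)) seg$end[1] - seg$start[1] else NA_real_
  # elevated run: contiguous usable bins around the gene staying at least
  # min_delta above the arm median
  chrom_bins <- which(profile$bins$chrom == region$chrom &
                        !is.na(profile$log2))
  elevated <- profile$log2[chrom_bins] >= arm_median + min_delta
  in_gene <- chrom_bins %in% gene_bins
  run_len <- 0
  if (any(elevated & in_gene)) {
    anchor <- which(elevated & in_gene)[1]
    lo <- anchor
    while (lo > 1 && elevated[lo - 1]) lo <- lo - 1
    hi <- anchor
    while (hi < length(elevated) && elevated[hi + 1]) hi <- hi + 1
    run_len <- profile$bins$end[chrom_bins[hi]] -
      profile$bins$start[chrom_bins[lo]]
  }
  crit <- list(
    min_log2 = min_log2, min_delta = min_delta, max_len = max_len,
    pass_level = gene_log2 >= min_log2,
    pass_delta = gene_log2 >= arm_median + min_delta,
    pass_focal = run_len > 0 && run_len <= max_len)
  structure(list(gene = if (!is.null(region$gene)) region$gene else NA,
                 gene_log2 = gene_log2, arm_median = arm_median,
                 arm_id = arm$arm_id, event_length = run_len,
                 segment_length = seg_len,
                 called = crit$pass_level && crit$pass_delta &&
                   crit$pass_focal,
                 criteria = crit),
            class = "focal_call")
}

#' @export
print.focal_call <- function(x, ...) {
  cat("<focal_call>", if (!is.na(x$gene)) x$gene else "region", "-",
      if (x$called) "AMPLIFIED" else "not called",
      sprintf("(gene log2 %.3f, arm %s median %.3f, event %s)\n",
              x$gene_log2, x$arm_id, x$arm_median,
              if (x$event_length > 0)
                paste0(round(x$event_length / 1e6, 1), " Mb")
              else "none"))
  invisible(x)
}

#' Plot a log2-ratio profile with tricolor segments
#'
#' Gains in red, losses in green, balanced segments in blue, following
#' the conventional rendering of plasma copy-number profiles.
#'
#' @param profile a `log2_profile`.
#' @param segments optional segment table overlaid as horizontal bars.
#' @param chrom optional single chromosome to restrict the plot to.
#' @param ylim y-axis limits.
#' @export
plot_log2_profile <- function(profile, segments = NULL, chrom = NULL,
                              ylim = c(-1.5, 1.5)) {
  bins <- profile$bins
  keep <- if (is.null(chrom)) rep(TRUE, nrow(bins)) else bins$chrom == chrom
  mids <- (bins$start[keep] + bins$end[keep]) / 2
  offs <- 0
  if (is.null(chrom)) {
    # lay chromosomes end to end
    lens <- tapply(bins$end, bins$chrom, max)[unique(bins$chrom)]
    offs <- setNames(cumsum(c(0, head(as.numeric(lens), -1))),
                     unique(bins$chrom))
    mids <- mids + offs[bins$chrom[keep]]
  }
  plot(mids, pmin(pmax(profile$log2[keep], ylim[1]), ylim[2]),
       pch = 16, cex = 0.35, col = "grey50", ylim = ylim,
       xlab = if (is.null(chrom)) "genome position" else
         paste("chromosome", chrom, "(bp)"),
       ylab = "log2 ratio", main = profile$sample_id)
  abline(h = 0, col = "grey70")
  if (!is.null(segments)) {
    segs <- if (is.null(chrom)) segments else
      segments[segments$chrom == chrom, ]
    cols <- c(gain = "red", loss = "green3", balanced = "blue")
    off <- if (is.null(chrom)) offs[segs$chrom] else 0
    graphics::segments(segs$start + off, segs$mean_log2,
                       segs$end + off, segs$mean_log2,
                       col = cols[segs$label], lwd = 3)
  }
  invisible(NULL)
}
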