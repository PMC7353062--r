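#' Copy-number event
#'
#' A genomic interval carried at `total_copies` in the tumor genome.
#' The diploid background (2 copies) is implicit, so `total_copies == 2`
#' is rejected.
#'
#' @param chrom chromosome name.
#' @param start,end bp, 0-based half-open.
#' @param total_copies integer copy number >= 0, != 2.
#' @export
cna_event <- function(chrom, start, end, total_copies) {
  if (start < 0 || end <= start) stop("event interval must satisfy 0 <= start < end")
  if (total_copies < 0 || total_copies == 2)
    stop("total_copies must be a nonnegative integer other than 2")
  list(chrom = as.character(chrom), start = start, end = end,
       total_copies = as.integer(total_copies))
}

#' Tumor genotype: a set of non-overlapping copy-number events
#'
#' @param events list of [cna_event()]s; events on the same chromosome
#'   must not overlap.
#' @export
tumor_genotype <- function(events = list()) {
  if (length(events)) {
    ev <- data.frame(chrom = vapply(events, `[[`, "", "chrom"),
                     start = vapply(events, `[[`, 0, "start"),
                     end = vapply(events, `[[`, 0, "end"))
    for (ch in unique(ev$chrom)) {
      e <- ev[ev$chrom == ch, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
        stop("events overlap on chromosome ", ch)
    }
  }
  structure(list(events = events, background_ploidy = 2L),
            class = "tumor_genotype")
}

#' A breast-cancer-like default genotype
#'
#' Whole-arm gains of 1q and 8q (3 copies), whole-arm losses of 16q and
#' 17p (1 copy), and optionally a focal amplification of the 1-Mb window
#' harboring FGFR1 (chr8:38-39 Mb, aligned to the default bin grid).
#'
#' @param build a `genome_build`.
#' @param focal_amp include the focal FGFR1 amplification?
#' @param focal_copies total copies of the focal event (default 16).
#' @export
default_tumor_genotype <- function(build = default_build(),
                                   focal_amp = FALSE, focal_copies = 16) {
  arms <- make_arms(build)
  arm_event <- function(id, copies) {
    a <- arms[arms$arm_id == id, ]
    cna_event(a$chrom, a$start, a$end, copies)
  }
  events <- list(arm_event("1q", 3), arm_event("8q", 3),
                 arm_event("16q", 1), arm_event("17p", 1))
  if (focal_amp)
    events <- c(events, list(cna_event("8", 38e6, 39e6, focal_copies)))
  tumor_genotype(events)
}

#' Simulation configuration
#'
#' @param tumor_fraction fraction of cfDNA derived from tumor cells, in
#'   `[0, 1]`.
#' @param total_reads expected total read count (default 6,430,000, the
#'   average depth of the sWGS assay being emulated; mFAST-SeqS-style arm
#'   profiles typically use 100,000).
#' @param dispersion negative-binomial size parameter *per megabase of
#'   region length*; larger values approach Poisson noise (default 200).
#'   A region of length L bp is drawn with size `dispersion * L / 1e6`,
#'   so a chromosome arm — a sum of many megabase-scale units — is
#'   proportionally less overdispersed than a single 1-Mb bin.
#' @param gc_bias_coeffs optional length-2 numeric `c(b1, b2)` giving a
#'   multiplicative bias `1 + b1*(gc-0.45) + b2*(gc-0.45)^2`, unity at
#'   GC = 0.45; `NULL` disables GC bias.
#' @param seed integer seed; every draw made under this configuration is
#'   reproducible.
#' @export
sim_config <- function(tumor_fraction, total_reads = 6430000,
                       dispersion = 200, gc_bias_coeffs = NULL, seed) {
  if (!is.numeric(tumor_fraction) || tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]")
  if (total_reads <= 0) stop("total_reads must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (!is.null(gc_bias_coeffs) && length(gc_bias_coeffs) != 2)
    stop("gc_bias_coeffs must be NULL or length 2")
  if (missing(seed)) stop("a seed is required")
  list(tumor_fraction = tumor_fraction, total_reads = total_reads,
       dispersion = dispersion, gc_bias_coeffs = gc_bias_coeffs,
       seed = as.integer(seed))
}

# evaluate code with a temporary RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Expected relative coverage of a region under tumor admixture
#'
#' The forward model: a region at `c` total copies in the tumor and 2 in
#' normal cells contributes relative coverage
#' `R(tf, c) = 1 - tf + tf * c / 2`, so `R` is 1 for copy-neutral regions,
#' linear in both tumor fraction and copy number, and the log2 ratio of a
#' noise-free profile is `log2(R)`.
#'
#' @param genotype a `tumor_genotype`.
#' @param tf tumor fraction in `[0, 1]`.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`;
#'   must lie fully inside or fully outside every event (pre-split
#'   straddling regions).
#' @return Relative coverage (1 = copy-neutral).
#' @export
expected_relative_coverage <- function(genotype, tf, region) {
  if (tf < 0 || tf > 1) stop("tf must be in [0, 1]")
  copies <- 2
  for (ev in genotype$events) {
    if (ev$chrom != region$chrom) next
    if (region$start >= ev$start && region$end <= ev$end) {
      copies <- ev$total_copies
    } else if (region$start < ev$end && region$end > ev$start) {
      stop("region straddles an event boundary; pre-split it")
    }
  }
  1 - tf + tf * copies / 2
}

# length-weighted relative coverage over regions that may straddle events
weighted_relative_coverage <- function(genotype, tf, regions) {
  R <- rep(1, nrow(regions))
  if (tf == 0 || !length(genotype$events)) return(R)
  for (ev in genotype$events) {
    idx <- overlapping_regions(regions, ev$chrom, ev$start, ev$end)
    if (!length(idx)) next
    ov <- pmin(regions$end[idx], ev$end) - pmax(regions$start[idx], ev$start)
    frac <- ov / (regions$end[idx] - regions$start[idx])
    R[idx] <- R[idx] + frac * tf * (ev$total_copies - 2) / 2
  }
  R
}

gc_bias_factor <- function(gc, coeffs) {
  if (is.null(coeffs)) return(rep(1, length(gc)))
  d <- ifelse(is.na(gc), 0, gc - 0.45)
  pmax(1 + coeffs[1] * d + coeffs[2] * d^2, 0.01)
}

#' Simulate a genome-wide bin-count profile
#'
#' Expected counts are proportional to bin length times the admixture
#' coverage [expected_relative_coverage()] times an optional GC bias
#' factor, normalized to `total_reads`, then drawn from a negative
#' binomial with the configured dispersion. Deterministic given the
#' configuration seed.
#'
#' @param genotype a `tumor_genotype`.
#' @param config a [sim_config()].
#' @param bins bin table from [make_bins()].
#' @param sample_id sample label.
#' @return A `bin_counts` profile.
#' @export
simulate_bin_counts <- function(genotype, config, bins, sample_id = "sim") {
  R <- weighted_relative_coverage(genotype, config$tumor_fraction, bins)
  gcf <- gc_bias_factor(bins$gc_fraction, config$gc_bias_coeffs)
  lambda <- (bins$end - bins$start) * R * gcf
  lambda <- lambda / sum(lambda) * config$total_reads
  size <- config$dispersion * (bins$end - bins$start) / 1e6
  counts <- with_seed(config$seed,
                      rnbinom(length(lambda), size = size, mu = lambda))
  bin_count_profile(sample_id, bins, counts)
}

#' Simulate an arm-level count profile (LINE-1 amplicon style)
#'
#' Baseline arm weights default to arm length; pass `weights` (named by
#' `arm_id`) to emulate non-uniform amplicon density.
#'
#' @inheritParams simulate_bin_counts
#' @param arms arm table from [make_arms()].
#' @param weights optional nonnegative baseline weights named by `arm_id`.
#' @return An `arm_counts` profile.
#' @export
simulate_arm_counts <- function(genotype, config, arms, weights = NULL,
                                sample_id = "sim") {
  if (is.null(weights)) {
    weights <- setNames(arms$end - arms$start, arms$arm_id)
  } else {
    if (!all(arms$arm_id %in% names(weights)))
      stop("weights must cover every arm_id")
    weights <- weights[arms$arm_id]
  }
  R <- weighted_relative_coverage(genotype, config$tumor_fraction, arms)
  lambda <- weights * R
  lambda <- lambda / sum(lambda) * config$total_reads
  size <- config$dispersion * (arms$end - arms$start) / 1e6
  counts <- with_seed(config$seed,
                      rnbinom(length(lambda), size = size, mu = lambda))
  arm_count_profile(sample_id, setNames(counts, arms$arm_id))
}

#' Simulate a healthy control cohort
#'
#' `n` independent tumor-fraction-zero profiles with distinct seeds
#' derived from the configuration seed (default n = 35, the size of the
#' reference control population the z-score stage emulates).
#'
#' @param n number of controls (>= 2; the reference SD is undefined
#'   below that).
#' @param config a [sim_config()]; its `tumor_fraction` is ignored
#'   (controls are tumor-free).
#' @param regions arm table (-> `arm_counts`) or bin table
#'   (-> `bin_counts`).
#' @param weights optional arm weights, as in [simulate_arm_counts()].
#' @return Named list of `n` profiles.
#' @export
simulate_control_cohort <- function(n = 35, config, regions, weights = NULL) {
  if (n < 2) stop("need at least 2 controls (reference SD undefined)")
  null_gt <- tumor_genotype()
  by_arm <- "arm_id" %in% names(regions)
  out <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$tumor_fraction <- 0
    cfg$seed <- config$seed + i
    id <- sprintf("control_%02d", i)
    if (by_arm) simulate_arm_counts(null_gt, cfg, regions, weights, id)
    else simulate_bin_counts(null_gt, cfg, regions, id)
  })
  setNames(out, vapply(out, `[[`, "", "sample_id"))
}

#' Simulate a patient cohort with linked survival
#'
#' Tumor fractions are drawn log-normal (default median 0.046, matching
#' the tumor-fraction median of the metastatic breast cancer cohort this
#' generator emulates); a stated prevalence of patients (default 0.2)
#' carries the focal FGFR1 amplification on top of the default arm-level
#' genotype. Survival is exponential with log-hazard linear in log tumor
#' fraction and administrative right-censoring at a fixed horizon.
#'
#' @param n number of patients.
#' @param tf_meanlog,tf_sdlog log-normal parameters of the tumor-fraction
#'   distribution (defaults `log(0.046)` and 1.2).
#' @param focal_prevalence probability that a patient carries the focal
#'   amplification (default 0.2).
#' @param focal_copies total copies of the focal event when present.
#' @param hazard_slope log-hazard increase per unit of
#'   `log(tf) - tf_meanlog`; 0 gives a null (survival-independent) cohort.
#' @param baseline_median_os median overall survival in months at the
#'   median tumor fraction (default 44).
#' @param censor_horizon administrative censoring time in months
#'   (default 72).
#' @param seed integer seed.
#' @param profiles which count profiles to generate alongside the sample
#'   sheet: `"none"` (fast; survival studies), `"arm"`, or `"bin"`.
#' @param build genome build used for genotypes and profiles.
#' @param total_reads,dispersion passed to the per-patient [sim_config()].
#' @return List with `samples` (data.frame: `case_id`, `true_tf`,
#'   `focal_amp`, `os_months`, `event`), `genotypes`, and optionally
#'   `profiles`.
#' @export
simulate_patient_cohort <- function(n, tf_meanlog = log(0.046),
                                    tf_sdlog = 1.2, focal_prevalence = 0.2,
                                    focal_copies = 16, hazard_slope = 0.5,
                                    baseline_median_os = 44,
                                    censor_horizon = 72, seed,
                                    profiles = c("none", "arm", "bin"),
                                    build = default_build(),
                                    total_reads = NULL, dispersion = 200) {
  profiles <- match.arg(profiles)
  if (missing(seed)) stop("a seed is required")
  if (tf_sdlog <= 0 || focal_prevalence < 0 || focal_prevalence > 1 ||
      baseline_median_os <= 0 || censor_horizon <= 0)
    stop("invalid cohort distribution parameters")
  sheet <- with_seed(seed, {
    tf <- pmin(pmax(rlnorm(n, tf_meanlog, tf_sdlog), 1e-4), 0.8)
    focal <- rbinom(n, 1, focal_prevalence) == 1
    rate <- log(2) / baseline_median_os *
      exp(hazard_slope * (log(tf) - tf_meanlog))
    t_death <- rexp(n, rate)
    data.frame(case_id = sprintf("P%03d", seq_len(n)), true_tf = tf,
               focal_amp = focal, os_months = pmin(t_death, censor_horizon),
               event = t_death <= censor_horizon, stringsAsFactors = FALSE)
  })
  genotypes <- lapply(sheet$focal_amp, function(f)
    default_tumor_genotype(build, focal_amp = f, focal_copies = focal_copies))
  names(genotypes) <- sheet$case_id
  out <- list(samples = sheet, genotypes = genotypes)
  if (profiles != "none") {
    regions <- if (profiles == "arm") make_arms(build) else make_bins(build)
    if (is.null(total_reads))
      total_reads <- if (profiles == "arm") 1e5 else 6430000
    out$profiles <- lapply(seq_len(n), function(i) {
      cfg <- sim_config(sheet$true_tf[i], total_reads = total_reads,
                        dispersion = dispersion, seed = seed + 1000 + i)
      if (profiles == "arm")
        simulate_arm_counts(genotypes[[i]], cfg, regions,
                            sample_id = sheet$case_id[i])
      else
        simulate_bin_counts(genotypes[[i]], cfg, regions,
                            sample_id = sheet$case_id[i])
    })
    names(out$profiles) <- sheet$case_id
  }
  out
}

#' Assign synthetic GC fractions to bins
#'
#' Smoothly varying GC content (long-range waves plus local noise)
#' clipped to a realistic range, for exercising the GC-correction stage.
#'
#' @param bins bin table.
#' @param seed integer seed.
#' @param range clip range for the GC fraction.
#' @return `bins` with `gc_fraction` filled in.
#' @export
simulate_gc_content <- function(bins, seed, range = c(0.33, 0.58)) {
  gc <- with_seed(seed, {
    wave <- 0.04 * sin(seq_len(nrow(bins)) / 40) +
      0.03 * sin(seq_len(nrow(bins)) / 7)
    0.43 + wave + rnorm(nrow(bins), 0, 0.015)
  })
  bins$gc_fraction <- pmin(pmax(gc, range[1]), range[2])
  bins
}
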