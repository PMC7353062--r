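#' Arms retained for aneuploidy scoring
#'
#' Drops the acrocentric short arms (no usable LINE-1 signal) and, by
#' default, the sex chromosomes: the z-score stage is calibrated on a
#' copy-neutral autosomal baseline, and the interpretation of X/Y
#' representation is cohort-dependent.
#'
#' @param arms arm table from [make_arms()].
#' @param include_sex keep X/Y arms?
#' @return Subset of `arms`.
#' @export
retained_arms <- function(arms, include_sex = FALSE) {
  keep <- !arms$acrocentric_short
  if (!include_sex) keep <- keep & !arms$chrom %in% c("X", "Y")
  arms[keep, ]
}

#' Normalize arm counts to fractions
#'
#' @param profile an `arm_counts` profile.
#' @param arm_ids arms to retain (default: every arm in the profile);
#'   typically `retained_arms(make_arms(build))$arm_id`.
#' @param min_reads depth below which a QC warning is emitted
#'   (default 100,000, the assay's minimum target depth); low-depth
#'   samples are flagged, not rejected.
#' @return Named vector of fractions summing to 1 over retained arms.
#' @export
normalize_arm_counts <- function(profile, arm_ids = names(profile$counts),
                                 min_reads = 1e5) {
  missing_arms <- setdiff(arm_ids, names(profile$counts))
  if (length(missing_arms))
    stop("profile lacks arms: ", paste(missing_arms, collapse = ", "))
  counts <- profile$counts[arm_ids]
  total <- sum(counts)
  if (total <= 0)
    stop("zero total count over retained arms for sample ",
         profile$sample_id)
  if (profile$total_reads < min_reads)
    warning("sample ", profile$sample_id, " has ", profile$total_reads,
            " reads (< ", format(min_reads, big.mark = ","), "); ",
            "z-scores may be unstable")
  counts / total
}

#' Build a control reference for arm z-scores
#'
#' Per-arm mean and SD (n-1 denominator) of normalized arm fractions over
#' a healthy control cohort, plus the control distribution of the
#' summed-squared-z statistic S computed leave-one-out: each control is
#' scored against the reference built from the remaining n-1 controls, so
#' its own S is free of self-inclusion bias.
#'
#' @param controls list of `arm_counts` profiles (>= 2; >= 3 for the
#'   leave-one-out S distribution).
#' @param arm_ids arms to retain; default drops nothing, so pass
#'   `retained_arms(...)$arm_id` for the standard autosomal-arm set.
#' @param min_reads QC threshold passed to [normalize_arm_counts()]
#'   (default 0: control cohorts are assumed depth-QCed upstream; the
#'   per-sample scoring path applies the 100,000-read flag instead).
#' @return Object of class `mfastseq_ref` with fields `arm_ids`, `mu`,
#'   `sigma`, `n_controls`, `control_S`, `control_S_mean`, `control_S_sd`.
#' @export
build_reference <- function(controls,
                            arm_ids = names(controls[[1]]$counts),
                            min_reads = 0) {
  if (length(controls) < 2) stop("need at least 2 controls")
  fr <- t(vapply(controls, normalize_arm_counts, numeric(length(arm_ids)),
                 arm_ids = arm_ids, min_reads = min_reads))
  mu <- colMeans(fr)
  sigma <- apply(fr, 2, sd)
  zero <- sigma == 0
  if (any(zero))
    stop("zero control SD for arm(s): ",
         paste(arm_ids[zero], collapse = ", "),
         " (controls are not independent?)")
  n <- nrow(fr)
  if (n >= 3) {
    S <- vapply(seq_len(n), function(j) {
      mu_j <- colMeans(fr[-j, , drop = FALSE])
      sd_j <- apply(fr[-j, , drop = FALSE], 2, sd)
      if (any(sd_j == 0))
        stop("zero leave-one-out SD; controls are not independent")
      sum(((fr[j, ] - mu_j) / sd_j)^2)
    }, numeric(1))
    S_mean <- mean(S)
    S_sd <- sd(S)
  } else {
    S <- numeric(0); S_mean <- NA_real_; S_sd <- NA_real_
  }
  structure(list(arm_ids = arm_ids, mu = mu, sigma = sigma,
                 n_controls = n, control_S = S, control_S_mean = S_mean,
                 control_S_sd = S_sd),
            class = "mfastseq_ref")
}

#' @export
print.mfastseq_ref <- function(x, ...) {
  cat("<mfastseq_ref>", x$n_controls, "controls,", length(x$arm_ids),
      "arms; control S:", round(x$control_S_mean, 2), "+/-",
      round(x$control_S_sd, 2), "\n")
  invisible(x)
}

#' Serialize / restore a control reference
#'
#' @param ref an `mfastseq_ref`.
#' @param path JSON file path.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(unclass(ref), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mu <- setNames(as.numeric(x$mu), x$arm_ids)
  x$sigma <- setNames(as.numeric(x$sigma), x$arm_ids)
  structure(x, class = "mfastseq_ref")
}

#' Per-arm z-scores against a control reference
#'
#' `z_a = (fraction_a - mu_a) / sigma_a` over the reference's retained
#' arms.
#'
#' @param sample an `arm_counts` profile.
#' @param ref an `mfastseq_ref`.
#' @param min_reads QC threshold passed to [normalize_arm_counts()].
#' @return Object of class `arm_zscores`: list with `sample_id` and the
#'   named vector `z`.
#' @export
arm_zscores <- function(sample, ref, min_reads = 1e5) {
  fr <- normalize_arm_counts(sample, arm_ids = ref$arm_ids,
                             min_reads = min_reads)
  structure(list(sample_id = sample$sample_id,
                 z = (fr - ref$mu) / ref$sigma),
            class = "arm_zscores")
}

#' Genome-wide aneuploidy z-score
#'
#' The arm z-scores are squared and summed into the statistic
#' `S = sum(z_a^2)`. Because S has expectation close to the number of
#' retained arms even for a perfectly normal sample, S is standardized a
#' second time against the leave-one-out control distribution:
#' `gw_z = (S - control_S_mean) / control_S_sd`. This two-stage score is
#' centered near 0 for healthy samples and reproduces the single-digit
#' dynamic range used with the conventional > 3 aneuploidy threshold;
#' set `standardized = FALSE` to obtain the raw S instead.
#'
#' @param z an `arm_zscores` object.
#' @param ref the `mfastseq_ref` the z-scores were computed against.
#' @param standardized return the control-standardized score (default)
#'   or raw S.
#' @return List with `sample_id`, `S`, and `gw_z` (`NA` in raw mode).
#' @export
genome_wide_zscore <- function(z, ref, standardized = TRUE) {
  stopifnot(inherits(z, "arm_zscores"))
  S <- sum(z$z^2)
  gw <- NA_real_
  if (standardized) {
    if (!is.finite(ref$control_S_sd) || ref$control_S_sd == 0)
      stop("control S SD is zero or unavailable; ",
           "need >= 3 independent controls")
    gw <- (S - ref$control_S_mean) / ref$control_S_sd
  }
  list(sample_id = z$sample_id, S = S, gw_z = gw)
}

#' Score a set of samples against a reference
#'
#' Convenience wrapper: per-sample S, genome-wide z-score and a low-depth
#' QC flag.
#'
#' @param samples list of `arm_counts` profiles.
#' @param ref an `mfastseq_ref`.
#' @param min_reads QC depth threshold.
#' @param standardized see [genome_wide_zscore()].
#' @return data.frame with `sample_id`, `S`, `gw_z`, `qc_low_reads`.
#' @export
mfastseq_scores <- function(samples, ref, min_reads = 1e5,
                            standardized = TRUE) {
  if (inherits(samples, "arm_counts")) samples <- list(samples)
  rows <- lapply(samples, function(s) {
    z <- suppressWarnings(arm_zscores(s, ref, min_reads = min_reads))
    g <- genome_wide_zscore(z, ref, standardized = standardized)
    data.frame(sample_id = g$sample_id, S = g$S, gw_z = g$gw_z,
               qc_low_reads = s$total_reads < min_reads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
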