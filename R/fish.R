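#' Classify a FISH measurement for gene amplification
#'
#' Two-tier scoring of interphase FISH counts (Schildhaus-style rules,
#' FGFR1/CEN8 by default). Main criteria — **amplified** if the
#' gene/centromere ratio is >= 2.0 OR the average number of gene signals
#' per tumor-cell nucleus is >= 6.0. Additional criteria —
#' **low_amplified** if the main criteria fail but at least 50% of tumor
#' cells carry >= 5 gene signals OR at least 10% carry >= 15 signals or
#' signal clusters. Otherwise **balanced**. Main criteria take
#' precedence, so a case meeting both tiers is `amplified`.
#'
#' @param m list or one-row data.frame with fields `ratio`,
#'   `avg_gene_signals`, `q5`, `q15` (cell quotients in `[0, 1]`) and
#'   optionally `avg_cen_signals`; when the centromere count is present,
#'   a ratio inconsistent with `avg_gene_signals / avg_cen_signals` by
#'   more than 10% triggers a warning (the centromere count is otherwise
#'   informational only).
#' @param ratio_cutoff,signals_cutoff main-criteria thresholds
#'   (defaults 2.0 and 6.0).
#' @param q5_cutoff,q15_cutoff additional-criteria thresholds
#'   (defaults 0.50 and 0.10).
#' @return List with `status` (one of `"amplified"`, `"low_amplified"`,
#'   `"balanced"`) and `criterion` (which rule fired).
#' @export
classify_fish <- function(m, ratio_cutoff = 2.0, signals_cutoff = 6.0,
                          q5_cutoff = 0.50, q15_cutoff = 0.10) {
  req <- c("ratio", "avg_gene_signals", "q5", "q15")
  vals <- lapply(req, function(f) m[[f]])
  if (any(vapply(vals, function(v)
    is.null(v) || length(v) != 1 || is.na(v), TRUE)))
    stop("measurement must provide non-missing fields: ",
         paste(req, collapse = ", "))
  names(vals) <- req
  if (any(vapply(vals, function(v) !is.finite(v) || v < 0, TRUE)))
    stop("FISH measurements must be finite and nonnegative")
  if (vals$q5 > 1 || vals$q15 > 1)
    stop("q5 and q15 are cell quotients and must lie in [0, 1]")
  cen <- m[["avg_cen_signals"]]
  if (!is.null(cen) && !is.na(cen) && cen > 0) {
    implied <- vals$avg_gene_signals / cen
    if (abs(implied - vals$ratio) / vals$ratio > 0.10)
      warning("ratio (", vals$ratio, ") inconsistent with ",
              "avg_gene_signals/avg_cen_signals (",
              round(implied, 2), ")")
  }
  if (vals$ratio >= ratio_cutoff)
    return(list(status = "amplified", criterion = "ratio"))
  if (vals$avg_gene_signals >= signals_cutoff)
    return(list(status = "amplified", criterion = "signals_per_nucleus"))
  if (vals$q5 >= q5_cutoff)
    return(list(status = "low_amplified", criterion = "q5"))
  if (vals$q15 >= q15_cutoff)
    return(list(status = "low_amplified", criterion = "q15"))
  list(status = "balanced", criterion = "none")
}

#' Classify a cohort of FISH measurements
#'
#' @param measurements data.frame with one row per case: `case_id` plus
#'   the fields of [classify_fish()].
#' @param ... threshold overrides passed to [classify_fish()].
#' @return List with `calls` (per-case data.frame ordered by `case_id`,
#'   with `status` and `criterion`) and `counts` (named vector over
#'   `amplified` / `low_amplified` / `balanced`).
#' @export
classify_cohort <- function(measurements, ...) {
  if (!is.data.frame(measurements) || !nrow(measurements))
    stop("need at least one measurement")
  if (!"case_id" %in% names(measurements))
    stop("measurements must have a case_id column")
  if (anyDuplicated(measurements$case_id))
    stop("duplicate case_id: ",
         paste(unique(measurements$case_id[
           duplicated(measurements$case_id)]), collapse = ", "))
  measurements <- measurements[order(measurements$case_id), ]
  res <- lapply(seq_len(nrow(measurements)), function(i)
    classify_fish(measurements[i, ], ...))
  calls <- data.frame(
    case_id = measurements$case_id,
    status = vapply(res, `[[`, "", "status"),
    criterion = vapply(res, `[[`, "", "criterion"),
    stringsAsFactors = FALSE)
  lev <- c("amplified", "low_amplified", "balanced")
  counts <- setNames(as.integer(table(factor(calls$status, levels = lev))),
                     lev)
  list(calls = calls, counts = counts)
}

#' FISH vs array concordance
#'
#' Joins FISH statuses and array copy-number records on `case_id` and
#' counts agreements, treating FISH `amplified` / `low_amplified` as
#' positive and array `gain` as positive.
#'
#' @param fish data.frame with `case_id` and `status` (e.g. the `calls`
#'   of [classify_cohort()]).
#' @param array data.frame with `case_id` and `status`
#'   (`"gain"` / `"no_gain"`), e.g. [read_oncoscan_table()].
#' @return List with `n` (joined cases), `concordant`, `fraction`,
#'   `percent` (rounded to nearest integer), `discordant` (case ids).
#' @export
concordance <- function(fish, array) {
  joined <- merge(fish[, c("case_id", "status")],
                  array[, c("case_id", "status")],
                  by = "case_id", suffixes = c("_fish", "_array"))
  if (!nrow(joined)) stop("no cases shared between FISH and array tables")
  fish_pos <- joined$status_fish %in% c("amplified", "low_amplified")
  array_pos <- joined$status_array == "gain"
  agree <- fish_pos == array_pos
  list(n = nrow(joined), concordant = sum(agree),
       fraction = mean(agree), percent = round(100 * mean(agree)),
       discordant = joined$case_id[!agree])
}

#' Summary statistics of FISH measurements
#'
#' @param measurements data.frame with `ratio` and `avg_gene_signals`.
#' @return data.frame of min / median / max for each quantity.
#' @export
summarize_fish <- function(measurements) {
  if (!nrow(measurements)) stop("need at least one measurement")
  stat <- function(v) c(min = min(v), median = median(v), max = max(v))
  out <- rbind(ratio = stat(measurements$ratio),
               avg_gene_signals = stat(measurements$avg_gene_signals))
  as.data.frame(out)
}

#' Read a FISH measurement table
#'
#' CSV schema: `case_id`, `ratio`, `avg_gene_signals`,
#' `avg_cen_signals`, `q5`, `q15` (additional columns are kept).
#'
#' @param path CSV path.
#' @export
read_fish_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(case_id = "character"))
  req <- c("case_id", "ratio", "avg_gene_signals", "q5", "q15")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("FISH table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' Read an array (Oncoscan-style) copy-number table
#'
#' CSV schema: `case_id`, `oncoscan_status` (`gain` / `no_gain`),
#' `copy_number`. The status is checked for consistency with the
#' copy-number gain threshold (warning only).
#'
#' @param path CSV path.
#' @param gain_cutoff copy number at or above which the array status is
#'   expected to read `gain` (default 3).
#' @return data.frame with a normalized `status` column.
#' @export
read_oncoscan_table <- function(path, gain_cutoff = 3) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(case_id = "character"))
  req <- c("case_id", "oncoscan_status", "copy_number")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("array table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$status <- tab$oncoscan_status
  implied <- ifelse(tab$copy_number >= gain_cutoff, "gain", "no_gain")
  if (any(implied != tab$status))
    warning("array status inconsistent with copy_number >= ",
            gain_cutoff, " for: ",
            paste(tab$case_id[implied != tab$status], collapse = ", "))
  tab
}

#' Bundled FGFR1 breast-cancer cohort tables
#'
#' Printed per-case measurements from a published metastatic breast
#' cancer cohort screened for FGFR1 amplification: tissue FISH scoring
#' of the 20 FISH-positive cases, array confirmation for the 11 cases
#' with sufficient DNA, and the plasma stage (genome-wide z-score,
#' tumor-fraction percentage, plasma amplification call) for the 20
#' plasma-profiled cases.
#'
#' @return data.frame (see [read_fish_table()], [read_oncoscan_table()],
#'   [read_sample_sheet()] for schemas).
#' @export
fgfr1_fish_cohort <- function() {
  read_fish_table(system.file("extdata", "fgfr1_fish_cohort.csv",
                              package = "plasmaCNV"))
}

#' @rdname fgfr1_fish_cohort
#' @export
fgfr1_oncoscan_cohort <- function() {
  read_oncoscan_table(system.file("extdata", "fgfr1_oncoscan_cohort.csv",
                                  package = "plasmaCNV"))
}

#' @rdname fgfr1_fish_cohort
#' @export
fgfr1_plasma_cohort <- function() {
  read_sample_sheet(system.file("extdata", "fgfr1_plasma_cohort.csv",
                                package = "plasmaCNV"))
}
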