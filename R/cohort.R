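#' Read a joined per-patient sample sheet
#'
#' CSV with one row per case. Required: `case_id`. Recognised optional
#' columns: `fish_status`, `oncoscan_status`, `gw_z`, `itf_percent`
#' (tumor fraction in percent, `[0, 100]`), `plasma_call` (`+` / `-`),
#' `cfdna_ng_per_ml`, `os_months` (>= 0), `event` (0/1 or logical).
#'
#' @param path CSV path.
#' @return data.frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                  colClasses = c(case_id = "character"))
  if (!"case_id" %in% names(tab))
    stop("sample sheet must have a case_id column")
  if (anyDuplicated(tab$case_id)) stop("duplicate case_id in sample sheet")
  if ("itf_percent" %in% names(tab)) {
    bad <- !is.na(tab$itf_percent) &
      (tab$itf_percent < 0 | tab$itf_percent > 100)
    if (any(bad)) stop("itf_percent outside [0, 100] for: ",
                       paste(tab$case_id[bad], collapse = ", "))
  }
  if ("os_months" %in% names(tab) &&
      any(!is.na(tab$os_months) & tab$os_months < 0))
    stop("os_months must be nonnegative")
  if ("event" %in% names(tab)) tab$event <- as.logical(tab$event)
  tab
}

#' Count values strictly above a cutoff
#'
#' Strict inequality: a value equal to the cutoff is not counted.
#'
#' @param values numeric vector (finite).
#' @param cutoff threshold.
#' @return Integer count.
#' @export
threshold_count <- function(values, cutoff) {
  if (any(!is.finite(values))) stop("values must be finite")
  sum(values > cutoff)
}

#' Median of a vector
#'
#' Standard sample median (mean of the central pair for even n).
#'
#' @param values numeric vector with at least one element.
#' @export
median_value <- function(values) {
  if (!length(values)) stop("median of an empty vector is undefined")
  if (any(!is.finite(values))) stop("values must be finite")
  median(values)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return R-squared on the raw values.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate (zero-variance) input")
  cor(x, y)^2
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood standard errors and log-log
#' transformed 95% confidence bounds; the median is the smallest time at
#' which the survival estimate drops to 0.5 or below (undefined, `NA`,
#' if never reached).
#'
#' @param times survival/censoring times (>= 0).
#' @param events event indicators (TRUE/1 = death observed).
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `km_curve`: data.frame `curve` (`time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`) plus `median` and `n`.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  if (!length(times)) stop("empty survival input")
  if (any(times < 0)) stop("times must be nonnegative")
  fit <- survfit(Surv(times, as.integer(events)) ~ 1,
                 conf.type = "log-log", conf.int = conf_level)
  med <- unname(summary(fit)$table["median"])
  structure(list(curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                                    n_event = fit$n.event, surv = fit$surv,
                                    lower = fit$lower, upper = fit$upper),
                 median = med, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>", x$n, "subjects,", sum(x$curve$n_event), "events;",
      "median", if (is.na(x$median)) "not reached" else
        paste(round(x$median, 1), "months"), "\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param times1,events1 survival data of group 1.
#' @param times2,events2 survival data of group 2.
#' @return List with `chi_square`, `p_value` (chi-squared, df = 1),
#'   `n1`, `n2`.
#' @export
logrank_test <- function(times1, events1, times2, events2) {
  if (!length(times1) || !length(times2))
    stop("both groups must be non-empty")
  if (sum(events1) + sum(events2) == 0)
    stop("no events in either group; log-rank test undefined")
  grp <- c(rep(1L, length(times1)), rep(2L, length(times2)))
  sd <- survdiff(Surv(c(times1, times2),
                      as.integer(c(events1, events2))) ~ grp)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE),
       n1 = length(times1), n2 = length(times2))
}

#' Median-split survival stratification
#'
#' Splits the cohort at the median of `variable` (values equal to the
#' median go to the LOW group, a fixed convention so that repeated runs
#' produce identical groups even when several samples sit exactly at the
#' median), estimates a Kaplan-Meier curve per group, and compares them
#' with the log-rank test.
#'
#' @param records data.frame of sample records with `os_months`, `event`
#'   and the stratification variable.
#' @param variable column name to stratify on (e.g. `"gw_z"`,
#'   `"itf_percent"`, `"cfdna_ng_per_ml"`).
#' @return List with `variable`, `cutoff`, `n_low`, `n_high`,
#'   `km_low`, `km_high`, `median_os_low`, `median_os_high`, `logrank`.
#' @export
stratify_and_test <- function(records, variable) {
  if (!variable %in% names(records))
    stop("variable not found in records: ", variable)
  ok <- !is.na(records[[variable]]) & !is.na(records$os_months) &
    !is.na(records$event)
  rec <- records[ok, ]
  if (nrow(rec) < 4)
    stop("need at least 4 records with ", variable, " and survival data")
  v <- rec[[variable]]
  cutoff <- median(v)
  high <- v > cutoff
  if (!any(high))
    stop("all values of ", variable, " are identical; cannot split")
  km_low <- km_estimate(rec$os_months[!high], rec$event[!high])
  km_high <- km_estimate(rec$os_months[high], rec$event[high])
  lr <- logrank_test(rec$os_months[!high], rec$event[!high],
                     rec$os_months[high], rec$event[high])
  list(variable = variable, cutoff = cutoff,
       n_low = sum(!high), n_high = sum(high),
       km_low = km_low, km_high = km_high,
       median_os_low = km_low$median, median_os_high = km_high$median,
       logrank = lr)
}

#' Plot two Kaplan-Meier curves
#'
#' @param strat result of [stratify_and_test()].
#' @param main plot title.
#' @export
plot_km_strata <- function(strat, main = strat$variable) {
  step_xy <- function(km) {
    t <- c(0, km$curve$time)
    s <- c(1, km$curve$surv)
    list(x = rep(t, each = 2)[-1], y = rep(s, each = 2)[-2 * length(s)])
  }
  lo <- step_xy(strat$km_low)
  hi <- step_xy(strat$km_high)
  plot(lo$x, lo$y, type = "l", col = "blue", ylim = c(0, 1),
       xlab = "months", ylab = "overall survival", main = main)
  lines(hi$x, hi$y, col = "red")
  legend("topright", bty = "n", col = c("blue", "red"), lty = 1,
         legend = c(sprintf("<= median (n=%d)", strat$n_low),
                    sprintf("> median (n=%d)", strat$n_high)))
  invisible(NULL)
}

#' Cohort-level summary report
#'
#' Joins the tissue (FISH, array) and plasma stages into one structured,
#' deterministic report: FISH status counts, concordance, plasma
#' threshold counts and medians, z-score/tumor-fraction correlation, and
#' (when survival columns are present) median-split survival tests.
#'
#' @param fish FISH measurement table (see [read_fish_table()]), or
#'   `NULL` to skip.
#' @param array array copy-number table (see [read_oncoscan_table()]),
#'   or `NULL`.
#' @param samples per-patient sample sheet (see [read_sample_sheet()]),
#'   or `NULL`.
#' @param z_cutoff aneuploidy z-score threshold (default 3).
#' @param itf_cutoff tumor-fraction threshold in percent (default 3).
#' @param survival_variables columns of `samples` to stratify survival
#'   on, when `os_months`/`event` are available.
#' @return Object of class `cfdna_report` (a nested list); serialize
#'   with [report_json()].
#' @export
build_report <- function(fish = NULL, array = NULL, samples = NULL,
                         z_cutoff = 3, itf_cutoff = 3,
                         survival_variables = c("gw_z", "itf_percent")) {
  if (is.null(fish) && is.null(array) && is.null(samples))
    stop("empty cohort: provide at least one of fish, array, samples")
  rep <- list()
  cls <- NULL
  if (!is.null(fish)) {
    cls <- classify_cohort(fish)
    rep$fish <- list(n = nrow(fish), counts = as.list(cls$counts),
                     summary = summarize_fish(fish))
  }
  if (!is.null(array) && !is.null(cls)) {
    conc <- concordance(cls$calls, array)
    rep$concordance <- conc
  }
  if (!is.null(samples)) {
    pl <- list(n = nrow(samples))
    if ("gw_z" %in% names(samples)) {
      z <- samples$gw_z[!is.na(samples$gw_z)]
      pl$median_z <- median_value(z)
      pl$max_z <- max(z)
      pl$n_z_above_cutoff <- threshold_count(z, z_cutoff)
    }
    if ("itf_percent" %in% names(samples)) {
      tf <- samples$itf_percent[!is.na(samples$itf_percent)]
      pl$median_itf <- median_value(tf)
      pl$n_itf_above_cutoff <- threshold_count(tf, itf_cutoff)
      if ("fish_status" %in% names(samples)) {
        sel <- !is.na(samples$itf_percent) &
          samples$itf_percent > itf_cutoff
        pl$n_fish_positive_above_cutoff <- sum(
          samples$fish_status[sel] %in% c("amplified", "low_amplified"))
      }
    }
    if (all(c("gw_z", "itf_percent") %in% names(samples))) {
      cc <- complete.cases(samples[, c("gw_z", "itf_percent")])
      pl$r_squared_z_itf <- r_squared(samples$gw_z[cc],
                                      samples$itf_percent[cc])
    }
    rep$plasma <- pl
    if (all(c("os_months", "event") %in% names(samples))) {
      rep$survival <- lapply(
        intersect(survival_variables, names(samples)),
        function(v) {
          s <- stratify_and_test(samples, v)
          list(variable = v, cutoff = s$cutoff, n_low = s$n_low,
               n_high = s$n_high, median_os_low = s$median_os_low,
               median_os_high = s$median_os_high,
               chi_square = s$logrank$chi_square,
               p_value = s$logrank$p_value)
        })
    }
  }
  structure(rep, class = "cfdna_report")
}

#' @export
print.cfdna_report <- function(x, ...) {
  cat("== cfDNA cohort report ==\n")
  if (!is.null(x$fish))
    cat(sprintf("FISH (n=%d): %d amplified, %d low-amplified, %d balanced\n",
                x$fish$n, x$fish$counts$amplified,
                x$fish$counts$low_amplified, x$fish$counts$balanced))
  if (!is.null(x$concordance))
    cat(sprintf("FISH/array concordance: %d/%d = %d%%%s\n",
                x$concordance$concordant, x$concordance$n,
                x$concordance$percent,
                if (length(x$concordance$discordant))
                  paste0(" (discordant: ",
                         paste(x$concordance$discordant, collapse = ", "),
                         ")") else ""))
  if (!is.null(x$plasma)) {
    p <- x$plasma
    if (!is.null(p$median_z))
      cat(sprintf("Plasma z-score: median %.1f, max %.1f, %d above cutoff\n",
                  p$median_z, p$max_z, p$n_z_above_cutoff))
    if (!is.null(p$median_itf))
      cat(sprintf("Tumor fraction: median %.1f%%, %d above cutoff%s\n",
                  p$median_itf, p$n_itf_above_cutoff,
                  if (!is.null(p$n_fish_positive_above_cutoff))
                    sprintf(" (%d FISH-positive)",
                            p$n_fish_positive_above_cutoff) else ""))
    if (!is.null(p$r_squared_z_itf))
      cat(sprintf("R^2 (z-score vs tumor fraction): %.2f\n",
                  p$r_squared_z_itf))
  }
  if (!is.null(x$survival))
    for (s in x$survival)
      cat(sprintf("Survival by median %s: log-rank chi^2 %.2f, p %.4g\n",
                  s$variable, s$chi_square, s$p_value))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report a `cfdna_report`.
#' @param path output path, or `NULL` to return the JSON string.
#' @export
report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
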