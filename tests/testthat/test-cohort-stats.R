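test_that("threshold counts and medians match sort-based oracles", {
  expect_equal(threshold_count(numeric(0), 3), 0)
  expect_equal(median_value(c(1, 2, 3)), 2)
  expect_error(median_value(numeric(0)), "empty")
  expect_error(threshold_count(c(1, NA), 0), "finite")
  set.seed(77)
  for (i in 1:50) {
    v <- round(rnorm(sample(1:40, 1), sd = 5), 2)
    cut <- rnorm(1)
    expect_equal(threshold_count(v, cut), length(v[sort(v) > cut]))
    s <- sort(v)
    n <- length(s)
    manual <- if (n %% 2 == 1) s[(n + 1) / 2]
              else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(median_value(v), manual)
  }
})

test_that("R-squared matches a sum-based computation and validates input", {
  x <- c(1, 2, 4); y <- c(2, 1, 5)
  n <- 3
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  expect_equal(r_squared(x, y), num / den)
  expect_equal(r_squared(1:10, 2 * (1:10) + 1), 1)
  expect_error(r_squared(1:3, rep(2, 3)), "degenerate")
  expect_error(r_squared(1:3, 1:4), "equal length")
  expect_error(r_squared(1:2, 1:2), "at least 3")
})

test_that("Kaplan-Meier estimates match hand-computed product-limit values", {
  # all censored: flat at 1, median undefined
  km <- km_estimate(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(km$curve$surv == 1))
  expect_true(is.na(km$median))
  # three events, no censoring: 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  ev <- km$curve[km$curve$n_event > 0, ]
  expect_equal(ev$surv, c(2/3, 1/3, 0))
  # interleaved events and censorings, hand-computed before implementation:
  # t=2 (6 at risk): 5/6; t=6 (4 at risk): 5/6*3/4 = 0.625;
  # t=10 (2 at risk): 0.625*1/2 = 0.3125; median = 10
  km <- km_estimate(c(2, 4, 6, 8, 10, 12), c(1, 0, 1, 0, 1, 0))
  ev <- km$curve[km$curve$n_event > 0, ]
  expect_equal(ev$time, c(2, 6, 10))
  expect_equal(ev$surv, c(5/6, 0.625, 0.3125))
  expect_equal(km$median, 10)
  expect_true(all(ev$lower <= ev$surv & ev$surv <= ev$upper, na.rm = TRUE))
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(11)
  for (i in 1:20) {
    t <- round(rexp(sample(5:30, 1), 0.1), 3)
    km <- km_estimate(t, rep(1, length(t)))
    ev <- km$curve[km$curve$n_event > 0, ]
    emp <- vapply(ev$time, function(u) mean(t > u), numeric(1))
    expect_equal(ev$surv, emp)
  }
})

test_that("log-rank matches a hand-computed example and its invariances", {
  # identical groups: chi-square 0, p = 1
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  # hand-computed: g1 = (1, 3) both events, g2 = (2, 4) both events;
  # O1 = 2, E1 = 4/3, V = 13/18 -> chi = (2/3)^2 / (13/18) = 8/13
  lr <- logrank_test(c(1, 3), c(1, 1), c(2, 4), c(1, 1))
  expect_equal(lr$chi_square, 8 / 13, tolerance = 1e-9)
  # symmetric in group order
  lr2 <- logrank_test(c(2, 4), c(1, 1), c(1, 3), c(1, 1))
  expect_equal(lr2$chi_square, lr$chi_square)
  # invariant to positive time rescaling
  lr3 <- logrank_test(c(1, 3) * 7.3, c(1, 1), c(2, 4) * 7.3, c(1, 1))
  expect_equal(lr3$chi_square, lr$chi_square)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "no events")
  expect_error(logrank_test(numeric(0), logical(0), 1, 1), "non-empty")
})

test_that("median-split stratification: ties to low group, errors on degenerate input", {
  rec <- data.frame(case_id = as.character(1:6),
                    itf_percent = c(1, 2, 3, 3, 5, 8),
                    os_months = c(30, 25, 20, 18, 10, 5),
                    event = c(1, 1, 1, 1, 1, 1))
  st <- stratify_and_test(rec, "itf_percent")
  expect_equal(st$cutoff, 3)
  expect_equal(st$n_low, 4)  # both values at the median go low
  expect_equal(st$n_high, 2)
  expect_error(stratify_and_test(rec[1:3, ], "itf_percent"), "at least 4")
  same <- rec; same$itf_percent <- 2
  expect_error(stratify_and_test(same, "itf_percent"), "identical")
  expect_error(stratify_and_test(rec, "nope"), "not found")
})

test_that("high tumor fraction stratum has worse survival in linked cohorts", {
  coh <- simulate_patient_cohort(150, seed = 9)$samples
  st <- stratify_and_test(coh, "true_tf")
  expect_lt(st$logrank$p_value, 0.05)
  # the high-tf stratum reaches its survival median; the low stratum
  # either never drops to 0.5 (median NA) or does so later
  surv_at <- function(km, t) {
    idx <- findInterval(t, km$curve$time)
    if (idx == 0) 1 else km$curve$surv[idx]
  }
  expect_lt(surv_at(st$km_high, 40), surv_at(st$km_low, 40))
  expect_true(is.na(st$median_os_low) ||
                st$median_os_high < st$median_os_low)
  # every KM curve is non-increasing from 1
  expect_true(all(diff(st$km_low$curve$surv) <= 0))
  expect_true(all(st$km_high$curve$surv <= 1))
})

test_that("the sample sheet reader parses the bundled plasma cohort", {
  tab <- fgfr1_plasma_cohort()
  expect_equal(nrow(tab), 20)
  expect_true(all(c("case_id", "fish_status", "gw_z", "itf_percent",
                    "plasma_call") %in% names(tab)))
  expect_true(all(tab$itf_percent >= 0 & tab$itf_percent <= 100))
  # invalid tumor fractions are rejected
  path <- tempfile(fileext = ".csv")
  bad <- tab; bad$itf_percent[1] <- 110
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_sample_sheet(path), "\\[0, 100\\]")
})

test_that("the cohort report is complete and byte-deterministic", {
  rep1 <- build_report(fish = fgfr1_fish_cohort(),
                       array = fgfr1_oncoscan_cohort(),
                       samples = fgfr1_plasma_cohort())
  expect_equal(rep1$fish$counts$amplified, 17)
  expect_equal(rep1$fish$counts$low_amplified, 3)
  expect_equal(rep1$concordance$percent, 91)
  expect_equal(rep1$plasma$median_z, 2.2)
  expect_equal(rep1$plasma$n_z_above_cutoff, 8)
  expect_equal(rep1$plasma$n_itf_above_cutoff, 12)
  expect_equal(rep1$plasma$median_itf, 4.6)
  rep2 <- build_report(fish = fgfr1_fish_cohort(),
                       array = fgfr1_oncoscan_cohort(),
                       samples = fgfr1_plasma_cohort())
  expect_identical(as.character(report_json(rep1)),
                   as.character(report_json(rep2)))
  expect_error(build_report(), "empty cohort")
})
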