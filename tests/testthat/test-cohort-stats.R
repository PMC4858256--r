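test_that("MOPP follows the perfusion-pressure formula", {
  expect_equal(compute_mopp(120, 80, 15), 2 / 3 * (80 + 40 / 3 - 15),
               tolerance = 1e-12)
  # SBP = DBP collapses MAP to that pressure
  expect_equal(compute_mopp(90, 90, 10), 2 / 3 * (90 - 10))
  # IOP equal to MAP leaves zero perfusion pressure
  expect_equal(compute_mopp(120, 80, 80 + 40 / 3), 0, tolerance = 1e-12)
  expect_error(compute_mopp(80, 120, 15), "systolic")
})

test_that("sample size reproduces the planning calculation and its behaviour", {
  expect_identical(sample_size_two_group(0.300, 0.06, 0.15), 28L)
  # doubling the detectable difference strictly reduces n
  expect_lt(sample_size_two_group(0.300, 0.06, 0.30),
            sample_size_two_group(0.300, 0.06, 0.15))
  expect_error(sample_size_two_group(0.3, 0.06, 0), "zero")
  # exact noncentral-t method agrees with the independent power oracle
  n_exact <- sample_size_two_group(0.300, 0.06, 0.15, method = "exact")
  n_oracle <- ceiling(stats::power.t.test(delta = 0.045, sd = 0.06,
                                          power = 0.8)$n)
  expect_equal(n_exact, n_oracle)
})

test_that("Monte-Carlo power at the planned n matches the analytic power", {
  mc <- power_montecarlo(28, 0.045, 0.06, n_rep = 4000, seed = 2)
  analytic <- onhperf:::power_t_two_sample(28, 0.045, 0.06, 0.05)
  expect_lt(abs(mc - analytic), 0.025)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  df <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 3),
    y = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
  res <- anova_oneway(df, "y")
  # independent sums-of-squares arithmetic
  gm <- mean(df$y)
  ssb <- 3 * sum((c(2, 3, 4) - gm)^2)
  ssw <- sum((df$y - rep(c(2, 3, 4), each = 3))^2)
  Fo <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic, Fo, tolerance = 1e-12)
  expect_equal(res$p_value, pf(Fo, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # same values in every group: F = 0, p = 1
  null_df <- tibble::tibble(group = rep(c("a", "b", "c"), each = 3),
                            y = rep(c(1, 2, 3), 3))
  res0 <- anova_oneway(null_df, "y")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(anova_oneway(df[1:4, ], "y"), "at least 2")
})

test_that("two-group t-tests match the closed-form pooled oracle", {
  df <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                       y = c(1, 2, 3, 2, 3, 4))
  tt <- ttest_two_group(df, "y")
  # closed form: pooled sd = 1, se = sqrt(2/3)
  expect_equal(tt$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(tt$p_value, 2 * pt(-abs(tt$statistic), 4), tolerance = 1e-12)
  expect_equal(round(tt$p_value, 3), 0.288)
  # pooled and welch coincide for equal n and equal variances
  tw <- ttest_two_group(df, "y", mode = "welch")
  expect_equal(tw$statistic, tt$statistic, tolerance = 1e-12)
  # identical groups: t = 0, p = 1 (constant case warns)
  same <- tibble::tibble(group = rep(c("a", "b"), each = 3), y = rep(2, 6))
  expect_warning(t0 <- ttest_two_group(same, "y"), "constant")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
})

test_that("two-group ANOVA equals the squared pooled t", {
  set.seed(81)
  df <- tibble::tibble(group = rep(c("a", "b"), c(9, 12)),
                       y = rnorm(21, rep(c(0, 0.8), c(9, 12))))
  Fv <- anova_oneway(df, "y")$statistic
  tv <- ttest_two_group(df, "y")$statistic
  expect_equal(Fv, tv^2, tolerance = 1e-10)
})

test_that("univariate regression matches its algebraic identities", {
  df <- tibble::tibble(x = 1:5, y = 2 * (1:5))
  # base R warns about the exact fit; the R^2 = 1 value is the point here
  fit_perfect <- suppressWarnings(univariate_regression(df, "x", "y"))
  expect_equal(fit_perfect$r_squared, 1)
  # centred orthogonal variables: R^2 = 0
  dfo <- tibble::tibble(x = c(-1, 0, 1, 0), y = c(0, 1, 0, -1))
  expect_equal(univariate_regression(dfo, "x", "y")$r_squared, 0,
               tolerance = 1e-14)
  # R^2 equals the squared Pearson correlation on random data
  set.seed(82)
  dfr <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  fit <- univariate_regression(dfr, "x", "y")
  expect_equal(fit$r_squared, cor(dfr$x, dfr$y)^2, tolerance = 1e-12)
  expect_error(univariate_regression(tibble::tibble(x = rep(1, 5), y = 1:5),
                                     "x", "y"), "constant")
})

test_that("population R-squared is recovered from a seeded bivariate Gaussian", {
  set.seed(83)
  n <- 10000
  x <- rnorm(n)
  y <- 0.4 * x + sqrt(1 - 0.16) * rnorm(n)
  fit <- univariate_regression(tibble::tibble(x = x, y = y), "x", "y")
  expect_lt(abs(fit$r_squared - 0.16), 0.02)
})

test_that("tidy and glance return the documented tibble shapes", {
  coh <- generate_cohort(cohort_spec(n = c(normal = 8, POAG = 8, NTG = 8),
                                     seed = 3))
  a <- anova_oneway(coh, "flux")
  expect_s3_class(tidy(a), "tbl_df")
  expect_equal(nrow(tidy(a)), 3)
  expect_named(glance(a), c("variable", "statistic", "df_between",
                            "df_within", "p_value"))
  r <- univariate_regression(coh, "rnfl", "flux")
  expect_equal(nrow(tidy(r)), 2)
  expect_equal(glance(r)$r_squared, summary(r$fit)$r.squared)
})

test_that("summary tables have the study's shape and serialize deterministically", {
  coh <- generate_cohort(cohort_spec(seed = 5))
  tabs <- build_tables(coh)
  expect_named(tabs, c("table1", "table2", "table4", "table5"))
  # 3 metrics x 3 groups, with ANOVA p attached
  expect_equal(nrow(tabs$table2), 9)
  expect_true("anova_p" %in% names(tabs$table2))
  # regression grid: 7 predictors x 3 metrics per group
  expect_equal(nrow(tabs$table5), 3 * 7 * 3)
  expect_equal(nrow(tabs$table4), 6)  # two group rows per metric
  # byte-identical CSVs for the same cohort
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tables(tabs, d1)
  write_tables(build_tables(generate_cohort(cohort_spec(seed = 5))), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # single group: ANOVA omitted with a warning
  expect_warning(one <- build_tables(dplyr::filter(coh, group == "POAG")),
                 "single group")
  expect_false("anova_p" %in% names(one$table2))
  w <- testthat::capture_warnings(
    build_tables(dplyr::select(coh, -dplyr::all_of("rim_area"))))
  expect_true(any(grepl("rim_area", w)))
})
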