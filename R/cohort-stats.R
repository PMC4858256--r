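#' Mean ocular perfusion pressure
#'
#' `MOPP = 2/3 * (MAP - IOP)` with mean arterial pressure
#' `MAP = DBP + (SBP - DBP) / 3`. Vectorized; all pressures in mmHg.
#'
#' @param sbp,dbp Systolic and diastolic blood pressure (mmHg);
#'   `sbp >= dbp` is required.
#' @param iop Intraocular pressure (mmHg).
#' @return MOPP in mmHg.
#' @export
#' @examples
#' compute_mopp(120, 80, 15)  # 2/3 * (93.33 - 15) = 52.22
compute_mopp <- function(sbp, dbp, iop) {
  if (any(!is.finite(sbp) | !is.finite(dbp) | !is.finite(iop))) {
    abort("pressures must be finite")
  }
  if (any(sbp < dbp)) abort("systolic pressure must be >= diastolic pressure")
  map <- dbp + (sbp - dbp) / 3
  2 / 3 * (map - iop)
}

#' Two-group sample size for a relative difference in means
#'
#' Per-group sample size for a two-sided, two-sample comparison of means
#' detecting a difference of `relative_difference * mean` at the given
#' power and significance level, assuming common SD `sd`. The default
#' `"normal"` method uses the classic normal-quantile formula
#' `n = 2 ((z_{1-a/2} + z_{power}) * sd / delta)^2`, rounded up — the
#' convention of common clinical sample-size calculators (for a POAG
#' normalized-flux mean of 0.300, SD 0.06, 15% difference, 80% power and
#' alpha 0.05 it yields 28 per group). Method `"exact"` instead finds the
#' smallest n whose exact noncentral-t power reaches the target, which
#' for the same inputs gives 29; the realized power at n = 28 is about
#' 0.787.
#'
#' @param mean Reference group mean.
#' @param sd Common standard deviation (> 0).
#' @param relative_difference Relative difference to detect (e.g. 0.15).
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param method `"normal"` or `"exact"`.
#' @return Integer sample size per group.
#' @export
#' @examples
#' sample_size_two_group(0.300, 0.06, 0.15)
sample_size_two_group <- function(mean, sd, relative_difference,
                                  power = 0.80, alpha = 0.05,
                                  method = c("normal", "exact")) {
  method <- match.arg(method)
  if (sd <= 0) abort("sd must be positive")
  if (power <= 0 || power >= 1) abort("power must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  delta <- mean * relative_difference
  if (delta == 0) abort("the targeted difference is zero; sample size is infinite")
  n_normal <- 2 * ((qnorm(1 - alpha / 2) + qnorm(power)) * sd / delta)^2
  if (method == "normal") return(as.integer(ceiling(n_normal)))
  n <- max(2L, as.integer(floor(n_normal)) - 2L)
  while (power_t_two_sample(n, delta, sd, alpha) < power) n <- n + 1L
  n
}

# Exact power of the two-sided pooled two-sample t-test (noncentral t).
power_t_two_sample <- function(n, delta, sd, alpha) {
  df <- 2 * n - 2
  ncp <- abs(delta) / (sd * sqrt(2 / n))
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

#' Monte-Carlo power of the two-sample t-test
#'
#' Simulated rejection rate of the two-sided pooled-variance t-test for a
#' true mean difference `delta` with common SD `sd` and `n` per group.
#'
#' @param n Per-group sample size.
#' @param delta True difference in means.
#' @param sd Common standard deviation.
#' @param alpha Two-sided significance level.
#' @param n_rep Number of simulated experiments.
#' @param seed Random seed.
#' @return Estimated power (rejection proportion).
#' @export
power_montecarlo <- function(n, delta, sd, alpha = 0.05,
                             n_rep = 10000L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * n_rep, 0, sd), n, n_rep)
  y <- matrix(rnorm(n * n_rep, delta, sd), n, n_rep)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = n))^2) / (n - 1)
  vy <- colSums((y - rep(my, each = n))^2) / (n - 1)
  sp2 <- (vx + vy) / 2
  tstat <- (my - mx) / sqrt(2 * sp2 / n)
  p <- 2 * pt(-abs(tstat), 2 * n - 2)
  mean(p < alpha)
}

group_summary <- function(data, variable, group, conf = 0.95) {
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = base::mean(.data[[variable]]),
      sd = stats::sd(.data[[variable]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_lo = .data$mean - qt(1 - (1 - conf) / 2, .data$n - 1) *
        .data$sd / sqrt(.data$n),
      ci_hi = .data$mean + qt(1 - (1 - conf) / 2, .data$n - 1) *
        .data$sd / sqrt(.data$n)
    )
}

#' One-way fixed-effects ANOVA across groups
#'
#' Compares a variable across the cohort groups with a one-way ANOVA and
#' summarises each group as mean, SD and a t-based 95% confidence
#' interval, the presentation used for the study's baseline tables.
#'
#' @param data Cohort data frame.
#' @param variable Name of the numeric column to compare.
#' @param group Name of the grouping column.
#' @return An object of class `onh_anova`; see [tidy()] and [glance()].
#' @export
anova_oneway <- function(data, variable, group = "group") {
  data <- dplyr::filter(as_tibble(data),
                        !is.na(.data[[variable]]), !is.na(.data[[group]]))
  counts <- table(data[[group]])
  if (length(counts) < 2L) abort("at least two groups are required")
  if (any(counts < 2L)) abort("every group needs at least 2 records")
  fit <- aov(stats::reformulate(group, variable), data = data)
  tab <- anova(fit)
  res <- structure(list(
    variable = variable,
    groups = group_summary(data, variable, group),
    statistic = tab$`F value`[1],
    df = c(between = tab$Df[1], within = tab$Df[2]),
    p_value = tab$`Pr(>F)`[1]
  ), class = "onh_anova")
  res
}

#' Two-group independent-samples t-test
#'
#' Two-sided comparison of a variable between exactly two groups. Mode
#' `"pooled"` (default) assumes equal variances; `"welch"` does not. When
#' both groups are constant with equal means the statistic is reported as
#' 0 with p = 1 (with a warning) instead of failing.
#'
#' @param data Cohort data frame restricted to two groups.
#' @param variable Numeric column to compare.
#' @param group Grouping column (must take exactly two values).
#' @param mode `"pooled"` or `"welch"`.
#' @return An object of class `onh_ttest`; see [tidy()] and [glance()].
#' @export
ttest_two_group <- function(data, variable, group = "group",
                            mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  data <- dplyr::filter(as_tibble(data),
                        !is.na(.data[[variable]]), !is.na(.data[[group]]))
  levs <- unique(data[[group]])
  if (length(levs) != 2L) abort("exactly two groups are required")
  x <- data[[variable]][data[[group]] == levs[1]]
  y <- data[[variable]][data[[group]] == levs[2]]
  if (length(x) < 2L || length(y) < 2L) abort("each group needs >= 2 records")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      warn("both groups constant with equal means; reporting t = 0, p = 1")
      tt <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
                 p.value = 1)
    } else {
      abort("both groups are constant with different means; t is undefined")
    }
  } else {
    tt <- t.test(x, y, var.equal = (mode == "pooled"))
  }
  structure(list(
    variable = variable,
    levels = as.character(levs),
    mode = mode,
    groups = group_summary(data, variable, group),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  ), class = "onh_ttest")
}

#' Univariate linear regression
#'
#' Ordinary least-squares fit of `y ~ x` reporting slope, intercept,
#' R^2 and the two-sided p-value for the slope — the study's univariate
#' correlation analysis between perfusion metrics and clinical measures.
#'
#' @param data Data frame.
#' @param x,y Names of predictor and response columns.
#' @return An object of class `onh_regression` wrapping the `lm` fit;
#'   see [tidy()] and [glance()].
#' @export
univariate_regression <- function(data, x, y) {
  data <- dplyr::filter(as_tibble(data),
                        !is.na(.data[[x]]), !is.na(.data[[y]]))
  if (nrow(data) < 3L) abort("at least 3 paired records are required")
  if (var(data[[x]]) == 0) abort("predictor is constant; slope is undefined")
  fit <- lm(stats::reformulate(x, y), data = data)
  sm <- summary(fit)
  structure(list(
    x = x, y = y, fit = fit, n = nrow(data),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4]
  ), class = "onh_regression")
}

#' @export
tidy.onh_anova <- function(x, ...) x$groups

#' @export
glance.onh_anova <- function(x, ...) {
  tibble(variable = x$variable, statistic = x$statistic,
         df_between = x$df[["between"]], df_within = x$df[["within"]],
         p_value = x$p_value)
}

#' @export
tidy.onh_ttest <- function(x, ...) x$groups

#' @export
glance.onh_ttest <- function(x, ...) {
  tibble(variable = x$variable, mode = x$mode, statistic = x$statistic,
         df = x$df, p_value = x$p_value)
}

#' @export
tidy.onh_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
         statistic = sm[, 3], p_value = sm[, 4])
}

#' @export
glance.onh_regression <- function(x, ...) {
  obj <- x
  tibble(x = obj$x, y = obj$y, n = obj$n, slope = obj$slope,
         intercept = obj$intercept, r_squared = obj$r_squared,
         p_value = obj$p_value)
}

#' @export
print.onh_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s: F(%d, %d) = %.4g, p = %.4g\n",
              x$variable, x$df[["between"]], x$df[["within"]],
              x$statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @export
print.onh_ttest <- function(x, ...) {
  cat(sprintf("%s t-test of %s (%s vs %s): t = %.4g, df = %.4g, p = %.4g\n",
              x$mode, x$variable, x$levels[1], x$levels[2],
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
print.onh_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s (n = %d): slope = %.4g, R^2 = %.4g, p = %.4g\n",
              x$y, x$x, x$n, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Build the study-shaped summary tables
#'
#' Produces tidy twins of the study's result tables from a QC-filtered
#' cohort:
#' * `table1` — demographics and structural biometrics by group with
#'   one-way ANOVA p-values;
#' * `table2` — the three perfusion metrics by group with ANOVA
#'   p-values;
#' * `table4` — POAG vs NTG comparison of the metrics by two-sided
#'   t-test;
#' * `table5` — univariate regression grid (R^2 and p) of each metric on
#'   each clinical variable, per group.
#'
#' Variables absent from the data are skipped with a warning; with a
#' single group the ANOVA columns are omitted (with a warning). No
#' multiple-testing correction is applied anywhere, matching the study's
#' analysis.
#'
#' @param cohort Cohort tibble (see [generate_cohort()]); rows failing
#'   QC should already be removed.
#' @param demographics Variables summarised in `table1`.
#' @param metrics The three perfusion metric columns.
#' @param regressors Predictors for the regression grid.
#' @param ttest_mode Passed to [ttest_two_group()].
#' @return Named list of tibbles: `table1`, `table2`, `table4`,
#'   `table5`.
#' @seealso [write_tables()]
#' @export
build_tables <- function(cohort,
                         demographics = c("age", "iop", "sbp", "dbp", "mopp",
                                          "rnfl", "cdr", "rim_area"),
                         metrics = c("flux", "vessel_area_density",
                                     "normalized_flux"),
                         regressors = c("vf_md", "vf_psd", "iop", "mopp",
                                        "rnfl", "cdr", "rim_area"),
                         ttest_mode = "pooled") {
  cohort <- as_tibble(cohort)
  keep <- function(vars, where) {
    miss <- setdiff(vars, names(cohort))
    if (length(miss)) {
      warn(paste0("skipping variables missing from the cohort (", where, "): ",
                  paste(miss, collapse = ", ")))
    }
    intersect(vars, names(cohort))
  }
  demographics <- keep(demographics, "table1")
  metrics <- keep(metrics, "table2/4/5")
  regressors <- keep(regressors, "table5")
  groups <- unique(cohort$group)
  multi <- length(groups) >= 2L
  if (!multi) warn("single group: ANOVA columns omitted")

  summarise_block <- function(vars) {
    purrr::map_dfr(vars, function(v) {
      gs <- group_summary(cohort, v, "group")
      gs$variable <- v
      if (multi) {
        gs$anova_p <- glance(anova_oneway(cohort, v))$p_value
      }
      dplyr::relocate(gs, "variable")
    })
  }
  table1 <- summarise_block(demographics)
  table2 <- summarise_block(metrics)

  table4 <- NULL
  if (all(c("POAG", "NTG") %in% groups)) {
    two <- dplyr::filter(cohort, .data$group %in% c("POAG", "NTG"))
    table4 <- purrr::map_dfr(metrics, function(v) {
      tt <- ttest_two_group(two, v, mode = ttest_mode)
      g <- glance(tt)
      dplyr::mutate(tidy(tt), variable = v,
                    t_statistic = g$statistic, t_p = g$p_value) |>
        dplyr::relocate("variable")
    })
  }

  table5 <- purrr::map_dfr(groups, function(g) {
    sub <- dplyr::filter(cohort, .data$group == g)
    purrr::map_dfr(regressors, function(xv) {
      purrr::map_dfr(metrics, function(mv) {
        gl <- glance(univariate_regression(sub, xv, mv))
        tibble(group = g, variable = xv, metric = mv,
               r_squared = gl$r_squared, p_value = gl$p_value, n = gl$n)
      })
    })
  })

  out <- list(table1 = table1, table2 = table2, table4 = table4,
              table5 = table5)
  out[!vapply(out, is.null, logical(1))]
}

#' Write summary tables as CSV files
#'
#' Deterministic CSV serialization of [build_tables()] output: the same
#' cohort yields byte-identical files.
#'
#' @param tables Named list of tibbles.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
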