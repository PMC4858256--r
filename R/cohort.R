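# Per-eye cohort simulation. Group means/SDs default to the published
# summary statistics of the three study groups (normal / POAG / NTG);
# metric-covariate correlations default to signed square roots of the
# reported univariate R^2 values, with signs following the clinically
# reported directions (perfusion decreases with worse mean deviation,
# higher PSD, thinner RNFL, larger cup/disc ratio, smaller rim area).

cohort_variables <- c("flux", "vessel_area_density", "normalized_flux",
                      "age", "iop", "sbp", "dbp", "rnfl", "cdr", "rim_area",
                      "vf_md", "vf_psd")

cohort_default_moments <- function() {
  list(
    normal = list(
      mean = c(flux = 0.33, vessel_area_density = 0.77, normalized_flux = 0.37,
               age = 68.6, iop = 13.5, sbp = 134.7, dbp = 80.4,
               rnfl = 90.0, cdr = 0.44, rim_area = 1.28,
               vf_md = 0.0, vf_psd = 1.8),
      sd = c(flux = 0.04, vessel_area_density = 0.02, normalized_flux = 0.04,
             age = 10.4, iop = 3.4, sbp = 20.5, dbp = 12.5,
             rnfl = 11.5, cdr = 0.17, rim_area = 0.20,
             vf_md = 1.0, vf_psd = 0.5)
    ),
    POAG = list(
      mean = c(flux = 0.24, vessel_area_density = 0.68, normalized_flux = 0.29,
               age = 64.6, iop = 14.8, sbp = 125.8, dbp = 78.2,
               rnfl = 64.9, cdr = 0.74, rim_area = 0.76,
               vf_md = -5.49, vf_psd = 5.82),
      sd = c(flux = 0.07, vessel_area_density = 0.08, normalized_flux = 0.05,
             age = 10.9, iop = 4.0, sbp = 19.0, dbp = 12.2,
             rnfl = 9.3, cdr = 0.10, rim_area = 0.19,
             vf_md = 6.79, vf_psd = 4.05)
    ),
    NTG = list(
      mean = c(flux = 0.25, vessel_area_density = 0.70, normalized_flux = 0.30,
               age = 66.2, iop = 12.0, sbp = 132.8, dbp = 74.7,
               rnfl = 71.6, cdr = 0.73, rim_area = 0.80,
               vf_md = -4.79, vf_psd = 6.93),
      sd = c(flux = 0.06, vessel_area_density = 0.07, normalized_flux = 0.05,
             age = 12.2, iop = 3.3, sbp = 15.6, dbp = 9.6,
             rnfl = 12.2, cdr = 0.09, rim_area = 0.18,
             vf_md = 5.04, vf_psd = 4.30)
    )
  )
}

# Assemble one group's correlation matrix from the metric-covariate block
# (signed sqrt of univariate R^2) plus fixed metric-metric and
# covariate-covariate structure. All three defaults are positive definite.
build_correlation <- function(metric_cov) {
  v <- cohort_variables
  R <- diag(length(v)); dimnames(R) <- list(v, v)
  set2 <- function(a, b, val) {
    R[a, b] <<- val; R[b, a] <<- val
  }
  set2("flux", "vessel_area_density", 0.75)
  set2("flux", "normalized_flux", 0.90)
  set2("vessel_area_density", "normalized_flux", 0.60)
  set2("sbp", "dbp", 0.60)
  set2("rnfl", "cdr", -0.50)
  set2("rnfl", "rim_area", 0.50)
  set2("cdr", "rim_area", -0.60)
  set2("vf_md", "vf_psd", -0.70)
  set2("vf_md", "rnfl", 0.50)
  set2("vf_psd", "rnfl", -0.40)
  for (m in names(metric_cov)) {
    for (cv in names(metric_cov[[m]])) set2(m, cv, metric_cov[[m]][[cv]])
  }
  R
}

cohort_default_correlations <- function() {
  r <- function(R2, sign = 1) sign * sqrt(R2)
  list(
    normal = build_correlation(list(
      flux = c(iop = r(0.02, -1), rnfl = r(0.10), cdr = r(0.10, -1),
               rim_area = r(0.08)),
      vessel_area_density = c(iop = r(0.03, -1), rnfl = r(0.26),
                              cdr = r(0.03, -1), rim_area = r(0.28)),
      normalized_flux = c(iop = r(0.02, -1), rnfl = r(0.08),
                          cdr = r(0.10, -1), rim_area = r(0.05))
    )),
    POAG = build_correlation(list(
      flux = c(vf_md = r(0.16), vf_psd = r(0.26, -1), iop = r(0.003, -1),
               rnfl = r(0.42), cdr = r(0.57, -1), rim_area = r(0.34)),
      vessel_area_density = c(vf_md = r(0.09), vf_psd = r(0.17, -1),
                              iop = r(0.03, -1), rnfl = r(0.20),
                              cdr = r(0.33, -1), rim_area = r(0.19)),
      normalized_flux = c(vf_md = r(0.16), vf_psd = r(0.23, -1),
                          iop = r(2e-4, -1), rnfl = r(0.46),
                          cdr = r(0.58, -1), rim_area = r(0.35))
    )),
    NTG = build_correlation(list(
      flux = c(vf_md = r(0.22), vf_psd = r(0.19, -1), iop = r(0.13, -1),
               rnfl = r(0.03), cdr = r(0.15, -1), rim_area = r(0.21)),
      vessel_area_density = c(vf_md = r(0.15), vf_psd = r(0.13, -1),
                              iop = r(0.13, -1), rnfl = r(0.07),
                              cdr = r(0.22, -1), rim_area = r(0.28)),
      normalized_flux = c(vf_md = r(0.20), vf_psd = r(0.18, -1),
                          iop = r(0.11, -1), rnfl = r(0.01),
                          cdr = r(0.09, -1), rim_area = r(0.16))
    ))
  )
}

#' Specify a simulated clinical cohort
#'
#' Describes per-group multivariate-Gaussian distributions of the three
#' perfusion metrics and the clinical covariates (age, IOP, blood
#' pressures, RNFL thickness, cup/disc ratio, rim area, visual-field MD
#' and PSD) for the three study groups. Defaults reproduce the published
#' group means and SDs; metric-covariate correlations default to signed
#' square roots of the published univariate R^2 values. Normal-group
#' visual-field indices (not measured in the study) default to healthy
#' values (MD 0 +/- 1 dB, PSD 1.8 +/- 0.5 dB).
#'
#' @param n Named integer vector of per-group sample sizes (each >= 2).
#' @param moments Per-group list with named `mean` and `sd` vectors over
#'   the cohort variables.
#' @param correlations Per-group correlation matrices (must be positive
#'   semi-definite).
#' @param p_male Per-group probability of male sex.
#' @param seed Random seed for [generate_cohort()].
#' @return An object of class `onh_cohort_spec`.
#' @export
cohort_spec <- function(n = c(normal = 28L, POAG = 30L, NTG = 31L),
                        moments = cohort_default_moments(),
                        correlations = cohort_default_correlations(),
                        p_male = c(normal = 16 / 28, POAG = 16 / 30,
                                   NTG = 12 / 31),
                        seed = 1L) {
  groups <- names(n)
  if (is.null(groups) || any(!nzchar(groups))) abort("n must be named by group")
  if (any(n < 2)) abort("each group needs at least 2 eyes")
  for (g in groups) {
    m <- moments[[g]]
    if (is.null(m)) abort(paste0("moments missing for group ", g))
    if (any(m$sd <= 0)) abort("all SDs must be strictly positive")
    if (!setequal(names(m$mean), cohort_variables) ||
        !setequal(names(m$sd), cohort_variables)) {
      abort("moments must cover exactly the cohort variables")
    }
    R <- correlations[[g]]
    if (is.null(R) || !isTRUE(all.equal(R, t(R))) ||
        min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort(paste0("correlation matrix for group ", g,
                   " is missing or not positive semi-definite"))
    }
  }
  structure(list(n = n, moments = moments, correlations = correlations,
                 p_male = p_male, seed = as.integer(seed)),
            class = "onh_cohort_spec")
}

#' Simulate a per-eye cohort table
#'
#' Draws one record per eye from the group-specific multivariate
#' Gaussians in the spec. Mean ocular perfusion pressure is derived from
#' the drawn pressures via [compute_mopp()] rather than sampled; the
#' perfusion metrics are clipped to `[0, 1]` and diastolic pressure to at
#' most the systolic value (both events are rare at the default
#' moments). Scan QC fields are filled with clean values.
#'
#' @param spec An `onh_cohort_spec`.
#' @return Tibble with one row per eye: `eye_id`, `group`, `sex`, the
#'   cohort variables, `mopp`, `signal_strength`, `motion`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 42))
#' dplyr::count(cohort, group)
generate_cohort <- function(spec) {
  if (!inherits(spec, "onh_cohort_spec")) {
    abort("spec must be created with cohort_spec()")
  }
  set.seed(spec$seed)
  out <- purrr::map(names(spec$n), function(g) {
    n <- spec$n[[g]]
    mu <- spec$moments[[g]]$mean[cohort_variables]
    sdv <- spec$moments[[g]]$sd[cohort_variables]
    R <- spec$correlations[[g]][cohort_variables, cohort_variables]
    Sigma <- diag(sdv) %*% R %*% diag(sdv)
    X <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
    df <- as_tibble(as.data.frame(X))
    names(df) <- cohort_variables
    for (m in c("flux", "vessel_area_density", "normalized_flux")) {
      df[[m]] <- pmin(pmax(df[[m]], 0), 1)
    }
    df$dbp <- pmin(df$dbp, df$sbp)
    df$group <- g
    df$sex <- ifelse(runif(n) < spec$p_male[[g]], "M", "F")
    df$signal_strength <- sample(6:10, n, replace = TRUE)
    df$motion <- FALSE
    df
  })
  out <- dplyr::bind_rows(out)
  out$mopp <- compute_mopp(out$sbp, out$dbp, out$iop)
  out$eye_id <- sprintf("eye%03d", seq_len(nrow(out)))
  dplyr::select(out, "eye_id", "group", "sex", dplyr::all_of(cohort_variables),
                "mopp", "signal_strength", "motion")
}

#' @export
print.onh_cohort_spec <- function(x, ...) {
  cat("<onh_cohort_spec> groups:",
      paste(sprintf("%s (n=%d)", names(x$n), x$n), collapse = ", "), "\n")
  invisible(x)
}
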