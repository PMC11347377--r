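default_covariate_table <- function() {
  # baseline distributions of a weight-loss cohort with obesity:
  # mean, SD and physical range (truncation bounds) per variable
  utils::read.csv(text = "name,mean,sd,lower,upper
age,46.30,10.97,21,65
weight_kg,101.56,15.17,71.3,149.8
bmi,34.08,2.75,30.2,39.7
waist_cm,105.75,11.54,76,135.2
hip_cm,118.00,8.07,101,136
whr,0.90,0.09,0.72,1.12
bodyfat_pct,38.61,7.05,22.8,52.3
sat_tv,15.55,3.96,7.47,24.93
sat_lv,14.09,3.69,6.44,22.77
vat_tv,5.70,2.32,1.91,12.93
vat_lv,4.57,2.04,1.29,11.08
sat_pdff_pct,90.39,1.33,86.18,92.61
vat_pdff_pct,78.85,4.10,67.43,85.66
norm_sat,0.35,0.09,0.18,0.60
norm_sat_upper,0.27,0.08,0.11,0.53
norm_sat_middle,0.35,0.10,0.18,0.58
norm_sat_lower,0.42,0.10,0.20,0.68
norm_sat_lv,0.32,0.08,0.15,0.55
norm_vat,0.13,0.05,0.04,0.28
norm_vat_upper,0.07,0.04,0.02,0.20
norm_vat_middle,0.20,0.08,0.05,0.44
norm_vat_lower,0.11,0.04,0.05,0.26
norm_vat_lv,0.10,0.04,0.03,0.24
vat_sat_ratio,0.39,0.21,0.12,1.15",
           stringsAsFactors = FALSE)
}

default_planted_models <- function() {
  # relative-loss responses on the fractional scale, with the lower-third
  # SAT burden and body fat driving SAT/VAT loss
  list(
    d_sat_tv = list(intercept = -0.42,
                    coef = c(norm_sat_lower = 0.24, bodyfat_pct = 0.003),
                    r2 = 0.32),
    d_sat_lv = list(intercept = -0.47,
                    coef = c(norm_sat_lower = 0.28, bodyfat_pct = 0.003),
                    r2 = 0.38),
    d_vat_tv = list(intercept = -0.35,
                    coef = c(norm_sat_lower = 0.32),
                    r2 = 0.23),
    d_vat_lv = list(intercept = -0.44,
                    coef = c(norm_sat = 1.03, norm_sat_middle = -0.49),
                    r2 = 0.32))
}

#' Specification of a synthetic tabular cohort
#'
#' Defines the sampling scheme for a cross-sectional cohort table: sample
#' size and sex split, truncated-normal baseline distributions per covariate
#' (physical ranges as truncation bounds), and planted linear models that
#' generate the relative-loss responses from baseline covariates plus
#' Gaussian noise whose SD is calibrated so the model explains the target
#' R^2 of the realized signal variance.
#'
#' Defaults emulate an 81-subject (49 female) low-calorie-diet cohort in
#' which smaller normalized lower-third SAT volume and lower body fat favor
#' greater relative adipose tissue loss. Covariates not involved in a
#' planted model are drawn independently; the generator plants the reported
#' predictive structure, not the full joint distribution.
#'
#' @param n cohort size (default 81).
#' @param n_female number of females (default 49); sex is coded 1 = female,
#'   0 = male.
#' @param covariates data frame with columns name, mean, sd, lower, upper.
#' @param models named list of planted models; each has \code{intercept},
#'   named \code{coef}, and either \code{r2} (target, in (0,1)) or
#'   \code{sigma}.
#' @param seed RNG seed (mandatory).
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n = 81L, n_female = 49L,
                        covariates = default_covariate_table(),
                        models = default_planted_models(),
                        seed = 1L) {
  stopifnot(n >= 2L, n_female >= 0L, n_female <= n)
  stopifnot(is.data.frame(covariates),
            all(c("name", "mean", "sd", "lower", "upper") %in%
                  names(covariates)))
  for (m in models) {
    stopifnot(is.numeric(m$intercept), is.numeric(m$coef),
              !is.null(names(m$coef)))
    bad <- setdiff(names(m$coef), covariates$name)
    if (length(bad))
      stop_arg("planted model uses unknown covariates: ",
               paste(bad, collapse = ", "))
    if (!is.null(m$r2) && (m$r2 <= 0 || m$r2 >= 1))
      stop_arg("planted R^2 must lie in (0, 1)")
    if (is.null(m$r2) && is.null(m$sigma))
      stop_arg("planted model needs r2 or sigma")
  }
  structure(list(n = as.integer(n), n_female = as.integer(n_female),
                 covariates = covariates, models = models,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a synthetic cohort table with planted regression structure
#'
#' Draws baseline covariates from truncated normal distributions, then
#' generates each response as \code{intercept + X b + noise} on the
#' fractional relative-change scale; percent-scale companions
#' (\code{<response>_pct}) are added. Noise SD is derived from the realized
#' signal variance and the target R^2 (\code{sigma^2 =
#' var(signal) (1 - R^2) / R^2}), so the sample R^2 fluctuates around the
#' target across seeds. Deterministic per seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return List with \code{table} (data frame: subject_id, sex, covariates,
#'   responses) and \code{truth} (per response: intercept, coefficients,
#'   noise SD, target and realized R^2).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  cov <- spec$covariates
  with_seed(spec$seed, {
    tab <- data.frame(subject_id = sprintf("S%03d", seq_len(spec$n)),
                      sex = rep(c(1, 0),
                                c(spec$n_female, spec$n - spec$n_female)))
    for (i in seq_len(nrow(cov)))
      tab[[cov$name[i]]] <- rtruncnorm(spec$n, cov$mean[i], cov$sd[i],
                                       cov$lower[i], cov$upper[i])
    truth <- list()
    for (resp in names(spec$models)) {
      m <- spec$models[[resp]]
      X <- as.matrix(tab[, names(m$coef), drop = FALSE])
      signal <- m$intercept + drop(X %*% m$coef)
      sigma <- if (!is.null(m$sigma)) m$sigma else {
        vs <- stats::var(signal)
        if (vs == 0) stop_arg("planted signal for '", resp,
                              "' has zero variance; R^2 target infeasible")
        sqrt(vs * (1 - m$r2) / m$r2)
      }
      y <- signal + stats::rnorm(spec$n, 0, sigma)
      tab[[resp]] <- y
      tab[[paste0(resp, "_pct")]] <- 100 * y
      realized_r2 <- if (stats::var(y) > 0)
        1 - stats::var(y - signal) / stats::var(y) else NA_real_
      truth[[resp]] <- list(intercept = m$intercept, coef = m$coef,
                            sigma = sigma, target_r2 = m$r2 %||% NA_real_,
                            realized_r2 = realized_r2)
    }
    list(table = tab, truth = truth)
  })
}
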