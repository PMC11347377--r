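#' Cohort analysis report
#'
#' Runs the full statistics layer on a two-timepoint cohort table and returns
#' the four standard report tables: a baseline/follow-up summary with paired
#' tests, standardized mean differences for the normalized third subvolumes
#' (overall and, when a \code{sex} column is present, per sex), a correlation
#' screen of baseline parameters against the relative-loss responses, and
#' stepwise regression models (top-k correlates plus age and sex as
#' mandatory covariates) for each response. p-values are reported raw, with
#' no multiplicity correction, reflecting an explorative design.
#'
#' Regressions are fitted on the fractional relative changes
#' (\code{d_*_pct / 100}), so coefficients are on the scale of a fraction of
#' baseline per unit of predictor. Stepwise models for a stratum are refused
#' (with a warning, returning \code{NULL}) when the stratum has fewer than
#' \code{candidates + 3} subjects.
#'
#' @param cohort long data frame: \code{subject_id}, \code{timepoint}
#'   (\code{"baseline"}/\code{"follow_up"}) plus metric columns following the
#'   package column dictionary.
#' @param responses names of change columns (percent scale, computed
#'   internally) to model; defaults to the four relative AT losses.
#' @param candidates baseline predictor columns for the correlation screen;
#'   default: the anthropometric and normalized imaging parameters present.
#' @param k number of top correlates entering each regression (default 5).
#' @param smd_columns columns receiving SMD analysis; default the six
#'   normalized third subvolumes.
#' @param by_sex also compute SMDs per sex stratum (default \code{TRUE} when
#'   a \code{sex} column exists).
#' @return List of data frames / model lists: \code{summary}, \code{smd},
#'   \code{correlations}, \code{models}, plus the derived \code{changes}
#'   table.
#' @export
analysis_report <- function(cohort,
                            responses = c("d_sat_tv_pct", "d_sat_lv_pct",
                                          "d_vat_tv_pct", "d_vat_lv_pct"),
                            candidates = NULL, k = 5,
                            smd_columns = c("norm_sat_upper",
                                            "norm_sat_middle",
                                            "norm_sat_lower",
                                            "norm_vat_upper",
                                            "norm_vat_middle",
                                            "norm_vat_lower"),
                            by_sex = "sex" %in% names(cohort)) {
  changes <- build_change_table(cohort)
  base <- cohort[cohort$timepoint == "baseline", , drop = FALSE]
  fu <- cohort[cohort$timepoint == "follow_up", , drop = FALSE]
  fu <- fu[match(base$subject_id, fu$subject_id), , drop = FALSE]
  num <- vapply(cohort, is.numeric, logical(1))
  metrics <- setdiff(names(cohort)[num], c("subject_id", "age", "sex"))

  summary_tab <- do.call(rbind, lapply(metrics, function(m) {
    b <- base[[m]]; f <- fu[[m]]
    pt <- tryCatch(paired_t(b, f), error = function(e) NULL)
    data.frame(parameter = m,
               baseline_mean = mean(b, na.rm = TRUE),
               baseline_sd = stats::sd(b, na.rm = TRUE),
               baseline_min = suppressWarnings(min(b, na.rm = TRUE)),
               baseline_max = suppressWarnings(max(b, na.rm = TRUE)),
               followup_mean = mean(f, na.rm = TRUE),
               followup_sd = stats::sd(f, na.rm = TRUE),
               followup_min = suppressWarnings(min(f, na.rm = TRUE)),
               followup_max = suppressWarnings(max(f, na.rm = TRUE)),
               p_paired = if (is.null(pt)) NA_real_ else pt$p)
  }))

  smd_columns <- intersect(smd_columns, metrics)
  strata <- list(all = rep(TRUE, nrow(base)))
  if (isTRUE(by_sex)) {
    strata$female <- base$sex == 1
    strata$male <- base$sex == 0
  }
  smd_tab <- do.call(rbind, unlist(lapply(names(strata), function(st) {
    sel <- strata[[st]]
    lapply(smd_columns, function(m) {
      s <- smd(base[[m]][sel], fu[[m]][sel])
      data.frame(stratum = st, parameter = m, n = s$n, smd = s$d,
                 ci_low = s$ci_low, ci_high = s$ci_high,
                 magnitude = s$magnitude)
    })
  }), recursive = FALSE))

  if (is.null(candidates)) {
    pool <- c("bmi", "bodyfat_pct", "waist_cm", "hip_cm", "whr",
              "sat_pdff_pct", "vat_pdff_pct", "norm_sat", "norm_sat_upper",
              "norm_sat_middle", "norm_sat_lower", "norm_sat_lv", "norm_vat",
              "norm_vat_upper", "norm_vat_middle", "norm_vat_lower",
              "norm_vat_lv", "vat_sat_ratio")
    candidates <- intersect(pool, names(changes))
  }
  responses <- intersect(responses, names(changes))

  cor_tab <- do.call(rbind, lapply(responses, function(resp) {
    sel <- screen_predictors(changes, resp, candidates, k = k)
    sc <- attr(sel, "correlations")
    cbind(response = resp, sc,
          top_k = sc$variable %in% utils::head(sel, k))
  }))

  fit_models <- function(tab, label = NULL) {
    out <- lapply(responses, function(resp) {
      sel <- screen_predictors(tab, resp, candidates, k = k)
      sel <- sel[vapply(sel, function(v)
        stats::sd(tab[[v]], na.rm = TRUE) > 0, logical(1))]
      frac <- tab
      yname <- paste0(".frac_", resp)
      frac[[yname]] <- tab[[resp]] / 100
      n_ok <- sum(stats::complete.cases(frac[, c(yname, sel), drop = FALSE]))
      if (n_ok <= length(sel) + 2L) {
        warning("stepwise model for '", resp, "'",
                if (!is.null(label)) paste0(" in stratum '", label, "'"),
                " not fitted: the number of independent variables (n = ",
                length(sel), ") is too large for the group size (n = ",
                n_ok, ")", call. = FALSE)
        return(NULL)
      }
      stepwise_ols(frac, yname, sel)
    })
    names(out) <- responses
    out
  }
  models <- fit_models(changes)

  list(summary = summary_tab, smd = smd_tab, correlations = cor_tab,
       models = models, changes = changes, fit_models = fit_models)
}

#' Stepwise models within strata
#'
#' Refits the report's stepwise regressions inside each level of a grouping
#' column (for example \code{sex}). Strata too small for the number of
#' candidate variables are refused with a warning and return \code{NULL},
#' matching the practice of not running a 7-variable stepwise model on a
#' subgroup of a few dozen subjects.
#'
#' @param report result of \code{\link{analysis_report}}.
#' @param by name of a grouping column in the report's change table.
#' @return Named list (one element per stratum) of model lists.
#' @export
stratified_models <- function(report, by = "sex") {
  changes <- report$changes
  if (!by %in% names(changes)) stop_arg("no column '", by, "' to stratify on")
  lapply(split(changes, changes[[by]]),
         function(sub) report$fit_models(sub, label = unique(sub[[by]])[1]))
}
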