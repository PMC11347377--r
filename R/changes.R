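#' Absolute change between timepoints
#'
#' Signed difference follow-up minus baseline, in the metric's own unit.
#' Losses therefore appear as negative numbers.
#'
#' @param base,follow finite numeric vectors (recycled pairwise).
#' @return \code{follow - base}.
#' @export
absolute_change <- function(base, follow) {
  if (any(!is.finite(base)) || any(!is.finite(follow)))
    stop_arg("absolute_change requires finite inputs")
  follow - base
}

#' Relative change between timepoints, in percent
#'
#' \code{100 * (follow - base) / base}; defined only for strictly positive
#' baselines. Losses appear as negative percentages.
#'
#' @inheritParams absolute_change
#' @return Relative change in percent of baseline.
#' @export
relative_change <- function(base, follow) {
  if (any(!is.finite(base)) || any(!is.finite(follow)))
    stop_arg("relative_change requires finite inputs")
  if (any(base <= 0))
    stop_arg("relative_change requires strictly positive baselines")
  100 * (follow - base) / base
}

#' Build a per-subject change table from two-timepoint records
#'
#' Takes a long table with one baseline and one follow-up row per subject and
#' returns one row per subject carrying the baseline values of every metric
#' plus, for each metric, the absolute change \code{d_<metric>} and the
#' relative change \code{d_<metric>_pct}. Relative changes are \code{NA}
#' where the baseline is not strictly positive; affected subjects are counted
#' in a message, never imputed.
#'
#' Cohort means of the per-subject absolute changes equal the difference of
#' the timepoint means (paired-mean identity). For relative changes the
#' cohort value is the mean of per-subject percentages, which differs from
#' the percentage change of the means on heterogeneous cohorts.
#'
#' @param cohort data frame with columns \code{subject_id},
#'   \code{timepoint} (\code{"baseline"} or \code{"follow_up"}) and numeric
#'   metric columns.
#' @param metrics which columns to difference; default all numeric columns
#'   except identifiers and the fixed covariates \code{age} and \code{sex}.
#' @return A data frame, one row per subject: \code{subject_id}, fixed
#'   covariates, baseline metrics (original names), then \code{d_*} and
#'   \code{d_*_pct} columns.
#' @export
build_change_table <- function(cohort, metrics = NULL) {
  stopifnot(is.data.frame(cohort))
  need <- c("subject_id", "timepoint")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop_arg("cohort table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(cohort$timepoint %in% c("baseline", "follow_up")))
    stop_arg("timepoint must be 'baseline' or 'follow_up'")
  tab <- table(cohort$subject_id, cohort$timepoint)
  bad <- rownames(tab)[tab[, "baseline"] != 1L | tab[, "follow_up"] != 1L]
  if (length(bad))
    stop_arg("subjects without exactly one baseline and one follow-up ",
             "record: ", paste(bad, collapse = ", "))
  fixed <- intersect(c("age", "sex"), names(cohort))
  if (is.null(metrics)) {
    num <- vapply(cohort, is.numeric, logical(1))
    metrics <- setdiff(names(cohort)[num], c("subject_id", fixed))
  }
  base <- cohort[cohort$timepoint == "baseline", , drop = FALSE]
  fu <- cohort[cohort$timepoint == "follow_up", , drop = FALSE]
  fu <- fu[match(base$subject_id, fu$subject_id), , drop = FALSE]
  out <- base[, c("subject_id", fixed, metrics), drop = FALSE]
  rownames(out) <- NULL
  for (m in metrics) {
    b <- base[[m]]; f <- fu[[m]]
    out[[paste0("d_", m)]] <- absolute_change(b, f)
    ok <- is.finite(b) & b > 0
    rel <- rep(NA_real_, length(b))
    rel[ok] <- relative_change(b[ok], f[ok])
    if (any(!ok))
      message(sum(!ok), " subject(s) excluded from d_", m,
              "_pct (nonpositive baseline)")
    out[[paste0("d_", m, "_pct")]] <- rel
  }
  out
}
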