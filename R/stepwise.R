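#' Rank candidate predictors by correlation with a response
#'
#' Computes the correlation of every candidate column with the response and
#' returns the k most strongly associated candidates (by |r|; ties broken by
#' input order), with the mandatory covariates appended (not counted in k,
#' not duplicated). Zero-variance candidates are dropped with a warning.
#'
#' @param table data frame.
#' @param response name of the response column.
#' @param candidates character vector of candidate column names.
#' @param k how many top candidates to keep (default 5).
#' @param mandatory covariates always appended (default \code{age} and
#'   \code{sex}, intersected with the table's columns).
#' @param method correlation method, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return Character vector of selected names, with attribute
#'   \code{correlations}: a data frame of variable, r, p, n for every
#'   screened candidate, ordered by |r|.
#' @export
screen_predictors <- function(table, response, candidates, k = 5,
                              mandatory = c("age", "sex"),
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table))
  miss <- setdiff(c(response, candidates), names(table))
  if (length(miss))
    stop_arg("columns not in table: ", paste(miss, collapse = ", "))
  if (k < 0) stop_arg("k must be non-negative")
  mandatory <- intersect(mandatory, names(table))
  y <- table[[response]]
  res <- lapply(candidates, function(v) {
    cr <- correlate(table[[v]], y, method = method)
    if (cr$degenerate)
      warning("candidate '", v, "' has zero variance; excluded from screen",
              call. = FALSE)
    data.frame(variable = v, r = cr$r, p = cr$p, n = cr$n)
  })
  res <- do.call(rbind, res)
  usable <- res[!is.na(res$r), , drop = FALSE]
  # order() is stable, so equal |r| keeps the candidates' input order
  usable <- usable[order(-abs(usable$r)), , drop = FALSE]
  if (k > nrow(usable)) {
    warning("k = ", k, " exceeds the ", nrow(usable),
            " usable candidates; returning all", call. = FALSE)
    k <- nrow(usable)
  }
  top <- utils::head(usable$variable, k)
  out <- c(top, setdiff(mandatory, top))
  attr(out, "correlations") <- usable
  out
}

#' Stepwise multiple linear regression with p-value entry/removal
#'
#' Forward-backward stepwise ordinary least squares starting from the
#' intercept-only model: at each iteration the excluded candidate with the
#' smallest partial t-test p-value enters if p < \code{p_enter}; then the
#' included term with the largest p-value leaves if p > \code{p_remove};
#' iteration stops when neither rule fires. Candidates that are perfectly
#' collinear with the current model are skipped with a warning. A repeated
#' model state (possible only with inconsistent thresholds) aborts with the
#' trace.
#'
#' @param table data frame holding response and candidate columns (numeric).
#' @param response name of the response column.
#' @param candidates character vector of candidate predictor names.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10); must be >=
#'   \code{p_enter}.
#' @param max_iter iteration cap (default 100).
#' @return A \code{stepwise_model}: \code{response}, \code{included} (in
#'   entry order), \code{coefficients} (data frame: term, b, se, t, p,
#'   including the intercept), \code{r_squared}, \code{n}, \code{trace}
#'   (data frame of enter/remove events), \code{excluded}, \code{fit}
#'   (the final \code{lm}).
#' @export
stepwise_ols <- function(table, response, candidates, p_enter = 0.05,
                         p_remove = 0.10, max_iter = 100L) {
  stopifnot(is.data.frame(table))
  miss <- setdiff(c(response, candidates), names(table))
  if (length(miss))
    stop_arg("columns not in table: ", paste(miss, collapse = ", "))
  if (p_enter > p_remove)
    stop_arg("p_enter must not exceed p_remove (cycling thresholds)")
  dat <- table[, c(response, candidates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(candidates) + 2L)
    stop_arg("need n > number of candidates + 2 (n = ", n, ", candidates = ",
             length(candidates), ")")
  const <- candidates[vapply(dat[candidates], function(x)
    stats::sd(x) == 0, logical(1))]
  if (length(const))
    stop_arg("constant candidate(s): ", paste(const, collapse = ", "))

  fit_with <- function(terms) {
    fml <- stats::reformulate(if (length(terms)) sprintf("`%s`", terms)
                              else "1", response = sprintf("`%s`", response))
    stats::lm(fml, data = dat)
  }
  term_p <- function(fit, term) {
    cf <- stats::coef(fit)
    names(cf) <- gsub("`", "", names(cf))
    if (is.na(cf[term])) return(NA_real_)  # aliased / collinear
    sm <- summary(fit)$coefficients
    rownames(sm) <- gsub("`", "", rownames(sm))
    sm[term, 4]
  }

  included <- character(0)
  trace <- list()
  states <- character(0)
  warned_collinear <- character(0)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      pvals <- vapply(pool, function(cand) {
        p <- term_p(fit_with(c(included, cand)), cand)
        if (is.na(p) && !cand %in% warned_collinear) {
          warning("candidate '", cand, "' is collinear with the current ",
                  "model; skipped", call. = FALSE)
          warned_collinear <<- c(warned_collinear, cand)
        }
        if (is.na(p)) Inf else p
      }, numeric(1))
      best <- which.min(pvals)  # ties: first in candidate order
      if (pvals[best] < p_enter) {
        included <- c(included, pool[best])
        trace[[length(trace) + 1L]] <-
          data.frame(step = length(trace) + 1L, action = "enter",
                     term = pool[best], p = pvals[best])
        changed <- TRUE
      }
    }
    # backward step
    if (length(included)) {
      fit <- fit_with(included)
      ps <- vapply(included, function(tm) term_p(fit, tm), numeric(1))
      worst <- which.max(ps)
      if (!is.na(ps[worst]) && ps[worst] > p_remove) {
        trace[[length(trace) + 1L]] <-
          data.frame(step = length(trace) + 1L, action = "remove",
                     term = included[worst], p = ps[worst])
        included <- included[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
    key <- paste(sort(included), collapse = "|")
    if (key %in% states)
      stop_arg("stepwise selection cycled; trace: ",
               paste(vapply(trace, function(e)
                 paste0(e$action, ":", e$term), character(1)),
                 collapse = " -> "))
    states <- c(states, key)
    if (iter == max_iter)
      stop_arg("stepwise selection did not converge in ", max_iter,
               " iterations")
  }

  fit <- fit_with(included)
  sm <- summary(fit)
  cf <- sm$coefficients
  terms_clean <- gsub("`", "", rownames(cf))
  coefs <- data.frame(term = terms_clean, b = cf[, 1], se = cf[, 2],
                      t = cf[, 3], p = cf[, 4], row.names = NULL)
  structure(list(
    response = response,
    included = included,
    coefficients = coefs,
    r_squared = sm$r.squared,
    n = n,
    p_enter = p_enter, p_remove = p_remove,
    trace = if (length(trace)) do.call(rbind, trace)
            else data.frame(step = integer(), action = character(),
                            term = character(), p = numeric()),
    excluded = setdiff(candidates, included),
    fit = fit), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, digits = 3, ...) {
  cat(sprintf("Stepwise OLS for '%s' (enter p < %.2g, remove p > %.2g)\n",
              x$response, x$p_enter, x$p_remove))
  cat(sprintf("  n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  if (length(x$included)) {
    print(format(x$coefficients, digits = digits), row.names = FALSE)
  } else cat("  intercept-only model (no candidate entered)\n")
  if (length(x$excluded))
    cat("  not included:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
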