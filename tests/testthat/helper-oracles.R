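# Independent oracles used across the test files. These deliberately avoid
# the package's code paths (and lm() for the stepwise oracle): plain matrix
# algebra and per-element loops.

# OLS coefficient p-values via normal equations (solve(), not lm's QR)
oracle_ols_p <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- as.vector(beta) / se
  2 * stats::pt(-abs(tval), df)
}

# Brute-force forward-backward stepwise with p-value entry/removal rules.
# Returns the included set (entry order) and the event trace.
oracle_stepwise <- function(table, response, candidates, p_enter = 0.05,
                            p_remove = 0.10) {
  y <- table[[response]]
  included <- character(0)
  trace <- character(0)
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      pvals <- vapply(pool, function(cand) {
        X <- cbind(1, as.matrix(table[, c(included, cand), drop = FALSE]))
        p <- tryCatch(oracle_ols_p(X, y), error = function(e) NULL)
        if (is.null(p)) Inf else p[length(p)]
      }, numeric(1))
      best <- which.min(pvals)
      if (pvals[best] < p_enter) {
        included <- c(included, pool[best])
        trace <- c(trace, paste0("enter:", pool[best]))
        changed <- TRUE
      }
    }
    if (length(included)) {
      X <- cbind(1, as.matrix(table[, included, drop = FALSE]))
      ps <- oracle_ols_p(X, y)[-1]
      worst <- which.max(ps)
      if (ps[worst] > p_remove) {
        trace <- c(trace, paste0("remove:", included[worst]))
        included <- included[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(included = included, trace = trace)
}

trace_of <- function(model) {
  if (nrow(model$trace) == 0) character(0)
  else paste0(model$trace$action, ":", model$trace$term)
}

# slice-center thirds rule evaluated one slice at a time
oracle_thirds <- function(n_slices) {
  vapply(seq_len(n_slices) - 1L, function(s) {
    center <- (s + 0.5)  # in units of slice thickness
    if (center < n_slices / 3) 1L
    else if (center < 2 * n_slices / 3) 2L
    else 3L
  }, integer(1))
}

# small random cohort for stepwise equivalence checks: some candidates carry
# signal, some are noise
random_stepwise_instance <- function(seed, n = 81L) {
  set.seed(seed)
  k <- sample(3:7, 1)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  n_sig <- sample(0:min(2, k), 1)
  beta <- numeric(k)
  if (n_sig > 0)
    beta[sample(k, n_sig)] <- runif(n_sig, 0.2, 0.8) * sample(c(-1, 1),
                                                              n_sig, TRUE)
  y <- drop(X %*% beta) + rnorm(n)
  cbind(data.frame(y = y), as.data.frame(X))
}

# a quick low-resolution phantom spec for unit tests
small_phantom_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(dim = c(64L, 48L, 27L), spacing = c(3, 3, 6),
         n_depot_slices = 24L, torso_semiaxes = c(80, 60),
         sat_thickness_mm = c(12, 16, 20),
         vat_fraction = c(0.2, 0.5, 0.35), seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# two-timepoint long table built from the cross-sectional generator: the
# follow-up row scales each metric by a drawn retention, giving known
# per-subject changes
simulate_longitudinal <- function(n = 40L, seed = 1L) {
  coh <- make_cohort(cohort_spec(n = n, n_female = round(n * 0.6),
                                 seed = seed))$table
  coh <- coh[, !grepl("^d_", names(coh))]
  set.seed(seed + 1L)
  metrics <- setdiff(names(coh)[vapply(coh, is.numeric, logical(1))],
                     c("sex", "age"))
  base <- coh
  base$timepoint <- "baseline"
  fu <- coh
  fu$timepoint <- "follow_up"
  for (m in metrics)
    fu[[m]] <- fu[[m]] * (1 + rnorm(n, -0.2, 0.05))
  rbind(base, fu)
}
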