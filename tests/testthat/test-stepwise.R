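test_that("predictor screen ranks by |r| and appends mandatory covariates", {
  set.seed(1)
  n <- 200
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    age = rnorm(n, 46, 11), sex = rbinom(n, 1, 0.6))
  tab$y <- tab$x2 + rnorm(n, 0, 1e-4)
  sel <- screen_predictors(tab, "y", c("x1", "x2", "x3"), k = 2)
  expect_equal(sel[1], "x2")
  expect_true(all(c("age", "sex") %in% sel))

  sel0 <- screen_predictors(tab, "y", c("x1", "x2", "x3"), k = 0)
  expect_equal(sort(unclass(sel0)), c("age", "sex"))

  expect_warning(sel_all <- screen_predictors(tab, "y", c("x1", "x2"),
                                              k = 5), "exceeds")
  expect_equal(sort(setdiff(sel_all, c("age", "sex"))), c("x1", "x2"))

  tab$flat <- 1
  expect_warning(screen_predictors(tab, "y", c("x1", "flat"), k = 1),
                 "zero variance")
})

test_that("screen recovers a planted correlation ordering", {
  planted <- c(a = 0.52, b = 0.49, c = 0.47, d = 0.47, e = 0.43,
               f = 0.30, g = 0.15)
  set.seed(9)
  n <- 2000
  y <- rnorm(n)
  tab <- data.frame(y = y)
  for (nm in names(planted))
    tab[[nm]] <- planted[nm] * y + sqrt(1 - planted[nm]^2) * rnorm(n)
  sel <- screen_predictors(tab, "y", names(planted), k = 5,
                           mandatory = character(0))
  expect_equal(sort(unclass(sel)), sort(names(planted)[1:5]))
})

test_that("a single strongly predictive candidate is entered", {
  set.seed(2)
  tab <- data.frame(x = rnorm(81))
  tab$y <- 2 * tab$x + rnorm(81, 0, 0.5)
  m <- stepwise_ols(tab, "y", "x")
  expect_equal(m$included, "x")
  expect_equal(trace_of(m), "enter:x")
  expect_equal(m$coefficients$b[m$coefficients$term == "x"], 2,
               tolerance = 0.1)
})

test_that("pure-noise candidates mostly yield the intercept-only model", {
  n_seeds <- 400
  empty <- 0L
  for (seed in 1:n_seeds) {
    set.seed(seed)
    tab <- as.data.frame(matrix(rnorm(81 * 8), 81,
                                dimnames = list(NULL, c("y", paste0("x", 1:7)))))
    m <- stepwise_ols(tab, "y", paste0("x", 1:7))
    if (length(m$included) == 0) empty <- empty + 1L
  }
  # theoretical no-entry rate for 7 independent null candidates: 0.95^7
  expect_equal(empty / n_seeds, 0.95^7, tolerance = 0.06)
})

test_that("a planted two-term model dominates selection in the strong regime", {
  n <- 81
  selections <- character(20)
  for (seed in 1:20) {
    set.seed(seed)
    tab <- data.frame(x1 = rnorm(n, 0.42, 0.10), x2 = rnorm(n, 38, 7))
    for (j in 3:7) tab[[paste0("x", j)]] <- rnorm(n)
    tab$y <- -0.42 + 0.24 * tab$x1 + 0.003 * tab$x2 + rnorm(n, 0, 0.02)
    m <- stepwise_ols(tab, "y", paste0("x", 1:7))
    # the true predictors always enter in this high-power regime
    expect_true(all(c("x1", "x2") %in% m$included))
    oracle <- oracle_stepwise(tab, "y", paste0("x", 1:7))
    expect_equal(m$included, oracle$included)
    expect_equal(trace_of(m), oracle$trace)
    selections[seed] <- paste(sort(m$included), collapse = "+")
  }
  # the exact planted set is the modal selection
  expect_equal(names(which.max(table(selections))), "x1+x2")
})

test_that("stepwise selection matches the matrix-algebra oracle", {
  for (seed in 1:100) {
    tab <- random_stepwise_instance(seed)
    cands <- setdiff(names(tab), "y")
    m <- stepwise_ols(tab, "y", cands)
    oracle <- oracle_stepwise(tab, "y", cands)
    expect_equal(m$included, oracle$included, info = paste("seed", seed))
    expect_equal(trace_of(m), oracle$trace, info = paste("seed", seed))
    # convergence guarantees
    if (length(m$included)) {
      ps <- m$coefficients$p[m$coefficients$term != "(Intercept)"]
      expect_true(all(ps <= 0.10))
    }
  }
})

test_that("no excluded candidate would enter the converged model", {
  for (seed in c(4, 17, 33)) {
    tab <- random_stepwise_instance(seed)
    cands <- setdiff(names(tab), "y")
    m <- stepwise_ols(tab, "y", cands)
    for (cand in m$excluded) {
      refit <- stats::lm(stats::reformulate(c(m$included, cand), "y"),
                         data = tab)
      p <- summary(refit)$coefficients[cand, 4]
      expect_gte(p, 0.05)
    }
  }
})

test_that("collinear candidates are skipped with a warning", {
  set.seed(5)
  tab <- data.frame(x1 = rnorm(81))
  tab$x2 <- 2 * tab$x1                # perfectly collinear
  tab$y <- tab$x1 + rnorm(81, 0, 0.1)
  expect_warning(m <- stepwise_ols(tab, "y", c("x1", "x2")), "collinear")
  expect_equal(m$included, "x1")
})

test_that("invalid stepwise configurations are rejected", {
  tab <- data.frame(y = rnorm(20), x = rnorm(20), flat = 1)
  expect_error(stepwise_ols(tab, "y", "x", p_enter = 0.2, p_remove = 0.1),
               "p_enter")
  expect_error(stepwise_ols(tab, "y", "flat"), "constant")
  small <- data.frame(y = rnorm(5), x1 = rnorm(5), x2 = rnorm(5),
                      x3 = rnorm(5))
  expect_error(stepwise_ols(small, "y", paste0("x", 1:3)), "n >")
})
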