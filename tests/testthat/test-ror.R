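# Disproportionality statistics: tabulation, crude r-OR, logistic fit,
# adjusted r-OR, signal rule, VIF.

test_that("tabulation enumerates the 2x2 cells", {
  tab <- ror_table(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))

  none <- ror_table(c(0, 0, 0), c(1, 0, 1))
  expect_equal(none$a + none$b, 0L)

  v <- expand_table(10, 20, 5, 40)
  tab2 <- ror_table(v$cases, v$exposure)
  expect_equal(unlist(tab2[c("a", "b", "c", "d")]),
               c(a = 10L, b = 20L, c = 5L, d = 40L))
  expect_equal(tab2$a + tab2$b + tab2$c + tab2$d, 75L)

  expect_error(ror_table(c(1, 0), c(1, 0, 1)), "index mismatch")
  expect_error(
    ror_table(c(x = 1L, y = 0L), c(x = 1L, z = 0L)), "index mismatch")
})

test_that("crude r-OR reproduces the closed-form fixture", {
  est <- crude_ror(ror_table(expand_table(10, 20, 5, 40)$cases,
                             expand_table(10, 20, 5, 40)$exposure))
  expect_equal(est$point, 4.000, tolerance = 1e-12)
  expect_equal(est$ci_low, 1.204, tolerance = 5e-4)
  expect_equal(est$ci_high, 13.284, tolerance = 5e-4)
  expect_equal(est$se_log, sqrt(1 / 10 + 1 / 20 + 1 / 5 + 1 / 40))
  expect_equal(est$n_exposed_cases, 10L)
  expect_equal(est$signal, "signal")

  ident <- crude_ror(structure(list(a = 5L, b = 5L, c = 5L, d = 5L),
                               class = "ror_table"))
  expect_equal(ident$point, 1)
  expect_equal(ident$signal, "no_signal")
})

test_that("zero cells trigger the Haldane-Anscombe correction and flag", {
  tab <- structure(list(a = 0L, b = 10L, c = 5L, d = 100L),
                   class = "ror_table")
  est <- crude_ror(tab)
  expect_equal(est$point, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_equal(est$point, 0.870, tolerance = 5e-4)
  expect_true(est$low_count_flag)
  expect_equal(est$n_exposed_cases, 0L)  # pre-correction count
  expect_error(crude_ror(tab, correction = "none"), "zero cell")
  # low-count flag also fires below 10 exposed cases without zeros
  low <- crude_ror(structure(list(a = 9L, b = 20L, c = 5L, d = 40L),
                             class = "ror_table"))
  expect_true(low$low_count_flag)
})

test_that("crude r-OR is invariant to row order and monotone in a", {
  v <- expand_table(12, 30, 9, 50)
  perm <- sample(length(v$cases))
  est1 <- crude_ror(ror_table(v$cases, v$exposure))
  est2 <- crude_ror(ror_table(v$cases[perm], v$exposure[perm]))
  expect_identical(est1, est2)

  points <- vapply(10:14, function(a) {
    crude_ror(structure(list(a = a, b = 30L, c = 9L, d = 50L),
                        class = "ror_table"))$point
  }, numeric(1))
  expect_true(all(diff(points) > 0))
})

test_that("the saturated logistic fit matches the 2x2 closed form exactly", {
  v <- expand_table(10, 20, 5, 40)
  fit <- fit_logistic(matrix(v$exposure, dimnames = list(NULL, "exposed")),
                      v$cases)
  expect_true(fit$converged)
  expect_equal(unname(exp(coef(fit)["exposed"])), 4.000, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["(Intercept)"]), log(20 / 40),
               tolerance = 1e-9)
  # Wald-on-saturated equals Woolf algebraically
  expect_equal(sqrt(vcov(fit)["exposed", "exposed"]),
               sqrt(1 / 10 + 1 / 20 + 1 / 5 + 1 / 40), tolerance = 1e-6)
})

test_that("fitted case probabilities average to the observed case rate", {
  set.seed(8)
  y <- rbinom(200, 1, 0.3)
  x <- rbinom(200, 1, 0.5)
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "z")), y)
  p <- stats::plogis(coef(fit)["(Intercept)"] + coef(fit)["z"] * x)
  expect_equal(mean(p), mean(y), tolerance = 1e-8)
})

test_that("perfect separation is reported as such", {
  y <- c(rep(1, 20), rep(0, 20))
  x <- y  # exposure perfectly predicts case
  expect_error(
    fit_logistic(matrix(x, dimnames = list(NULL, "exposed")), y),
    "separation.*exposed")
})

test_that("constant covariates are rejected by the fitter", {
  y <- rep(0:1, 10)
  X <- cbind(flat = rep(1, 20), ok = rep(c(0, 1), 10))
  expect_error(fit_logistic(X, y), "constant covariate.*flat")
})

test_that("adjusted r-OR agrees with the crude estimator on a 2x2 table", {
  v <- expand_table(10, 20, 5, 40)
  fit <- fit_logistic(matrix(v$exposure, dimnames = list(NULL, "exposed")),
                      v$cases)
  adj <- adjusted_ror(fit, "exposed", n_exposed_cases = 10L)
  crude <- crude_ror(ror_table(v$cases, v$exposure), correction = "none")
  expect_equal(adj$point, crude$point, tolerance = 1e-6)
  expect_equal(adj$ci_low, crude$ci_low, tolerance = 1e-6)
  expect_equal(adj$ci_high, crude$ci_high, tolerance = 1e-6)
  expect_equal(adj$method, "adjusted")

  expect_error(adjusted_ror(fit, "absent"), "unknown term")
})

test_that("a null coefficient with known SE gives the textbook Wald CI", {
  fake <- structure(
    list(coefficients = c("(Intercept)" = -2, drug = 0),
         vcov = matrix(c(0.04, 0, 0, 0.01), 2, 2,
                       dimnames = list(c("(Intercept)", "drug"),
                                       c("(Intercept)", "drug"))),
         converged = TRUE, n_iterations = 5L, deviance = 1, n = 100L),
    class = "pv_logit")
  est <- adjusted_ror(fake, "drug")
  expect_equal(est$point, 1)
  expect_equal(est$ci_low, 0.822, tolerance = 5e-4)
  expect_equal(est$ci_high, 1.217, tolerance = 5e-4)
  expect_equal(est$signal, "no_signal")
})

test_that("the signal rule fires only when the lower bound exceeds one", {
  mk <- function(point, lo, hi) list(point = point, ci_low = lo, ci_high = hi)
  expect_equal(classify_signal(mk(3.35, 3.25, 3.44)), "signal")
  expect_equal(classify_signal(mk(1.04, 0.99, 1.09)), "no_signal")
  # below-one estimates are never a protective claim
  expect_equal(classify_signal(mk(0.80, 0.70, 0.92)), "no_signal")
  expect_equal(classify_signal(mk(1.5, 1.0, 2.2)), "no_signal")  # lo == 1
})

test_that("adjusted exposure estimate ignores the dummy reference choice", {
  set.seed(42)
  n <- 600
  x <- rbinom(n, 1, 0.3)
  g <- sample(c("a", "b", "c"), n, replace = TRUE)
  y <- rbinom(n, 1, stats::plogis(-1.5 + 0.8 * x + 0.3 * (g == "b")))
  X1 <- cbind(x = x, g_b = as.numeric(g == "b"), g_c = as.numeric(g == "c"))
  X2 <- cbind(x = x, g_a = as.numeric(g == "a"), g_c = as.numeric(g == "c"))
  f1 <- fit_logistic(X1, y)
  f2 <- fit_logistic(X2, y)
  expect_equal(coef(f1)[["x"]], coef(f2)[["x"]], tolerance = 1e-8)
})

test_that("variance-inflation factors match hand calculations", {
  ortho <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  v <- compute_vif(ortho)
  expect_equal(v$vif, c(1, 1), tolerance = 1e-12)
  expect_false(any(v$flagged))

  hand <- cbind(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 1, 2))
  v2 <- compute_vif(hand)
  expect_equal(v2$vif, c(2, 2), tolerance = 1e-12)

  dup <- cbind(x1 = c(0, 1, 0, 1, 1), x2 = c(0, 1, 0, 1, 1),
               x3 = c(1, 0, 0, 1, 0))
  expect_warning(v3 <- compute_vif(dup), "collinear")
  expect_true(all(is.infinite(v3$vif[1:2])))
})

test_that("logistic coefficient equals ad/bc across random tables", {
  set.seed(99)
  for (i in 1:20) {
    cells <- sample(1:40, 4, replace = TRUE)
    v <- expand_table(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(matrix(v$exposure, dimnames = list(NULL, "e")),
                        v$cases)
    oracle <- oracle_woolf(cells[1], cells[2], cells[3], cells[4])
    adj <- adjusted_ror(fit, "e")
    expect_equal(adj$point, unname(oracle["or"]), tolerance = 1e-6)
    expect_equal(adj$ci_low, unname(oracle["lo"]), tolerance = 1e-6)
    expect_equal(adj$ci_high, unname(oracle["hi"]), tolerance = 1e-6)
  }
})
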