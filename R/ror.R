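# Disproportionality statistics: 2x2 tabulation, crude reporting odds ratio
# with Woolf CI and Haldane-Anscombe correction, logistic ML fit, Wald
# adjusted r-OR, lower-bound signal rule, variance-inflation factors.

Z95 <- 1.96  # used for both Woolf and Wald intervals so the saturated-model
             # identity (Wald CI == Woolf CI on a 2x2 table) holds exactly

#' Tabulate cases by exposure
#'
#' @param cases,exposure 0/1 vectors over the same reports; if both are named
#'   the names must agree (order-insensitively).
#' @return object of class `ror_table`: list with cells `a` (exposed cases),
#'   `b` (unexposed cases), `c` (exposed non-cases), `d` (unexposed
#'   non-cases).
#' @export
ror_table <- function(cases, exposure) {
  if (length(cases) != length(exposure)) {
    stop("index mismatch: case and exposure vectors differ in length",
         call. = FALSE)
  }
  if (!is.null(names(cases)) && !is.null(names(exposure))) {
    if (!setequal(names(cases), names(exposure))) {
      stop("index mismatch: case and exposure vectors index different reports",
           call. = FALSE)
    }
    exposure <- exposure[names(cases)]
  }
  cases <- as.integer(cases); exposure <- as.integer(exposure)
  stopifnot(all(cases %in% 0:1), all(exposure %in% 0:1))
  structure(list(a = sum(cases == 1L & exposure == 1L),
                 b = sum(cases == 1L & exposure == 0L),
                 c = sum(cases == 0L & exposure == 1L),
                 d = sum(cases == 0L & exposure == 0L)),
            class = "ror_table")
}

#' @export
print.ror_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("case", "non-case"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

new_ror_estimate <- function(point, ci_low, ci_high, se_log, method,
                             n_exposed_cases, low_count_flag) {
  est <- structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                        se_log = se_log, method = method,
                        n_exposed_cases = n_exposed_cases,
                        low_count_flag = low_count_flag,
                        signal = "no_signal"),
                   class = "ror_estimate")
  est$signal <- classify_signal(est)
  est
}

#' Crude reporting odds ratio from a 2x2 table
#'
#' Point estimate (a d)/(b c) with the Woolf standard error of the log odds
#' ratio, sqrt(1/a + 1/b + 1/c + 1/d), and a 95\% CI exp(log OR -/+ 1.96 se).
#' If any cell is zero and `correction = "haldane_anscombe"`, 0.5 is added to
#' all four cells before estimation and the low-count flag is set. The flag
#' is also set whenever there are fewer than 10 exposed cases (pre-correction
#' count, which is also what `n_exposed_cases` reports).
#'
#' @param table a [ror_table()].
#' @param correction "haldane_anscombe" (default) or "none"; with "none" a
#'   zero cell is an error.
#' @return object of class `ror_estimate` with `method = "crude"`.
#' @export
crude_ror <- function(table, correction = c("haldane_anscombe", "none")) {
  stopifnot(inherits(table, "ror_table"))
  correction <- match.arg(correction)
  cells <- c(table$a, table$b, table$c, table$d)
  a_raw <- table$a
  low <- a_raw < 10L
  if (any(cells == 0L)) {
    if (correction == "none") {
      stop("undefined estimate: zero cell in 2x2 table and correction ",
           "disabled", call. = FALSE)
    }
    cells <- cells + 0.5
    low <- TRUE
  }
  point <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  new_ror_estimate(point = point,
                   ci_low = exp(log(point) - Z95 * se),
                   ci_high = exp(log(point) + Z95 * se),
                   se_log = se, method = "crude",
                   n_exposed_cases = a_raw, low_count_flag = low)
}

#' @export
print.ror_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("r-OR (%s): %.*f [%.*f-%.*f]%s%s\n",
              x$method, digits, x$point, digits, x$ci_low, digits, x$ci_high,
              if (x$signal == "signal") "  *signal*" else "",
              if (x$low_count_flag) "  (low count)" else ""))
  invisible(x)
}

#' Signal classification of an r-OR estimate
#'
#' A disproportionality signal is declared if and only if the lower bound of
#' the 95\% CI exceeds 1 (which implies the point estimate exceeds 1).
#' Estimates below 1 are never interpreted as protective — case/non-case
#' analysis cannot establish the absence of an association — so they are
#' classified "no_signal" like any other non-significant result.
#'
#' @param estimate a `ror_estimate` (or any list with `ci_low`).
#' @return "signal" or "no_signal".
#' @export
classify_signal <- function(estimate) {
  if (is.null(estimate$ci_low) || !is.finite(estimate$ci_low)) {
    stop("classify_signal: estimate lacks a finite ci_low", call. = FALSE)
  }
  if (estimate$ci_low > 1) "signal" else "no_signal"
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits the binomial logistic model y ~ intercept + X by iteratively
#' reweighted least squares. The coefficient covariance is the inverse
#' observed information at the optimum. Non-convergence within `max_iter`
#' iterations is an error, as is complete or quasi-complete separation
#' (detected as a diverging coefficient, |beta| > 15 on the log-odds scale
#' with boundary fitted probabilities), reported with the offending column
#' named.
#'
#' @param design a `design_matrix` from [build_design_matrix()], or a plain
#'   numeric matrix of covariates (no intercept column; one is added).
#' @param cases 0/1 response vector; if named and the design has rownames,
#'   it is aligned by name.
#' @param tolerance relative deviance-change convergence criterion
#'   (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return object of class `pv_logit`: list with `coefficients`, `vcov`,
#'   `converged`, `n_iterations`, `deviance`, `n`, `roles`.
#' @export
fit_logistic <- function(design, cases, tolerance = 1e-8, max_iter = 100L) {
  roles <- NULL
  if (inherits(design, "design_matrix")) {
    roles <- design$roles
    X <- design$X
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (!is.null(names(cases)) && !is.null(rownames(X))) {
    if (!setequal(names(cases), rownames(X))) {
      stop("index mismatch: case vector and design matrix index different ",
           "reports", call. = FALSE)
    }
    cases <- cases[rownames(X)]
  }
  y <- as.numeric(cases)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  const <- apply(X, 2L, function(v) length(unique(v)) < 2L)
  if (any(const)) {
    stop("constant covariate column(s) in design: ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }

  Xi <- cbind("(Intercept)" = 1, X)
  fit <- suppressWarnings(
    stats::glm.fit(Xi, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tolerance,
                                                maxit = max_iter))
  )
  beta <- fit$coefficients

  big <- abs(beta[-1]) > 15
  boundary <- fit$boundary ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  if (any(big) && boundary) {
    stop("separation detected (diverging coefficient) for column(s): ",
         paste(names(beta[-1])[big], collapse = ", "), call. = FALSE)
  }
  if (!fit$converged) {
    stop("logistic fit did not converge within ", max_iter, " iterations",
         call. = FALSE)
  }

  # a few Newton-Raphson polish steps: the deviance-based IRLS stop leaves
  # coefficient error around 1e-6 x SE, which would blur the exact saturated
  # 2x2 identity with the closed-form estimator
  for (k in 1:5) {
    mu <- stats::plogis(drop(Xi %*% beta))
    info <- crossprod(Xi * sqrt(mu * (1 - mu)))
    step <- tryCatch(drop(solve(info, crossprod(Xi, y - mu))),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || max(abs(step)) > 0.5) break
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  mu <- stats::plogis(drop(Xi %*% beta))
  deviance <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
  info <- crossprod(Xi * sqrt(mu * (1 - mu)))
  vcov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    stop("singular information matrix; check for collinear covariates",
         call. = FALSE)
  })
  dimnames(vcov) <- list(names(beta), names(beta))

  structure(list(coefficients = beta, vcov = vcov, converged = fit$converged,
                 n_iterations = fit$iter, deviance = deviance,
                 n = length(y), roles = roles),
            class = "pv_logit")
}

#' @export
coef.pv_logit <- function(object, ...) object$coefficients

#' @export
vcov.pv_logit <- function(object, ...) object$vcov

#' @export
print.pv_logit <- function(x, ...) {
  cat("<pv_logit> n =", x$n, "| deviance =", format(x$deviance, digits = 6),
      "|", x$n_iterations, "IRLS iterations\n")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se,
                    or = exp(x$coefficients))
  print(format(tab, digits = 4))
  invisible(x)
}

#' Adjusted reporting odds ratio from a logistic fit
#'
#' exp(beta) for the named exposure term, with a Wald 95\% CI
#' exp(beta -/+ 1.96 SE) from the fit's covariance matrix.
#'
#' @param fit a converged `pv_logit`.
#' @param term_name covariate column name of the exposure.
#' @param n_exposed_cases exposed-case count carried over from the crude
#'   tabulation (used for the low-count flag); NA if unknown.
#' @return object of class `ror_estimate` with `method = "adjusted"`.
#' @export
adjusted_ror <- function(fit, term_name, n_exposed_cases = NA_integer_) {
  stopifnot(inherits(fit, "pv_logit"))
  if (!isTRUE(fit$converged)) {
    stop("adjusted_ror requires a converged fit", call. = FALSE)
  }
  if (!term_name %in% names(fit$coefficients)) {
    stop("unknown term '", term_name, "'; fit has: ",
         paste(setdiff(names(fit$coefficients), "(Intercept)"),
               collapse = ", "), call. = FALSE)
  }
  b <- fit$coefficients[[term_name]]
  se <- sqrt(fit$vcov[term_name, term_name])
  new_ror_estimate(point = exp(b),
                   ci_low = exp(b - Z95 * se),
                   ci_high = exp(b + Z95 * se),
                   se_log = se, method = "adjusted",
                   n_exposed_cases = n_exposed_cases,
                   low_count_flag = !is.na(n_exposed_cases) &&
                     n_exposed_cases < 10L)
}

#' Variance-inflation factors of a design matrix
#'
#' Classical VIFs on the dummy-coded covariate matrix: for each column j,
#' VIF_j = 1/(1 - R^2_j), where R^2_j is from the OLS regression of column j
#' on all other columns (with intercept). Exactly collinear columns are
#' reported with infinite VIF. Columns with VIF > 5 are flagged.
#'
#' @param design a `design_matrix` or plain numeric matrix with at least two
#'   non-constant columns.
#' @param flag_threshold VIF level above which a column is flagged (default 5).
#' @return data.frame with columns `column`, `vif`, `flagged`, of class
#'   `vif_table`.
#' @export
compute_vif <- function(design, flag_threshold = 5) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (ncol(X) < 2L) {
    stop("compute_vif needs at least two covariate columns", call. = FALSE)
  }
  const <- apply(X, 2L, function(v) length(unique(v)) < 2L)
  if (any(const)) {
    stop("constant column(s): ", paste(colnames(X)[const], collapse = ", "),
         call. = FALSE)
  }
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    f <- stats::lm.fit(others, yj)
    rss <- sum(f$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out <- data.frame(column = colnames(X), vif = vifs,
                    flagged = vifs > flag_threshold,
                    stringsAsFactors = FALSE)
  if (any(is.infinite(vifs))) {
    warning("exactly collinear column(s): ",
            paste(out$column[is.infinite(vifs)], collapse = ", "),
            call. = FALSE)
  }
  class(out) <- c("vif_table", "data.frame")
  out
}
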