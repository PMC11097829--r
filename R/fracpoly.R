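## Fractional-polynomial meta-regression of LACE estimates.
##
## A fractional polynomial of degree d in x has terms x^p for powers p from
## {-2, -1, -0.5, 0, 0.5, 1, 2, 3}, with x^0 read as ln x and a repeated
## power p at degree 2 contributing x^p * ln x as its second term. The LACE
## estimate in stratum s is the local slope of the causal dose-response
## curve h, so LACE_s is meta-regressed on the analytic derivative of the
## basis evaluated at the stratum mean exposure, by weighted least squares
## with inverse-variance weights and no intercept. Powers are selected by
## maximum weighted Gaussian likelihood.

fp_power_grid <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# undifferentiated basis h_j(x)
fp_basis <- function(x, powers) {
  k <- length(powers)
  B <- matrix(NA_real_, length(x), k)
  for (j in seq_len(k)) {
    p <- powers[j]
    repeated <- j == 2L && powers[1L] == powers[2L]
    B[, j] <- if (!repeated) {
      if (p == 0) log(x) else x^p
    } else {
      if (p == 0) log(x)^2 else x^p * log(x)
    }
  }
  B
}

# analytic derivative d/dx of fp_basis
fp_dbasis <- function(x, powers) {
  k <- length(powers)
  B <- matrix(NA_real_, length(x), k)
  for (j in seq_len(k)) {
    p <- powers[j]
    repeated <- j == 2L && powers[1L] == powers[2L]
    B[, j] <- if (!repeated) {
      if (p == 0) 1 / x else p * x^(p - 1)
    } else {
      if (p == 0) 2 * log(x) / x else x^(p - 1) * (p * log(x) + 1)
    }
  }
  B
}

# weighted no-intercept least squares with known variances; returns NULL on
# a singular design
fp_wls <- function(y, se, X) {
  w <- 1 / se^2
  XtW <- t(X * w)
  A <- XtW %*% X
  qrA <- qr(A)
  if (qrA$rank < ncol(X)) return(NULL)
  beta <- solve(qrA, XtW %*% y)
  vcov <- solve(qrA)
  fitted <- as.vector(X %*% beta)
  loglik <- sum(stats::dnorm(y, fitted, se, log = TRUE))
  list(coef = as.vector(beta), vcov = vcov, fitted = fitted,
       loglik = loglik)
}

fp_power_sets <- function(degree) {
  if (degree == 1L) {
    lapply(fp_power_grid, function(p) p)
  } else {
    out <- list()
    for (i in seq_along(fp_power_grid))
      for (j in i:length(fp_power_grid))
        out[[length(out) + 1L]] <- c(fp_power_grid[i], fp_power_grid[j])
    out
  }
}

#' Fit a fractional-polynomial dose-response model to LACE estimates
#'
#' Meta-regresses stratum LACE estimates on the analytic derivative of a
#' fractional-polynomial basis evaluated at the stratum mean exposures,
#' by inverse-variance-weighted least squares without intercept, selecting
#' the power (multi)set of the given degree that maximises the weighted
#' Gaussian log-likelihood. Under the instrumental-variable assumptions the
#' fitted derivative is the local causal effect, and its antiderivative —
#' anchored at `reference` — is the causal dose-response curve on the log
#' hazard ratio scale.
#'
#' @param laceset a [lace()] result, or any `data.frame` with columns
#'   `mean_exposure`, `lace`, `se`.
#' @param degree 1 or 2.
#' @param reference reference exposure (kg/m^2) at which the reconstructed
#'   curve is 0; default 25.
#' @return Object of class `"fracpoly_fit"`: `degree`, `powers`, `coef`,
#'   `vcov`, `loglik`, `fitted`, `reference`, `laceset`, `q_stat`
#'   (Cochran heterogeneity statistic of the selected fit, diagnostic
#'   only), `skipped` (power sets with singular designs).
#' @examples
#' ls <- data.frame(mean_exposure = c(10, 20, 25),
#'                  lace = 0.5 / c(10, 20, 25), se = 0.01)
#' fit <- fit_fracpoly(ls, degree = 1)
#' fit$powers  # 0, i.e. h(x) = beta * ln x
#' @export
fit_fracpoly <- function(laceset, degree = 2, reference = 25) {
  stopifnot(degree %in% c(1L, 2L))
  need <- c("mean_exposure", "lace", "se")
  missing <- setdiff(need, names(laceset))
  if (length(missing))
    stop_ctx("laceset missing columns: ", paste(missing, collapse = ", "))
  ok <- is.finite(laceset$lace) & is.finite(laceset$se) & laceset$se > 0
  d <- laceset[ok, , drop = FALSE]
  if (nrow(d) < degree + 2)
    stop_ctx("need at least degree + 2 = ", degree + 2,
             " strata with finite LACE and SE")
  if (any(d$mean_exposure <= 0))
    stop_ctx("all mean exposures must be positive (fractional powers ",
             "undefined otherwise)")
  if (reference <= 0) stop_ctx("reference must be positive")
  best <- NULL
  skipped <- list()
  for (powers in fp_power_sets(degree)) {
    X <- fp_dbasis(d$mean_exposure, powers)
    fit <- fp_wls(d$lace, d$se, X)
    if (is.null(fit)) {
      skipped[[length(skipped) + 1L]] <- powers
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$powers <- powers
    }
  }
  if (is.null(best))
    stop_ctx("every candidate power set gave a singular design")
  q_stat <- sum((d$lace - best$fitted)^2 / d$se^2)
  structure(list(degree = as.integer(degree), powers = best$powers,
                 coef = best$coef, vcov = best$vcov, loglik = best$loglik,
                 fitted = best$fitted, reference = reference,
                 laceset = d, q_stat = q_stat,
                 skipped = skipped),
            class = "fracpoly_fit")
}

#' @export
print.fracpoly_fit <- function(x, ...) {
  cat("fracpoly_fit: degree", x$degree, "| powers (",
      paste(x$powers, collapse = ", "), ") | coef (",
      paste(sprintf("%.4g", x$coef), collapse = ", "),
      ") | loglik", sprintf("%.3f", x$loglik),
      "| reference", x$reference, "kg/m^2\n")
  invisible(x)
}

#' Reconstruct the dose-response curve with pointwise confidence bounds
#'
#' Integrates a fitted fractional-polynomial derivative model back to the
#' curve scale: `curve(x) = sum_j coef_j (b_j(x) - b_j(reference))` with
#' `b_j` the undifferentiated basis, so the curve is the log hazard ratio
#' relative to the reference exposure and is exactly 0 (with zero variance)
#' at the reference. Pointwise variances come from the coefficient
#' covariance and the basis-difference vector; bounds are normal 95%
#' limits. A causal effect is evident at an exposure where the lower and
#' upper bounds both have a positive (or both a negative) slope — see
#' [effect_evident()].
#'
#' @param fit a [fit_fracpoly()] result.
#' @param grid positive exposure values; default 200 equally spaced points
#'   between the 1st and 99th percentile of the stratum means, with the
#'   reference forced onto the grid.
#' @return `data.frame` of class `"curve_points"`: `exposure`, `estimate`,
#'   `se`, `lower`, `upper`; attribute `"extrapolated"` flags grid values
#'   outside the span of the stratum means.
#' @export
reconstruct_curve <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "fracpoly_fit"))
  means <- fit$laceset$mean_exposure
  if (is.null(grid)) {
    lo <- stats::quantile(means, 0.01, names = FALSE)
    hi <- stats::quantile(means, 0.99, names = FALSE)
    grid <- sort(unique(c(seq(lo, hi, length.out = 200L), fit$reference)))
  }
  if (any(grid <= 0)) stop_ctx("grid values must be positive")
  D <- fp_basis(grid, fit$powers) -
    fp_basis(rep(fit$reference, length(grid)), fit$powers)
  est <- as.vector(D %*% fit$coef)
  v <- rowSums((D %*% fit$vcov) * D)
  v[v < 0] <- 0  # guard tiny negative rounding
  se <- sqrt(v)
  zc <- stats::qnorm(0.975)
  out <- data.frame(exposure = grid, estimate = est, se = se,
                    lower = est - zc * se, upper = est + zc * se)
  class(out) <- c("curve_points", "data.frame")
  attr(out, "extrapolated") <- grid < min(means) | grid > max(means)
  attr(out, "reference") <- fit$reference
  out
}

#' Exposure ranges where a causal effect is evident
#'
#' Recomputes, from a reconstructed curve, the smallest grid value above
#' which both confidence bounds have a positive finite-difference slope
#' (`harmful_above`) and the largest grid value below which both have a
#' negative slope (`protective_below`). These operationalise statements
#' such as "a harmful effect of increasing exposure is evident above
#' x kg/m^2". `NA` when no such contiguous tail exists.
#'
#' @param curve a [reconstruct_curve()] result.
#' @return List with `harmful_above` and `protective_below`.
#' @export
effect_evident <- function(curve) {
  stopifnot(inherits(curve, "curve_points"))
  x <- curve$exposure
  dl <- diff(curve$lower) / diff(x)
  du <- diff(curve$upper) / diff(x)
  both_pos <- dl > 0 & du > 0
  both_neg <- dl < 0 & du < 0
  harmful <- NA_real_
  if (all(both_pos)) harmful <- x[1L]
  else if (any(!both_pos) && both_pos[length(both_pos)]) {
    last_bad <- max(which(!both_pos))
    harmful <- x[last_bad + 1L]
  }
  protective <- NA_real_
  if (all(both_neg)) protective <- x[length(x)]
  else if (any(!both_neg) && both_neg[1L]) {
    first_bad <- min(which(!both_neg))
    protective <- x[first_bad]
  }
  list(harmful_above = harmful, protective_below = protective)
}

#' Linearity test for the LACE series
#'
#' Likelihood-ratio comparison of the best-fitting degree-1 fractional
#' polynomial against the linear model (power 1, constant derivative):
#' twice the log-likelihood gap referred to a chi-squared distribution with
#' 1 degree of freedom. Because the best power is selected by maximum
#' likelihood, the reference distribution is approximate and the test is
#' mildly anti-conservative; rejection indicates that a linear causal
#' effect is a suboptimal description of the LACE estimates.
#'
#' @param laceset a [lace()] result (>= 4 strata).
#' @return List with `statistic`, `p_value`, `best_power`.
#' @export
test_linearity <- function(laceset) {
  ok <- is.finite(laceset$lace) & is.finite(laceset$se) & laceset$se > 0
  if (sum(ok) < 4L) stop_ctx("linearity test needs at least 4 strata")
  best1 <- fit_fracpoly(laceset, degree = 1)  # reference irrelevant to loglik
  d <- laceset[ok, , drop = FALSE]
  lin <- fp_wls(d$lace, d$se, fp_dbasis(d$mean_exposure, 1))
  stat <- max(0, 2 * (best1$loglik - lin$loglik))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       best_power = best1$powers)
}

#' Trend test for the LACE series
#'
#' Inverse-variance-weighted meta-regression of the LACE estimates on the
#' stratum mean exposures, `lace_s = g0 + g1 * mean_s`, with a two-sided
#' normal (known-variance) test of `g1 = 0`. Rejection indicates a linear
#' trend in the localised effects across the exposure distribution.
#'
#' @param laceset a [lace()] result (>= 3 strata).
#' @return List with `slope`, `se`, `z`, `p_value`.
#' @export
test_trend <- function(laceset) {
  ok <- is.finite(laceset$lace) & is.finite(laceset$se) & laceset$se > 0
  d <- laceset[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop_ctx("trend test needs at least 3 strata")
  if (stats::var(d$mean_exposure) == 0)
    stop_ctx("all mean exposures equal: trend undefined")
  X <- cbind(1, d$mean_exposure)
  fit <- fp_wls(d$lace, d$se, X)
  if (is.null(fit)) stop_ctx("singular design in trend test")
  slope <- fit$coef[2L]
  se <- sqrt(fit$vcov[2L, 2L])
  z <- slope / se
  list(slope = slope, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}
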