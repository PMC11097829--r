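#' Non-linear Mendelian randomisation with stratification on the exposure
#'
#' Fits the full stratified non-linear Mendelian randomisation model:
#' partitions the sample into `q` exposure strata ([stratify()]), estimates
#' a localised average causal effect in each stratum as the ratio of the
#' instrument-outcome log hazard ratio (Cox regression on the age
#' timescale) to the instrument-exposure slope ([lace()]), optionally
#' stabilises the stratum estimates by sample perturbation combined with
#' Rubin's rules ([perturb_iterate()], [pool_lace()]), and meta-regresses
#' the LACE estimates on derivatives of fractional polynomials of degrees 1
#' and 2 ([fit_fracpoly()]), with linearity and trend tests and a
#' reconstructed dose-response curve ([reconstruct_curve()]).
#'
#' @param formula model formula of the form
#'   `Surv(entry_age, exit_age, event) ~ exposure | instrument`, where the
#'   left-hand side is a [survival::Surv()] survival object on the age
#'   timescale (2-argument `Surv(time, event)` is taken as entry at 0) and
#'   the right-hand side names the exposure and the instrument (genetic
#'   score), separated by `|`.
#' @param data `data.frame` in which the formula and covariates are
#'   evaluated.
#' @param q number of strata (default 100).
#' @param method `"doubly_ranked"` (default) or `"residual"`.
#' @param covariates adjustment covariates for the stratum regressions: a
#'   one-sided formula (e.g. `~ age_at_baseline + I(age_at_baseline^2) +
#'   sex`) or character vector of terms; default none.
#' @param reference reference exposure for the reconstructed curve
#'   (default 25 kg/m^2).
#' @param degree degree of the reported fractional polynomial (default 2;
#'   degree 1 is always fitted as well).
#' @param m_perturb number of sample-perturbation iterations; 0 (default)
#'   disables perturbation, values >= 2 enable it.
#' @param n_remove individuals removed per perturbation iteration
#'   (default 12).
#' @param seed integer seed for stratification tie-breaks, trimming, and
#'   perturbation draws.
#' @param weak_floor minimum tolerated instrument-exposure slope magnitude.
#' @return An object of class `"nlmr"` with components `lace` (the
#'   stratum estimates used for meta-regression), `fits` (degree-1 and
#'   degree-2 [fit_fracpoly()] objects), `p_linearity`, `p_trend`, `curve`,
#'   `strata`, `instrument_strength`, `reference`, `seed`, `call`.
#' @examples
#' ch <- simulate_cohort(sim_config(n_individuals = 3000,
#'                                  dose_response = dose_linear(0.03),
#'                                  seed = 3))
#' fit <- nlmr(survival::Surv(entry_age, exit_age, event) ~ exposure | score,
#'             data = ch, q = 10,
#'             covariates = ~ age_at_baseline + I(age_at_baseline^2) + sex)
#' summary(fit)
#' @export
nlmr <- function(formula, data, q = 100,
                 method = c("doubly_ranked", "residual"),
                 covariates = NULL, reference = 25, degree = 2,
                 m_perturb = 0, n_remove = 12, seed = 1L,
                 weak_floor = 1e-6) {
  method <- match.arg(method)
  stopifnot(degree %in% c(1L, 2L))
  parsed <- parse_nlmr_formula(formula, data)
  cov_terms <- parse_covariates(covariates)
  wdat <- data
  wdat$entry_age <- parsed$entry
  wdat$exit_age <- parsed$exit
  wdat$event <- parsed$event
  wdat$exposure <- parsed$exposure
  wdat$score <- parsed$score
  if (!"id" %in% names(wdat)) wdat$id <- seq_len(nrow(wdat))
  validate_cohort(wdat)

  assignment <- stratify(wdat, q, method = method, seed = seed)
  if (m_perturb >= 2) {
    iters <- perturb_iterate(wdat, q, method = method,
                             covariates = cov_terms, m = m_perturb,
                             n_remove = n_remove, seed = seed)
    lace_tab <- pool_lace(iters)
  } else {
    iters <- NULL
    lace_tab <- lace(wdat, assignment, covariates = cov_terms,
                     weak_floor = weak_floor)
  }
  fits <- list(degree1 = fit_fracpoly(lace_tab, 1, reference),
               degree2 = fit_fracpoly(lace_tab, 2, reference))
  lin <- test_linearity(lace_tab)
  trd <- test_trend(lace_tab)
  reported <- fits[[paste0("degree", degree)]]
  curve <- reconstruct_curve(reported)
  strength <- stratum_instrument_strength(wdat, assignment,
                                          covariates = cov_terms)
  structure(list(
    call = match.call(), method = method, q = as.integer(q),
    covariates = cov_terms, reference = reference,
    degree = as.integer(degree), seed = as.integer(seed),
    m_perturb = as.integer(m_perturb), n_remove = as.integer(n_remove),
    n = nrow(wdat), n_trimmed = length(assignment$trimmed_ids),
    strata = assignment, lace = lace_tab, fits = fits,
    p_linearity = lin$p_value, linearity = lin,
    p_trend = trd$p_value, trend = trd,
    curve = curve, instrument_strength = strength
  ), class = "nlmr")
}

parse_nlmr_formula <- function(formula, data) {
  if (length(formula) != 3L)
    stop_ctx("formula must have the form Surv(...) ~ exposure | instrument")
  lhs <- eval(formula[[2L]], data, environment(formula))
  if (!survival::is.Surv(lhs))
    stop_ctx("left-hand side must be a survival::Surv object")
  if (ncol(lhs) == 3L) {
    entry <- lhs[, 1L]; exit <- lhs[, 2L]; event <- lhs[, 3L]
  } else {
    entry <- rep(0, nrow(lhs)); exit <- lhs[, 1L]; event <- lhs[, 2L]
  }
  rhs <- formula[[3L]]
  if (!(is.call(rhs) && identical(rhs[[1L]], as.name("|"))))
    stop_ctx("right-hand side must be `exposure | instrument`")
  exposure <- eval(rhs[[2L]], data, environment(formula))
  score <- eval(rhs[[3L]], data, environment(formula))
  list(entry = entry, exit = exit, event = as.integer(event),
       exposure = exposure, score = score)
}

parse_covariates <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "formula"))
    return(attr(stats::terms(covariates), "term.labels"))
  as.character(covariates)
}

#' @export
print.nlmr <- function(x, digits = 4, ...) {
  cat("Non-linear Mendelian randomisation (", x$method, " stratification)\n",
      sep = "")
  cat("  n =", x$n, "| strata =", x$q, "| trimmed =", x$n_trimmed,
      if (x$m_perturb >= 2)
        paste("| perturbation: m =", x$m_perturb, ", removing", x$n_remove),
      "\n")
  rep_fit <- x$fits[[paste0("degree", x$degree)]]
  cat("  reported fractional polynomial: degree ", x$degree, ", powers (",
      paste(rep_fit$powers, collapse = ", "), ")\n", sep = "")
  cat("  coefficients:", paste(sprintf("%.*g", digits, rep_fit$coef),
                               collapse = ", "), "\n")
  cat("  p_linearity =", format.pval(x$p_linearity, digits = 3),
      "| p_trend =", format.pval(x$p_trend, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.nlmr <- function(object, ...) {
  rep_fit <- object$fits[[paste0("degree", object$degree)]]
  se <- sqrt(diag(rep_fit$vcov))
  coefs <- cbind(Estimate = rep_fit$coef, `Std. Error` = se,
                 z = rep_fit$coef / se,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(rep_fit$coef / se)))
  rownames(coefs) <- fp_term_names(rep_fit$powers)
  ev <- effect_evident(object$curve)
  out <- list(call = object$call, method = object$method, q = object$q,
              n = object$n, n_strata_used = nrow(object$lace),
              degree = object$degree, powers = rep_fit$powers,
              coefficients = coefs, loglik = rep_fit$loglik,
              q_stat = rep_fit$q_stat,
              p_linearity = object$p_linearity, p_trend = object$p_trend,
              top_bottom_ratio =
                attr(object$instrument_strength, "top_bottom_ratio"),
              effect_evident = ev, reference = object$reference,
              m_perturb = object$m_perturb)
  class(out) <- "summary.nlmr"
  out
}

fp_term_names <- function(powers) {
  nm <- character(length(powers))
  for (j in seq_along(powers)) {
    p <- powers[j]
    repeated <- j == 2L && powers[1L] == powers[2L]
    nm[j] <- if (!repeated) {
      if (p == 0) "log(x)" else paste0("x^", p)
    } else {
      if (p == 0) "log(x)^2" else paste0("x^", p, "*log(x)")
    }
  }
  nm
}

#' @export
print.summary.nlmr <- function(x, ...) {
  cat("Non-linear Mendelian randomisation (", x$method,
      " stratification)\n\n", sep = "")
  cat("Strata:", x$n_strata_used, "of", x$q, "used | n =", x$n, "\n")
  if (is.finite(x$top_bottom_ratio))
    cat("Instrument-exposure slope, top/bottom stratum ratio:",
        sprintf("%.2f", x$top_bottom_ratio), "\n")
  cat("\nFractional polynomial (degree ", x$degree, "), powers (",
      paste(x$powers, collapse = ", "), "), curve relative to ",
      x$reference, " kg/m^2:\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nWeighted log-likelihood:", sprintf("%.3f", x$loglik),
      "| heterogeneity Q:", sprintf("%.2f", x$q_stat), "\n")
  cat("Linearity test p =", format.pval(x$p_linearity, digits = 3),
      "| trend test p =", format.pval(x$p_trend, digits = 3), "\n")
  ev <- x$effect_evident
  if (is.finite(ev$harmful_above))
    cat("Harmful effect evident above",
        sprintf("%.1f", ev$harmful_above), "kg/m^2\n")
  if (is.finite(ev$protective_below))
    cat("Harmful effect of decrease evident below",
        sprintf("%.1f", ev$protective_below), "kg/m^2\n")
  if (x$m_perturb >= 2)
    cat("Stratum estimates combined over", x$m_perturb,
        "perturbation iterations by Rubin's rules\n")
  invisible(x)
}

#' @export
coef.nlmr <- function(object, ...) {
  fit <- object$fits[[paste0("degree", object$degree)]]
  stats::setNames(fit$coef, fp_term_names(fit$powers))
}

#' @export
vcov.nlmr <- function(object, ...) {
  fit <- object$fits[[paste0("degree", object$degree)]]
  v <- fit$vcov
  dimnames(v) <- list(fp_term_names(fit$powers), fp_term_names(fit$powers))
  v
}

#' @export
fitted.nlmr <- function(object, ...) {
  fit <- object$fits[[paste0("degree", object$degree)]]
  stats::setNames(fit$fitted, object$lace$stratum[
    is.finite(object$lace$lace)])
}

#' Standardised meta-regression residuals
#'
#' `(lace - fitted derivative) / se` for the reported fit; under a correct
#' model and accurate stratum SEs these are approximately standard normal.
#'
#' @param object an `"nlmr"` fit.
#' @param ... unused.
#' @export
residuals.nlmr <- function(object, ...) {
  fit <- object$fits[[paste0("degree", object$degree)]]
  (fit$laceset$lace - fit$fitted) / fit$laceset$se
}

#' Predict the dose-response curve at new exposure values
#'
#' @param object an `"nlmr"` fit.
#' @param newdata numeric vector of exposure values (kg/m^2), or a
#'   `data.frame` with an `exposure` column; default the fitted curve grid.
#' @param ... unused.
#' @return A [reconstruct_curve()] `data.frame` (`exposure`, `estimate`,
#'   `se`, `lower`, `upper`), log hazard ratio relative to the reference.
#' @export
predict.nlmr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$curve)
  x <- if (is.data.frame(newdata)) newdata$exposure else newdata
  if (is.null(x)) stop_ctx("newdata must supply exposure values")
  reconstruct_curve(object$fits[[paste0("degree", object$degree)]],
                    grid = as.numeric(x))
}

#' Plot the reconstructed dose-response curve
#'
#' Black curve with grey pointwise 95% confidence limits and the reference
#' exposure marked, on the log hazard ratio scale.
#'
#' @param x an `"nlmr"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nlmr <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$exposure, cv$estimate, type = "n",
                 ylim = range(cv$lower, cv$upper),
                 xlab = expression("Exposure (kg/m"^2 * ")"),
                 ylab = "Log hazard ratio vs reference", ...)
  graphics::lines(cv$exposure, cv$lower, col = "grey60")
  graphics::lines(cv$exposure, cv$upper, col = "grey60")
  graphics::lines(cv$exposure, cv$estimate, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = x$reference, lty = 3)
  invisible(x)
}

#' Write the report bundle of a fitted model
#'
#' Writes, under `dir`: `lace.tsv` (stratum estimates), `curve_degree1.tsv`
#' and `curve_degree2.tsv` (reconstructed curves with bounds),
#' `instrument_strength.tsv`, `fit.json` (selected powers, coefficients,
#' covariance, log-likelihoods, test p-values) and `manifest.json` (call,
#' method, q, seeds, covariates, package version). All content is
#' deterministic given the fit, so a rerun with the same manifest
#' reproduces the files byte-for-byte. Effect-evident thresholds are not
#' stored: they are recomputed from the curve files via [effect_evident()].
#'
#' @param fit an `"nlmr"` fit.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_nlmr_report <- function(fit, dir) {
  stopifnot(inherits(fit, "nlmr"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(fit$lace), "lace.tsv")
  wt(as.data.frame(reconstruct_curve(fit$fits$degree1)), "curve_degree1.tsv")
  wt(as.data.frame(reconstruct_curve(fit$fits$degree2)), "curve_degree2.tsv")
  wt(as.data.frame(fit$instrument_strength), "instrument_strength.tsv")
  jsonlite::write_json(list(
    degree1 = list(powers = fit$fits$degree1$powers,
                   coef = fit$fits$degree1$coef,
                   vcov = fit$fits$degree1$vcov,
                   loglik = fit$fits$degree1$loglik),
    degree2 = list(powers = fit$fits$degree2$powers,
                   coef = fit$fits$degree2$coef,
                   vcov = fit$fits$degree2$vcov,
                   loglik = fit$fits$degree2$loglik),
    p_linearity = fit$p_linearity, p_trend = fit$p_trend
  ), file.path(dir, "fit.json"), digits = NA)
  jsonlite::write_json(list(
    call = paste(deparse(fit$call), collapse = " "),
    method = fit$method, q = fit$q, seed = fit$seed,
    m_perturb = fit$m_perturb, n_remove = fit$n_remove,
    covariates = fit$covariates %||% character(0),
    reference = fit$reference, n = fit$n, n_trimmed = fit$n_trimmed,
    package_version = as.character(utils::packageVersion("stratamr"))
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
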