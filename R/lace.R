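#' Instrument-outcome association from Cox regression on the age timescale
#'
#' Fits a Cox proportional-hazards model with attained age as the timescale
#' — `Surv(entry_age, exit_age, event)`, i.e. left truncation at study entry
#' — returning the log hazard ratio per unit of `score_col`, with Efron tie
#' handling and additive covariates. This is the numerator association of a
#' stratum-specific Mendelian randomisation estimate.
#'
#' @param data `data.frame` with `entry_age`, `exit_age`, `event`, the score
#'   column and any covariates.
#' @param covariates character vector of covariate terms (may include
#'   expressions such as `"I(age_at_baseline^2)"`).
#' @param score_col name of the instrument column (default `"score"`).
#' @return List with `beta`, `se`, `n`, `events` and `flag` (`"ok"` or
#'   `"nonconvergent"` when the partial likelihood is monotone, i.e. has no
#'   finite maximum).
#' @examples
#' d <- data.frame(entry_age = 0, exit_age = 1:4, event = 1,
#'                 score = c(1, 0, 1, 0))
#' cox_association(d)$beta  # log((1 + sqrt(17))/2)
#' @export
cox_association <- function(data, covariates = NULL, score_col = "score") {
  need <- c("entry_age", "exit_age", "event", score_col)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop_ctx("data missing columns: ", paste(missing, collapse = ", "))
  if (any(data$exit_age <= data$entry_age))
    stop_ctx("exit_age must exceed entry_age for every row")
  if (sum(data$event) < 1)
    stop_ctx("no events in subset: association inestimable")
  rhs <- c(score_col, covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(entry_age, exit_age, event) ~",
    paste(rhs, collapse = " + ")))
  flag <- "ok"
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        flag <<- "nonconvergent"
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  if (!score_col %in% rownames(cf) || is.na(cf[score_col, "coef"]))
    stop_ctx("score coefficient inestimable (degenerate design)")
  beta <- cf[score_col, "coef"]
  se <- cf[score_col, "se(coef)"]
  if (!is.finite(beta) || !is.finite(se)) flag <- "nonconvergent"
  list(beta = beta, se = se, n = nrow(data),
       events = as.integer(sum(data$event)), flag = flag)
}

#' Localised average causal effects per stratum
#'
#' For each stratum of an assignment, estimates the localised average causal
#' effect (LACE) as a ratio of coefficients: the association of the genetic
#' score with the outcome (log hazard ratio from [cox_association()])
#' divided by the association of the score with the exposure (least-squares
#' slope), both per 1 SD of the score and adjusted for the same covariates.
#' The standard error is the first-order delta approximation
#' `se(beta_gy) / |beta_gx|`, which ignores the sampling error of the
#' denominator (conventional with individual-level data and a per-stratum
#' F statistic well above weak-instrument territory); `second_order = TRUE`
#' adds the denominator-variance term
#' `sqrt(se_gy^2/gx^2 + gy^2 se_gx^2/gx^4)`.
#'
#' Strata whose instrument-exposure slope falls below `weak_floor` in
#' absolute value, with zero score variance, no events, or a monotone Cox
#' partial likelihood are excluded from the returned set and listed in the
#' `"excluded"` attribute with a reason.
#'
#' @param cohort cohort `data.frame`.
#' @param assignment a [stratify()] result for this cohort.
#' @param covariates character vector of covariate terms used in both
#'   regressions (e.g. `c("age_at_baseline", "I(age_at_baseline^2)",
#'   "sex")`).
#' @param weak_floor minimum tolerated `|beta_gx|` (default 1e-6).
#' @param second_order use the two-term delta SE.
#' @return A `data.frame` of class `"lace_set"`, ordered by mean exposure:
#'   `stratum`, `n`, `events`, `mean_exposure`, `beta_gx`, `se_gx`,
#'   `beta_gy`, `se_gy`, `lace`, `se`.
#' @export
lace <- function(cohort, assignment, covariates = NULL, weak_floor = 1e-6,
                 second_order = FALSE) {
  stopifnot(inherits(assignment, "strata_assignment"))
  validate_cohort(cohort)
  dat <- cohort_by_stratum(cohort, assignment)
  sd_g <- stats::sd(dat$score)
  if (!is.finite(sd_g) || sd_g == 0) stop_ctx("score has zero variance")
  dat$score_std <- dat$score / sd_g
  fml_x <- stats::reformulate(c("score_std", covariates),
                              response = "exposure")
  rows <- list()
  excluded <- list()
  for (s in sort(unique(dat$.stratum))) {
    d <- dat[dat$.stratum == s, , drop = FALSE]
    if (stats::var(d$score_std) == 0) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(stratum = s, reason = "zero_score_variance")
      next
    }
    cf_x <- tryCatch(summary(stats::lm(fml_x, data = d))$
                       coefficients["score_std", ],
                     error = function(e) NULL)
    if (is.null(cf_x) || !is.finite(cf_x[["Estimate"]])) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(stratum = s, reason = "exposure_regression_failed")
      next
    }
    gx <- cf_x[["Estimate"]]; se_gx <- cf_x[["Std. Error"]]
    if (abs(gx) < weak_floor) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(stratum = s, reason = "weak_instrument")
      next
    }
    cy <- tryCatch(cox_association(d, covariates, "score_std"),
                   error = function(e) NULL)
    if (is.null(cy) || cy$flag != "ok") {
      excluded[[length(excluded) + 1L]] <-
        data.frame(stratum = s,
                   reason = if (is.null(cy)) "cox_failed"
                            else "monotone_likelihood")
      next
    }
    se <- if (second_order)
      sqrt(cy$se^2 / gx^2 + cy$beta^2 * se_gx^2 / gx^4)
    else cy$se / abs(gx)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, n = nrow(d), events = cy$events,
      mean_exposure = mean(d$exposure),
      beta_gx = gx, se_gx = se_gx, beta_gy = cy$beta, se_gy = cy$se,
      lace = cy$beta / gx, se = se)
  }
  if (!length(rows)) stop_ctx("no stratum yielded a LACE estimate")
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_exposure), ]
  rownames(out) <- NULL
  class(out) <- c("lace_set", "data.frame")
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else NULL
  attr(out, "covariates") <- covariates
  out
}

#' @export
print.lace_set <- function(x, ...) {
  cat("lace_set:", nrow(x), "strata | mean exposure ",
      sprintf("%.1f-%.1f", min(x$mean_exposure), max(x$mean_exposure)),
      "kg/m^2\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more strata\n")
  ex <- attr(x, "excluded")
  if (!is.null(ex)) cat("  excluded strata:", nrow(ex), "\n")
  invisible(x)
}

#' Genetic associations with candidate competing risk factors in strata
#'
#' Instrument-validity diagnostic: regresses each named trait on the
#' standardised genetic score, overall and within each stratum, by least
#' squares (binary traits on the 0/1 scale, so associations are comparable
#' across strata on one scale). An autosomal score cannot causally affect
#' age or sex, so systematic stratum-level associations with them indicate
#' selection into the sample or stratification artefacts.
#'
#' @param cohort cohort `data.frame`.
#' @param assignment a [stratify()] result.
#' @param traits character vector of cohort columns to check.
#' @return `data.frame` with `stratum` (0 = overall), `trait`, `n`, `beta`,
#'   `se`, `z`, and `reason` (`NA` or `"constant_trait"`), ordered for a
#'   strata x traits heatmap.
#' @export
covariate_check <- function(cohort, assignment, traits) {
  stopifnot(inherits(assignment, "strata_assignment"))
  missing <- setdiff(traits, names(cohort))
  if (length(missing))
    stop_ctx("traits not in cohort: ", paste(missing, collapse = ", "))
  dat <- cohort_by_stratum(cohort, assignment)
  dat$score_std <- dat$score / stats::sd(dat$score)
  one <- function(d, s) {
    do.call(rbind, lapply(traits, function(tr) {
      y <- d[[tr]]
      if (length(unique(y)) < 2L)
        return(data.frame(stratum = s, trait = tr, n = nrow(d),
                          beta = NA_real_, se = NA_real_, z = NA_real_,
                          reason = "constant_trait"))
      cf <- summary(stats::lm(y ~ d$score_std))$coefficients[2L, ]
      data.frame(stratum = s, trait = tr, n = nrow(d),
                 beta = cf[["Estimate"]], se = cf[["Std. Error"]],
                 z = cf[["Estimate"]] / cf[["Std. Error"]],
                 reason = NA_character_)
    }))
  }
  out <- rbind(one(dat, 0L),
               do.call(rbind, lapply(split(dat, dat$.stratum),
                                     function(d) one(d, d$.stratum[1L]))))
  rownames(out) <- NULL
  out
}
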