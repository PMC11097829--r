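#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every generative assumption of [simulate_cohort()]:
#' genotypes, the weighted allele score and its explained exposure variance,
#' instrument-effect heterogeneity, confounding, the causal dose-response on
#' a survival hazard, the entry/censoring scheme, and an optional
#' participation (selection) model.
#'
#' @param n_individuals number of cohort rows to generate.
#' @param n_variants number of independent biallelic variants.
#' @param allele_freqs effect-allele frequencies, recycled to `n_variants`;
#'   each in (0, 1). Default: equally spaced in \[0.1, 0.9\].
#' @param variant_weights per-allele weights of the genetic score (external
#'   GWAS units); recycled to `n_variants`, not all zero. Default 1.
#' @param target_r2 fraction of exposure variance explained by the score,
#'   in (0, 1). Default 0.02, the order reported for a 73-variant adult BMI
#'   score in large European-ancestry cohorts (1.6--2%).
#' @param heterogeneity non-negative dial for variation of the instrument
#'   effect across the exposure distribution. The per-individual effect is
#'   `base * (1 + heterogeneity * Phi(liability))` with `Phi` the standard
#'   normal CDF of the standardised non-genetic exposure component, so the
#'   effect is a monotone positive function of exposure liability and the
#'   rank-preserving assumption of the doubly-ranked method holds by
#'   construction. 0 gives the constant genetic effect the residual method
#'   assumes; 2 gives a top/bottom percentile slope ratio of about 3, and 6
#'   of about 7, the orders observed in large cohorts.
#' @param confounder_effect_x effect of the standard-normal confounder on
#'   the exposure (kg/m^2 per SD, before final moment matching).
#' @param confounder_effect_y effect of the confounder on the log-hazard.
#' @param sex_effect_y log-hazard difference for `sex = 1` vs `sex = 0`
#'   (default 0.4, the order of the male-female gap in adult all-cause
#'   mortality); gives the sex covariate a real role in adjustment and
#'   selection experiments.
#' @param dose_response a [dose_linear()], [dose_quadratic()] or
#'   [dose_jshape()] curve mapping exposure to the causal log-hazard shift.
#' @param baseline_hazard Weibull baseline on the age timescale: named
#'   vector `c(shape=, scale=)`, both positive. The default
#'   (shape 8, scale 95 years) gives adult all-cause mortality of a
#'   realistic order over follow-up to age 85.
#' @param entry_age_range ages (years) between which study entry is uniform.
#' @param admin_censor_age administrative censoring age (years); must exceed
#'   the upper entry age.
#' @param exposure_mean,exposure_sd marginal moments of the generated
#'   exposure (kg/m^2); defaults 27 and 4.5, typical of adult BMI in
#'   European cohorts.
#' @param selection optional named list of logistic coefficients
#'   (`intercept`, `age`, `sex`, `confounder`, `exposure`) for the
#'   probability of participation; `age` and `exposure` enter centred at the
#'   mid entry age and at `exposure_mean`. `NULL` (default) selects everyone.
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   exactly.
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_cohort()], [apply_selection()]
#' @export
sim_config <- function(n_individuals = 10000,
                       n_variants = 25,
                       allele_freqs = NULL,
                       variant_weights = NULL,
                       target_r2 = 0.02,
                       heterogeneity = 0,
                       confounder_effect_x = 1,
                       confounder_effect_y = 0.1,
                       sex_effect_y = 0.4,
                       dose_response = dose_linear(0),
                       baseline_hazard = c(shape = 8, scale = 95),
                       entry_age_range = c(40, 70),
                       admin_censor_age = 85,
                       exposure_mean = 27,
                       exposure_sd = 4.5,
                       selection = NULL,
                       seed = 1L) {
  if (!is_count(n_individuals))
    stop_ctx("n_individuals must be a positive integer")
  if (!is_count(n_variants))
    stop_ctx("n_variants must be a positive integer")
  allele_freqs <- allele_freqs %||% seq(0.1, 0.9, length.out = n_variants)
  allele_freqs <- rep_len(allele_freqs, n_variants)
  if (any(!is.finite(allele_freqs)) || any(allele_freqs <= 0) ||
      any(allele_freqs >= 1))
    stop_ctx("allele_freqs must all lie strictly in (0, 1)")
  variant_weights <- rep_len(variant_weights %||% 1, n_variants)
  if (any(!is.finite(variant_weights)))
    stop_ctx("variant_weights must be finite")
  if (all(variant_weights == 0))
    stop_ctx("variant_weights are all zero: the score has no variance, so ",
             "any target_r2 > 0 is unattainable")
  if (!is.numeric(target_r2) || length(target_r2) != 1L ||
      target_r2 <= 0 || target_r2 >= 1)
    stop_ctx("target_r2 must lie strictly in (0, 1)")
  if (!is.numeric(heterogeneity) || heterogeneity < 0)
    stop_ctx("heterogeneity must be >= 0")
  if (!inherits(dose_response, "dose_response"))
    stop_ctx("dose_response must be built by dose_linear(), ",
             "dose_quadratic() or dose_jshape()")
  bh <- baseline_hazard
  if (is.null(names(bh)) || !all(c("shape", "scale") %in% names(bh)))
    stop_ctx("baseline_hazard must be a named vector c(shape=, scale=)")
  if (bh[["shape"]] <= 0 || bh[["scale"]] <= 0)
    stop_ctx("Weibull baseline shape and scale must be positive")
  if (length(entry_age_range) != 2L || diff(entry_age_range) < 0 ||
      any(entry_age_range < 0))
    stop_ctx("entry_age_range must be an increasing non-negative interval")
  if (admin_censor_age <= entry_age_range[2L])
    stop_ctx("admin_censor_age must exceed the upper entry age")
  if (exposure_sd <= 0) stop_ctx("exposure_sd must be positive")
  if (!is.null(selection)) {
    allowed <- c("intercept", "age", "sex", "confounder", "exposure")
    if (!is.list(selection) || is.null(names(selection)) ||
        !all(names(selection) %in% allowed))
      stop_ctx("selection must be a named list with names among: ",
               paste(allowed, collapse = ", "))
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    allele_freqs = allele_freqs,
    variant_weights = variant_weights,
    target_r2 = target_r2,
    heterogeneity = heterogeneity,
    confounder_effect_x = confounder_effect_x,
    confounder_effect_y = confounder_effect_y,
    sex_effect_y = sex_effect_y,
    dose_response = dose_response,
    baseline_hazard = c(shape = unname(bh[["shape"]]),
                        scale = unname(bh[["scale"]])),
    entry_age_range = as.numeric(entry_age_range),
    admin_censor_age = admin_censor_age,
    exposure_mean = exposure_mean,
    exposure_sd = exposure_sd,
    selection = selection,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: n =", x$n_individuals, "| variants =", x$n_variants,
      "| target R2 =", x$target_r2, "| heterogeneity =", x$heterogeneity,
      "\n  dose_response:", x$dose_response$family,
      "| Weibull(", x$baseline_hazard[["shape"]], ",",
      x$baseline_hazard[["scale"]], ") | entry",
      paste(x$entry_age_range, collapse = "-"),
      "| censor", x$admin_censor_age,
      "| selection:", if (is.null(x$selection)) "none" else "logistic",
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with the statistical structure assumed by stratified
#' Mendelian randomisation of an exposure on a survival outcome:
#' independent biallelic genotypes, a weighted allele score calibrated
#' in-sample to explain `target_r2` of the exposure variance, a latent
#' standard-normal confounder acting on both exposure and log-hazard, an
#' optional monotone heterogeneity of the instrument effect across the
#' exposure-liability distribution, survival times from a Weibull
#' proportional-hazards model on the age timescale with uniform study entry
#' (left truncation) and administrative censoring, and an optional logistic
#' participation model.
#'
#' The exposure is built as
#' `exposure = scale(a * m * z + L)` where `z` is the standardised score,
#' `L = confounder_effect_x * U + eps` the non-genetic component,
#' `m = 1 + heterogeneity * Phi(L)` the per-individual effect multiplier,
#' and `a` is calibrated so that the genetic component carries `target_r2`
#' of the variance; the result is then moment-matched to
#' (`exposure_mean`, `exposure_sd`). Event times are inverse-transform
#' samples from the Weibull cumulative hazard conditional on survival to the
#' entry age, with log-hazard `dose_response(exposure) +
#' confounder_effect_y * U + sex_effect_y * sex`.
#'
#' @param config a [sim_config()] object.
#' @return A `data.frame` with one row per individual and columns
#'   `id`, `score` (raw weighted score), `exposure` (kg/m^2), `entry_age`,
#'   `exit_age`, `event` (1 = death), `sex` (0/1), `age_at_baseline`,
#'   `confounder` (latent U, emitted for adjustment experiments),
#'   `selected` (0/1), and genotype dosage columns `g1..gV`. The attribute
#'   `"sim_config"` carries the config.
#' @examples
#' ch <- simulate_cohort(sim_config(n_individuals = 500, seed = 7))
#' summary(ch$exposure)
#' mean(ch$event)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_ctx("config must be a sim_config object")
  n <- config$n_individuals
  V <- config$n_variants
  with_seed(config$seed, {
    G <- matrix(stats::rbinom(n * V, 2L, rep(config$allele_freqs, each = n)),
                nrow = n, ncol = V)
    colnames(G) <- paste0("g", seq_len(V))
    score <- as.vector(G %*% config$variant_weights)
    if (stats::var(score) <= 0)
      stop_ctx("simulated score has zero variance; target_r2 = ",
               config$target_r2, " is unattainable with these weights and ",
               "allele frequencies")
    z <- (score - mean(score)) / stats::sd(score)

    U <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    L <- config$confounder_effect_x * U + eps
    m <- 1 + config$heterogeneity * stats::pnorm((L - mean(L)) / stats::sd(L))
    gen <- m * z
    a <- sqrt(config$target_r2 / (1 - config$target_r2) *
                stats::var(L) / stats::var(gen))
    xr <- a * gen + L
    exposure <- config$exposure_mean +
      config$exposure_sd * (xr - mean(xr)) / stats::sd(xr)

    sex <- stats::rbinom(n, 1L, 0.5)
    lp <- dose_eval(config$dose_response, exposure) +
      config$confounder_effect_y * U + config$sex_effect_y * sex
    entry <- stats::runif(n, config$entry_age_range[1L],
                          config$entry_age_range[2L])
    shape <- config$baseline_hazard[["shape"]]
    scale <- config$baseline_hazard[["scale"]]
    # inverse-transform sampling of the Weibull conditional on survival to
    # entry: H0(T) = H0(entry) + E / exp(lp), E ~ Exp(1)
    tt <- scale * ((entry / scale)^shape + stats::rexp(n) * exp(-lp))^(1 / shape)
    exit <- pmin(tt, config$admin_censor_age)
    event <- as.integer(tt <= config$admin_censor_age)

    selected <- rep(1L, n)
    if (!is.null(config$selection)) {
      co <- config$selection
      eta <- (co$intercept %||% 0) +
        (co$age %||% 0) * (entry - mean(config$entry_age_range)) +
        (co$sex %||% 0) * sex +
        (co$confounder %||% 0) * U +
        (co$exposure %||% 0) * (exposure - config$exposure_mean)
      selected <- stats::rbinom(n, 1L, stats::plogis(eta))
    }

    cohort <- data.frame(
      id = seq_len(n),
      score = score,
      exposure = exposure,
      entry_age = entry,
      exit_age = exit,
      event = event,
      sex = sex,
      age_at_baseline = entry,
      confounder = U,
      selected = selected
    )
    cohort <- cbind(cohort, as.data.frame(G))
    attr(cohort, "sim_config") <- config
    cohort
  })
}

#' Restrict a cohort to its selected participants
#'
#' Applies the participation mechanism drawn by [simulate_cohort()]: keeps
#' the rows with `selected == 1` and records the selection fraction. Used by
#' the selection-bias experiment to emulate non-random recruitment into a
#' study.
#'
#' @param cohort a cohort `data.frame` carrying a 0/1 `selected` column.
#' @return The selected subset, with attribute `"selection_fraction"`.
#' @export
apply_selection <- function(cohort) {
  if (!"selected" %in% names(cohort))
    stop_ctx("cohort has no `selected` column")
  keep <- cohort$selected == 1L
  if (!any(keep))
    stop_ctx("no individuals selected; weaken the selection coefficients ",
             "(e.g. a less negative intercept)")
  out <- cohort[keep, , drop = FALSE]
  attr(out, "selection_fraction") <- mean(keep)
  attr(out, "sim_config") <- attr(cohort, "sim_config")
  out
}

#' Validate a cohort table
#'
#' Checks the row-level contracts every analysis function relies on:
#' `exit_age > entry_age`, `event` in \{0, 1\}, finite score and exposure.
#'
#' @param cohort a cohort `data.frame`.
#' @param require character vector of required column names.
#' @return Invisibly, the cohort.
#' @keywords internal
validate_cohort <- function(cohort,
                            require = c("score", "exposure", "entry_age",
                                        "exit_age", "event")) {
  missing <- setdiff(require, names(cohort))
  if (length(missing))
    stop_ctx("cohort is missing columns: ", paste(missing, collapse = ", "))
  if (any(cohort$exit_age <= cohort$entry_age))
    stop_ctx("exit_age must exceed entry_age for every row")
  if (!all(cohort$event %in% c(0L, 1L)))
    stop_ctx("event must be 0/1")
  if ("score" %in% names(cohort) && any(!is.finite(cohort$score)))
    stop_ctx("score must be finite")
  invisible(cohort)
}
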