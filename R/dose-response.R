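#' Dose-response curves for the cohort simulator
#'
#' Constructors for the causal exposure to log-hazard mappings understood by
#' [simulate_cohort()]. All curves are parameterised relative to the
#' conventional BMI reference of 25 kg/m^2, so that the Weibull baseline
#' hazard of the simulator is the hazard of an individual at the reference
#' exposure: `dose_linear(beta)` contributes `beta * (x - 25)` to the
#' log-hazard, `dose_quadratic(beta1, beta2)` contributes
#' `beta1 * (x - 25) + beta2 * (x - 25)^2`, and `dose_jshape()` is piecewise
#' linear with a kink at its `minimum` (slope `slope_low` below it,
#' `slope_high` above it), the qualitative J-shape reported for adiposity
#' and mortality.
#'
#' @param beta,beta1,beta2 slope coefficients on the log-hazard scale, per
#'   kg/m^2 of exposure.
#' @param minimum exposure value (kg/m^2) at which the J-shaped curve attains
#'   its minimum.
#' @param slope_low,slope_high log-hazard slopes per kg/m^2 below and above
#'   the minimum.
#' @return An object of class `"dose_response"`: a list with elements
#'   `family` and the curve parameters, evaluable via `dose_eval()`.
#' @examples
#' curve <- dose_jshape()
#' dose_eval(curve, c(20, 25, 30))
#' @export
dose_linear <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  structure(list(family = "linear", beta = beta), class = "dose_response")
}

#' @rdname dose_linear
#' @export
dose_quadratic <- function(beta1, beta2) {
  stopifnot(is.finite(beta1), is.finite(beta2))
  structure(list(family = "quadratic", beta1 = beta1, beta2 = beta2),
            class = "dose_response")
}

#' @rdname dose_linear
#' @export
dose_jshape <- function(minimum = 25, slope_low = -0.05, slope_high = 0.05) {
  stopifnot(is.finite(minimum), is.finite(slope_low), is.finite(slope_high))
  structure(list(family = "jshape", minimum = minimum,
                 slope_low = slope_low, slope_high = slope_high),
            class = "dose_response")
}

#' @rdname dose_linear
#' @param curve a `"dose_response"` object.
#' @param x numeric vector of exposure values (kg/m^2).
#' @export
dose_eval <- function(curve, x) {
  stopifnot(inherits(curve, "dose_response"))
  switch(curve$family,
    linear = curve$beta * (x - 25),
    quadratic = curve$beta1 * (x - 25) + curve$beta2 * (x - 25)^2,
    jshape = ifelse(x < curve$minimum,
                    curve$slope_low * (x - curve$minimum),
                    curve$slope_high * (x - curve$minimum)),
    stop_ctx("unknown dose_response family: ", curve$family)
  )
}

#' @export
print.dose_response <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("dose_response:", x$family, "(",
      paste(names(pars), unlist(pars), sep = " = ", collapse = ", "),
      ") on the log-hazard scale, reference 25 kg/m^2\n")
  invisible(x)
}
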