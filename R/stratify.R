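#' Stratify a cohort on the exposure for non-linear Mendelian randomisation
#'
#' Partitions the analytic sample into `q` ordered strata by one of two
#' methods.
#'
#' **Residual method** (`method = "residual"`): the exposure is regressed on
#' the instrument (the genetic score, plus any declared covariates) by least
#' squares; strata are near-equal-size quantile groups of the residual,
#' lowest residuals in stratum 1. The residual is independent of the
#' instrument by construction, but instrument validity within strata
#' additionally requires the instrument's effect on the exposure to be the
#' same for everyone (the constant genetic effect assumption).
#'
#' **Doubly-ranked method** (`method = "doubly_ranked"`): individuals are
#' sorted by instrument value and cut into consecutive prestrata of size
#' `q`; within each prestratum the k-th smallest exposure is assigned to
#' stratum k. Each prestratum therefore contributes exactly one member to
#' each stratum. This requires only the weaker rank-preserving assumption:
#' that the ordering of individuals by exposure would be unchanged at any
#' fixed instrument value.
#'
#' Instrument ties are broken by a seeded random perturbation applied to the
#' ranks only (stored values are never modified). When `n` is not a
#' multiple of `q`, `n mod q` individuals are removed by a seeded random
#' draw before forming prestrata and listed in `trimmed_ids`; the residual
#' method uses all rows.
#'
#' @param cohort cohort `data.frame` with columns `score`, `exposure` (and
#'   `id`; row numbers are used if absent).
#' @param q number of strata, >= 2.
#' @param method `"doubly_ranked"` or `"residual"`.
#' @param covariates character vector of cohort columns to include in the
#'   residualising regression (residual method only; default none, i.e.
#'   regression on the score alone).
#' @param seed integer seed governing tie-breaks and trimming.
#' @return An object of class `"strata_assignment"`: list with `method`,
#'   `q`, `stratum_of` (named integer vector, id -> stratum in 1..q),
#'   `trimmed_ids`, `seed`, `stratum_means` (mean exposure), and
#'   `stratum_sizes`.
#' @examples
#' ch <- data.frame(id = LETTERS[1:6], score = 1:6,
#'                  exposure = c(10, 5, 8, 9, 2, 7))
#' stratify(ch, q = 2)
#' @export
stratify <- function(cohort, q, method = c("doubly_ranked", "residual"),
                     covariates = NULL, seed = 1L) {
  method <- match.arg(method)
  if (!is_count(q) || q < 2) stop_ctx("q must be an integer >= 2")
  need <- c("score", "exposure")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop_ctx("cohort missing columns: ", paste(missing, collapse = ", "))
  n <- nrow(cohort)
  if (n < q) stop_ctx("n (", n, ") must be at least q (", q, ")")
  bad <- !is.finite(cohort$score) | !is.finite(cohort$exposure)
  if (any(bad)) {
    ids <- if ("id" %in% names(cohort)) cohort$id[bad] else which(bad)
    stop_ctx("non-finite score or exposure for ids: ",
             paste(utils::head(ids, 10L), collapse = ", "))
  }
  ids <- as.character(if ("id" %in% names(cohort)) cohort$id else seq_len(n))

  if (method == "residual") {
    if (n < 2 * q) stop_ctx("residual method needs n >= 2q")
    if (stats::var(cohort$exposure) == 0) stop_ctx("constant exposure")
    if (stats::var(cohort$score) == 0) stop_ctx("score has zero variance")
    rhs <- c("score", covariates)
    fml <- stats::reformulate(rhs, response = "exposure")
    res <- stats::resid(stats::lm(fml, data = cohort))
    u <- with_seed(seed, stats::runif(n))
    r <- order(order(res, u))  # residual ranks, ties broken by seeded u
    stratum <- as.integer(ceiling(r * q / n))
    keep_ids <- ids
    trimmed <- character(0)
  } else {
    n_pre <- n %/% q
    r_extra <- n %% q
    u <- with_seed(seed, list(trim = sample.int(n, r_extra),
                              tie = stats::runif(n)))
    keep <- setdiff(seq_len(n), u$trim)
    trimmed <- ids[u$trim]
    g <- cohort$score[keep]
    x <- cohort$exposure[keep]
    tie <- u$tie[keep]
    # sort by instrument (seeded tie-break), consecutive blocks of size q
    o_score <- order(g, tie)
    prestratum <- integer(length(keep))
    prestratum[o_score] <- rep(seq_len(n_pre), each = q)
    # within each prestratum, k-th smallest exposure -> stratum k
    o <- order(prestratum, x, tie)
    stratum <- integer(length(keep))
    stratum[o] <- rep.int(seq_len(q), n_pre)
    keep_ids <- ids[keep]
  }

  names(stratum) <- keep_ids
  x_kept <- cohort$exposure[match(keep_ids, ids)]
  means <- as.vector(tapply(x_kept, stratum, mean))
  sizes <- as.vector(table(factor(stratum, levels = seq_len(q))))
  structure(list(method = method, q = as.integer(q), stratum_of = stratum,
                 trimmed_ids = trimmed, seed = as.integer(seed),
                 stratum_means = means, stratum_sizes = sizes),
            class = "strata_assignment")
}

#' @export
print.strata_assignment <- function(x, ...) {
  cat("strata_assignment:", x$method, "| q =", x$q,
      "| n =", length(x$stratum_of),
      "| trimmed =", length(x$trimmed_ids),
      "| seed =", x$seed, "\n")
  cat("  stratum mean exposure: ",
      paste(sprintf("%.2f", utils::head(x$stratum_means, 5L)),
            collapse = ", "),
      if (x$q > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Per-stratum instrument strength
#'
#' Within each stratum, the least-squares slope (and SE) of the exposure on
#' the genetic score standardised to unit SD over the analytic sample,
#' optionally adjusted for covariates. Under a constant genetic effect these
#' slopes are equal across strata; a rising profile across doubly-ranked
#' strata is the diagnostic that the constant-effect assumption — and hence
#' the residual stratification method — fails. The attribute
#' `"top_bottom_ratio"` is the slope in the top stratum divided by that in
#' the bottom stratum.
#'
#' @param cohort cohort `data.frame`.
#' @param assignment a [stratify()] result for this cohort.
#' @param covariates character vector of adjustment columns (default none).
#' @return `data.frame` with columns `stratum`, `n`, `mean_exposure`,
#'   `beta`, `se`, `flag` (`"ok"` or `"zero_score_variance"`), and
#'   attribute `"top_bottom_ratio"`.
#' @export
stratum_instrument_strength <- function(cohort, assignment,
                                        covariates = NULL) {
  stopifnot(inherits(assignment, "strata_assignment"))
  dat <- cohort_by_stratum(cohort, assignment)
  sd_g <- stats::sd(dat$score)
  if (!is.finite(sd_g) || sd_g == 0) stop_ctx("score has zero variance")
  dat$score_std <- dat$score / sd_g
  rhs <- c("score_std", covariates)
  fml <- stats::reformulate(rhs, response = "exposure")
  out <- lapply(split(dat, dat$.stratum), function(d) {
    if (nrow(d) < 3L || stats::var(d$score_std) == 0)
      return(data.frame(stratum = d$.stratum[1L], n = nrow(d),
                        mean_exposure = mean(d$exposure),
                        beta = NA_real_, se = NA_real_,
                        flag = "zero_score_variance"))
    fit <- stats::lm(fml, data = d)
    cf <- summary(fit)$coefficients["score_std", ]
    data.frame(stratum = d$.stratum[1L], n = nrow(d),
               mean_exposure = mean(d$exposure),
               beta = cf[["Estimate"]], se = cf[["Std. Error"]], flag = "ok")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$stratum), ]
  ok <- out$flag == "ok"
  ratio <- if (ok[1L] && ok[nrow(out)])
    out$beta[nrow(out)] / out$beta[1L] else NA_real_
  attr(out, "top_bottom_ratio") <- ratio
  out
}

# join stratum index onto the cohort rows that were assigned
cohort_by_stratum <- function(cohort, assignment) {
  ids <- as.character(if ("id" %in% names(cohort)) cohort$id
                      else seq_len(nrow(cohort)))
  idx <- match(names(assignment$stratum_of), ids)
  if (anyNA(idx))
    stop_ctx("assignment ids not found in cohort; was the assignment built ",
             "from this cohort?")
  dat <- cohort[idx, , drop = FALSE]
  dat$.stratum <- unname(assignment$stratum_of)
  dat
}
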