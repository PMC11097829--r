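#' Construct a weighted genetic score
#'
#' Computes the externally weighted allele score
#' `score_i = sum_v dosage_iv * weight_v`: the number of exposure-increasing
#' alleles carried at each variant multiplied by that variant's published
#' per-allele association with the exposure, summed over variants. Effect
#' alleles are assumed pre-harmonised between the dosage columns and the
#' weights table.
#'
#' Rows with a missing dosage at any scored variant are excluded by default
#' (score `NA`), mirroring the usual analytic exclusion of participants
#' without complete variant data; `missing = "mean"` instead imputes the
#' per-variant mean dosage, with a message.
#'
#' @param genotypes matrix or data.frame of per-variant dosages in \[0, 2\],
#'   columns named by variant id.
#' @param weights a weights table from [read_weights()] or any data.frame
#'   with columns `variant_id` and `weight` (optionally `effect_allele`).
#' @param standardize if `TRUE`, divide by the sample SD of the score so it
#'   is on the per-1-SD reporting scale.
#' @param missing `"exclude"` (default) or `"mean"`.
#' @return Numeric score vector, `NA` for excluded rows; attribute
#'   `"n_excluded"` counts them.
#' @examples
#' g <- cbind(rs1 = c(2, 1, 0), rs2 = c(1, 1, 2), rs3 = c(0, 0, 1))
#' w <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
#'                 weight = c(0.1, 0.05, 0.3))
#' build_score(g, w)
#' @export
build_score <- function(genotypes, weights, standardize = FALSE,
                        missing = c("exclude", "mean")) {
  missing <- match.arg(missing)
  if (!is.data.frame(weights) ||
      !all(c("variant_id", "weight") %in% names(weights)))
    stop_ctx("weights must have columns variant_id and weight")
  if (anyDuplicated(weights$variant_id))
    stop_ctx("duplicate variant_id in weights table")
  if (any(!is.finite(weights$weight)))
    stop_ctx("weights must be finite")
  if (all(weights$weight == 0))
    stop_ctx("all weights are zero: degenerate instrument")
  G <- as.matrix(genotypes)
  absent <- setdiff(weights$variant_id, colnames(G))
  if (length(absent))
    stop_ctx("variants in weights absent from genotypes: ",
             paste(absent, collapse = ", "))
  G <- G[, weights$variant_id, drop = FALSE]
  rng <- range(G, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2)
    stop_ctx("dosages must lie in [0, 2]")
  n_excluded <- 0L
  if (anyNA(G)) {
    if (missing == "mean") {
      mu <- colMeans(G, na.rm = TRUE)
      idx <- which(is.na(G), arr.ind = TRUE)
      G[idx] <- mu[idx[, 2L]]
      message("mean-imputed ", nrow(idx), " missing dosages across ",
              length(unique(idx[, 2L])), " variants")
    } else {
      n_excluded <- sum(!stats::complete.cases(G))
    }
  }
  score <- as.vector(G %*% weights$weight)
  if (standardize) {
    s <- stats::sd(score, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop_ctx("score has zero variance; cannot standardize")
    score <- score / s
  }
  attr(score, "n_excluded") <- n_excluded
  score
}

#' Inverse-normal rank transform
#'
#' Maps the value at (mid-)rank `r` to the standard-normal quantile of
#' `(r - 3/8) / (n + 1/4)` (Blom offset). Ties receive their average rank.
#' Used as a sensitivity analysis for the exposure scale: the transform is a
#' strictly monotone function of the ranks, so stratification and ordering
#' are preserved.
#'
#' @param values numeric vector, length >= 2, no missing values.
#' @return Numeric vector of the same length.
#' @examples
#' inverse_normal_transform(c(3, 1, 2))
#' @export
inverse_normal_transform <- function(values) {
  if (anyNA(values)) stop_ctx("missing values not allowed")
  n <- length(values)
  if (n < 2L) stop_ctx("need at least 2 values")
  if (length(unique(values)) == 1L)
    stop_ctx("all values identical: transform undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}
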