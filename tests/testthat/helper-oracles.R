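# Independent oracles, written from the definitions and kept free of any
# package internals.

# Brute-force double ranking: sort by instrument, cut consecutive blocks of
# size q (prestrata), assign the k-th smallest exposure in each block to
# stratum k. Requires n divisible by q and no ties.
oracle_doubly_ranked <- function(score, exposure, q) {
  n <- length(score)
  stopifnot(n %% q == 0, !anyDuplicated(score), !anyDuplicated(exposure))
  o <- order(score)
  stratum <- integer(n)
  for (b in seq_len(n %/% q)) {
    idx <- o[((b - 1L) * q + 1L):(b * q)]
    stratum[idx[order(exposure[idx])]] <- seq_len(q)
  }
  stratum
}

# Explicit Efron partial log-likelihood for left-truncated survival data
# with a single covariate.
oracle_efron_loglik <- function(beta, entry, exit, event, z) {
  eta <- beta * z
  ll <- 0
  for (t in sort(unique(exit[event == 1]))) {
    D <- which(event == 1 & exit == t)
    R <- which(entry < t & exit >= t)
    d <- length(D)
    sum_d <- sum(exp(eta[D]))
    sum_r <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) ll <- ll - log(sum_r - l / d * sum_d)
  }
  ll
}

oracle_efron_mle <- function(entry, exit, event, z, interval = c(-8, 8)) {
  stats::optimize(function(b) oracle_efron_loglik(b, entry, exit, event, z),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Closed-form inverse-variance weighted simple regression (for trend test).
oracle_wls_line <- function(x, y, se) {
  w <- 1 / se^2
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  se_slope <- sqrt(1 / sum(w * (x - xb)^2))
  list(slope = slope, se = se_slope)
}

# Exposure-quantile ("naive") stratification, used only to demonstrate the
# collider it induces; not part of the package API.
naive_exposure_strata <- function(exposure, q) {
  n <- length(exposure)
  as.integer(ceiling(rank(exposure, ties.method = "first") * q / n))
}

surv_formula <- survival::Surv(entry_age, exit_age, event) ~ exposure | score
age_sex_covs <- c("age_at_baseline", "I(age_at_baseline^2)", "sex")

ivw_mean <- function(laceset) {
  w <- 1 / laceset$se^2
  sum(w * laceset$lace) / sum(w)
}
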