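test_that("cox_association solves the hand-written partial likelihood", {
  # 4 subjects, events at distinct times in id order, z = (1,0,1,0):
  # the score equation reduces to u^2 - u - 4 = 0 with u = exp(beta)
  d <- data.frame(entry_age = 0, exit_age = 1:4, event = 1,
                  score = c(1, 0, 1, 0))
  fit <- cox_association(d)
  expect_equal(fit$beta, log((1 + sqrt(17)) / 2), tolerance = 1e-6)
  expect_equal(fit$events, 4L)
})

test_that("cox_association agrees with a numerically maximised Efron likelihood", {
  set.seed(99)
  for (rep in 1:8) {
    n <- sample(8:20, 1)
    d <- data.frame(entry_age = runif(n, 0, 2),
                    score = rnorm(n))
    d$exit_age <- d$entry_age + sample(1:6, n, replace = TRUE) / 2  # ties
    d$event <- rbinom(n, 1, 0.8)
    if (sum(d$event) < 2) d$event[1:2] <- 1L
    got <- cox_association(d)
    want <- oracle_efron_mle(d$entry_age, d$exit_age, d$event, d$score)
    if (got$flag == "ok") expect_equal(got$beta, want, tolerance = 1e-6)
  }
})

test_that("cox_association enforces its contracts", {
  d <- data.frame(entry_age = 0, exit_age = 1:4, event = 1,
                  score = c(1, 0, 1, 0))
  d0 <- d; d0$event <- 0
  expect_error(cox_association(d0), "no events")
  dbad <- d; dbad$entry_age[2] <- 9
  expect_error(cox_association(dbad), "exceed entry_age")
  dconst <- d; dconst$score <- 1
  expect_error(cox_association(dconst), "inestimable")
})

test_that("LACE is the coefficient ratio with a delta-method SE", {
  ch <- simulate_cohort(sim_config(n_individuals = 4000,
                                   dose_response = dose_linear(0.03),
                                   seed = 41))
  asg <- stratify(ch, 4, method = "doubly_ranked", seed = 1)
  lt <- lace(ch, asg, covariates = age_sex_covs)
  expect_s3_class(lt, "lace_set")
  expect_equal(lt$lace, lt$beta_gy / lt$beta_gx, tolerance = 1e-12)
  expect_equal(lt$se, lt$se_gy / abs(lt$beta_gx), tolerance = 1e-12)
  expect_true(all(diff(lt$mean_exposure) > 0))

  lt2 <- lace(ch, asg, covariates = age_sex_covs, second_order = TRUE)
  expect_equal(lt2$se,
               sqrt(lt$se_gy^2 / lt$beta_gx^2 +
                      lt$beta_gy^2 * lt$se_gx^2 / lt$beta_gx^4),
               tolerance = 1e-12)
  expect_true(all(lt2$se > lt$se))
})

test_that("LACE is invariant to rescaling the score", {
  ch <- simulate_cohort(sim_config(n_individuals = 3000, seed = 43))
  asg <- stratify(ch, 3, method = "doubly_ranked", seed = 1)
  lt <- lace(ch, asg)
  ch2 <- ch
  ch2$score <- 17.3 * ch$score
  asg2 <- stratify(ch2, 3, method = "doubly_ranked", seed = 1)
  lt2 <- lace(ch2, asg2)
  expect_equal(lt2$lace, lt$lace, tolerance = 1e-9)
  expect_equal(lt2$se, lt$se, tolerance = 1e-9)
})

test_that("stratified pipeline recovers a linear causal effect", {
  ch <- simulate_cohort(sim_config(n_individuals = 20000,
                                   dose_response = dose_linear(0.03),
                                   heterogeneity = 1, seed = 47))
  asg <- stratify(ch, 20, method = "doubly_ranked", seed = 1)
  lt <- lace(ch, asg, covariates = age_sex_covs)
  w <- 1 / lt$se^2
  est <- ivw_mean(lt)
  expect_lt(abs(est - 0.03), 3 * sqrt(1 / sum(w)))
})

test_that("null-effect z-statistics reject at the nominal rate", {
  z <- unlist(lapply(1:20, function(s) {
    ch <- simulate_cohort(sim_config(n_individuals = 10000,
                                     dose_response = dose_linear(0),
                                     seed = 600 + s))
    asg <- stratify(ch, 10, method = "doubly_ranked", seed = s)
    lt <- lace(ch, asg, covariates = age_sex_covs)
    lt$lace / lt$se
  }))
  frac <- mean(abs(z) > 1.96)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.11)
})

test_that("weak-instrument strata are excluded with a reason", {
  ch <- simulate_cohort(sim_config(n_individuals = 2000, seed = 53))
  asg <- stratify(ch, 4, method = "doubly_ranked", seed = 1)
  lt <- lace(ch, asg)
  floor_mid <- sort(abs(lt$beta_gx))[2]  # excludes at least the weakest
  lt2 <- lace(ch, asg, weak_floor = floor_mid * (1 + 1e-9))
  ex <- attr(lt2, "excluded")
  expect_true(!is.null(ex) && "weak_instrument" %in% ex$reason)
  expect_lt(nrow(lt2), nrow(lt))
  expect_error(lace(ch, asg, weak_floor = Inf), "no stratum")
})

test_that("covariate checks cover zero for traits independent of the score", {
  cover <- unlist(lapply(1:10, function(s) {
    ch <- simulate_cohort(sim_config(n_individuals = 8000, seed = 700 + s))
    asg <- stratify(ch, 20, method = "doubly_ranked", seed = s)
    cc <- covariate_check(ch, asg, traits = c("sex"))
    cc <- cc[cc$stratum > 0, ]
    abs(cc$z) < qnorm(0.975)
  }))
  expect_gt(mean(cover), 0.90)   # 95% nominal coverage, binomial slack
  expect_lt(mean(cover), 0.99)
})

test_that("selection leaves its fingerprint on stratum age/sex associations", {
  mean_abs_z <- function(sel, seed) {
    cfg <- sim_config(n_individuals = 30000, selection = sel, seed = seed)
    ch <- apply_selection(simulate_cohort(cfg))
    # wide strata: within-stratum exposure variation keeps the collider
    # path from score to the selection predictors open
    asg <- stratify(ch, 5, method = "doubly_ranked", seed = 1)
    cc <- covariate_check(ch, asg,
                          traits = c("age_at_baseline", "sex"))
    mean(abs(cc$z[cc$stratum > 0]))
  }
  base <- mean_abs_z(NULL, 61)
  biased <- mean_abs_z(list(intercept = 0.7, age = -0.25, sex = -1.5,
                            exposure = -0.8), 61)
  expect_lt(base, 1.6)     # near the null mean of |N(0,1)| ~ 0.8
  expect_gt(biased, base + 0.5)
})

test_that("the exposure itself shows rising stratum associations under heterogeneity", {
  ch <- simulate_cohort(sim_config(n_individuals = 20000, heterogeneity = 2,
                                   seed = 67))
  asg <- stratify(ch, 10, method = "doubly_ranked", seed = 1)
  cc <- covariate_check(ch, asg, traits = "exposure")
  cc <- cc[cc$stratum > 0, ]
  expect_true(all(cc$beta > 0))
  expect_gt(cor(cc$stratum, cc$beta, method = "spearman"), 0.7)
  st <- stratum_instrument_strength(ch, asg)
  expect_equal(cc$beta, st$beta, tolerance = 1e-9)
})

test_that("constant traits are flagged rather than estimated", {
  ch <- simulate_cohort(sim_config(n_individuals = 1000, seed = 71))
  ch$flat <- 1
  asg <- stratify(ch, 2, method = "doubly_ranked", seed = 1)
  cc <- covariate_check(ch, asg, traits = "flat")
  expect_true(all(cc$reason == "constant_trait"))
  expect_true(all(is.na(cc$beta)))
  expect_error(covariate_check(ch, asg, traits = "nope"), "nope")
})
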