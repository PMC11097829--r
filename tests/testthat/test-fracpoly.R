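flat_lace <- function(value = 0.2, means = c(10, 15, 20, 25, 30),
                      se = 0.05) {
  data.frame(mean_exposure = means, lace = value, se = se)
}

test_that("constant LACE selects the linear power with its coefficient", {
  fit <- fit_fracpoly(flat_lace(), degree = 1)
  expect_equal(fit$powers, 1)
  expect_equal(fit$coef, 0.2, tolerance = 1e-10)
  lin <- test_linearity(flat_lace())
  expect_equal(lin$statistic, 0, tolerance = 1e-9)
  expect_equal(lin$p_value, 1, tolerance = 1e-9)
})

test_that("noiseless 1/x LACE identifies the logarithmic curve exactly", {
  ls <- data.frame(mean_exposure = c(10, 20, 25),
                   lace = 0.5 / c(10, 20, 25), se = 0.01)
  fit <- fit_fracpoly(ls, degree = 1)
  expect_equal(fit$powers, 0)
  expect_equal(fit$coef, 0.5, tolerance = 1e-9)
  # strictly better than every other degree-1 power
  for (p in setdiff(c(-2, -1, -0.5, 0.5, 1, 2, 3), 0)) {
    X <- stratamr:::fp_dbasis(ls$mean_exposure, p)
    other <- stratamr:::fp_wls(ls$lace, ls$se, X)
    expect_lt(other$loglik, fit$loglik)
  }
  # with tiny SEs the linearity test rejects at any fixed level
  ls4 <- data.frame(mean_exposure = c(10, 15, 20, 25),
                    lace = 0.5 / c(10, 15, 20, 25), se = 1e-4)
  expect_lt(test_linearity(ls4)$p_value, 1e-10)
})

test_that("curve reconstruction integrates the fitted derivative", {
  # linear fit: slope 0.2 -> curve(30) - curve(25) = 1
  fit <- fit_fracpoly(flat_lace(), degree = 1, reference = 25)
  cv <- reconstruct_curve(fit, grid = c(25, 30))
  expect_equal(cv$estimate, c(0, 1), tolerance = 1e-9)
  expect_equal(cv$se[1], 0, tolerance = 1e-12)
  expect_equal(cv$lower[1], 0, tolerance = 1e-12)
  expect_equal(cv$upper[1], 0, tolerance = 1e-12)

  # power-0 fit: beta 0.5 -> curve(x) = 0.5 log(x/25)
  ls <- data.frame(mean_exposure = c(10, 20, 25),
                   lace = 0.5 / c(10, 20, 25), se = 0.01)
  fit0 <- fit_fracpoly(ls, degree = 1, reference = 25)
  x <- c(5, 10, 25, 40)
  cv0 <- reconstruct_curve(fit0, grid = x)
  expect_equal(cv0$estimate, 0.5 * log(x / 25), tolerance = 1e-9)
  expect_error(reconstruct_curve(fit0, grid = c(-1, 10)), "positive")
})

test_that("degree-2 fit recovers a quadratic dose-response within its CI", {
  b1 <- -0.04; b2 <- 0.004   # h(x) = b1 (x-25) + b2 (x-25)^2
  means <- seq(20, 35, length.out = 12)
  truth <- function(x) b1 * (x - 25) + b2 * (x - 25)^2
  covered_all <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    ls <- data.frame(mean_exposure = means,
                     lace = b1 + 2 * b2 * (means - 25) + rnorm(12, 0, 0.01),
                     se = 0.01)
    fit <- fit_fracpoly(ls, degree = 2, reference = 25)
    cv <- reconstruct_curve(fit, grid = seq(20, 35, length.out = 60))
    all(cv$lower <= truth(cv$exposure) & truth(cv$exposure) <= cv$upper)
  }, NA)
  expect_gte(sum(covered_all), 18)
})

test_that("trend test matches closed-form weighted least squares", {
  ls <- data.frame(mean_exposure = c(10, 20, 30),
                   lace = c(0.1, 0.2, 0.3), se = 0.05)
  got <- test_trend(ls)
  want <- oracle_wls_line(ls$mean_exposure, ls$lace, ls$se)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$se, want$se, tolerance = 1e-10)
  expect_equal(got$slope, 0.01, tolerance = 1e-10)
  expect_equal(got$se, sqrt(1 / 80000), tolerance = 1e-10)
  expect_equal(got$se, 0.003536, tolerance = 1e-3)
  expect_equal(got$z, 2.828, tolerance = 1e-3)
  expect_equal(got$p_value, 0.004678, tolerance = 1e-4)

  # flat series: zero slope, p = 1
  flat <- test_trend(flat_lace())
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1, tolerance = 1e-9)

  # permutation invariance
  perm <- ls[c(3, 1, 2), ]
  expect_equal(test_trend(perm)$p_value, got$p_value, tolerance = 1e-12)
})

test_that("log-likelihoods nest: degree 2 >= degree 1 >= linear", {
  set.seed(88)
  for (rep in 1:10) {
    k <- sample(6:15, 1)
    ls <- data.frame(mean_exposure = sort(runif(k, 15, 40)),
                     lace = rnorm(k, 0.02, 0.05),
                     se = runif(k, 0.02, 0.1))
    f1 <- fit_fracpoly(ls, degree = 1)
    f2 <- fit_fracpoly(ls, degree = 2)
    lin <- stratamr:::fp_wls(ls$lace, ls$se,
                             stratamr:::fp_dbasis(ls$mean_exposure, 1))
    expect_gte(f2$loglik, f1$loglik - 1e-9)
    expect_gte(f1$loglik, lin$loglik - 1e-9)
  }
})

test_that("rescaling LACE and SE rescales the curve and preserves p-values", {
  set.seed(12)
  ls <- data.frame(mean_exposure = sort(runif(8, 18, 35)),
                   lace = rnorm(8, 0.03, 0.02), se = runif(8, 0.01, 0.05))
  c_scale <- 3.7
  ls2 <- transform(ls, lace = c_scale * lace, se = c_scale * se)
  f <- fit_fracpoly(ls, degree = 2)
  f2 <- fit_fracpoly(ls2, degree = 2)
  expect_equal(f2$powers, f$powers)
  expect_equal(f2$coef, c_scale * f$coef, tolerance = 1e-9)
  cv <- reconstruct_curve(f, grid = c(20, 25, 30))
  cv2 <- reconstruct_curve(f2, grid = c(20, 25, 30))
  expect_equal(cv2$estimate, c_scale * cv$estimate, tolerance = 1e-9)
  expect_equal(test_linearity(ls2)$p_value, test_linearity(ls)$p_value,
               tolerance = 1e-9)
  expect_equal(test_trend(ls2)$p_value, test_trend(ls)$p_value,
               tolerance = 1e-9)
})

test_that("effect-evident thresholds are read off the confidence bounds", {
  # monotone harmful curve with tight bounds: evident from the grid start
  fit <- fit_fracpoly(flat_lace(se = 0.001), degree = 1, reference = 25)
  cv <- reconstruct_curve(fit, grid = seq(20, 30, 0.5))
  ev <- effect_evident(cv)
  expect_equal(ev$harmful_above, 20)
  expect_true(is.na(ev$protective_below))

  # protective (negative slope) everywhere
  fitn <- fit_fracpoly(flat_lace(value = -0.2, se = 0.001), degree = 1)
  cvn <- reconstruct_curve(fitn, grid = seq(20, 30, 0.5))
  evn <- effect_evident(cvn)
  expect_equal(evn$protective_below, 30)
  expect_true(is.na(evn$harmful_above))
})

test_that("fracpoly contracts are enforced", {
  ls <- flat_lace()
  expect_error(fit_fracpoly(ls[1:2, ], degree = 1), "at least")
  ls_neg <- transform(ls, mean_exposure = mean_exposure - 12)
  expect_error(fit_fracpoly(ls_neg, degree = 1), "positive")
  expect_error(test_linearity(ls[1:3, ]), "4 strata")
  expect_error(test_trend(ls[1:2, ]), "3 strata")
  same <- transform(ls, mean_exposure = 25)
  expect_error(test_trend(same), "equal")
})
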