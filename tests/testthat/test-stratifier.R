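test_that("residual stratification reproduces the closed-form example", {
  ch <- data.frame(id = 1:4, score = c(0, 0, 1, 1),
                   exposure = c(1, 2, 4, 7))
  # two-group least squares: slope 4, intercept 1.5,
  # residuals (-0.5, 0.5, -1.5, 1.5)
  res <- resid(lm(exposure ~ score, data = ch))
  expect_equal(unname(res), c(-0.5, 0.5, -1.5, 1.5))
  asg <- stratify(ch, 2, method = "residual")
  expect_equal(unname(asg$stratum_of[c("1", "3")]), c(1L, 1L))
  expect_equal(unname(asg$stratum_of[c("2", "4")]), c(2L, 2L))
})

test_that("with a null instrument, residual strata equal exposure strata", {
  set.seed(11)
  ch <- data.frame(id = 1:400, score = rep(c(0, 1), 200),
                   exposure = rnorm(400))
  ch$exposure <- ch$exposure - ave(ch$exposure, ch$score)  # exact slope 0
  asg <- stratify(ch, 4, method = "residual")
  expect_equal(unname(asg$stratum_of),
               naive_exposure_strata(ch$exposure, 4))
})

test_that("doubly-ranked stratification reproduces the hand enumeration", {
  ch <- data.frame(id = LETTERS[1:6], score = 1:6,
                   exposure = c(10, 5, 8, 9, 2, 7))
  asg <- stratify(ch, 2, method = "doubly_ranked")
  expect_equal(names(asg$stratum_of)[asg$stratum_of == 1],
               c("B", "C", "E"))
  expect_equal(names(asg$stratum_of)[asg$stratum_of == 2],
               c("A", "D", "F"))
  expect_equal(asg$stratum_means, c(5, 8.667), tolerance = 1e-3)
  expect_equal(asg$stratum_sizes, c(3L, 3L))
})

test_that("remainders are trimmed to equal stratum sizes", {
  set.seed(5)
  ch <- data.frame(id = 1:13, score = rnorm(13), exposure = rnorm(13))
  asg <- stratify(ch, 4, method = "doubly_ranked", seed = 2)
  expect_length(asg$trimmed_ids, 1L)
  expect_equal(asg$stratum_sizes, rep(3L, 4))
  expect_setequal(c(names(asg$stratum_of), asg$trimmed_ids),
                  as.character(1:13))
})

test_that("tied exposures still give equal stratum means", {
  ch <- data.frame(id = 1:20, score = rnorm(20), exposure = rep(5, 20))
  asg <- stratify(ch, 4, method = "doubly_ranked", seed = 3)
  expect_equal(asg$stratum_means, rep(5, 4))
})

test_that("stratification contracts are enforced", {
  ch <- data.frame(id = 1:10, score = rnorm(10), exposure = rnorm(10))
  expect_error(stratify(ch, 1), "q must be")
  expect_error(stratify(ch, 11), "at least q")
  expect_error(stratify(data.frame(id = 1, score = 1, exposure = NaN), 2),
               "q|at least")
  chbad <- ch; chbad$exposure[4] <- NaN
  expect_error(stratify(chbad, 2), "non-finite.*4")
  chconst <- ch; chconst$exposure <- 1
  expect_error(stratify(chconst, 2, method = "residual"), "constant")
})

test_that("each prestratum contributes one member to each stratum", {
  set.seed(42)
  for (rep in 1:20) {
    q <- sample(2:8, 1)
    n_pre <- sample(2:10, 1)
    n <- q * n_pre + sample(0:(q - 1), 1)
    ch <- data.frame(id = 1:n, score = rnorm(n), exposure = rnorm(n))
    asg <- stratify(ch, q, method = "doubly_ranked", seed = rep)
    kept <- names(asg$stratum_of)
    o <- order(ch$score[match(kept, as.character(ch$id))])
    pre <- integer(length(kept))
    pre[o] <- rep(seq_len(length(kept) %/% q), each = q)
    tab <- table(pre, asg$stratum_of)
    expect_true(all(tab == 1L))
    # stratum mean exposure nondecreasing (strict here: no ties)
    expect_true(all(diff(asg$stratum_means) > 0))
  }
})

test_that("assignments are reproducible under a fixed seed", {
  ch <- data.frame(id = 1:103, score = sample(rep(1:20, 6))[1:103],
                   exposure = rnorm(103))
  a <- stratify(ch, 10, method = "doubly_ranked", seed = 9)
  b <- stratify(ch, 10, method = "doubly_ranked", seed = 9)
  expect_identical(a, b)
  d <- stratify(ch, 10, method = "doubly_ranked", seed = 10)
  expect_false(identical(a$trimmed_ids, d$trimmed_ids))
})

test_that("doubly-ranked strata keep the instrument balanced where exposure strata do not", {
  ch <- simulate_cohort(sim_config(n_individuals = 20000, heterogeneity = 1,
                                   confounder_effect_x = 2, seed = 17))
  grand <- mean(ch$score)
  dev_z <- function(stratum) {
    vapply(split(ch$score, stratum), function(g)
      abs(mean(g) - grand) / (sd(g) / sqrt(length(g))), 0)
  }
  asg <- stratify(ch, 10, method = "doubly_ranked", seed = 1)
  z_dr <- dev_z(asg$stratum_of[as.character(ch$id)])
  z_naive <- dev_z(naive_exposure_strata(ch$exposure, 10))
  expect_true(all(z_dr < 4))          # instrument independent of stratum
  expect_gt(max(z_naive), 10)         # collider: naive strata sort the score
})

test_that("a single stratum reproduces the full-sample slope", {
  ch <- simulate_cohort(sim_config(n_individuals = 500, seed = 23))
  ch$id <- seq_len(nrow(ch))
  asg <- stratify(ch, 2, method = "doubly_ranked", seed = 1)
  asg$stratum_of[] <- 1L   # collapse to one stratum
  asg$q <- 1L
  st <- stratum_instrument_strength(ch, asg)
  full <- coef(lm(exposure ~ I(score / sd(score)), data = ch))[2]
  expect_equal(st$beta[1], unname(full), tolerance = 1e-10)
})

test_that("strata export writes the assignment and its provenance", {
  ch <- data.frame(id = 1:13, score = rnorm(13), exposure = rnorm(13))
  asg <- stratify(ch, 4, method = "doubly_ranked", seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_strata(asg, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 13L)
  expect_equal(sum(tab$trimmed), 1L)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$q, 4L)
  expect_equal(side$stratum_sizes, rep(3L, 4))
})
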