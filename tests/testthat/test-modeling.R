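test_that("the similarity-score transform is 10 * (1 - rod)", {
  expect_equal(rod_transform(0), 10)
  expect_equal(rod_transform(1), 0)
  expect_equal(rod_transform(0.105), 8.95)
  expect_equal(rod_transform(c(0.2, 0.5)), c(8, 5))
  expect_error(rod_transform(-0.1), ">= 0")
})

test_that("a saturated 2x2 logistic fit recovers the cross-product ratio", {
  # hilum absent/present by metastasis status: 24/15 vs 10/88
  counts <- data.frame(
    hilum_absent = c(1, 1, 0, 0),
    metastasis = c(1, 0, 1, 0),
    n = c(24, 15, 10, 88)
  )
  dat <- counts[rep(seq_len(4), counts$n), c("hilum_absent", "metastasis")]
  fit <- fit_logistic(metastasis ~ hilum_absent, dat)
  or <- fit$coefficients$odds_ratio[fit$coefficients$term == "hilum_absent"]
  expect_equal(or, (24 * 88) / (15 * 10), tolerance = 1e-8)
  expect_equal(round(or, 6), 14.08)
  ci <- fit$coefficients[fit$coefficients$term == "hilum_absent", ]
  expect_lt(ci$ci_low, or)
  expect_gt(ci$ci_high, or)
  expect_equal(or, exp(ci$estimate))
})

test_that("a null predictor yields an odds ratio near 1", {
  set.seed(61)
  n <- 10000L
  dat <- data.frame(y = rbinom(n, 1, 0.3), x = rnorm(n))
  fit <- fit_logistic(y ~ x, dat)
  or <- fit$coefficients$odds_ratio[fit$coefficients$term == "x"]
  expect_gt(or, 0.95)
  expect_lt(or, 1.05)
})

test_that("known coefficients are recovered within 3 standard errors", {
  set.seed(62)
  n <- 5000L
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  fit <- fit_logistic(y ~ x, data.frame(x = x, y = y))
  cf <- fit$coefficients
  expect_lt(abs(cf$estimate[cf$term == "(Intercept)"] - (-1)),
            3 * cf$se[cf$term == "(Intercept)"])
  expect_lt(abs(cf$estimate[cf$term == "x"] - 0.8), 3 * cf$se[cf$term == "x"])
  expect_true(fit$converged)
  mu <- stats::fitted(fit$glm)
  expect_true(all(mu > 0 & mu < 1))
})

test_that("separation and collinearity are reported, not silently fitted", {
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  y <- as.integer(x > 0)
  fit <- suppressWarnings(fit_logistic(y ~ x, data.frame(x = x, y = y)))
  expect_true(fit$separation)
  expect_false(fit$converged)

  set.seed(63)
  dat <- data.frame(y = rbinom(40, 1, 0.5), a = rnorm(40))
  dat$b <- 2 * dat$a
  expect_error(fit_logistic(y ~ a + b, dat), "collinear")
  dat$cst <- 1.5
  expect_error(fit_logistic(y ~ cst, dat), "constant")
  expect_error(fit_logistic(y ~ a, transform(dat, y = 0)), "both classes")
})

test_that("the univariable screen sizes and orders candidates correctly", {
  set.seed(64)
  n <- 137L
  dat <- data.frame(group = rep(c(1L, 0L), c(39L, 98L)))
  dat$strong <- rnorm(n, mean = dat$group * 2)
  dat$noise <- rnorm(n)
  sc <- univariable_screen(dat, c("noise", "strong"), threshold = 0.001)
  expect_identical(sc$variable, "strong")
  all_tab <- attr(sc, "all")
  expect_identical(all_tab$variable[1L], "strong")

  sc_all <- univariable_screen(dat, c("noise", "strong"), threshold = 1.0)
  expect_identical(sc_all$variable, c("strong", "noise"))
  expect_error(univariable_screen(dat, "missing_col"), "unknown")

  # pure-noise candidates pass a 0.001 screen at roughly its nominal rate
  set.seed(65)
  hits <- 0L
  for (i in 1:1000) {
    dat$noise <- rnorm(n)
    p <- compare_groups(dat, "noise", "continuous")$p_value
    if (p < 0.001) hits <- hits + 1L
  }
  expect_lte(hits, 6L)
})

test_that("forward selection keeps real predictors and drops duplicates", {
  set.seed(66)
  n <- 600L
  x <- rnorm(n)
  dat <- data.frame(x = x, y = rbinom(n, 1, plogis(-1 + x)))
  spec1 <- logistic_model_spec(outcome = "y", predictors = "x")
  sel1 <- forward_select(spec1, dat)
  expect_identical(sel1$selected, "x")
  expect_s3_class(sel1$fit, "logistic_fit")

  # a duplicate column is screened in but rejected as collinear
  dat$x2 <- dat$x
  spec2 <- logistic_model_spec(outcome = "y", predictors = c("x", "x2"))
  sel2 <- forward_select(spec2, dat)
  expect_identical(sel2$selected, "x")
  expect_match(sel2$trace$action[sel2$trace$variable == "x2"], "collinear")

  # nothing passes an extreme screen: explicit empty model
  dat$pure_noise <- rnorm(n)
  spec3 <- logistic_model_spec(outcome = "y", predictors = "pure_noise",
                               enter_threshold = 1e-6)
  sel3 <- forward_select(spec3, dat)
  expect_length(sel3$selected, 0L)
  expect_null(sel3$fit)

  expect_error(logistic_model_spec(outcome = "y", predictors = c("a", "a")),
               "distinct")
})

test_that("ROD predictors enter through the transform and flip sign", {
  co <- derive_cohort_parameters(
    generate_cohort(cohort_config(n_patients = 2000L, seed = 67L))
  )
  raw <- fit_logistic(group ~ rod_att40, co)
  co$rod_att40_sim <- rod_transform(co$rod_att40)
  sim <- fit_logistic(group ~ rod_att40_sim, co)
  b_raw <- raw$coefficients$estimate[raw$coefficients$term == "rod_att40"]
  b_sim <- sim$coefficients$estimate[sim$coefficients$term == "rod_att40_sim"]
  expect_lt(b_raw, 0)
  expect_gt(b_sim, 0)
  # an affine transform rescales the coefficient exactly: beta_sim = -beta_raw/10
  expect_equal(b_sim, -b_raw / 10)

  spec <- logistic_model_spec(outcome = "group", predictors = "rod_att40",
                              transforms = c(rod_att40 = "rod_transform"))
  sel <- forward_select(spec, co)
  expect_identical(sel$selected, "rod_att40")
  b <- sel$fit$coefficients$estimate[sel$fit$coefficients$term == "rod_att40"]
  expect_gt(b, 0)
})
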