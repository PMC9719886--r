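test_that("Mann-Whitney exact p equals the enumeration oracle", {
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$statistic, 2)

  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$statistic %in% c(0, 9))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(8)
    y <- rnorm(8, 0.5)
    got <- mann_whitney(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, mw_enumeration_p(x, y))
  }
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney normal approximation tracks the exact p closely", {
  # with n1 = n2 = 8 and no ties the continuity-corrected normal
  # approximation stays within 0.015 of the exact enumeration p (its
  # worst-case error at this sample size is ~0.011)
  set.seed(52)
  for (i in 1:25) {
    x <- rnorm(8)
    y <- rnorm(8, runif(1, 0, 1.5))
    exact <- mw_enumeration_p(x, y)
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(approx - exact), 0.015)
  }
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 9, 9), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1)
  set.seed(53)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_enumeration_p(tab))
  }
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "chi_squared")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("chi-squared matches the closed form for 2x2 tables", {
  prop <- matrix(c(10, 20, 15, 30, 5, 10), 2)
  r <- chi_squared(prop)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2)

  tab <- matrix(c(10, 20, 20, 10), 2)
  want <- 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30)
  got <- chi_squared(tab)
  expect_equal(got$statistic, want)
  expect_equal(round(got$statistic, 2), 6.67)

  set.seed(54)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 8) + 1, 2)
    n <- sum(t2)
    closed <- n * (t2[1, 1] * t2[2, 2] - t2[1, 2] * t2[2, 1])^2 /
      (sum(t2[1, ]) * sum(t2[2, ]) * sum(t2[, 1]) * sum(t2[, 2]))
    expect_equal(chi_squared(t2)$statistic, closed)
  }
  expect_error(chi_squared(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("Spearman correlation uses midranks and the t approximation", {
  x <- c(1, 4, 9, 20)
  expect_equal(spearman_cor(x, x^3 + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  # tied example against a hand-computed midrank oracle
  xt <- c(1, 2, 2, 3, 5)
  yt <- c(2, 2, 4, 4, 9)
  rho_oracle <- stats::cor(rank(xt), rank(yt))
  got <- spearman_cor(xt, yt)
  expect_equal(got$rho, rho_oracle)
  tstat <- rho_oracle * sqrt(3 / (1 - rho_oracle^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), 3))

  # agreement with the reference implementation's asymptotic route
  set.seed(55)
  xr <- rnorm(30)
  yr <- 0.5 * xr + rnorm(30)
  ref <- suppressWarnings(stats::cor.test(xr, yr, method = "spearman",
                                          exact = FALSE))
  expect_equal(spearman_cor(xr, yr)$rho, unname(ref$estimate))

  # invariance under strictly monotone transforms
  expect_equal(spearman_cor(exp(xr), yr)$rho, spearman_cor(xr, yr)$rho)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("compare_groups dispatches tests and reports exclusions", {
  co <- derive_cohort_parameters(generate_cohort(cohort_config(seed = 8L)))
  cont <- compare_groups(co, "rod_att40", "continuous")
  expect_equal(cont$test, "Mann-Whitney U")
  # similarity is higher (ROD smaller) in the metastasis group
  expect_lt(cont$summary$mean[cont$summary$group == "metastasis"],
            cont$summary$mean[cont$summary$group == "non_metastasis"])

  cat2 <- compare_groups(co, "hilum_present", "categorical")
  expect_equal(cat2$test, "Fisher exact")
  cat3 <- compare_groups(co, "nuclear_grade", "categorical")
  expect_equal(cat3$test, "chi-squared")
  expect_gt(cat3$n_excluded, 0)

  expect_error(compare_groups(co, "not_a_column", "continuous"), "unknown")

  # degenerate single-patient group: range collapses to that value
  co2 <- co[c(which(co$group == 1)[1L], which(co$group == 0)), ]
  one <- compare_groups(co2, "ki67_pct", "continuous")
  met_row <- one$summary[one$summary$group == "metastasis", ]
  expect_equal(met_row$min, met_row$max)
  expect_equal(met_row$n, 1)
})

test_that("compare_groups holds its type-I error rate under the null", {
  set.seed(56)
  n_rep <- 1000L
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    dat <- data.frame(group = rep(c(0L, 1L), each = 30L), v = rnorm(60))
    p <- compare_groups(dat, "v", "continuous")$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_rep, 0.03)
  expect_lt(rejections / n_rep, 0.07)
})
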