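test_that("RM-ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(19)
  for (i in 1:5) {
    m <- matrix(rnorm(15, 0.45, 0.08), 5, 3)
    got <- rm_anova_gg(m, pairwise = FALSE)
    ora <- oracle_rm_anova(m)
    expect_equal(got$f_value, ora$f, tolerance = 1e-10)
    expect_equal(got$epsilon_gg, ora$eps, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p_gg, tolerance = 1e-10)
    expect_equal(got$eta_squared, ora$eta2, tolerance = 1e-10)
    expect_equal(got$partial_eta_squared, ora$peta2, tolerance = 1e-10)
  }
})

test_that("RM-ANOVA agrees with car::Anova as an independent package check", {
  skip_if_not_installed("car")
  set.seed(23)
  m <- matrix(rnorm(40, 0.45, 0.05), 10, 4) +
    outer(rnorm(10, 0, 0.03), rep(1, 4))
  got <- rm_anova_gg(m, pairwise = FALSE)
  fit <- lm(m ~ 1)
  s <- summary(car::Anova(fit, idata = data.frame(cond = factor(1:4)),
                          idesign = ~cond, type = 3),
               multivariate = FALSE)
  expect_equal(got$f_value, unname(s$univariate.tests[2, 5]),
               tolerance = 1e-8)
  expect_equal(got$epsilon_gg, unname(s$pval.adjustments[1, 1]),
               tolerance = 1e-8)
  expect_equal(got$mauchly_w, unname(s$sphericity.tests[1, 1]),
               tolerance = 1e-8)
  expect_equal(got$mauchly_p, unname(s$sphericity.tests[1, 2]),
               tolerance = 1e-8)
})

test_that("degenerate designs behave as the model dictates", {
  # identical columns: zero effect sum of squares
  m <- matrix(rep(c(0.4, 0.5, 0.45, 0.42), 3), 4, 3)
  expect_equal(rm_anova_gg(m, pairwise = FALSE)$f_value, 0)

  # two conditions: sphericity holds trivially
  set.seed(3)
  m2 <- matrix(rnorm(20, 0.5, 0.05), 10, 2)
  expect_equal(rm_anova_gg(m2, pairwise = FALSE)$epsilon_gg, 1)

  expect_error(rm_anova_gg(matrix(c(1, 2, NA, 4), 2, 2)), "missing")
  expect_error(rm_anova_gg(matrix(1:4, 2, 2)), "participants")
})

test_that("F is invariant to grand and participant-wise constant shifts", {
  set.seed(29)
  m <- matrix(rnorm(21, 0.45, 0.06), 7, 3)
  f0 <- rm_anova_gg(m, pairwise = FALSE)$f_value
  expect_equal(rm_anova_gg(m + 5, pairwise = FALSE)$f_value, f0)
  expect_equal(rm_anova_gg(m + rnorm(7), pairwise = FALSE)$f_value, f0)
  # epsilon bounded by its theoretical range
  e <- rm_anova_gg(m, pairwise = FALSE)$epsilon_gg
  expect_gte(e, 1 / 2)
  expect_lte(e, 1)
})

test_that("Holm adjustment equals the step-down oracle and p.adjust", {
  set.seed(31)
  m <- matrix(rnorm(24, 0.5, 0.05), 8, 3)
  pw <- holm_pairwise(m)
  expect_equal(pw$p_holm, oracle_holm(pw$p_raw))
  expect_equal(pw$p_holm, p.adjust(pw$p_raw, "holm"))
  expect_true(all(pw$p_holm >= pw$p_raw))
  # adjusted p monotone in the raw ranking
  o <- order(pw$p_raw)
  expect_true(all(diff(pw$p_holm[o]) >= 0))
  # smallest raw p multiplied by the number of tests in the first step
  expect_equal(min(pw$p_holm), min(1, min(pw$p_raw) * nrow(pw)))
})

test_that("null data reject at about alpha after GG correction", {
  set.seed(37)
  n_rep <- 400
  rej <- 0
  for (i in seq_len(n_rep)) {
    m <- matrix(rnorm(7 * 10, 0.45, 0.05), 10, 7) +
      outer(rnorm(10, 0, 0.08), rep(1, 7))
    if (rm_anova_gg(m, pairwise = FALSE)$p_value < 0.05) rej <- rej + 1
  }
  rate <- rej / n_rep
  # GG is mildly conservative under sphericity; allow the usual MC band
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
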