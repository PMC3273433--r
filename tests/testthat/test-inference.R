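none_row <- function() cross_counts("none", 99, 1283, 146, 106)

test_that("log-likelihood honors the impossible-observation contract", {
  p0 <- segregation_params(0, 0)
  clean <- cross_counts("wt", 10, 500, 0, 0)
  expect_equal(log_likelihood(p0, clean), 0)  # single-class multinomial
  dirty <- cross_counts("x", 10, 500, 3, 0)
  expect_identical(log_likelihood(p0, dirty), -Inf)
})

test_that("log-likelihood at the closed-form fit dominates a dense grid", {
  cc <- none_row()
  fit <- fit_mle(cc)
  orc <- oracle_grid_fit(cc$n_x0, cc$n_xxy, cc$n_other,
                         step = 5e-4, d_max = 0.6, l_max = 0.6)
  ll_fit <- log_likelihood(segregation_params(fit$d_hat, fit$l_hat), cc)
  const <- lgamma(1284) - lgamma(147) - lgamma(107) - lgamma(1032)
  expect_gte(ll_fit, orc$loglik + const)
  expect_lt(abs(fit$d_hat - orc$d), 2 * orc$step)
  expect_lt(abs(fit$l_hat - orc$l), 2 * orc$step)
  # spec-quoted rates maximize the likelihood within grid tolerance
  ll_quoted <- log_likelihood(segregation_params(0.2763, 0.2085), cc)
  expect_gte(ll_quoted, orc$loglik + const - 1e-3)
})

test_that("MLE closed form reproduces the reference fits", {
  expect_equal(fit_mle(cross_counts("wt", 1, 1000, 0, 0))$d_hat, 0)
  expect_equal(fit_mle(cross_counts("wt", 1, 1000, 0, 0))$l_hat, 0)

  f <- fit_mle(none_row())
  expect_lt(abs(f$d_hat - 0.276), 1e-3)
  expect_lt(abs(f$l_hat - 0.209), 1e-3)
  expect_false(any(f$at_boundary))
  expect_lt(f$numeric_gap, 1e-8)

  f2 <- fit_mle(cross_counts("AtSPO11-2", 71, 1187, 178, 88))
  expect_gt(f2$l_hat, f$l_hat)
})

test_that("round trip through the forward model recovers interior rates", {
  set.seed(11)
  n_cases <- 25
  for (i in seq_len(n_cases)) {
    # build exact expected counts from rational frequencies with f0 >= f2
    N <- 2000L
    n2 <- sample(10:150, 1)
    n0 <- n2 + sample(0:150, 1)
    cc <- cross_counts("synthetic", 1, N, n0, n2)
    fit <- fit_mle(cc)
    pr <- progeny_class_probabilities(segregation_params(fit$d_hat, fit$l_hat))
    expect_equal(pr$f_x0_son, n0 / N, tolerance = 1e-12)
    expect_equal(pr$f_xxy_daughter, n2 / N, tolerance = 1e-12)
    refit <- fit_mle(cross_counts("again", 1, N, n0, n2))
    expect_equal(refit$d_hat, fit$d_hat, tolerance = 1e-6)
    expect_equal(refit$l_hat, fit$l_hat, tolerance = 1e-6)
  }
})

test_that("estimates depend on counts only through (n_x0, n_xxy, N)", {
  a <- fit_mle(cross_counts("a", 99, 1283, 146, 106))
  b <- fit_mle(cross_counts("b", 7, 1283, 146, 106))
  expect_equal(a$d_hat, b$d_hat)
  expect_equal(a$l_hat, b$l_hat)
})

test_that("closed form agrees with grid search on random count tables", {
  set.seed(23)
  for (i in seq_len(100)) {
    N <- sample(200:2000, 1)
    n0 <- rbinom(1, N, 0.12)
    n2 <- rbinom(1, N - n0, 0.09)
    cc <- cross_counts("r", 1, N, n0, n2)
    fit <- fit_mle(cc)
    orc <- oracle_grid_fit(n0, n2, N - n0 - n2,
                           step = 0.004, d_max = 0.8, l_max = 0.8)
    # the (d, l) likelihood ridge is shallow, so the discrete argmax can sit
    # a couple of grid steps off the analytic optimum
    expect_lt(abs(fit$d_hat - orc$d), 3 * 0.004)
    expect_lt(abs(fit$l_hat - orc$l), 3 * 0.004)
    const <- lgamma(N + 1) - lgamma(n0 + 1) - lgamma(n2 + 1) -
      lgamma(N - n0 - n2 + 1)
    expect_gte(fit$loglik + 1e-9, orc$loglik + const)
  }
})

test_that("boundary clamping triggers when diplo-X exceeds nullo-X", {
  cc <- cross_counts("b", 10, 1000, 80, 120)
  fit <- fit_mle(cc)
  expect_true(fit$at_boundary[["l"]])
  expect_equal(fit$l_hat, 0)
  orc <- oracle_grid_fit(80, 120, 800, step = 1e-3, d_max = 0.6, l_max = 0.3)
  expect_lt(abs(fit$d_hat - orc$d), 1e-3 + 1e-9)
  expect_equal(orc$l, 0)
})

test_that("inconsistent counts raise an error", {
  # f0 large enough that d + l would exceed 1
  expect_error(fit_mle(cross_counts("impossible", 1, 100, 90, 2)),
               class = "nullox_validation_error")
})

test_that("profile and bootstrap intervals agree and shrink with N", {
  fit <- fit_mle(none_row())
  fp <- confidence_intervals(fit, method = "profile")
  fb <- confidence_intervals(fit, method = "bootstrap", seed = 99,
                             n_boot = 2000)
  for (f in list(fp, fb)) {
    expect_true(f$ci_d[["lower"]] < fit$d_hat && fit$d_hat < f$ci_d[["upper"]])
    expect_true(f$ci_l[["lower"]] < fit$l_hat && fit$l_hat < f$ci_l[["upper"]])
  }
  expect_lt(max(abs(fp$ci_d - fb$ci_d)), 0.02)
  expect_lt(max(abs(fp$ci_l - fb$ci_l)), 0.03)

  # consistency limit: a million-progeny cross at the same frequencies
  big <- cross_counts("big", 1, 1283000, 146000, 106000)
  fbig <- confidence_intervals(fit_mle(big), method = "profile")
  expect_lt(diff(fbig$ci_d), 0.01)
  expect_lt(diff(fbig$ci_l), 0.02)
  expect_lt(diff(fbig$ci_d), diff(fp$ci_d))

  # zero exceptional counts: both rates clamp, lower bounds exactly 0
  f0 <- confidence_intervals(fit_mle(cross_counts("wt", 1, 1000, 0, 0)))
  expect_identical(f0$ci_l[["lower"]], 0)
  expect_identical(f0$ci_d[["lower"]], 0)
  expect_error(confidence_intervals(fit, method = "bootstrap"),
               class = "nullox_config_error")
  expect_error(confidence_intervals(fit, level = 1.2),
               class = "nullox_domain_error")
})

test_that("likelihood-ratio comparison behaves at the null and on real rows", {
  none <- none_row()
  self <- compare_to_control(none, cross_counts("copy", 99, 1283, 146, 106))
  expect_equal(self$lrt$stat, 0, tolerance = 1e-6)
  expect_equal(self$lrt$p_value, 1, tolerance = 1e-6)
  expect_equal(self$lrt_l_only$stat, 0, tolerance = 1e-6)

  at2 <- compare_to_control(cross_counts("AtSPO11-2", 71, 1187, 178, 88), none)
  # the multinomial LRT detects the loss-rate increase at the 5% level;
  # it is far less extreme than the published 2x2 chi test, whose binomial
  # treatment of the excess count understates its variance
  expect_lt(at2$lrt_l_only$p_value, 0.05)
  expect_gt(at2$lrt_l_only$stat, 0)
  expect_lte(at2$lrt_l_only$stat, at2$lrt$stat + 1e-6)

  degenerate <- suppressWarnings(
    compare_to_control(cross_counts("empty", 1, 0, 0, 0), none))
  expect_true(degenerate$flagged)
  expect_true(is.na(degenerate$lrt$p_value))
})
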