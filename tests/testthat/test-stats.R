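test_that("fertility percent reproduces the published rows and handles edges", {
  expect_identical(
    fertility_percent(fecundity_record("hom", 107, 6109, 1568))$percent, 26L)
  expect_identical(
    fertility_percent(fecundity_record("het", 37, 3768, 3309))$percent, 88L)
  expect_identical(
    fertility_percent(fecundity_record("sterile", 10, 100, 0))$percent, 0L)
  expect_equal(fertility_percent(fecundity_record("x", 1, 6109, 1568))$raw,
               100 * 1568 / 6109)
  expect_error(fertility_percent(fecundity_record("none", 1, 0, 0)),
               class = "nullox_domain_error")
})

test_that("class frequencies round half-up to the requested precision", {
  expect_equal(class_frequency_percent(146, 1283), 11.4)
  expect_equal(class_frequency_percent(106, 1283), 8.3)
  expect_equal(class_frequency_percent(0, 50), 0.0)
  expect_equal(class_frequency_percent(3, 3434, decimals = 2), 0.09)
  expect_equal(class_frequency_percent(1, 8), 12.5)
  expect_equal(class_frequency_percent(1, 8, decimals = 0), 13)  # half-up
  expect_error(class_frequency_percent(1, 0), class = "nullox_domain_error")
  expect_error(class_frequency_percent(5, 4), class = "nullox_validation_error")
})

test_that("round_half_up breaks ties away from zero", {
  expect_equal(round_half_up(c(2.5, 3.5, -2.5, 2.44999)), c(3, 4, -3, 2))
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("excess nullo-X statistic matches the published derived column", {
  e1 <- excess_nullo(cross_counts("none", 99, 1283, 146, 106))
  expect_identical(e1$excess_count, 40L)
  expect_equal(e1$excess_percent, 3.1)
  e2 <- excess_nullo(cross_counts("AtSPO11-2", 71, 1187, 178, 88))
  expect_identical(e2$excess_count, 90L)
  expect_equal(e2$excess_percent, 7.6)
  e3 <- excess_nullo(cross_counts("balanced", 10, 1000, 10, 10))
  expect_identical(e3$excess_count, 0L)
  expect_equal(e3$excess_percent, 0.0)
  expect_true(is.na(e1$p_value) && is.na(e1$tier))
  expect_warning(excess_nullo(cross_counts("neg", 10, 1000, 5, 20)),
                 class = "nullox_warning")
})

test_that("excess chi-square equals the base-R Pearson oracle", {
  ctrl <- cross_counts("none", 99, 1283, 146, 106)
  tests <- list(cross_counts("a", 74, 1204, 138, 95),
                cross_counts("b", 71, 1187, 178, 88),
                cross_counts("c", 97, 1384, 184, 106))
  for (tc in tests) {
    got <- chi_square_excess(tc, ctrl)
    m <- matrix(c(tc$n_x0 - tc$n_xxy, tc$total_progeny - (tc$n_x0 - tc$n_xxy),
                  40, 1283 - 40), 2, byrow = TRUE)
    orc <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(got$chi2, unname(orc$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, orc$p.value, tolerance = 1e-12)
  }
})

test_that("excess chi-square is symmetric and scales linearly with counts", {
  a <- cross_counts("a", 10, 1187, 178, 88)
  b <- cross_counts("b", 10, 1283, 146, 106)
  ab <- chi_square_excess(a, b)
  ba <- chi_square_excess(b, a)
  expect_equal(ab$chi2, ba$chi2, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  a2 <- cross_counts("a2", 10, 2 * 1187, 2 * 178, 2 * 88)
  b2 <- cross_counts("b2", 10, 2 * 1283, 2 * 146, 2 * 106)
  expect_equal(chi_square_excess(a2, b2)$chi2, 2 * ab$chi2, tolerance = 1e-10)
  same <- chi_square_excess(a, a)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
})

test_that("small expected cells warn and report a Fisher P alongside", {
  t1 <- cross_counts("t", 5, 40, 3, 1)
  c1 <- cross_counts("c", 5, 45, 2, 1)
  expect_warning(res <- chi_square_excess(t1, c1), class = "nullox_warning")
  expect_false(is.na(res$fisher_p))
  expect_equal(res$fisher_p, fisher.test(res$table)$p.value, tolerance = 1e-12)
})

test_that("cytology chi-square matches its oracle and handles degenerate margins", {
  eq <- chi_square_cytology(
    cytology_counts("a", "dsb_signal", "2-8", 16, 220, 2),
    cytology_counts("b", "dsb_signal", "2-8", 16, 220, 2))
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p_value, 1)

  strong <- chi_square_cytology(
    cytology_counts("rescue", "dsb_signal", "2-8", 180, 180, 2),
    cytology_counts("none", "dsb_signal", "2-8", 16, 220, 2))
  orc <- suppressWarnings(chisq.test(
    matrix(c(180, 0, 16, 204), 2, byrow = TRUE), correct = FALSE))
  expect_equal(strong$chi2, unname(orc$statistic), tolerance = 1e-12)
  expect_lt(strong$p_value, 1e-3)
  expect_identical(strong$tier, "***")

  zero <- chi_square_cytology(
    cytology_counts("a", "dsb_signal", "2-8", 0, 100, 2),
    cytology_counts("b", "dsb_signal", "2-8", 0, 100, 2))
  expect_equal(zero$chi2, 0)
  expect_equal(zero$p_value, 1)
})

test_that("significance tiers follow the star convention at the boundaries", {
  expect_identical(significance_tier(6.9e-7), "***")
  expect_identical(significance_tier(1.6e-3), "**")
  expect_identical(significance_tier(1e-3), "**")   # boundary -> weaker tier
  expect_identical(significance_tier(1e-2), "*")
  expect_identical(significance_tier(0.049999), "*")
  expect_identical(significance_tier(5e-2), "ns")
  expect_identical(significance_tier(0.5), "ns")
  expect_error(significance_tier(1.5), class = "nullox_domain_error")
})

test_that("Wilson interval matches the direct formula", {
  for (case in list(c(0, 100), c(50, 100), c(254, 278), c(16, 220))) {
    ci <- binomial_ci(case[1], case[2])
    orc <- oracle_wilson(case[1], case[2])
    expect_equal(unname(ci), pmin(pmax(orc, 0), 1), tolerance = 1e-12)
  }
  expect_equal(binomial_ci(0, 100)[["lower"]], 0)
  ci50 <- binomial_ci(50, 100)
  expect_equal(ci50[["lower"]] + ci50[["upper"]], 1, tolerance = 1e-12)
  ci <- binomial_ci(254, 278)
  expect_true(ci[["lower"]] < 0.9137 && 0.9137 < ci[["upper"]])
  expect_error(binomial_ci(0, 0), class = "nullox_domain_error")
})
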