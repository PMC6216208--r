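test_that("trend test reproduces the RIT2 association and degenerates safely", {
  res <- catt_test(c(176, 477, 335), c(330, 1172, 1018))
  expect_equal(signif(res$p_value, 3), 1.37e-5)
  expect_equal(res$df, 1L)
  expect_false(res$degenerate)

  same <- suppressWarnings(catt_test(c(10, 20, 10), c(10, 20, 10)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_warning(mono <- catt_test(c(0, 0, 10), c(0, 0, 20)), "monomorphic")
  expect_equal(mono$statistic, 0)
  expect_equal(mono$p_value, 1)
  expect_true(mono$degenerate)
})

test_that("trend test is invariant to simultaneous genotype-order reversal", {
  set.seed(11)
  for (i in 1:20) {
    ca <- as.vector(rmultinom(1, 200, c(0.2, 0.5, 0.3))) + 1
    co <- as.vector(rmultinom(1, 300, c(0.1, 0.4, 0.5))) + 1
    expect_equal(catt_test(ca, co)$p_value,
                 catt_test(rev(ca), rev(co))$p_value)
  }
})

test_that("trend statistic matches the independent score-test implementation", {
  set.seed(23)
  for (i in 1:50) {
    ca <- as.vector(rmultinom(1, sample(50:400, 1), c(0.2, 0.5, 0.3))) + 1
    co <- as.vector(rmultinom(1, sample(50:400, 1), c(0.15, 0.45, 0.4))) + 1
    ref <- stats::prop.trend.test(ca, ca + co, score = 0:2)
    mine <- catt_test(ca, co)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("trend p agrees with the conditional permutation oracle on small tables", {
  # the conditional null is discrete, so the asymptotic p must fall inside
  # the [strict, inclusive] permutation band widened by Monte-Carlo error
  set.seed(31)
  tables <- replicate(4, list(
    case = as.vector(rmultinom(1, 150, c(0.12, 0.44, 0.44))) + 1,
    control = as.vector(rmultinom(1, 150, c(0.09, 0.42, 0.49))) + 1
  ), simplify = FALSE)
  for (tb in tables) {
    band <- catt_permutation_band(tb$case, tb$control, n_resamples = 2e4)
    p <- catt_test(tb$case, tb$control)$p_value
    expect_gte(p, band$strict - 5 * band$se)
    expect_lte(p, band$inclusive + 5 * band$se)
  }
})

test_that("genotypic 2x3 test reproduces the printed chi-squared result", {
  res <- genotypic_chi2_test(c(176, 477, 335), c(330, 1172, 1018))
  expect_equal(signif(res$p_value, 2), 6.8e-5)
  expect_equal(res$df, 2L)

  flat <- genotypic_chi2_test(c(30, 60, 30), c(60, 120, 60))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("genotypic test equals the hand-summed Pearson formula and drops empty columns", {
  ca <- c(5, 5, 0); co <- c(0, 5, 5)
  obs <- rbind(ca, co)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  hand <- sum((obs - expected)^2 / expected)
  expect_equal(genotypic_chi2_test(ca, co)$statistic, hand)

  # empty pooled column reduces df to 1
  res <- genotypic_chi2_test(c(0, 5, 5), c(0, 10, 2))
  expect_equal(res$df, 1L)
  expect_error(genotypic_chi2_test(c(0, 0, 5), c(0, 0, 9)), "fewer than 2")
})

test_that("exact HWE test reproduces printed control values and tiny enumerations", {
  expect_equal(round(hwe_exact_test(c(330, 1172, 1018)), 4), 0.8296)
  expect_equal(round(hwe_exact_test(c(58, 704, 1759)), 4), 0.2146)
  expect_equal(hwe_exact_test(c(0, 0, 200)), 1)
  # two minor alleles among n = 2: configurations het in {0, 2} have null
  # probabilities 1/3 and 2/3; observed het = 0 gives p = 1/3
  expect_equal(hwe_exact_test(c(1, 0, 1)), 1 / 3)
  expect_equal(hwe_exact_test(c(0, 2, 0)), 1)
})

test_that("exact HWE test matches the recurrence-based enumeration oracle", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    g <- as.vector(rmultinom(1, n, c(0.2, 0.4, 0.4)))
    expect_equal(hwe_exact_test(g), hwe_recurrence_p(g), tolerance = 1e-10)
  }
})

test_that("asymptotic HWE chi-square differs from the exact test where expected counts are small", {
  # the printed control value is consistent with the exact test, not the
  # 1-df asymptotic statistic, which motivates the exact default
  exact <- hwe_exact_test(c(330, 1172, 1018))
  asym <- hwe_chisq_test(c(330, 1172, 1018))$p_value
  expect_equal(round(exact, 4), 0.8296)
  expect_gt(abs(round(asym, 4) - 0.8296), 0.005)
})

test_that("allelic OR reproduces the reported estimate with Wald interval", {
  res <- allelic_or(c(176, 477, 335), c(330, 1172, 1018))
  expect_equal(round(res$or, 2), 1.27)
  expect_equal(round(res$ci_low, 2), 1.14)
  expect_equal(round(res$ci_high, 2), 1.41)
  expect_false(res$corrected)

  null <- allelic_or(c(10, 20, 10), c(10, 20, 10))
  expect_equal(null$or, 1)
  expect_lt(null$ci_low, 1)
  expect_gt(null$ci_high, 1)
})

test_that("zero allele cells trigger the Haldane-Anscombe correction", {
  res <- allelic_or(c(10, 0, 0), c(0, 0, 10))
  expect_true(res$corrected)
  expect_equal(res$or, (20.5 * 20.5) / (0.5 * 0.5))
  expect_true(is.finite(res$se))
})
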