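test_that("Pearson chi-square matches the textbook formula and known tables", {
  # published lobe-location table
  lobes <- rbind(c(17, 4, 4, 8, 6), c(25, 4, 8, 17, 5))
  res <- pearson_chi_square(lobes)
  expect_equal(res$df, 4)
  expect_equal(round(res$p_value, 3), 0.699)

  # balanced table: zero statistic, p = 1
  flat <- pearson_chi_square(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # sex table: exact Pearson statistic (no continuity correction)
  sex <- pearson_chi_square(rbind(c(13, 26), c(24, 35)))
  expect_equal(sex$df, 1)
  expect_equal(round(sex$statistic, 3), 0.539)

  # oracle: sum((O - E)^2 / E) from first principles on random tables
  set.seed(8)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(pearson_chi_square(tab)$statistic, sum((tab - e)^2 / e))
  }

  expect_error(pearson_chi_square(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("group comparison reports both tests and handles edge cases", {
  x <- c(1, 2, 3, 4, 5)
  df <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                       LD_mm = c(x, x))
  res <- compare_groups(df, "LD_mm")
  expect_equal(res$p_wilcoxon, 1)           # identical samples
  expect_equal(res$p_welch, 1)

  # constant feature: undefined test, flagged not crashed
  cst <- tibble::tibble(group = rep(c("a", "b"), each = 4), MA_mm2 = 2)
  rc <- compare_groups(cst, "MA_mm2")
  expect_true(is.na(rc$p_value))
  expect_match(rc$flag, "constant")

  # published BiA/SmA group contrast is essentially always significant
  set.seed(12)
  p_vals <- replicate(20, {
    d <- tibble::tibble(
      group = rep(c("PGL_MIA", "IAC"), c(39, 59)),
      BiA_SmA = c(rnorm(39, 1.055, 0.042), rnorm(59, 1.136, 0.080)))
    compare_groups(d, "BiA_SmA")$p_value
  })
  expect_true(all(p_vals < 0.001))

  # headline p switches between Welch and Mann-Whitney
  set.seed(13)
  d2 <- tibble::tibble(group = rep(c("a", "b"), each = 20),
                       LD_mm = rnorm(40))
  expect_equal(compare_groups(d2, "LD_mm", test = "wilcoxon")$p_value,
               compare_groups(d2, "LD_mm")$p_wilcoxon)
})

test_that("logistic fit recovers known coefficients and reports ORs", {
  set.seed(42)
  n <- 5000
  x1 <- rnorm(n, 1.10, 0.08)
  x2 <- rnorm(n, 16, 6.5)
  p <- plogis(-34.571 + 28.443 * x1 + 0.27 * x2)
  dat <- tibble::tibble(
    BiA_SmA = x1, LD_mm = x2,
    group = factor(ifelse(rbinom(n, 1, p) == 1, "IAC", "PGL_MIA"),
                   levels = c("PGL_MIA", "IAC")))
  fit <- fit_logistic(dat)
  td <- tidy(fit)
  truth <- c(-34.571, 28.443, 0.27)
  # every coefficient within its own Wald 95% CI at this n
  expect_true(all(abs(td$estimate - truth) < 1.96 * td$std_error * 1.5))
  expect_lt(max(abs(td$estimate / truth - 1)), 0.15)
  expect_false(glance(fit)$separation)

  # the printed per-mm odds ratio of LD is exp(0.27)
  expect_equal(round(exp(0.27), 3), 1.310)
})

test_that("wald coverage of the logistic fit is near nominal", {
  set.seed(77)
  truth <- c(-34.571, 28.443, 0.27)
  cover <- matrix(FALSE, 25, 3)
  for (r in 1:25) {
    n <- 2000
    x1 <- rnorm(n, 1.10, 0.08)
    x2 <- rnorm(n, 16, 6.5)
    y <- rbinom(n, 1, plogis(-34.571 + 28.443 * x1 + 0.27 * x2))
    d <- tibble::tibble(BiA_SmA = x1, LD_mm = x2,
                        group = ifelse(y == 1, "IAC", "PGL_MIA"))
    td <- tidy(fit_logistic(d))
    cover[r, ] <- abs(td$estimate - truth) <= 1.96 * td$std_error
  }
  expect_true(all(colSums(cover) >= 21))   # ~95% nominal per coefficient
})

test_that("uninformative features yield odds ratios covering one", {
  set.seed(14)
  d <- tibble::tibble(BiA_SmA = rnorm(300, 1.1, 0.05),
                      LD_mm = rnorm(300, 15, 5),
                      group = sample(c("PGL_MIA", "IAC"), 300, TRUE))
  td <- tidy(fit_logistic(d))[-1, ]
  expect_true(all(td$or_ci_lo <= 1 & td$or_ci_hi >= 1))
})

test_that("perfect separation is flagged, not silent", {
  d <- tibble::tibble(BiA_SmA = c(rep(1.0, 20), rep(1.5, 20)),
                      LD_mm = rnorm(40, 15, 1),
                      group = rep(c("PGL_MIA", "IAC"), each = 20))
  expect_warning(fit <- fit_logistic(d), "separation")
  expect_true(fit$separation)
})

test_that("the published probability equation behaves as printed", {
  # logit zero by construction on the decision line
  x1_mid <- (34.571 - 0.27 * 11.56) / 28.443
  expect_equal(published_probability(x1_mid, 11.56), 0.5, tolerance = 1e-6)

  # direct evaluation at the invasive-group means
  expect_equal(published_probability(1.136, 19.488), 0.9526, tolerance = 1e-4)

  # strictly increasing in both arguments, saturating at 1
  g <- seq(1, 1.4, by = 0.05)
  expect_true(all(diff(published_probability(g, 15)) > 0))
  expect_true(all(diff(published_probability(1.1, seq(5, 30, 5))) > 0))
  expect_equal(published_probability(5, 20), 1, tolerance = 1e-9)

  expect_error(published_probability(0.9, 10), ">= 1")
  expect_error(published_probability(1.1, -2), "> 0")
})
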