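test_that("contingency tables are built from cohort factors with dropped-record accounting", {
  fx <- run_pipeline(read_cohort(study_fixture_path()))$cohort
  tab <- build_contingency(fx, "consensus_final", "inhibitor_status")
  expect_identical(sort(as.integer(rowSums(tab)), decreasing = TRUE), c(229L, 67L))
  expect_identical(as.integer(sum(tab)), 296L)
  expect_identical(attr(tab, "dropped"), 111L)  # unknown-status records

  one_cell <- as_cohort(data.frame(
    variant_id = c("a", "b", "c"), protein_change = c("R1C", "R2C", "R3C"),
    severity = "severe", inhibitor_status = "positive"))
  one_cell$grp <- c("x", "x", "x")
  expect_error(build_contingency(one_cell, "grp", "inhibitor_status"),
               "fewer than two levels")

  all_unknown <- as_cohort(data.frame(
    variant_id = c("a", "b"), protein_change = c("R1C", "L2I"),
    severity = "severe", inhibitor_status = "unknown"))
  all_unknown$cls <- c("inter", "intra")
  expect_error(build_contingency(all_unknown, "cls", "inhibitor_status"),
               "fewer than two levels")
})

test_that("chi-square matches the hand formula and flags the expected-count rule", {
  perfect <- matrix(c(10, 10, 10, 10), 2)
  r0 <- chi_square_test(perfect)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # all margins 40 -> every expected count 20; hand sum of (O-E)^2/E = 12.8
  r1 <- chi_square_test(matrix(c(28, 12, 12, 28), 2))
  expect_equal(r1$statistic, 12.8)
  expect_identical(r1$df, 1L)
  expect_true(r1$valid)

  r2 <- chi_square_test(matrix(c(3, 1, 1, 3), 2))
  expect_false(r2$valid)

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "marginal")

  # invariance under row/column permutation and transposition
  tab <- matrix(c(28, 12, 7, 33), 2)
  s <- chi_square_test(tab)$statistic
  expect_equal(chi_square_test(tab[2:1, ])$statistic, s)
  expect_equal(chi_square_test(tab[, 2:1])$statistic, s)
  expect_equal(chi_square_test(t(tab))$statistic, s)
})

test_that("goodness-of-fit chi-square reproduces the hand computations", {
  r <- gof_chi_square(c(28, 12), c(0.5, 0.5))
  expect_equal(r$statistic, 6.4)  # (28-20)^2/20 + (12-20)^2/20
  expect_identical(r$df, 1L)
  expect_equal(gof_chi_square(c(20, 20), c(0.5, 0.5))$statistic, 0)
  expect_equal(gof_chi_square(c(40, 0), c(0.5, 0.5))$statistic, 40)
  expect_error(gof_chi_square(c(10, 10), c(1, 0)), "zero")
  expect_error(gof_chi_square(c(10, 10), c(0.6, 0.6)), "sum to 1")
})

test_that("two-proportion z test is antisymmetric and degenerates correctly", {
  eq <- two_proportion_normal_test(15, 60, 25, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  a <- two_proportion_normal_test(28, 40, 12, 40)
  b <- two_proportion_normal_test(12, 40, 28, 40)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(two_proportion_normal_test(5, 4, 1, 10), "0 <= x <= n")
})

test_that("the deleterious/neutral inhibitor-rate comparison agrees with a permutation oracle", {
  # 31/229 vs 9/67 positives: the headline cohort comparison
  r <- two_proportion_normal_test(31, 229, 9, 67)
  expect_true(r$p_value > 0.9 && r$p_value <= 1)
  # permutation oracle: fix margins (40 positives among 296), resample the
  # split hypergeometrically 1e5 times and compare |z| tails
  set.seed(20260924)
  x1 <- stats::rhyper(1e5, 229, 67, 40)
  pp <- 40 / 296
  se <- sqrt(pp * (1 - pp) * (1 / 229 + 1 / 67))
  z_perm <- (x1 / 229 - (40 - x1) / 67) / se
  p_perm <- mean(abs(z_perm) >= abs(r$statistic) - 1e-12)
  # the hypergeometric null is discrete; the observed split is the most
  # balanced achievable, so the permutation p saturates near 1
  expect_equal(r$p_value, p_perm, tolerance = 0.05)
})

test_that("z squared equals the uncorrected chi-square statistic algebraically", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(50:400, 1); n2 <- sample(50:400, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    z <- two_proportion_normal_test(x1, n1, x2, n2)$statistic
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE)
    chi <- chi_square_test(tab)$statistic
    expect_equal(z^2, chi, tolerance = 1e-9)
  }
})

test_that("Fisher's exact test agrees with direct hypergeometric enumeration", {
  enum_fisher <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    supp <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(supp, m, n, k)
    sum(probs[probs <= stats::dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  for (tab in list(matrix(c(1, 9, 9, 1), 2, byrow = TRUE),
                   matrix(c(0, 10, 10, 0), 2, byrow = TRUE),
                   matrix(c(5, 5, 5, 5), 2, byrow = TRUE),
                   matrix(c(7, 2, 3, 11), 2, byrow = TRUE))) {
    expect_equal(fisher_exact(tab)$p_value, enum_fisher(tab), tolerance = 1e-8)
  }
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
})

test_that("the chi-square test holds its nominal type-I error under a simulated null", {
  # 1e4 replicate 2x2 tables, 200 per arm, equal true proportions 0.3
  set.seed(314159)
  n <- 200L; reps <- 1e4L
  x1 <- stats::rbinom(reps, n, 0.3)
  x2 <- stats::rbinom(reps, n, 0.3)
  pp <- (x1 + x2) / (2 * n)
  ok <- pp > 0 & pp < 1
  z <- (x1[ok] - x2[ok]) / n / sqrt(pp[ok] * (1 - pp[ok]) * (2 / n))
  # z^2 is the Pearson statistic (identity checked above), so the rejection
  # rate of the chi-square test at alpha = 0.05 is the normal tail rate
  reject <- mean(2 * stats::pnorm(-abs(z)) <= 0.05)
  expect_equal(reject, 0.05, tolerance = 0.01 / 0.05)
})

test_that("test results serialize to a one-row-per-test frame", {
  res <- list(chi = chi_square_test(matrix(c(28, 12, 12, 28), 2)),
              gof = gof_chi_square(c(28, 12), c(0.5, 0.5)))
  df <- tests_to_frame(res)
  expect_identical(nrow(df), 2L)
  expect_identical(df$test, c("chi", "gof"))
  expect_true(all(df$p_value >= 0 & df$p_value <= 1))
})
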