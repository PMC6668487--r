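test_that("covariate residualization removes linear structure", {
  # constant covariates: residuals are centered values
  v <- c(3, 5, 9, 11)
  cv <- data.frame(z = rep(1, 4))
  expect_equal(as.numeric(adjustCovariates(v, cv)), v - mean(v))

  # values exactly linear in age: residuals vanish
  set.seed(4)
  age <- runif(30, 50, 80)
  ylin <- 2 + 0.3 * age
  r <- adjustCovariates(ylin, data.frame(age = age))
  expect_true(all(abs(r) < 1e-9))

  # planted confounder: adjusted correlation near zero at n = 200
  set.seed(11)
  z <- rnorm(200)
  x <- z + rnorm(200)
  y <- z + rnorm(200)
  rx <- adjustCovariates(x, data.frame(z = z))
  ry <- adjustCovariates(y, data.frame(z = z))
  expect_lt(abs(cor(rx, ry)), 0.1)
  expect_gt(cor(x, y), 0.3)  # confounding was real before adjustment

  # collinear covariates are refused by name
  cv2 <- data.frame(a = age, b = 2 * age)
  expect_error(adjustCovariates(ylin, cv2), "collinear.*b")

  # missing covariates drop subjects but keep positions
  cvm <- data.frame(age = age)
  cvm$age[3] <- NA
  expect_message(rm3 <- adjustCovariates(ylin, cvm), "dropping 1")
  expect_true(is.na(rm3[3]))
  expect_equal(attr(rm3, "used"), setdiff(1:30, 3))
})

test_that("Welch t-tests from raw data and summaries agree and flag the HAMD contrast", {
  expect_equal(welchTest(c(1, 1, 1), c(1, 1, 1)), list(t = 0, df = 4, p = 1))
  expect_equal(tTestFromSummary(5, 2, 1, 5, 2, 1)$t, 0)
  expect_equal(tTestFromSummary(5, 2, 1, 5, 2, 1)$p, 1)

  # depression-scale contrast from the demographic table: decisive
  hamd <- tTestFromSummary(31, 8.5, 1.8, 23, 3.7, 0.8)
  expect_lt(hamd$p, 0.001)
  expect_gt(hamd$t, 10)

  # raw samples constructed with exactly those moments reproduce t
  mk <- function(n, m, s) {
    z <- scale(rnorm(n))  # exact mean 0, sd 1
    as.numeric(m + s * z)
  }
  set.seed(2)
  a <- mk(31, 8.5, 1.8); b <- mk(23, 3.7, 0.8)
  raw <- welchTest(a, b)
  expect_equal(raw$t, hamd$t, tolerance = 1e-9)
  expect_equal(raw$df, hamd$df, tolerance = 1e-9)

  expect_error(tTestFromSummary(1, 0, 1, 5, 0, 1))
  expect_error(tTestFromSummary(5, 0, 0, 5, 0, 1))
})

test_that("Fisher exact p matches full enumeration over fixed margins", {
  expect_equal(fisherExact2x2(5, 5, 5, 5), 1)

  # perfectly discordant table: only the two extreme tables are as extreme
  p <- fisherExact2x2(0, 10, 10, 0)
  expect_equal(p, 2 * stats::dhyper(0, 10, 10, 10), tolerance = 1e-12)

  set.seed(8)
  for (i in 1:12) {
    tab <- as.vector(stats::rmultinom(1, size = sample(8:20, 1),
                                      prob = rep(0.25, 4)))
    if (any(tab[1] + tab[2] == 0, tab[3] + tab[4] == 0,
            tab[1] + tab[3] == 0, tab[2] + tab[4] == 0)) next
    expect_equal(fisherExact2x2(tab[1], tab[2], tab[3], tab[4]),
                 exactFisherP(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-7)
  }
  expect_error(fisherExact2x2(0, 0, 3, 4), "margin")
})

test_that("permutation test: constants, exact enumeration at 3 vs 2, affine invariance", {
  lab <- c("PSD", "PSD", "PSD", "PSND", "PSND")
  con <- suppressWarnings(permutationTest(rep(2, 5), lab, B = 200, seed = 1))
  expect_equal(con$observed_diff, 0)
  expect_equal(con$p_perm, 1)

  # tiny case: empirical p approaches the exact enumeration over C(5,3) sets
  v <- c(5.1, 4.0, 6.2, 1.0, 2.5)
  pex <- exactPermutationP(v, c(TRUE, TRUE, TRUE, FALSE, FALSE), "greater")
  pt <- permutationTest(v, lab, B = 4000, seed = 9, direction = "greater")
  expect_lt(abs(pt$p_perm - pex), 0.02)

  # positive affine rescaling leaves the p-value unchanged (same seed)
  p1 <- permutationTest(v, lab, B = 500, seed = 3, direction = "greater")
  p2 <- permutationTest(10 + 4 * v, lab, B = 500, seed = 3,
                        direction = "greater")
  expect_identical(p1$p_perm, p2$p_perm)

  # reproducibility and the +1 floor
  expect_identical(pt$p_perm,
                   permutationTest(v, lab, B = 4000, seed = 9,
                                   direction = "greater")$p_perm)
  expect_gte(pt$p_perm, 1 / 4001)
  expect_warning(permutationTest(v, lab, B = 50, seed = 1), "coarse")
})

test_that("Spearman correlation handles monotone data, ties, and covariates", {
  expect_equal(spearmanCor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCor(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearmanCor(1:10, rep(2, 10)), "constant")
  expect_error(spearmanCor(1:3, 3:1), "at least 4")

  # planted monotone association at n = 31 recovered on average
  rho_gen <- 0.7
  rhos <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    z <- rnorm(31)
    x <- z
    y <- rho_gen * z + sqrt(1 - rho_gen^2) * rnorm(31)
    spearmanCor(x, exp(y))$rho  # monotone transform leaves rho alone
  }, numeric(1))
  target <- 6 / pi * asin(rho_gen / 2)  # Gaussian-copula Spearman
  expect_lt(abs(mean(rhos) - target), 0.1)

  # covariate-adjusted: association through a shared covariate vanishes
  prhos <- vapply(1:30, function(s) {
    set.seed(2000 + s)
    z <- rnorm(60)
    x <- z + rnorm(60)
    y <- z + rnorm(60)
    spearmanCor(x, y, covariates = data.frame(z = z))$rho
  }, numeric(1))
  expect_lt(abs(mean(prhos)), 0.1)
})

test_that("Bonferroni correction multiplies, caps and preserves order", {
  expect_equal(as.numeric(bonferroni(0.01, 90)), 0.9)
  expect_equal(as.numeric(bonferroni(0.05, 90)), 1)
  p <- c(0.001, 0.04, 0.2, 0.0004)
  adj <- bonferroni(p, 10)
  expect_equal(order(adj), order(p))
  expect_equal(attr(adj, "family_size"), 10)
})
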