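test_that("mutant status applies strict read-evidence thresholds", {
  gm <- gm_from_gt(matrix(GT_HET, 2, 4))
  gm$DP[] <- 100L
  gm$AD[1, ] <- c(40L, 10L, 11L, 40L)
  gm$AD[2, ] <- 40L
  gm$DP[2, 4] <- 20L  # depth not > 20 at locus 2
  gm$AD[2, 4] <- 5L
  s <- mutant_status(gm, 1, all_variants = 1:2)
  expect_equal(unname(s), c("mutant",      # AAF 0.4, alt 40
                            "wildtype",    # alt 10 fails strict > 10
                            "mutant",      # alt 11 passes
                            "unevaluable"))# depth rule at the *other* locus
  # AAF threshold: alt 11 of depth 200 is 0.055 <= 0.1
  gm$DP[1, 3] <- 200L
  expect_equal(unname(mutant_status(gm, 1, all_variants = 1)[3]), "wildtype")
})

test_that("co-occurrence tables drop unevaluable cells and sum correctly", {
  sa <- c(a = "mutant", b = "mutant", c = "wildtype", d = "unevaluable",
          e = "wildtype")
  sb <- c(a = "mutant", b = "wildtype", c = "mutant", d = "mutant",
          e = "wildtype")
  tab <- cooccurrence_table(sa, sb)
  expect_equal(sum(tab), 4L)
  expect_equal(tab["A+", "B+"], 1L)
  expect_equal(tab["A+", "B-"], 1L)
  expect_equal(tab["A-", "B+"], 1L)
  expect_error(cooccurrence_table(c("unevaluable", "mutant"),
                                  c("mutant", "unevaluable")),
               "fewer than 2")
})

test_that("chi-squared p matches the textbook statistic", {
  # oracle: direct Pearson formula on [[20,5],[5,20]]
  tab <- matrix(c(20, 5, 5, 20), 2, 2)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expd)^2 / expd)
  expect_equal(chi_squared_cooccurrence(tab),
               pchisq(stat, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(chi_squared_cooccurrence(matrix(c(50, 0, 0, 50), 2, 2)), 1e-4)
  # independence-proportional table: statistic 0, p = 1
  expect_equal(chi_squared_cooccurrence(matrix(c(40, 10, 40, 10), 2, 2)), 1)
  expect_warning(p <- chi_squared_cooccurrence(matrix(c(5, 5, 0, 0), 2, 2)),
                 "undefined")
  expect_true(is.na(p))
})

test_that("doublet fraction matches Poisson droplet simulation", {
  expect_lt(doublet_fraction(1e-6), 1e-5)  # vanishes with lambda
  lam <- seq(0.05, 1, 0.05)
  expect_true(all(diff(doublet_fraction(lam)) > 0))  # monotone increasing
  # Monte-Carlo oracle: occupied droplets with >= 2 nuclei
  set.seed(123)
  occ <- rpois(1e6, 0.1)
  occ <- occ[occ >= 1]
  frac_mc <- mean(occ >= 2)
  se <- sqrt(frac_mc * (1 - frac_mc) / length(occ))
  expect_lt(abs(doublet_fraction(0.1) - frac_mc), 3 * se)
})

test_that("expected doublet multi-mutants match droplet co-encapsulation", {
  expect_equal(expected_doublet_multimutants(1000, 0.25, 0.25, 0), 0)
  expect_equal(expected_doublet_multimutants(500, 0.1, 0.2, 0.05),
               expected_doublet_multimutants(500, 0.2, 0.1, 0.05))
  expect_error(expected_doublet_multimutants(100, 0.3, 0.3, 0.05),
               "exclusive")
  # Monte-Carlo oracle: droplets under exclusive clones at 2*VAF fractions
  set.seed(77)
  lam <- 0.2; f_a <- 0.5; f_b <- 0.3
  occ <- rpois(4e5, lam)
  occ <- occ[occ >= 1 & occ <= 2]  # formula models doublets, not triplets
  n_barcodes <- length(occ)
  both <- vapply(occ, function(k) {
    cl <- sample(c("A", "B", "none"), k, replace = TRUE,
                 prob = c(f_a, f_b, 1 - f_a - f_b))
    any(cl == "A") && any(cl == "B")
  }, logical(1))
  obs <- sum(both)
  dfrac <- mean(occ >= 2)
  expd <- expected_doublet_multimutants(n_barcodes, f_a / 2, f_b / 2, dfrac)
  expect_lt(abs(obs - expd) / sqrt(expd), 3)  # within 3 Poisson SD
})

test_that("Poisson upper tail equals the direct series sum", {
  expect_equal(poisson_pvalue(0, 2), 1)
  tail_sum <- sum(exp(-1) / factorial(10:60))
  expect_equal(poisson_pvalue(10, 1), tail_sum, tolerance = 1e-12)
  p_seq <- vapply(1:10, poisson_pvalue, 0, expected = 2)
  expect_true(all(diff(p_seq) < 0))  # decreasing in the observed count
  expect_equal(poisson_pvalue(3, 0, expected_floor = 1e-6),
               ppois(2, 1e-6, lower.tail = FALSE))
})

test_that("full co-mutation test flags same-clone variants", {
  # 200 cells: 80 double mutants, 120 double wild-type (co-occurring clone)
  nv <- 2; nc <- 200
  gm <- gm_from_gt(matrix(GT_REF, nv, nc))
  gm$DP[] <- 100L
  gm$AD[, 1:80] <- 45L
  gm$AD[, 81:nc] <- 0L
  res <- comutation_test(gm, 1, 2, comut_config(loading_lambda = 0.1))
  expect_equal(res$observed_multimutants, 80L)
  expect_lt(res$chi2_p, 1e-4)
  expect_lt(res$poisson_p, 1e-4)
  expect_gt(res$observed_multimutants, res$expected_multimutants)
})
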