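test_that("probe normalization divides by probe count", {
  mat <- matrix(c(8, 6, 4, 2), 2, 2)
  rownames(mat) <- c("A4", "B1")
  cohort <- makeCohort(mat, n_probes = c(4L, 1L))
  norm <- probeNormalize(cohort)
  expect_equal(exprMatrix(norm)["A4", ], exprMatrix(cohort)["A4", ] / 4)
  expect_equal(exprMatrix(norm)["B1", ], exprMatrix(cohort)["B1", ])
  expect_equal(unname(exprMatrix(norm)["A4", 1]), 2)

  ## n_probes = 1 everywhere is the identity
  ident <- makeCohort(mat)
  expect_equal(exprMatrix(probeNormalize(ident)), exprMatrix(ident))

  set.seed(1)
  m2 <- matrix(rnorm(50), 10, 5)
  np <- sample(1:6, 10, replace = TRUE)
  c2 <- makeCohort(m2, n_probes = np)
  expect_equal(exprMatrix(probeNormalize(c2)), m2 / np, tolerance = 1e-15,
               ignore_attr = TRUE)

  bad <- makeCohort(mat, n_probes = c(0L, 1L))
  expect_error(probeNormalize(bad), "n_probes")
})

test_that("one-way ANOVA matches brute-force sums of squares", {
  set.seed(7)
  n <- 48
  groups <- rep(c("WNT", "SHH", "group3", "group4"), each = n / 4)
  values <- rnorm(n, mean = rep(c(5, 6, 7, 7.5), each = n / 4))
  mat <- matrix(values, 1, n)
  rownames(mat) <- "G1"
  cohort <- makeCohort(mat, subgroup = groups)
  res <- subgroupAnova(cohort, "G1")

  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(x)
    length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(values, groups, function(x)
    sum((x - mean(x))^2)))
  sst <- sum((values - grand)^2)
  k <- 4
  fOracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$statistic, fOracle, tolerance = 1e-10)
  expect_equal(res$pValue, pf(fOracle, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)
  ## sum-of-squares conservation
  expect_equal(ssb + ssw, sst, tolerance = 1e-9 * sst)
  ## sample order must not matter
  perm <- sample(n)
  res2 <- subgroupAnova(makeCohort(mat[, perm, drop = FALSE],
                                   subgroup = groups[perm]), "G1")
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
})

test_that("ANOVA handles constants, two groups (F = t^2) and tiny groups", {
  const <- makeCohort(matrix(3, 1, 12, dimnames = list("G1", NULL)),
                      subgroup = rep(c("WNT", "SHH", "group3", "group4"),
                                     3))
  res <- subgroupAnova(const, "G1")
  expect_equal(res$statistic, 0)
  expect_equal(res$pValue, 1)

  set.seed(8)
  vals <- rnorm(20)
  two <- makeCohort(matrix(vals, 1, 20, dimnames = list("G1", NULL)),
                    subgroup = rep(c("group3", "group4"), each = 10))
  aovRes <- subgroupAnova(two, "G1")
  tRes <- twoGroupTest(two, "G1",
                       grouping = rep(c("a", "b"), each = 10),
                       varEqual = TRUE)
  expect_equal(aovRes$statistic, tRes$statistic^2, tolerance = 1e-12)
  expect_equal(aovRes$pValue, tRes$pValue, tolerance = 1e-12)

  ## a 1-sample subgroup is excluded with a warning, not an error
  lop <- makeCohort(matrix(rnorm(11), 1, 11, dimnames = list("G1", NULL)),
                    subgroup = c("WNT", rep(c("group3", "group4"), each = 5)))
  expect_warning(res3 <- subgroupAnova(lop, "G1"), "WNT")
  expect_equal(res3$excluded, "WNT")
  expect_equal(sum(res3$groupStats$n), 10)
})

test_that("two-group test matches textbook Welch formulas", {
  set.seed(9)
  a <- rnorm(14, 5, 1.3)
  b <- rnorm(9, 6, 0.7)
  mat <- matrix(c(a, b), 1, 23, dimnames = list("G1", NULL))
  cohort <- makeCohort(mat, i17q = c(rep(1L, 14), rep(0L, 9)))
  res <- twoGroupTest(cohort, "G1", grouping = "i17q")

  se2a <- var(a) / length(a)
  se2b <- var(b) / length(b)
  tOracle <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  dfOracle <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  expect_equal(res$statistic, tOracle, tolerance = 1e-12)
  expect_equal(res$df, dfOracle, tolerance = 1e-12)
  expect_equal(res$pValue, 2 * pt(-abs(tOracle), dfOracle),
               tolerance = 1e-12)
  expect_equal(res$direction, "lower")

  ## identical classes
  same <- makeCohort(matrix(rep(c(1, 2), 6), 1, 12,
                            dimnames = list("G1", NULL)))
  res0 <- twoGroupTest(same, "G1", grouping = rep(c("x", "y"), each = 6))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$pValue, 1)

  expect_error(twoGroupTest(cohort, "G1",
                            grouping = c(rep("a", 22), "b")),
               "degenerate class")
})

test_that("suppressed dosage gene tests lower in i17q samples", {
  directions <- vapply(1:40, function(s) {
    cohort <- simulateExpressionCohort(
      simConfig(nSamples = 40, nFeatures = 60, nChr17Features = 20,
                focalExcessLog2 = 1, seed = s))
    twoGroupTest(cohort, "TP53", grouping = "i17q")$direction
  }, "")
  expect_true(all(directions == "lower"))
})

test_that("grouping by sex and restriction to one subgroup work", {
  cfg <- simConfig(nSamples = 120, i17qFraction = 0.4, nFeatures = 60,
                   nChr17Features = 20, seed = 51L)
  cohort <- simulateExpressionCohort(cfg)
  bySex <- twoGroupTest(cohort, "ESRRG", grouping = "sex")
  expect_equal(sum(bySex$groupStats$n), 120)
  withinG4 <- twoGroupTest(cohort, "TP53", grouping = "i17q",
                           within = "group4")
  expect_equal(sum(withinG4$groupStats$n), sum(subgroups(cohort) == "group4"))
  expect_error(twoGroupTest(cohort, "TP53", within = "WNT2"), "WNT2")
})

test_that("pooled proportions combine printed ratios", {
  p <- pooledProportion(c(3, 1), c(4, 6))
  expect_equal(p$fraction, 0.4)
  expect_equal(p$percent, 40)
  expect_error(pooledProportion(c(5), c(4)), "successes")
})
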