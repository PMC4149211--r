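test_that("configuration validation names the offending field", {
  expect_error(simConfig(i17qFraction = 1), "i17qFraction")
  expect_error(simConfig(hemizygousFold = 1.2), "hemizygousFold")
  expect_error(simConfig(duplicatedFold = 0.9), "duplicatedFold")
  expect_error(simConfig(trueAFRange = c(0.1, 0.6)), "trueAFRange")
  expect_error(simConfig(artifactRate = -1), "artifactRate")
  expect_error(simConfig(nChr17Features = 50, nFeatures = 40),
               "nChr17Features")
  expect_error(simConfig(hazardByGroup = c(0.1, 0.2)), "hazardByGroup")
})

test_that("a fixed seed gives bit-identical generator output", {
  cfg <- simConfig(nSamples = 6, seed = 7L)
  a <- simulateVariantReplicates(cfg)
  b <- simulateVariantReplicates(cfg)
  expect_identical(variantCalls(a$replicates), variantCalls(b$replicates))
  expect_identical(variantCalls(a$pooled), variantCalls(b$pooled))
  expect_identical(a$truth, b$truth)
  expect_identical(
    exprMatrix(simulateExpressionCohort(cfg)),
    exprMatrix(simulateExpressionCohort(cfg)))
  expect_identical(simulateSurvivalCohort(cfg), simulateSurvivalCohort(cfg))
})

test_that("without artifacts every emitted variant is true and fully replicated", {
  cfg <- simConfig(nSamples = 30, trueVariantRate = 2, artifactRate = 0,
                   seed = 11L)
  sim <- simulateVariantReplicates(cfg)
  expect_true(all(sim$truth$status == "true"))
  reps <- variantCalls(sim$replicates)
  perVariant <- table(paste(reps$sample_id, reps$chrom, reps$pos, reps$alt))
  expect_true(all(perVariant == cfg@nReplicates))
  expect_true(all(reps$af >= 0.2 & reps$af <= 0.6))
})

test_that("artifact co-occurrence across replicates matches the closed form", {
  ## artifacts only; a site co-occurs when hit independently in both
  ## replicates, so P(co-occurrence at a site) = (rate / nSites)^2
  nSamples <- 1000L
  rate <- 5
  nSites <- 2000L
  cfg <- simConfig(nSamples = nSamples, trueVariantRate = 0,
                   artifactRate = rate, nSites = nSites, seed = 41L)
  sim <- simulateVariantReplicates(cfg)
  expect_true(all(sim$truth$status == "artifact"))
  reps <- variantCalls(sim$replicates)
  hits <- table(paste(reps$sample_id, reps$chrom, reps$pos))
  observed <- sum(hits >= 2L)
  expected <- nSamples * nSites * (rate / nSites)^2
  expect_lt(abs(observed - expected), 4 * sqrt(expected) + 1)
})

test_that("noiseless expression cohorts reproduce the configured folds exactly", {
  cfg <- simConfig(nSamples = 20, nFeatures = 60, nChr17Features = 30,
                   noiseSD = 0, focalExcessLog2 = 0, seed = 5L)
  cohort <- simulateExpressionCohort(cfg)
  folds <- computeFoldChanges(cohort)
  folds$compartment <- partitionByBreakpoint(folds, cfg@breakpoint)
  expect_equal(folds$fold[folds$compartment == "hemizygous"],
               rep(0.5, sum(folds$compartment == "hemizygous")))
  expect_equal(folds$fold[folds$compartment == "duplicated"],
               rep(1.5, sum(folds$compartment == "duplicated")))
  expect_equal(folds$fold[folds$compartment == "other"],
               rep(1, sum(folds$compartment == "other")))

  ## extra log2 suppression of the focal gene is additive in log space
  cfg2 <- simConfig(nSamples = 20, nFeatures = 60, nChr17Features = 30,
                    noiseSD = 0, focalExcessLog2 = 1, seed = 5L)
  folds2 <- computeFoldChanges(simulateExpressionCohort(cfg2))
  expect_equal(folds2$fold[folds2$gene == "TP53"], 0.5 / 2)
})

test_that("simulated fold-change moments match the generative values", {
  ## hemizygous feature: per-feature log2 fold ~ Normal(log2(0.5),
  ## noiseSD * sqrt(1/n1 + 1/n0)); check mean and SD within 3 SE
  cfg <- simConfig(nSamples = 100, i17qFraction = 0.5, nFeatures = 1010,
                   nChr17Features = 1000, noiseSD = 0.2, seed = 13L)
  cohort <- simulateExpressionCohort(cfg)
  folds <- computeFoldChanges(cohort)
  folds$compartment <- partitionByBreakpoint(folds, cfg@breakpoint)
  hemi <- log2(folds$fold[folds$compartment == "hemizygous" &
                            folds$gene != "TP53"])
  m <- length(hemi)
  expect_gte(m, 490)
  n1 <- sum(i17qStatus(cohort) == 1L)
  n0 <- sum(i17qStatus(cohort) == 0L)
  sdTheory <- 0.2 * sqrt(1 / n1 + 1 / n0)
  expect_lt(abs(mean(hemi) - log2(0.5)), 3 * sdTheory / sqrt(m))
  expect_lt(abs(sd(hemi) - sdTheory), 3 * sdTheory / sqrt(2 * (m - 1)))
})

test_that("i17q-positive samples concentrate in group 4", {
  cohort <- simulateExpressionCohort(
    simConfig(nSamples = 400, i17qFraction = 0.5, seed = 17L))
  sg <- subgroups(cohort)[i17qStatus(cohort) == 1L]
  expect_true(all(sg %in% c("group3", "group4")))
  expect_gt(mean(sg == "group4"), 0.75)
})

test_that("breakpoint outside chromosome 17 is rejected", {
  expect_error(simulateExpressionCohort(simConfig(breakpoint = 9e7)),
               "outside the simulated chromosome 17 range")
})

test_that("survival cohort respects censoring and DFS <= OS", {
  cfg <- simConfig(nSamples = 200, censorTime = 24, seed = 19L)
  clin <- simulateSurvivalCohort(cfg)
  expect_true(all(clin$dfs_time <= clin$os_time))
  expect_true(all(clin$os_time <= 24))
  expect_true(any(clin$os_event), info = "some deaths before the horizon")

  zero <- simulateSurvivalCohort(simConfig(nSamples = 50, censorTime = 0,
                                           seed = 19L))
  expect_true(all(zero$os_time == 0))
  expect_false(any(zero$os_event))
  expect_false(any(zero$dfs_event))
})

test_that("survival strata follow the configured hazards", {
  cfg <- simConfig(nSamples = 4000, censorTime = 1e6,
                   hazardByGroup = c(low = 0.02, high = 0.1), seed = 23L)
  clin <- simulateSurvivalCohort(cfg)
  mLow <- mean(clin$os_time[clin$stratum == "low"])
  mHigh <- mean(clin$os_time[clin$stratum == "high"])
  expect_lt(abs(mLow - 50) / 50, 0.1)
  expect_lt(abs(mHigh - 10) / 10, 0.1)
  expect_error(
    simulateSurvivalCohort(cfg, riskAssignment = rep("unknown", 4000)),
    "hazardByGroup")
})

test_that("the packaged mutation table loads with its published shape", {
  tab <- loadTable1()
  expect_equal(nrow(tab), 13L)
  expect_equal(length(unique(tab$sample_id)), 10L)
  s32 <- tab[tab$sample_id == "32", ]
  expect_equal(s32$gene, "GPS2")
  expect_equal(s32$function_class, "splice_site")
  expect_equal(s32$chrom, "chr17")
  expect_equal(s32$start, 7217225)
  expect_equal(s32$ref, "C")
  expect_equal(s32$obs, "T")
  expect_error(loadTable1("/nonexistent/table.tsv"), "not found")
  corrupt <- tempfile(fileext = ".tsv")
  writeLines("sample_id\tgene\nonly\ttwo", corrupt)
  expect_error(loadTable1(corrupt), "corrupt")
})
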