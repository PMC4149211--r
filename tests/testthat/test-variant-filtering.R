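test_that("caller thresholds are inclusive at their boundaries", {
  calls <- variantCallSet(rbind(
    makeCalls(qual = 30, mapq = 30, af = 0.20, pos = 1L),
    makeCalls(qual = 29.9, mapq = 50, af = 0.5, pos = 2L),
    makeCalls(qual = 100, mapq = 29.9, af = 0.5, pos = 3L),
    makeCalls(qual = 100, mapq = 50, af = 0.19, pos = 4L)))
  kept <- variantCalls(applyCallThresholds(calls))
  expect_equal(kept$pos, 1L)
  expect_equal(length(applyCallThresholds(variantCallSet(makeCalls(0)))), 0L)
})

test_that("annotation filter drops silent classes and common polymorphisms", {
  calls <- variantCallSet(rbind(
    makeCalls(function_class = "splice_site", pop_af = NA, pos = 1L),
    makeCalls(function_class = "synonymous", pos = 2L),
    makeCalls(function_class = "intronic", pos = 3L),
    makeCalls(function_class = "nonsynonymous", pop_af = 0.01, pos = 4L),
    makeCalls(function_class = "nonsynonymous", pop_af = 0.011, pos = 5L)))
  kept <- variantCalls(applyAnnotationFilters(calls))
  ## splice-site novel variant kept; pop_af exactly 1% kept (rule is > 1%)
  expect_equal(kept$pos, c(1L, 4L))
  bad <- makeCalls(pos = 9L)
  bad$function_class <- "missense"
  expect_error(applyAnnotationFilters(bad), "unknown function_class.*missense")
})

test_that("concordance requires a replicate strictly above 5%", {
  pooled <- variantCallSet(rbind(makeCalls(pos = 1L), makeCalls(pos = 2L)))
  reps <- variantCallSet(rbind(
    makeCalls(replicate_id = "r1", pos = 1L, af = 0.06),
    makeCalls(replicate_id = "r2", pos = 1L, af = 0.009),
    makeCalls(replicate_id = "r1", pos = 2L, af = 0.05),
    makeCalls(replicate_id = "r2", pos = 2L, af = 0.04)))
  kept <- variantCalls(applyConcordanceFilter(pooled, reps))
  expect_equal(kept$pos, 1L)

  orphan <- variantCallSet(makeCalls(sample_id = "S999"))
  expect_error(applyConcordanceFilter(orphan, reps), "S999")
  ## pooled rows in the replicate set never count as the supporting replicate
  pooledOnly <- variantCallSet(
    rbind(makeCalls(replicate_id = "pooled", pos = 2L, af = 0.4),
          makeCalls(replicate_id = "r1", pos = 2L, af = 0.01)))
  expect_equal(length(applyConcordanceFilter(
    variantCallSet(makeCalls(pos = 2L)), pooledOnly)), 0L)
})

test_that("pipeline retention equals brute-force evaluation of all rules", {
  sim <- simulateVariantReplicates(
    simConfig(nSamples = 60, trueVariantRate = 2, artifactRate = 8,
              nSites = 3000, seed = 101L))
  res <- filterVariants(sim$pooled, sim$replicates, truth = sim$truth)

  pdf <- variantCalls(sim$pooled)
  rdf <- variantCalls(sim$replicates)
  keyOf <- function(df) paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt)
  keep <- logical(nrow(pdf))
  for (i in seq_len(nrow(pdf))) {
    v <- pdf[i, ]
    concordant <- FALSE
    for (j in which(rdf$sample_id == v$sample_id)) {
      r <- rdf[j, ]
      if (r$chrom == v$chrom && r$pos == v$pos && r$ref == v$ref &&
          r$alt == v$alt && r$af > 0.05)
        concordant <- TRUE
    }
    keep[i] <- v$qual >= 30 && v$mapq >= 30 && v$af >= 0.20 &&
      !(v$function_class %in% c("synonymous", "intronic")) &&
      (is.na(v$pop_af) || v$pop_af <= 0.01) &&
      concordant
  }
  expect_setequal(keyOf(variantCalls(res$calls)), keyOf(pdf[keep, ]))

  ## threshold and annotation filters commute
  a <- applyAnnotationFilters(applyCallThresholds(sim$pooled))
  b <- applyCallThresholds(applyAnnotationFilters(sim$pooled))
  expect_setequal(keyOf(variantCalls(a)), keyOf(variantCalls(b)))
})

test_that("sensitivity is exactly 1 when true variants replicate at AF >= 0.2", {
  sim <- simulateVariantReplicates(
    simConfig(nSamples = 80, trueVariantRate = 1.5, artifactRate = 6,
              seed = 103L))
  rep <- filterVariants(sim$pooled, sim$replicates, truth = sim$truth)$report
  expect_identical(rep@sensitivity, 1)
  expect_true(rep@sensitivityDefined)
  expect_true(all(diff(rep@stageCounts) <= 0L))
})

test_that("performance report handles degenerate denominators", {
  truth <- data.frame(sample_id = "S001", chrom = "chr7", pos = 101L,
                      ref = "G", alt = "A", status = "artifact")
  rep <- evaluateFilterPerformance(makeCalls(0), truth)
  expect_false(rep@sensitivityDefined)
  expect_true(is.na(rep@sensitivity))
  expect_identical(rep@specificity, 1)

  allKept <- evaluateFilterPerformance(
    makeCalls(1, pos = 101L),
    data.frame(sample_id = "S001", chrom = "chr7", pos = 101L, ref = "G",
               alt = "A", status = "true"))
  expect_identical(allKept@sensitivity, 1)
  expect_false(allKept@specificityDefined)

  expect_error(
    evaluateFilterPerformance(makeCalls(1, pos = 999L), truth),
    "absent from the truth table")
})

test_that("mutation-table summaries count mutations, patients and shares", {
  tab <- loadTable1()
  s <- summarizeMutationTable(tab, cohortSize = 57)
  expect_equal(s$nMutations, 13)
  expect_equal(s$nPatients, 10)
  expect_equal(s$patientPercent, 18)
  expect_equal(unname(s$genePercent["MLL3"]), 85)
  expect_equal(unname(s$functionClassPercent["nonsynonymous"]), 69)

  ## duplicating one sample's record under a fresh ID adds exactly 1 patient
  extra <- tab[1, ]
  extra$sample_id <- "99"
  s2 <- summarizeMutationTable(rbind(tab, extra), cohortSize = 57)
  expect_equal(s2$nPatients, s$nPatients + 1L)

  empty <- summarizeMutationTable(tab[0, ], cohortSize = 57)
  expect_equal(empty$nMutations, 0)
  expect_equal(empty$nPatients, 0)
  expect_error(summarizeMutationTable(tab, cohortSize = 5), "smaller")
})

test_that("retained calls convert to deduplicated mutation records", {
  calls <- rbind(makeCalls(pos = 10L), makeCalls(pos = 10L),
                 makeCalls(pos = 11L, function_class = "synonymous"))
  tab <- asMutationTable(calls)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$start, 10L)
  expect_named(tab, c("sample_id", "gene", "function_class", "chrom",
                      "start", "ref", "obs", "damaging_tally"))
})
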