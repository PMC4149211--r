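test_that("product-limit estimator handles censoring and no-event input", {
  noEvents <- makeClinical(time = c(3, 5, 9), event = c(FALSE, FALSE, FALSE))
  km <- kmCurve(noEvents, "OS")
  expect_true(all(km@surv == 1))

  ## events at 1 and 2 with a censoring at 1.5: after the censoring only one
  ## subject remains at risk, so the second event drops survival to 0
  ## (verified against survival::survfit)
  clin <- makeClinical(time = c(1, 1.5, 2), event = c(TRUE, FALSE, TRUE))
  km2 <- kmCurve(clin, "OS")
  expect_equal(km2@time, c(1, 1.5, 2))
  expect_equal(km2@surv, c(2 / 3, 2 / 3, 0), tolerance = 1e-15)
  expect_equal(km2@nRisk, c(3, 2, 1))

  expect_error(kmCurve(makeClinical(-1, TRUE), "OS"), "non-negative")
})

test_that("KM estimate matches the survival package on random cohorts", {
  set.seed(60)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    time <- round(rexp(n, 0.05), 2)
    event <- runif(n) < 0.7
    clin <- makeClinical(time, event)
    km <- kmCurve(clin, "OS")
    ref <- survival::survfit(survival::Surv(time, event) ~ 1)
    expect_equal(km@time, ref$time, tolerance = 1e-12)
    expect_equal(km@surv, ref$surv, tolerance = 1e-12)
    expect_equal(km@nRisk, ref$n.risk, tolerance = 1e-12)
    expect_equal(km@nEvent, ref$n.event, tolerance = 1e-12)
  }
})

test_that("log-rank statistic matches the hand-computed O-E/V formula", {
  ## group A events at 1 and 2; group B censored at 3 and 4
  time <- c(1, 2, 3, 4)
  event <- c(TRUE, TRUE, FALSE, FALSE)
  group <- c("A", "A", "B", "B")
  clin <- makeClinical(time, event, group = group)
  lr <- logrankTest(clin, grouping = group, endpoint = "OS")
  ## t=1: n=4, n_A=2, d=1 -> E_A = 1/2, V = (2/4)(2/4)(3/3) = 1/4
  ## t=2: n=3, n_A=1, d=1 -> E_A = 1/3, V = (1/3)(2/3)(2/2) = 2/9
  oByHand <- 2
  eByHand <- 1 / 2 + 1 / 3
  vByHand <- 1 / 4 + 2 / 9
  expect_equal(lr$chisq, (oByHand - eByHand)^2 / vByHand, tolerance = 1e-15)
  expect_equal(lr$observed[1], 2)
  expect_equal(lr$expected[1], eByHand, tolerance = 1e-15)

  ## identical groups: statistic 0, p 1
  dup <- makeClinical(c(1, 2, 3, 1, 2, 3),
                      c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                      group = rep(c("A", "B"), each = 3))
  lr0 <- logrankTest(dup, grouping = rep(c("A", "B"), each = 3),
                     endpoint = "OS")
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$pValue, 1)
})

test_that("log-rank matches survdiff and is invariant to relabeling and time transforms", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    time <- round(rexp(n, 0.05), 2) + 0.01
    event <- runif(n) < 0.7
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(group)) < 2) group[1:2] <- c("A", "B")
    clin <- makeClinical(time, event, group = group)
    lr <- logrankTest(clin, grouping = group, endpoint = "OS")
    ref <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(lr$chisq, ref$chisq, tolerance = 1e-12)

    swapped <- logrankTest(clin, grouping = ifelse(group == "A", "Z", "A"),
                           endpoint = "OS")
    expect_equal(swapped$chisq, lr$chisq, tolerance = 1e-12)

    mono <- makeClinical(log1p(time), event, group = group)
    expect_equal(logrankTest(mono, grouping = group, endpoint = "OS")$chisq,
                 lr$chisq, tolerance = 1e-12)
  }
})

test_that("combined molecular risk is the OR of the two flags", {
  recs <- data.frame(
    patient_id = sprintf("P%d", 1:4),
    mutation_positive = c(TRUE, TRUE, FALSE, FALSE),
    i17q_positive = c(TRUE, FALSE, TRUE, FALSE))
  out <- assignCombinedRisk(recs)
  expect_equal(out$molecular_risk,
               c("molecular-high", "molecular-high", "molecular-high",
                 "molecular-low"))
  recs$i17q_positive[2] <- NA
  expect_error(assignCombinedRisk(recs), "P2")
})

test_that("the survival grid reports every requested cell", {
  clin <- simulateSurvivalCohort(simConfig(nSamples = 80, seed = 71L))
  rep <- runSurvivalAnalysis(clin)
  expect_equal(nrow(rep), 12)  # 3 stratifiers x 2 endpoints x 2 subsets
  expect_true(all(rep$pValue >= 0 & rep$pValue <= 1))
  curves <- attr(rep, "curves")
  expect_equal(length(curves), 12)
  expect_s4_class(curves[[1]][[1]], "SurvivalCurve")

  noSR <- clin
  noSR$risk_group <- "HR"
  expect_error(runSurvivalAnalysis(noSR, subsets = "SR"), "SR")
})

test_that("survival analysis has power under a strong group effect", {
  ## hazard ratio 5, n = 60: median log-rank p over seeds is well below 0.01
  ps <- vapply(1:40, function(s) {
    cfg <- simConfig(nSamples = 60, censorTime = 60,
                     hazardByGroup = c(low = 0.01, high = 0.05), seed = s)
    clin <- simulateSurvivalCohort(cfg)
    runSurvivalAnalysis(clin, stratifiers = "combined", endpoints = "OS",
                        subsets = "all")$pValue
  }, 0)
  expect_lt(median(ps), 0.01)
})
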