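#' @import methods
NULL

## Controlled vocabulary for functional annotation classes carried on calls.
FUNCTION_CLASSES <- c("nonsynonymous", "stopgain", "frameshift",
                      "splice_site", "synonymous", "intronic", "other")

MB_SUBGROUPS <- c("WNT", "SHH", "group3", "group4")

## Columns every variant call table must carry.  `replicate_id` is "pooled"
## for calls made on compiled (multi-replicate) alignments.
VARIANT_CALL_COLUMNS <- c("sample_id", "replicate_id", "chrom", "pos",
                          "ref", "alt", "qual", "mapq", "af",
                          "function_class", "pop_af", "gene")

#' Simulation configuration for synthetic medulloblastoma cohorts
#'
#' Holds every tunable of the synthetic-data generators: the variant-replicate
#' simulator (FFPE amplicon calls with per-replicate artifacts), the
#' expression-cohort simulator (chromosome 17 dosage structure with an i17q
#' breakpoint) and the survival simulator (exponential event times per risk
#' stratum).  Construct with [simConfig()], which supplies defaults.
#'
#' @slot nSamples number of tumors simulated.
#' @slot nReplicates independent amplification/sequencing replicates per
#'   sample (at least 2; the concordance filter requires replicates).
#' @slot trueVariantRate expected number of true somatic variants per sample
#'   (Poisson mean).
#' @slot artifactRate expected number of artifact calls per replicate
#'   (Poisson mean); artifacts arise independently in each replicate.
#' @slot trueAFRange allele-fraction interval for true variants, within
#'   \[0.2, 0.6\].
#' @slot artifactAFShape two Beta shape parameters; artifact allele fractions
#'   are drawn as `0.3 * Beta(shape1, shape2)`, right-skewed and bounded
#'   below 0.3.
#' @slot nSites number of targetable amplicon positions artifacts can hit.
#' @slot meanDepth,depthSdLog per-replicate site read depth is lognormal with
#'   `meanlog = log(meanDepth)` and `sdlog = depthSdLog`; depths weight the
#'   pooled allele fraction.
#' @slot nFeatures,nChr17Features expression features simulated in total and
#'   on chromosome 17.
#' @slot breakpoint 1-based chromosome 17 coordinate of the i17q breakpoint
#'   (17p11.2); features below it are hemizygous in i17q-positive tumors,
#'   features at or above it duplicated.
#' @slot hemizygousFold,duplicatedFold linear expression folds applied to the
#'   two compartments in i17q-positive samples (defaults 0.5 and 1.5).
#' @slot focalExcessLog2 additional log2 suppression of the focal gene (TP53)
#'   in i17q-positive samples beyond the dosage term; 0 under the
#'   pure-dosage null.
#' @slot i17qFraction fraction of samples that are i17q-positive.
#' @slot group4Prob probability an i17q-positive sample is labeled group 4
#'   (otherwise group 3).
#' @slot noiseSD standard deviation of the Gaussian log2 expression noise.
#' @slot hazardByGroup named positive event rates (per month) for the
#'   survival strata.
#' @slot censorTime administrative censoring horizon in months.
#' @slot seed integer random seed; a fixed seed gives bit-identical output.
#' @seealso [simConfig()], [simulateVariantReplicates()],
#'   [simulateExpressionCohort()], [simulateSurvivalCohort()]
#' @export
setClass("SimConfig",
  representation(
    nSamples = "integer",
    nReplicates = "integer",
    trueVariantRate = "numeric",
    artifactRate = "numeric",
    trueAFRange = "numeric",
    artifactAFShape = "numeric",
    nSites = "integer",
    meanDepth = "numeric",
    depthSdLog = "numeric",
    nFeatures = "integer",
    nChr17Features = "integer",
    breakpoint = "numeric",
    hemizygousFold = "numeric",
    duplicatedFold = "numeric",
    focalExcessLog2 = "numeric",
    i17qFraction = "numeric",
    group4Prob = "numeric",
    noiseSD = "numeric",
    hazardByGroup = "numeric",
    censorTime = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  msgs <- character(0)
  chkScalar <- function(field, lower = 0, strict = FALSE) {
    x <- slot(object, field)
    if (length(x) != 1L || is.na(x) ||
        (strict && x <= lower) || (!strict && x < lower))
      msgs <<- c(msgs, bad(field, sprintf("must be a single value %s %s",
                                          if (strict) ">" else ">=", lower)))
  }
  chkScalar("nSamples", 1)
  chkScalar("nReplicates", 1)
  chkScalar("trueVariantRate", 0)
  chkScalar("artifactRate", 0)
  chkScalar("nSites", 1)
  chkScalar("meanDepth", 0, strict = TRUE)
  chkScalar("depthSdLog", 0)
  chkScalar("nFeatures", 1)
  chkScalar("nChr17Features", 0)
  chkScalar("breakpoint", 0, strict = TRUE)
  chkScalar("focalExcessLog2", -Inf)
  chkScalar("noiseSD", 0)
  chkScalar("censorTime", 0)
  r <- object@trueAFRange
  if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] ||
      r[1] < 0.2 || r[2] > 0.6)
    msgs <- c(msgs, bad("trueAFRange",
                        "must be an increasing interval within [0.2, 0.6]"))
  s <- object@artifactAFShape
  if (length(s) != 2L || any(is.na(s)) || any(s <= 0))
    msgs <- c(msgs, bad("artifactAFShape", "must be two positive Beta shapes"))
  f <- object@i17qFraction
  if (length(f) != 1L || is.na(f) || f <= 0 || f >= 1)
    msgs <- c(msgs, bad("i17qFraction", "must lie strictly between 0 and 1"))
  p <- object@group4Prob
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    msgs <- c(msgs, bad("group4Prob", "must lie in [0, 1]"))
  if (!(object@hemizygousFold < 1))
    msgs <- c(msgs, bad("hemizygousFold", "must be < 1"))
  if (!(object@duplicatedFold > 1))
    msgs <- c(msgs, bad("duplicatedFold", "must be > 1"))
  if (object@nChr17Features > object@nFeatures)
    msgs <- c(msgs, bad("nChr17Features", "cannot exceed nFeatures"))
  h <- object@hazardByGroup
  if (length(h) < 1L || is.null(names(h)) || any(!nzchar(names(h))) ||
      any(is.na(h)) || any(h <= 0))
    msgs <- c(msgs, bad("hazardByGroup", "must be named positive rates"))
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, bad("seed", "must be a single integer"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param nSamples,nReplicates cohort size and amplification replicates per
#'   sample.
#' @param trueVariantRate,artifactRate Poisson means: true somatic variants
#'   per sample, artifact calls per replicate.
#' @param trueAFRange allele-fraction interval for true variants (within
#'   \[0.2, 0.6\]).
#' @param artifactAFShape Beta shape parameters for the artifact
#'   allele-fraction distribution `0.3 * Beta(a, b)`.
#' @param nSites targetable amplicon positions.
#' @param meanDepth,depthSdLog lognormal per-replicate read-depth model.
#' @param nFeatures,nChr17Features expression features overall / on chr17.
#' @param breakpoint i17q breakpoint coordinate on chromosome 17 (1-based).
#' @param hemizygousFold,duplicatedFold linear dosage folds for the two
#'   chromosome 17 compartments in i17q-positive tumors.
#' @param focalExcessLog2 extra log2 suppression of the focal gene.
#' @param i17qFraction fraction of i17q-positive samples.
#' @param group4Prob probability an i17q-positive sample is group 4.
#' @param noiseSD Gaussian log2 noise standard deviation.
#' @param hazardByGroup named event rates per survival stratum (per month).
#' @param censorTime administrative censoring horizon (months).
#' @param seed integer random seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSamples = 10, seed = 1)
#' cfg
#' @export
simConfig <- function(nSamples = 57L,
                      nReplicates = 2L,
                      trueVariantRate = 0.25,
                      artifactRate = 5,
                      trueAFRange = c(0.2, 0.6),
                      artifactAFShape = c(1, 3),
                      nSites = 20000L,
                      meanDepth = 500,
                      depthSdLog = 1,
                      nFeatures = 1000L,
                      nChr17Features = 120L,
                      breakpoint = 2e7,
                      hemizygousFold = 0.5,
                      duplicatedFold = 1.5,
                      focalExcessLog2 = 0,
                      i17qFraction = 0.3,
                      group4Prob = 0.85,
                      noiseSD = 0.25,
                      hazardByGroup = c(low = 0.01, high = 0.05),
                      censorTime = 60,
                      seed = 1L) {
  asInt <- function(x, field) {
    if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x))
      stop(sprintf("invalid '%s': must be a single integer", field),
           call. = FALSE)
    as.integer(x)
  }
  obj <- new("SimConfig",
    nSamples = asInt(nSamples, "nSamples"),
    nReplicates = asInt(nReplicates, "nReplicates"),
    trueVariantRate = as.numeric(trueVariantRate),
    artifactRate = as.numeric(artifactRate),
    trueAFRange = as.numeric(trueAFRange),
    artifactAFShape = as.numeric(artifactAFShape),
    nSites = asInt(nSites, "nSites"),
    meanDepth = as.numeric(meanDepth),
    depthSdLog = as.numeric(depthSdLog),
    nFeatures = asInt(nFeatures, "nFeatures"),
    nChr17Features = asInt(nChr17Features, "nChr17Features"),
    breakpoint = as.numeric(breakpoint),
    hemizygousFold = as.numeric(hemizygousFold),
    duplicatedFold = as.numeric(duplicatedFold),
    focalExcessLog2 = as.numeric(focalExcessLog2),
    i17qFraction = as.numeric(i17qFraction),
    group4Prob = as.numeric(group4Prob),
    noiseSD = as.numeric(noiseSD),
    hazardByGroup = structure(as.numeric(hazardByGroup),
                              names = names(hazardByGroup)),
    censorTime = as.numeric(censorTime),
    seed = asInt(seed, "seed")
  )
  msg <- validObject(obj, test = TRUE)
  if (!isTRUE(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  obj
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  samples: %d x %d replicates | true rate %.3g/sample, artifacts %.3g/replicate\n",
              object@nSamples, object@nReplicates,
              object@trueVariantRate, object@artifactRate))
  cat(sprintf("  expression: %d features (%d on chr17), breakpoint %.0f, folds %.2f/%.2f, focal excess %.2f log2\n",
              object@nFeatures, object@nChr17Features, object@breakpoint,
              object@hemizygousFold, object@duplicatedFold,
              object@focalExcessLog2))
  cat(sprintf("  i17q fraction %.2f | noise SD %.2f | seed %d\n",
              object@i17qFraction, object@noiseSD, object@seed))
})

#' A set of variant calls
#'
#' Thin validated container around a data frame of variant calls, one row per
#' called variant in one sample and replicate (or in the pooled,
#' compiled-replicate alignment, flagged by `replicate_id == "pooled"`).
#' Required columns are `sample_id`, `replicate_id`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, `qual` (Phred call quality), `mapq`, `af` (alternate allele
#' fraction), `function_class`, `pop_af` (maximum documented population
#' allele frequency, `NA` when the variant is absent from dbSNP/1000
#' genomes/6500 exomes) and `gene`.  Extra columns (e.g. read depth) are
#' preserved.
#'
#' @slot calls the underlying `data.frame`.
#' @seealso [variantCallSet()], [variantCalls()], [applyCallThresholds()]
#' @export
setClass("VariantCallSet", representation(calls = "data.frame"))

setValidity("VariantCallSet", function(object) {
  df <- object@calls
  missing <- setdiff(VARIANT_CALL_COLUMNS, names(df))
  if (length(missing))
    return(sprintf("missing call columns: %s", paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(is.na(df$af)) || any(df$af < 0 | df$af > 1))
    return("'af' must lie in [0, 1]")
  if (any(is.na(df$pos)) || any(df$pos < 1))
    return("'pos' must be >= 1")
  if (any(df$ref == df$alt))
    return("'ref' and 'alt' must differ")
  unknown <- setdiff(unique(df$function_class), c(FUNCTION_CLASSES, NA))
  if (length(unknown))
    return(sprintf("unknown function_class value(s): %s",
                   paste(unknown, collapse = ", ")))
  TRUE
})

#' Create a VariantCallSet from a data frame
#'
#' @param calls data frame with the columns documented in
#'   [VariantCallSet-class].
#' @return a `VariantCallSet`.
#' @export
variantCallSet <- function(calls) {
  stopifnot(is.data.frame(calls))
  rownames(calls) <- NULL
  new("VariantCallSet", calls = as.data.frame(calls))
}

setMethod("show", "VariantCallSet", function(object) {
  df <- object@calls
  cat(sprintf("VariantCallSet: %d calls, %d sample(s), replicates: %s\n",
              nrow(df), length(unique(df$sample_id)),
              paste(sort(unique(df$replicate_id)), collapse = ", ")))
  if (nrow(df)) {
    print(utils::head(df, 5L))
    if (nrow(df) > 5L) cat(sprintf("  ... and %d more rows\n", nrow(df) - 5L))
  }
})

#' @describeIn VariantCallSet-class number of calls in the set.
#' @param x a `VariantCallSet`.
#' @export
setMethod("length", "VariantCallSet", function(x) nrow(x@calls))

#' Expression cohort with feature and sample annotations
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a log2
#' expression matrix (assay `"log2expr"`, features x samples) with the
#' feature metadata (`gene`, `chrom`, `pos`, `n_probes`) and sample metadata
#' (`subgroup` in WNT/SHH/group3/group4, `i17q_status` in 0/1, `sex`) that
#' the dosage, subgroup-comparison and i17q analyses require.
#'
#' @seealso [expressionCohort()], [simulateExpressionCohort()],
#'   [computeFoldChanges()]
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  msgs <- character(0)
  needRow <- setdiff(c("gene", "chrom", "pos", "n_probes"), names(rd))
  if (length(needRow))
    msgs <- c(msgs, sprintf("missing feature metadata: %s",
                            paste(needRow, collapse = ", ")))
  needCol <- setdiff(c("subgroup", "i17q_status", "sex"), names(cd))
  if (length(needCol))
    msgs <- c(msgs, sprintf("missing sample metadata: %s",
                            paste(needCol, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(rownames(object)))
      msgs <- c(msgs, "duplicate feature identifiers")
    if (!all(cd$i17q_status %in% c(0L, 1L)))
      msgs <- c(msgs, "i17q_status must be 0 or 1")
    if (!all(cd$subgroup %in% c(MB_SUBGROUPS, NA)))
      msgs <- c(msgs, sprintf("subgroup must be one of %s",
                              paste(MB_SUBGROUPS, collapse = ", ")))
    if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
      msgs <- c(msgs, "assay 'log2expr' is required")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionCohort
#'
#' @param log2expr numeric matrix of log2 expression, features x samples,
#'   with feature row names and sample column names.
#' @param featureData data frame (one row per feature) with columns `gene`,
#'   `chrom`, `pos`, `n_probes`.
#' @param sampleData data frame (one row per sample) with columns `subgroup`,
#'   `i17q_status`, `sex`.
#' @return an [ExpressionCohort-class].
#' @export
expressionCohort <- function(log2expr, featureData, sampleData) {
  log2expr <- as.matrix(log2expr)
  if (nrow(featureData) != nrow(log2expr))
    stop(sprintf("feature metadata has %d rows but matrix has %d features",
                 nrow(featureData), nrow(log2expr)), call. = FALSE)
  if (nrow(sampleData) != ncol(log2expr))
    stop(sprintf("sample metadata has %d rows but matrix has %d samples",
                 nrow(sampleData), ncol(log2expr)), call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = log2expr),
    rowData = S4Vectors::DataFrame(featureData),
    colData = S4Vectors::DataFrame(sampleData)
  )
  obj <- new("ExpressionCohort", se)
  msg <- validObject(obj, test = TRUE)
  if (!isTRUE(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  obj
}

setMethod("show", "ExpressionCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("ExpressionCohort: %d features x %d samples (%d i17q-positive)\n",
              nrow(object), ncol(object), sum(cd$i17q_status == 1L)))
  tab <- table(factor(cd$subgroup, levels = MB_SUBGROUPS))
  cat("  subgroups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  cat(sprintf("  chr17 features: %d\n",
              sum(.isChr17(SummarizedExperiment::rowData(object)$chrom))))
})

#' Result of the focal-gene dosage-excess test
#'
#' Returned by [focalExcessTest()].  Carries the per-feature fold-expression
#' table with compartment labels, the hemizygous background moments (linear
#' fold scale), the focal gene's standardized deviation from that background,
#' and the Bonferroni-corrected test of excess suppression.
#'
#' @slot focalGene focal gene symbol.
#' @slot folds data frame: feature, gene, chrom, pos, fold (linear),
#'   compartment (hemizygous / duplicated / other).
#' @slot backgroundMean,backgroundSd mean and SD of the hemizygous-compartment
#'   background folds, excluding the focal gene.
#' @slot focalFold,focalZ focal gene's fold and its standardized deviation
#'   from the background.
#' @slot tStatistic,df,pRaw Welch t-test of the focal gene against the
#'   background.
#' @slot nTests Bonferroni factor used.
#' @slot pCorrected `min(1, pRaw * nTests)`.
#' @slot alpha significance level.
#' @slot flagged `TRUE` when `pCorrected < alpha`.
#' @slot belowTwoSD `TRUE` when the focal fold sits more than 2 background
#'   SDs below the background mean (`focalZ < -2`).
#' @slot mode comparison units used (`"per-sample"` or `"per-feature"`).
#' @export
setClass("DosageTestResult",
  representation(
    focalGene = "character",
    folds = "data.frame",
    backgroundMean = "numeric",
    backgroundSd = "numeric",
    focalFold = "numeric",
    focalZ = "numeric",
    tStatistic = "numeric",
    df = "numeric",
    pRaw = "numeric",
    nTests = "integer",
    pCorrected = "numeric",
    alpha = "numeric",
    flagged = "logical",
    belowTwoSD = "logical",
    mode = "character"
  )
)

setValidity("DosageTestResult", function(object) {
  if (length(object@pRaw) == 1L && !is.na(object@pRaw)) {
    expect <- min(1, object@pRaw * object@nTests)
    if (abs(object@pCorrected - expect) > 1e-12)
      return("pCorrected must equal min(1, pRaw * nTests)")
    if (object@flagged && !(object@pCorrected < object@alpha))
      return("flagged requires pCorrected < alpha")
  }
  TRUE
})

setMethod("show", "DosageTestResult", function(object) {
  cat(sprintf("Focal dosage-excess test for %s (%s units)\n",
              object@focalGene, object@mode))
  cat(sprintf("  hemizygous background: n=%d, mean fold %.3f, SD %.3f\n",
              object@nTests - 1L, object@backgroundMean, object@backgroundSd))
  cat(sprintf("  focal fold %.3f (z = %.2f%s)\n", object@focalFold,
              object@focalZ,
              if (isTRUE(object@belowTwoSD)) ", > 2 SD below background" else ""))
  cat(sprintf("  t = %.3f, raw p = %.3g, Bonferroni x%d -> p = %.3g %s\n",
              object@tStatistic, object@pRaw, object@nTests,
              object@pCorrected,
              if (isTRUE(object@flagged)) "(significant)" else ""))
})

#' Filter performance report
#'
#' Stage-wise retention counts of the variant-filtering pipeline, plus
#' sensitivity (retained true variants / all true variants) and specificity
#' (rejected artifacts / all artifacts) when a truth table is supplied.
#' Either rate is `NA` with its `*Defined` flag `FALSE` when the
#' corresponding denominator is empty.
#'
#' @slot stageCounts named integer counts, monotonically non-increasing.
#' @slot sensitivity,specificity performance rates in \[0, 1\] or `NA`.
#' @slot sensitivityDefined,specificityDefined whether the denominators were
#'   non-empty.
#' @export
setClass("FilterReport",
  representation(
    stageCounts = "integer",
    sensitivity = "numeric",
    specificity = "numeric",
    sensitivityDefined = "logical",
    specificityDefined = "logical"
  )
)

setValidity("FilterReport", function(object) {
  k <- object@stageCounts
  if (length(k) >= 2L && any(diff(k) > 0L))
    return("stage counts must be monotonically non-increasing")
  for (r in c(object@sensitivity, object@specificity))
    if (!is.na(r) && (r < 0 || r > 1))
      return("performance rates must lie in [0, 1]")
  TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport\n")
  k <- object@stageCounts
  if (length(k))
    cat(paste(sprintf("  %-12s %d", names(k), k), collapse = "\n"), "\n")
  fmt <- function(x, ok) if (isTRUE(ok)) sprintf("%.4f", x) else "undefined"
  cat(sprintf("  sensitivity: %s\n",
              fmt(object@sensitivity, object@sensitivityDefined)))
  cat(sprintf("  specificity: %s\n",
              fmt(object@specificity, object@specificityDefined)))
})

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate at every distinct observed time.  The survival
#' probability starts at 1, is non-increasing and right-continuous; at tied
#' times events are processed before censorings (both remain in the risk set
#' at their own time).
#'
#' @slot time distinct observed times, increasing.
#' @slot surv product-limit survival estimate at each time.
#' @slot nRisk,nEvent,nCensor at-risk, event and censoring counts.
#' @slot endpoint `"OS"` or `"DFS"` (or a free-text label).
#' @seealso [kmCurve()]
#' @export
setClass("SurvivalCurve",
  representation(
    time = "numeric",
    surv = "numeric",
    nRisk = "numeric",
    nEvent = "numeric",
    nCensor = "numeric",
    endpoint = "character"
  )
)

setValidity("SurvivalCurve", function(object) {
  s <- object@surv
  if (length(s)) {
    if (any(s < 0 | s > 1)) return("survival must lie in [0, 1]")
    if (any(diff(s) > 1e-12)) return("survival must be non-increasing")
  }
  if (is.unsorted(object@time, strictly = TRUE) && length(object@time) > 1L)
    return("times must be strictly increasing")
  TRUE
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve (%s): %d subjects, %d events over %d distinct times\n",
              object@endpoint,
              if (length(object@nRisk)) object@nRisk[1L] else 0L,
              sum(object@nEvent), length(object@time)))
  if (length(object@time)) {
    idx <- unique(round(seq(1L, length(object@time),
                            length.out = min(6L, length(object@time)))))
    print(data.frame(time = object@time[idx], n.risk = object@nRisk[idx],
                     n.event = object@nEvent[idx], survival = object@surv[idx]),
          row.names = FALSE)
  }
})

#' @describeIn SurvivalCurve-class step-function plot of the estimate.
#' @param x,y a `SurvivalCurve` (and ignored `y`).
#' @param ... forwarded to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "SurvivalCurve", y = "missing"),
  function(x, y, ...) {
    graphics::plot(c(0, x@time), c(1, x@surv), type = "s",
                   xlab = "time (months)", ylab = "survival",
                   ylim = c(0, 1), ...)
    invisible(x)
  })
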