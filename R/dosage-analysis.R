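# Chromosome 17 dosage analysis: fold-expression normalization of
# i17q-positive tumors by i17q-negative tumors, partition of chromosome 17
# into hemizygous and duplicated compartments at the 17p11.2 breakpoint,
# and the Bonferroni-corrected test of whether the focal gene (TP53) is
# suppressed beyond its compartment's dosage background.

#' Per-feature fold-expression of i17q-positive versus negative tumors
#'
#' For every feature, the linear fold is the ratio of class geometric means:
#' `2 ^ (mean log2 expression over i17q-positive samples - mean over
#' i17q-negative samples)`.  A pure hemizygous dosage effect therefore shows
#' as fold 0.5, a duplication as 1.5.
#'
#' @param cohort an [ExpressionCohort-class] with at least 2 samples in each
#'   i17q status class.
#' @return data frame: `feature`, `gene`, `chrom`, `pos`, `fold`.
#' @examples
#' cohort <- simulateExpressionCohort(simConfig(nSamples = 20, seed = 5))
#' head(computeFoldChanges(cohort))
#' @export
computeFoldChanges <- function(cohort) {
  stopifnot(is(cohort, "ExpressionCohort"))
  status <- i17qStatus(cohort)
  for (cls in c(1L, 0L))
    if (sum(status == cls) < 2L)
      stop(sprintf("need at least 2 i17q-%s samples, found %d",
                   if (cls == 1L) "positive" else "negative",
                   sum(status == cls)), call. = FALSE)
  mat <- exprMatrix(cohort)
  fold <- 2^(rowMeans(mat[, status == 1L, drop = FALSE]) -
               rowMeans(mat[, status == 0L, drop = FALSE]))
  rd <- SummarizedExperiment::rowData(cohort)
  data.frame(feature = rownames(cohort), gene = rd$gene, chrom = rd$chrom,
             pos = rd$pos, fold = unname(fold), stringsAsFactors = FALSE)
}

#' Partition features by the i17q breakpoint
#'
#' Chromosome 17 features telomeric to the breakpoint (position strictly
#' below it) fall in the hemizygous compartment (one copy in i17q tumors);
#' features at or beyond the breakpoint are duplicated (three copies);
#' everything off chromosome 17 is `other`.
#'
#' @param features an [ExpressionCohort-class] or a data frame with `chrom`
#'   and `pos` columns.
#' @param breakpoint 1-based chromosome 17 breakpoint coordinate
#'   (default 2e7, within 17p11.2).
#' @return factor with levels `hemizygous`, `duplicated`, `other`.
#' @export
partitionByBreakpoint <- function(features, breakpoint = 2e7) {
  if (!is.numeric(breakpoint) || length(breakpoint) != 1L || breakpoint <= 0)
    stop("breakpoint must be a single positive coordinate", call. = FALSE)
  if (is(features, "ExpressionCohort"))
    features <- as.data.frame(SummarizedExperiment::rowData(features))
  .requireCols(features, c("chrom", "pos"), "feature table")
  onChr17 <- .isChr17(features$chrom)
  if (any(onChr17 & is.na(features$pos))) {
    bad <- which(onChr17 & is.na(features$pos))
    lab <- if ("gene" %in% names(features)) features$gene[bad] else bad
    stop(sprintf("chromosome 17 feature(s) without position: %s",
                 paste(lab, collapse = ", ")), call. = FALSE)
  }
  out <- rep("other", nrow(features))
  out[onChr17 & features$pos < breakpoint] <- "hemizygous"
  out[onChr17 & features$pos >= breakpoint] <- "duplicated"
  factor(out, levels = c("hemizygous", "duplicated", "other"))
}

#' Test the focal gene for suppression beyond the dosage background
#'
#' Implements the dosage-excess analysis: every feature's fold-expression
#' (i17q-positive normalized by i17q-negative) is computed, chromosome 17 is
#' partitioned at the breakpoint, and the focal gene — which must lie in the
#' hemizygous compartment — is compared with the background distribution of
#' all other hemizygous-compartment folds.  Reported are the background mean
#' and SD on the linear fold scale, the focal gene's standardized deviation
#' (`focalZ`, with an indicator for sitting more than 2 SD below the
#' background), and a Welch t-test with Bonferroni correction by the number
#' of hemizygous-compartment features.
#'
#' Two comparison modes are provided because the units of the background
#' comparison are a genuine modeling choice:
#' \describe{
#'   \item{`per-sample` (default)}{the focal gene's per-i17q-sample
#'     normalized log2 values (each positive sample minus the negative-class
#'     mean) against the per-feature log2 folds of the background.}
#'   \item{`per-feature`}{the focal gene's per-i17q-sample normalized log2
#'     values against the pooled per-i17q-sample normalized log2 values of
#'     all background features.}
#' }
#'
#' @param cohort an [ExpressionCohort-class].
#' @param focalGene focal gene symbol (default `"TP53"`).
#' @param breakpoint chromosome 17 breakpoint coordinate.
#' @param alpha significance level for the corrected flag (default 0.05).
#' @param mode comparison units, `"per-sample"` or `"per-feature"`.
#' @param nTests Bonferroni factor; defaults to the number of
#'   hemizygous-compartment features.
#' @return a [DosageTestResult-class].
#' @examples
#' cfg <- simConfig(nSamples = 60, nFeatures = 300, nChr17Features = 100,
#'                  focalExcessLog2 = 1, seed = 9)
#' focalExcessTest(simulateExpressionCohort(cfg))
#' @export
focalExcessTest <- function(cohort, focalGene = "TP53", breakpoint = 2e7,
                            alpha = 0.05,
                            mode = c("per-sample", "per-feature"),
                            nTests = NULL) {
  mode <- match.arg(mode)
  folds <- computeFoldChanges(cohort)
  folds$compartment <- partitionByBreakpoint(folds, breakpoint)
  if (!focalGene %in% folds$gene)
    stop(sprintf("focal gene %s is not in the cohort", focalGene),
         call. = FALSE)
  focalRow <- which(folds$gene == focalGene)[1L]
  if (folds$compartment[focalRow] != "hemizygous")
    stop(sprintf("focal gene %s is not in the hemizygous compartment (%s)",
                 focalGene, folds$compartment[focalRow]), call. = FALSE)
  bgRows <- setdiff(which(folds$compartment == "hemizygous"), focalRow)
  if (length(bgRows) < 10L)
    stop(sprintf("only %d background hemizygous features; need at least 10 for a stable SD",
                 length(bgRows)), call. = FALSE)

  bgFolds <- folds$fold[bgRows]
  bgMean <- mean(bgFolds)
  bgSd <- stats::sd(bgFolds)
  focalFold <- folds$fold[focalRow]
  focalZ <- if (bgSd == 0) {
    d <- focalFold - bgMean
    if (d == 0) 0 else sign(d) * Inf
  } else (focalFold - bgMean) / bgSd

  status <- i17qStatus(cohort)
  mat <- exprMatrix(cohort)
  negMean <- rowMeans(mat[, status == 0L, drop = FALSE])
  ## per-positive-sample normalized log2 values (log2 of per-sample fold)
  normPos <- mat[, status == 1L, drop = FALSE] - negMean
  focalVals <- normPos[folds$feature[focalRow], ]
  bgVals <- switch(mode,
    "per-sample" = log2(bgFolds),
    "per-feature" = as.numeric(normPos[folds$feature[bgRows], ]))
  ht <- .safeTTest(as.numeric(focalVals), bgVals)

  nTests <- if (is.null(nTests)) length(bgRows) + 1L else as.integer(nTests)
  pCorr <- min(1, ht$p.value * nTests)
  new("DosageTestResult",
      focalGene = focalGene,
      folds = folds,
      backgroundMean = bgMean, backgroundSd = bgSd,
      focalFold = focalFold, focalZ = focalZ,
      tStatistic = ht$statistic, df = ht$df, pRaw = ht$p.value,
      nTests = nTests, pCorrected = pCorr, alpha = alpha,
      flagged = pCorr < alpha, belowTwoSD = focalZ < -2,
      mode = mode)
}

#' Fold-expression profile of a p53-pathway gene panel
#'
#' For each panel gene: the i17q fold-expression, a Welch t-test of log2
#' values between i17q-positive and negative samples, Bonferroni correction
#' by the panel size, and a star level (`*` for corrected p below the first
#' alpha, `**` below the second).  Panel categories (e.g. core regulators,
#' chIP-seq targets, signal transducers) are carried through from the input.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param panel data frame with columns `gene` and `category`; every gene
#'   must be present in the cohort.
#' @param alphaLevels two decreasing significance levels for the star
#'   annotation (default 0.05, 0.01).
#' @return data frame: `gene`, `category`, `fold`, `tStatistic`, `pRaw`,
#'   `pCorrected`, `stars`.
#' @export
pathwayPanelProfile <- function(cohort, panel, alphaLevels = c(0.05, 0.01)) {
  stopifnot(is(cohort, "ExpressionCohort"))
  .requireCols(panel, c("gene", "category"), "gene panel")
  if (length(alphaLevels) != 2L || alphaLevels[1] <= alphaLevels[2])
    stop("alphaLevels must be two decreasing significance levels",
         call. = FALSE)
  rd <- SummarizedExperiment::rowData(cohort)
  missing <- setdiff(panel$gene, rd$gene)
  if (length(missing))
    stop(sprintf("panel gene(s) absent from the cohort: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  status <- i17qStatus(cohort)
  mat <- exprMatrix(cohort)
  nTests <- nrow(panel)
  res <- lapply(seq_len(nTests), function(i) {
    row <- which(rd$gene == panel$gene[i])[1L]
    pos <- mat[row, status == 1L]
    neg <- mat[row, status == 0L]
    ht <- .safeTTest(pos, neg)
    pCorr <- min(1, ht$p.value * nTests)
    data.frame(gene = panel$gene[i], category = panel$category[i],
               fold = 2^(mean(pos) - mean(neg)),
               tStatistic = ht$statistic, pRaw = ht$p.value,
               pCorrected = pCorr,
               stars = if (pCorr < alphaLevels[2]) "**" else
                 if (pCorr < alphaLevels[1]) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
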