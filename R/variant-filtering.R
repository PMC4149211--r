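# Stringent retention of amplicon variant calls from FFPE tumors: caller
# thresholds, annotation/population filters, and the cross-replicate
# concordance rule, plus mutation-table summaries and truth-based
# performance evaluation.

#' Apply variant-caller thresholds
#'
#' Retains calls meeting the caller's minimum quality, mapping quality and
#' alternate allele fraction.  All three bounds are inclusive: a call at
#' exactly the minimum is retained.
#'
#' @param x a [VariantCallSet-class] (or equivalent data frame).
#' @param minQual minimum Phred call quality (default 30).
#' @param minMapq minimum mapping quality (default 30).
#' @param minAF minimum alternate allele fraction (default 0.20).
#' @return a `VariantCallSet` of the retained calls.
#' @export
applyCallThresholds <- function(x, minQual = 30, minMapq = 30, minAF = 0.20) {
  if (any(c(minQual, minMapq, minAF) < 0))
    stop("thresholds must be non-negative", call. = FALSE)
  df <- .asCallDF(x)
  keep <- df$qual >= minQual & df$mapq >= minMapq & df$af >= minAF
  variantCallSet(df[keep, , drop = FALSE])
}

#' Apply annotation and population-frequency filters
#'
#' Removes putative synonymous and intronic (non-splice-site) changes, and
#' documented polymorphisms whose maximum population allele frequency across
#' dbSNP / 1000 genomes / 6500 exomes exceeds `maxPopAF` (strictly: a
#' variant documented at exactly 1% is retained).  Variants absent from all
#' databases (`pop_af` is `NA`) are treated as novel and retained.
#'
#' @param x a [VariantCallSet-class] (or equivalent data frame); every call
#'   must carry a known `function_class`.
#' @param maxPopAF population-frequency cutoff (default 0.01).
#' @return a `VariantCallSet` of the retained calls.
#' @export
applyAnnotationFilters <- function(x, maxPopAF = 0.01) {
  df <- .asCallDF(x)
  unknown <- setdiff(unique(df$function_class), FUNCTION_CLASSES)
  if (length(unknown) || anyNA(df$function_class))
    stop(sprintf("unknown function_class value(s): %s",
                 paste(c(unknown[!is.na(unknown)],
                         if (anyNA(df$function_class)) "NA"),
                       collapse = ", ")), call. = FALSE)
  keep <- !(df$function_class %in% c("synonymous", "intronic")) &
    (is.na(df$pop_af) | df$pop_af <= maxPopAF)
  variantCallSet(df[keep, , drop = FALSE])
}

#' Apply the replicate-concordance filter
#'
#' A call made on the compiled (pooled) alignments of a sample is retained
#' only if at least one individual amplification replicate of the same
#' sample shows the same variant (chromosome, position, ref, alt) at an
#' allele fraction strictly above `minReplicateAF`.  A replicate observation
#' at exactly the cutoff does not qualify.
#'
#' @param pooled a [VariantCallSet-class] of pooled-run calls.
#' @param replicates a `VariantCallSet` of per-replicate calls; every sample
#'   present in `pooled` must have replicate data.
#' @param minReplicateAF replicate allele-fraction cutoff, exclusive
#'   (default 0.05).
#' @return a `VariantCallSet` of the retained pooled calls.
#' @export
applyConcordanceFilter <- function(pooled, replicates, minReplicateAF = 0.05) {
  pdf <- .asCallDF(pooled, "pooled")
  rdf <- .asCallDF(replicates, "replicates")
  rdf <- rdf[rdf$replicate_id != "pooled", , drop = FALSE]
  orphan <- setdiff(unique(pdf$sample_id), unique(rdf$sample_id))
  if (length(orphan))
    stop(sprintf("no replicate data for sample(s): %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  supported <- unique(.variantKey(rdf[rdf$af > minReplicateAF, , drop = FALSE]))
  variantCallSet(pdf[.variantKey(pdf) %in% supported, , drop = FALSE])
}

#' Run the full variant-retention pipeline
#'
#' Chains the three retention stages in the order used for reporting: caller
#' thresholds on the pooled calls, annotation/population filters, then the
#' replicate-concordance rule.  When a truth table is supplied the report
#' also carries sensitivity and specificity.
#'
#' @param pooled,replicates pooled-run and per-replicate
#'   [VariantCallSet-class] objects.
#' @param minQual,minMapq,minAF caller thresholds (inclusive).
#' @param maxPopAF population-frequency cutoff.
#' @param minReplicateAF replicate concordance cutoff (exclusive).
#' @param truth optional truth table as returned by
#'   [simulateVariantReplicates()] (`sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `status`).
#' @return list with `calls` (retained `VariantCallSet`) and `report`
#'   (a [FilterReport-class] with stage counts and, given truth,
#'   sensitivity/specificity).
#' @examples
#' sim <- simulateVariantReplicates(simConfig(nSamples = 8, seed = 2))
#' res <- filterVariants(sim$pooled, sim$replicates, truth = sim$truth)
#' res$report
#' @export
filterVariants <- function(pooled, replicates,
                           minQual = 30, minMapq = 30, minAF = 0.20,
                           maxPopAF = 0.01, minReplicateAF = 0.05,
                           truth = NULL) {
  s0 <- length(pooled <- variantCallSet(.asCallDF(pooled, "pooled")))
  s1 <- applyCallThresholds(pooled, minQual, minMapq, minAF)
  s2 <- applyAnnotationFilters(s1, maxPopAF)
  s3 <- applyConcordanceFilter(s2, replicates, minReplicateAF)
  counts <- c(candidates = s0, caller_thresholds = length(s1),
              annotation = length(s2), concordance = length(s3))
  report <- if (is.null(truth))
    new("FilterReport", stageCounts = as.integer(counts) |>
          stats::setNames(names(counts)),
        sensitivity = NA_real_, specificity = NA_real_,
        sensitivityDefined = FALSE, specificityDefined = FALSE)
  else
    evaluateFilterPerformance(s3, truth, stageCounts = counts)
  list(calls = s3, report = report)
}

#' Evaluate filter performance against a truth table
#'
#' Sensitivity is the fraction of true variants retained; specificity is the
#' fraction of artifacts rejected.  A rate with an empty denominator is
#' reported as `NA` with its `*Defined` flag unset.
#'
#' @param retained retained calls ([VariantCallSet-class] or data frame).
#' @param truth truth table labeling every candidate variant
#'   (`sample_id`, `chrom`, `pos`, `ref`, `alt`, `status` in
#'   `"true"`/`"artifact"`).  Every retained variant must appear in it.
#' @param stageCounts optional named counts for the report.
#' @return a [FilterReport-class].
#' @export
evaluateFilterPerformance <- function(retained, truth, stageCounts = NULL) {
  rdf <- .asCallDF(retained, "retained")
  .requireCols(truth, c("sample_id", "chrom", "pos", "ref", "alt", "status"),
               "truth table")
  truthKey <- .variantKey(truth)
  retKey <- unique(.variantKey(rdf))
  stray <- setdiff(retKey, truthKey)
  if (length(stray))
    stop(sprintf("%d retained variant(s) absent from the truth table",
                 length(stray)), call. = FALSE)
  isTrue <- truth$status == "true"
  nTrue <- sum(isTrue)
  nArt <- sum(!isTrue)
  sens <- if (nTrue > 0L) sum(truthKey[isTrue] %in% retKey) / nTrue else
    NA_real_
  spec <- if (nArt > 0L) sum(!truthKey[!isTrue] %in% retKey) / nArt else
    NA_real_
  if (is.null(stageCounts))
    stageCounts <- c(candidates = nrow(truth), retained = nrow(rdf))
  new("FilterReport",
      stageCounts = stats::setNames(as.integer(stageCounts),
                                    names(stageCounts)),
      sensitivity = sens, specificity = spec,
      sensitivityDefined = nTrue > 0L, specificityDefined = nArt > 0L)
}

#' Convert retained calls to a reportable mutation table
#'
#' Produces the reportable-mutation shape (one row per distinct
#' sample/site/alternate allele): sample, gene, exonic function,
#' coordinates, observed allele and, when carried on the input, the
#' damage-predictor tally.
#'
#' @param x retained calls ([VariantCallSet-class] or data frame).
#' @return data frame of mutation records with columns `sample_id`, `gene`,
#'   `function_class`, `chrom`, `start`, `ref`, `obs`, `damaging_tally`.
#' @export
asMutationTable <- function(x) {
  df <- .asCallDF(x)
  df <- df[!(df$function_class %in% c("synonymous", "intronic")), ,
           drop = FALSE]
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    gene = df$gene,
    function_class = df$function_class,
    chrom = df$chrom,
    start = df$pos,
    ref = df$ref,
    obs = df$alt,
    damaging_tally = if ("damaging_tally" %in% names(df))
      df$damaging_tally else NA_character_,
    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$sample_id, out$chrom, out$start, out$obs)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a mutation table
#'
#' Counts mutations and affected patients and reports per-gene and
#' per-functional-class shares.  Percentages are rounded to the nearest
#' integer, the convention used in cohort reports.
#'
#' @param records mutation table (e.g. from [asMutationTable()] or
#'   [loadTable1()]), deduplicated to one row per
#'   sample/chromosome/start/observed allele.
#' @param cohortSize total number of patients screened; when supplied the
#'   affected-patient percentage is reported.
#' @return list with `nMutations`, `nPatients`, `patientPercent` (or `NA`
#'   without `cohortSize`), `genePercent` and `functionClassPercent` (named,
#'   integer-rounded), plus the raw fraction tables `geneFraction` and
#'   `functionClassFraction`.
#' @examples
#' summarizeMutationTable(loadTable1(), cohortSize = 57)[1:3]
#' @export
summarizeMutationTable <- function(records, cohortSize = NULL) {
  .requireCols(records, c("sample_id", "gene", "function_class"),
               "mutation table")
  n <- nrow(records)
  nPatients <- length(unique(records$sample_id))
  if (!is.null(cohortSize) && cohortSize < nPatients)
    stop(sprintf("cohort size %d is smaller than the %d mutated patients",
                 cohortSize, nPatients), call. = FALSE)
  fracOf <- function(v) if (n == 0L) numeric(0) else
    sort(table(v) / n, decreasing = TRUE)
  geneFrac <- fracOf(records$gene)
  classFrac <- fracOf(records$function_class)
  list(
    nMutations = n,
    nPatients = nPatients,
    patientPercent = if (is.null(cohortSize)) NA_real_ else
      round(100 * nPatients / cohortSize),
    genePercent = round(100 * geneFrac),
    functionClassPercent = round(100 * classFrac),
    geneFraction = geneFrac,
    functionClassFraction = classFrac
  )
}
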