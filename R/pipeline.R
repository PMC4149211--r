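# End-to-end orchestration: simulate or read inputs, filter variants,
# summarize mutations, run the dosage and expression analyses and the
# survival grid, and write every result with a provenance record.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

## default p53-pathway panel on the simulated chip: the two core dosage
## genes plus chromosome-17-neutral pathway members
.defaultPanel <- function(cohort) {
  rd <- SummarizedExperiment::rowData(cohort)
  extras <- setdiff(rd$gene[!(.isChr17(rd$chrom))], c("MLL3", "KDM6A",
                                                      "ZMYM3", "ESRRG"))
  extras <- utils::head(extras, 4L)
  data.frame(
    gene = c("TP53", "PPM1D", extras),
    category = c("core", "core",
                 rep(c("chipseq_target", "transducer"),
                     length.out = length(extras))),
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the analysis chain end to end: variant filtering (caller
#' thresholds, annotation/population filters, replicate concordance) with a
#' performance report when truth is available; mutation-table summary;
#' focal-gene dosage-excess test and p53-panel profile; subgroup ANOVA and
#' i17q two-group tests for the chromatin-remodeling genes; and the
#' survival grid.  Inputs are read from `config$inputs` when paths are
#' given, otherwise simulated from `config$sim` under `config$seed`.  All
#' results are written under `config$outDir` along with a provenance record
#' (config echo, config hash, seed, stage counts) sufficient to re-execute
#' the run.
#'
#' @param config a [runConfig()] list.
#' @return invisibly, a list with every intermediate result (`filter`,
#'   `mutationTable`, `mutationSummary`, `dosage`, `panel`, `expression`,
#'   `survival`, `files`).
#' @examples
#' \donttest{
#' cfg <- runConfig(seed = 1, outDir = tempfile(),
#'                  sim = list(nSamples = 20, nFeatures = 120,
#'                             nChr17Features = 40))
#' res <- runFullPipeline(cfg)
#' res$mutationSummary$nMutations
#' }
#' @export
runFullPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  simCfg <- .stage("configuration",
                   do.call(simConfig, c(config$sim,
                                        list(seed = config$seed))))

  ## ---- inputs -----------------------------------------------------------
  inputs <- config$inputs
  truth <- NULL
  if (length(inputs)) {
    for (p in unlist(inputs))
      if (!file.exists(p) && !dir.exists(p))
        stop(sprintf("stage 'inputs' failed: input path not found: %s", p),
             call. = FALSE)
  }
  if (!is.null(inputs$variantDir)) {
    vf <- list.files(inputs$variantDir, pattern = "\\.vcf$",
                     full.names = TRUE)
    calls <- .stage("read variants",
                    do.call(rbind, lapply(vf, function(p)
                      variantCalls(readVariantFile(p)))))
    calls <- variantCallSet(calls)
    df <- variantCalls(calls)
    pooled <- variantCallSet(df[df$replicate_id == "pooled", , drop = FALSE])
    reps <- variantCallSet(df[df$replicate_id != "pooled", , drop = FALSE])
    tp <- file.path(inputs$variantDir, "truth.tsv")
    if (file.exists(tp))
      truth <- utils::read.delim(tp, stringsAsFactors = FALSE,
                                 colClasses = c(sample_id = "character"))
  } else {
    sim <- .stage("simulate variants", simulateVariantReplicates(simCfg))
    pooled <- sim$pooled
    reps <- sim$replicates
    truth <- sim$truth
  }
  cohort <- if (!is.null(inputs$expression))
    .stage("read expression",
           readExpressionBundle(inputs$expression, inputs$features,
                                inputs$samples))
  else .stage("simulate expression", simulateExpressionCohort(simCfg))
  clinical <- if (!is.null(inputs$clinical))
    .stage("read clinical", readClinicalTable(inputs$clinical))
  else .stage("simulate clinical", simulateSurvivalCohort(simCfg))

  ## ---- variant filtering and mutation summary ---------------------------
  filt <- .stage("variant filtering",
                 filterVariants(pooled, reps,
                                minQual = config$minQual,
                                minMapq = config$minMapq,
                                minAF = config$minAF,
                                maxPopAF = config$maxPopAF,
                                minReplicateAF = config$minReplicateAF,
                                truth = truth))
  mutTab <- .stage("mutation table", asMutationTable(filt$calls))
  mutSummary <- .stage("mutation summary",
                       summarizeMutationTable(mutTab,
                                              cohortSize = config$cohortSize))

  ## ---- dosage analysis --------------------------------------------------
  dosage <- .stage("dosage test",
                   focalExcessTest(cohort, focalGene = config$focalGene,
                                   breakpoint = config$breakpoint,
                                   alpha = config$alpha))
  panel <- .stage("panel profile",
                  pathwayPanelProfile(cohort, .defaultPanel(cohort)))

  ## ---- subgroup / i17q expression tests ---------------------------------
  crGenes <- intersect(c("MLL3", "KDM6A", "ZMYM3", "GPS2"),
                       SummarizedExperiment::rowData(cohort)$gene)
  expression <- .stage("expression comparisons", lapply(
    stats::setNames(crGenes, crGenes), function(g) list(
      anova = subgroupAnova(cohort, g),
      i17q = twoGroupTest(cohort, g, grouping = "i17q"))))

  ## ---- survival ---------------------------------------------------------
  clinical2 <- .stage("combined risk", assignCombinedRisk(clinical))
  survivalReport <- .stage("survival analysis",
                           runSurvivalAnalysis(clinical2))

  ## ---- outputs ----------------------------------------------------------
  files <- .stage("write outputs", {
    f <- character(0)
    p <- file.path(outDir, "mutation_table.tsv")
    utils::write.table(mutTab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f <- c(f, p)
    p <- file.path(outDir, "filter_report.json")
    jsonlite::write_json(list(
      stageCounts = as.list(filt$report@stageCounts),
      sensitivity = filt$report@sensitivity,
      specificity = filt$report@specificity), p, auto_unbox = TRUE,
      digits = NA, na = "null")
    f <- c(f, p)
    p <- file.path(outDir, "mutation_summary.json")
    jsonlite::write_json(lapply(mutSummary, as.list), p, auto_unbox = TRUE,
                         digits = NA, na = "null")
    f <- c(f, p)
    p <- file.path(outDir, "dosage_test.json")
    jsonlite::write_json(list(
      focalGene = dosage@focalGene, mode = dosage@mode,
      backgroundMean = dosage@backgroundMean,
      backgroundSd = dosage@backgroundSd,
      focalFold = dosage@focalFold, focalZ = dosage@focalZ,
      tStatistic = dosage@tStatistic, pRaw = dosage@pRaw,
      nTests = dosage@nTests, pCorrected = dosage@pCorrected,
      flagged = dosage@flagged, belowTwoSD = dosage@belowTwoSD),
      p, auto_unbox = TRUE, digits = NA)
    f <- c(f, p)
    p <- file.path(outDir, "fold_expression.tsv")
    utils::write.table(dosage@folds, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f <- c(f, p)
    p <- file.path(outDir, "panel_profile.tsv")
    utils::write.table(panel, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f <- c(f, p)
    p <- file.path(outDir, "expression_tests.json")
    jsonlite::write_json(lapply(expression, function(e) list(
      anova = list(F = e$anova$statistic, p = e$anova$pValue),
      i17q = list(t = e$i17q$statistic, p = e$i17q$pValue,
                  direction = e$i17q$direction))),
      p, auto_unbox = TRUE, digits = NA)
    f <- c(f, p)
    p <- file.path(outDir, "survival_report.tsv")
    utils::write.table(as.data.frame(survivalReport), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    f <- c(f, p)
    f
  })

  ## ---- provenance -------------------------------------------------------
  cfgPath <- file.path(outDir, "run_config.yaml")
  writeRunConfig(config, cfgPath)
  prov <- list(
    package = "iso17q",
    version = as.character(utils::packageVersion("iso17q")),
    seed = config$seed,
    configFile = basename(cfgPath),
    configHash = unname(tools::md5sum(cfgPath)),
    stageCounts = as.list(filt$report@stageCounts),
    files = basename(files))
  provPath <- file.path(outDir, "provenance.json")
  jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA)

  invisible(list(filter = filt, mutationTable = mutTab,
                 mutationSummary = mutSummary, dosage = dosage,
                 panel = panel, expression = expression,
                 survival = survivalReport,
                 files = c(files, cfgPath, provPath)))
}
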