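# Readers and writers for the package's on-disk formats.  Coordinates are
# 1-based (VCF convention) everywhere; TSV dialects use explicit headers.

VCF_INFO_FIELDS <- c("SAMPLE", "REP", "GENE", "FCLASS", "POPAF", "MQ")

.writeCallVcf <- function(df, path) {
  sampleName <- unique(df$sample_id)
  if (length(sampleName) != 1L)
    stop("a VCF holds calls of exactly one sample", call. = FALSE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=iso17q",
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Sample identifier">',
    '##INFO=<ID=REP,Number=1,Type=String,Description="Replicate identifier (pooled for compiled runs)">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=FCLASS,Number=1,Type=String,Description="Functional annotation class">',
    '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Maximum documented population allele frequency">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction">',
    '##FORMAT=<ID=DP,Number=1,Type=Float,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleName, sep = "\t"))
  depth <- if ("depth" %in% names(df)) df$depth else rep(NA_real_, nrow(df))
  info <- sprintf("SAMPLE=%s;REP=%s;GENE=%s;FCLASS=%s;POPAF=%s;MQ=%s",
                  df$sample_id, df$replicate_id, df$gene, df$function_class,
                  ifelse(is.na(df$pop_af), ".",
                         formatC(df$pop_af, format = "g", digits = 15)),
                  formatC(df$mapq, format = "g", digits = 15))
  body <- paste(df$chrom, df$pos, ".", df$ref, df$alt,
                formatC(df$qual, format = "g", digits = 15), "PASS", info,
                "AF:DP",
                paste(formatC(df$af, format = "g", digits = 15),
                      ifelse(is.na(depth), ".",
                             formatC(depth, format = "g", digits = 15)),
                      sep = ":"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write simulated variant calls as VCF files plus a truth table
#'
#' Emits one VCF per sample and replicate (`<sample>_<replicate>.vcf`), one
#' pooled VCF per sample (`<sample>_pooled.vcf`), and the truth table as
#' `truth.tsv`.
#'
#' @param sim result of [simulateVariantReplicates()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeVariantFiles <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (set in list(variantCalls(sim$replicates), variantCalls(sim$pooled))) {
    if (nrow(set) == 0L) next
    for (part in split(set, paste(set$sample_id, set$replicate_id))) {
      path <- file.path(dir, sprintf("%s_%s.vcf", part$sample_id[1L],
                                     part$replicate_id[1L]))
      .writeCallVcf(part, path)
      files <- c(files, path)
    }
  }
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, truthPath))
}

#' Read a variant file (VCF or TSV dialect)
#'
#' VCF input must carry the alternate allele fraction in a FORMAT field
#' (`AF` by default); sample/replicate identity, gene, functional class,
#' population frequency and mapping quality are read from the INFO column.
#' The TSV dialect is a plain headered table with the
#' [VariantCallSet-class] columns.
#'
#' @param path file to read.
#' @param dialect `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param afField FORMAT field holding the allele fraction (VCF only).
#' @return a [VariantCallSet-class].
#' @export
readVariantFile <- function(path, dialect = c("auto", "vcf", "tsv"),
                            afField = "AF") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(sample_id = "character",
                                           replicate_id = "character"))
    .requireCols(df, VARIANT_CALL_COLUMNS, sprintf("variant TSV %s", path))
    for (col in c("pos", "qual", "mapq", "af", "pop_af"))
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(df$pos) | !is.finite(df$af))
    if (length(bad))
      stop(sprintf("malformed record in %s at line %d", path, bad[1L] + 1L),
           call. = FALSE)
    return(variantCallSet(df))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variantCallSet(data.frame(
      sample_id = character(0), replicate_id = character(0),
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), qual = numeric(0), mapq = numeric(0),
      af = numeric(0), function_class = character(0), pop_af = numeric(0),
      gene = character(0))))
  fmtIds <- unique(unlist(regmatches(
    vcf@gt[, "FORMAT"], gregexpr("[A-Za-z0-9]+", vcf@gt[, "FORMAT"]))))
  if (!afField %in% fmtIds)
    stop(sprintf("VCF %s has no '%s' FORMAT field", path, afField),
         call. = FALSE)
  af <- suppressWarnings(as.numeric(
    vcfR::extract.gt(vcf, element = afField)[, 1L]))
  dp <- if ("DP" %in% fmtIds) suppressWarnings(as.numeric(
    vcfR::extract.gt(vcf, element = "DP")[, 1L])) else NA_real_
  getInfo <- function(id) vcfR::extract.info(vcf, element = id)
  popaf <- suppressWarnings(as.numeric(getInfo("POPAF")))
  mq <- suppressWarnings(as.numeric(getInfo("MQ")))
  df <- data.frame(
    sample_id = getInfo("SAMPLE"),
    replicate_id = getInfo("REP"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mapq = mq,
    af = af,
    function_class = getInfo("FCLASS"),
    pop_af = popaf,
    gene = getInfo("GENE"),
    depth = dp,
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$pos) | is.na(df$af))
  if (length(bad))
    stop(sprintf("malformed record in %s (record %d)", path, bad[1L]),
         call. = FALSE)
  variantCallSet(df)
}

#' Write a variant call table as TSV
#'
#' @param x a [VariantCallSet-class] or data frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeVariantTsv <- function(x, path) {
  utils::write.table(.asCallDF(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an expression cohort as a TSV bundle
#'
#' Three files: the log2 matrix (`expression.tsv`, features x samples with a
#' `feature` column), feature metadata (`features.tsv`) and sample metadata
#' (`samples.tsv`).
#'
#' @param cohort an [ExpressionCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths.
#' @export
writeExpressionBundle <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exprPath <- file.path(dir, "expression.tsv")
  featPath <- file.path(dir, "features.tsv")
  sampPath <- file.path(dir, "samples.tsv")
  mat <- exprMatrix(cohort)
  utils::write.table(
    data.frame(feature = rownames(mat), mat, check.names = FALSE),
    exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature = rownames(cohort),
               as.data.frame(SummarizedExperiment::rowData(cohort))),
    featPath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(cohort),
               as.data.frame(SummarizedExperiment::colData(cohort))),
    sampPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(exprPath, featPath, sampPath))
}

#' Read an expression cohort from a TSV bundle
#'
#' @param exprPath matrix TSV (first column `feature`, one column per
#'   sample).
#' @param featurePath feature metadata TSV (`feature`, `gene`, `chrom`,
#'   `pos`, `n_probes`).
#' @param samplePath sample metadata TSV (`sample`, `subgroup`,
#'   `i17q_status`, `sex`).
#' @return an [ExpressionCohort-class].
#' @export
readExpressionBundle <- function(exprPath, featurePath, samplePath) {
  for (p in c(exprPath, featurePath, samplePath))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  exprDf <- utils::read.delim(exprPath, check.names = FALSE,
                              stringsAsFactors = FALSE)
  .requireCols(exprDf, "feature", "expression matrix")
  mat <- as.matrix(exprDf[, -1L, drop = FALSE])
  rownames(mat) <- exprDf$feature
  feat <- utils::read.delim(featurePath, stringsAsFactors = FALSE)
  .requireCols(feat, c("feature", "gene", "chrom", "pos", "n_probes"),
               "feature metadata")
  samp <- utils::read.delim(samplePath, stringsAsFactors = FALSE)
  .requireCols(samp, c("sample", "subgroup", "i17q_status", "sex"),
               "sample metadata")
  if (nrow(feat) != nrow(mat))
    stop(sprintf("feature metadata has %d rows but matrix has %d features",
                 nrow(feat), nrow(mat)), call. = FALSE)
  missing <- setdiff(colnames(mat), samp$sample)
  if (length(missing))
    stop(sprintf("sample(s) in matrix missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(samp) != ncol(mat))
    stop(sprintf("sample metadata has %d rows but matrix has %d samples",
                 nrow(samp), ncol(mat)), call. = FALSE)
  if (anyDuplicated(feat$feature))
    stop("duplicate feature identifiers in metadata", call. = FALSE)
  feat <- feat[match(rownames(mat), feat$feature), , drop = FALSE]
  if (anyNA(feat$feature))
    stop("feature metadata does not cover every matrix feature",
         call. = FALSE)
  samp <- samp[match(colnames(mat), samp$sample), , drop = FALSE]
  fd <- feat[, c("gene", "chrom", "pos", "n_probes")]
  rownames(fd) <- feat$feature
  sd <- samp[, c("subgroup", "i17q_status", "sex")]
  rownames(sd) <- samp$sample
  expressionCohort(mat, fd, sd)
}

#' Read or write a clinical table
#'
#' @param path TSV with the clinical columns (`patient_id`, `risk_group`,
#'   `mutation_positive`, `i17q_positive`, `os_time`, `os_event`,
#'   `dfs_time`, `dfs_event`).
#' @return the validated clinical data frame.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  for (col in c("mutation_positive", "i17q_positive", "os_event",
                "dfs_event"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  .checkClinical(df)
  df
}

#' @rdname readClinicalTable
#' @param records clinical data frame to write.
#' @export
writeClinicalTable <- function(records, path) {
  .checkClinical(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run configuration for the end-to-end analysis
#'
#' Bundles every threshold and path of the full pipeline into a named list
#' that round-trips losslessly through YAML or JSON.
#'
#' @param seed integer seed forwarded to the simulators.
#' @param minQual,minMapq,minAF,maxPopAF,minReplicateAF variant-filter
#'   thresholds (see [filterVariants()]).
#' @param breakpoint,alpha,focalGene dosage-test settings.
#' @param cohortSize denominator for the mutation-summary patient
#'   percentage.
#' @param outDir output directory of [runFullPipeline()].
#' @param sim named list of [simConfig()] overrides used when no input
#'   paths are given.
#' @param inputs optional named list of input paths (`variantDir`,
#'   `expression`, `features`, `samples`, `clinical`); when absent the
#'   pipeline simulates its inputs.
#' @return a validated `runConfig` list.
#' @export
runConfig <- function(seed = 1L, minQual = 30, minMapq = 30, minAF = 0.20,
                      maxPopAF = 0.01, minReplicateAF = 0.05,
                      breakpoint = 2e7, alpha = 0.05, focalGene = "TP53",
                      cohortSize = 57L, outDir = "iso17q-results",
                      sim = list(), inputs = list()) {
  cfg <- list(seed = as.integer(seed), minQual = minQual, minMapq = minMapq,
              minAF = minAF, maxPopAF = maxPopAF,
              minReplicateAF = minReplicateAF, breakpoint = breakpoint,
              alpha = alpha, focalGene = focalGene,
              cohortSize = as.integer(cohortSize), outDir = outDir,
              sim = sim, inputs = inputs)
  for (field in c("minQual", "minMapq", "minAF", "maxPopAF",
                  "minReplicateAF", "breakpoint", "alpha")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("invalid '%s': must be a single non-negative number",
                   field), call. = FALSE)
  }
  if (cfg$minAF > 1 || cfg$maxPopAF > 1 || cfg$minReplicateAF > 1 ||
      cfg$alpha > 1)
    stop("fraction thresholds must lie in [0, 1]", call. = FALSE)
  class(cfg) <- "runConfig"
  cfg
}

#' @rdname runConfig
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$sim <- as.list(raw$sim)
  raw$inputs <- as.list(raw$inputs)
  do.call(runConfig, raw)
}

#' @rdname runConfig
#' @param config a `runConfig` to serialize.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "runConfig"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(unclass(config), path)
  else
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}
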