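# Synthetic cohorts with the statistical structure the downstream analyses
# assume: per-replicate FFPE amplicon variant calls, chromosome 17
# dosage-structured expression, and stratified survival.

CHR17_LENGTH <- 81195210

## Amplicon panel layout: the four chromatin-remodeling genes, with block
## sizes roughly proportional to coding footprint (MLL3 dominates).
PANEL_GENES <- data.frame(
  gene = c("MLL3", "KDM6A", "ZMYM3", "GPS2"),
  chrom = c("chr7", "chrX", "chrX", "chr17"),
  start = c(151830000, 44900000, 70460000, 7210000),
  frac = c(0.60, 0.20, 0.14, 0.06),
  stringsAsFactors = FALSE
)

BASES <- c("A", "C", "G", "T")
## deamination-biased substitution: C->T and G->A for C/G reference sites,
## transitions elsewhere
TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

## site index (1..nSites) -> gene / chrom / genomic coordinate / ref base
.siteInfo <- function(sites, nSites) {
  bounds <- cumsum(round(PANEL_GENES$frac * nSites))
  bounds[length(bounds)] <- nSites
  idx <- findInterval(sites - 1L, c(0L, bounds), rightmost.closed = FALSE)
  idx[idx > nrow(PANEL_GENES)] <- nrow(PANEL_GENES)
  offset <- sites - c(0L, bounds)[idx] - 1L
  data.frame(
    site = sites,
    gene = PANEL_GENES$gene[idx],
    chrom = PANEL_GENES$chrom[idx],
    pos = PANEL_GENES$start[idx] + offset,
    ref = BASES[(sites %% 4L) + 1L],
    stringsAsFactors = FALSE
  )
}

#' Simulate per-replicate variant calls with FFPE artifacts
#'
#' Emulates amplification-based sequencing of FFPE tumors with independent
#' amplification replicates per sample.  True somatic variants appear in
#' every replicate of their sample at an allele fraction drawn from
#' `trueAFRange`; artifact calls (crosslinking/deamination damage and PCR
#' jackpotting) arise independently in each replicate at uniformly chosen
#' panel sites with substitutions biased toward C>T / G>A and right-skewed
#' allele fractions below 0.3.  A pooled call set per sample mimics variant
#' calling on compiled alignments: the union of replicate calls with the
#' allele fraction recomputed as the read-depth-weighted mean across
#' replicates (replicates lacking the call contribute depth at allele
#' fraction 0).
#'
#' Site-level annotation (functional class, documented population frequency)
#' is a fixed property of the site, so the same artifact seen in two
#' replicates carries identical annotation.  True variants are treated as
#' novel somatic events: protein-altering classes, absent from population
#' databases.
#'
#' @param config a [SimConfig-class]; `nReplicates` must be at least 2.
#' @return list with elements `replicates` (a [VariantCallSet-class] of
#'   per-replicate calls), `pooled` (a `VariantCallSet` of compiled-run calls,
#'   `replicate_id == "pooled"`), and `truth` (data frame labeling every
#'   pooled variant `"true"` or `"artifact"`).
#' @examples
#' sim <- simulateVariantReplicates(simConfig(nSamples = 5, seed = 7))
#' table(sim$truth$status)
#' @export
simulateVariantReplicates <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nReplicates < 2L)
    stop("invalid 'nReplicates': the concordance design requires >= 2 replicates",
         call. = FALSE)
  set.seed(config@seed)
  nSites <- config@nSites
  nReps <- config@nReplicates
  repIds <- sprintf("r%d", seq_len(nReps))

  ## fixed per-site annotation (a property of the locus, shared by any
  ## artifact recurrence at that site)
  siteClass <- sample(FUNCTION_CLASSES, nSites, replace = TRUE,
                      prob = c(0.45, 0.05, 0.04, 0.06, 0.25, 0.10, 0.05))
  sitePopAF <- ifelse(stats::runif(nSites) < 0.85, NA_real_,
                      stats::runif(nSites, 0, 0.05))

  rDepth <- function(n) stats::rlnorm(n, log(config@meanDepth),
                                      config@depthSdLog)

  repRows <- vector("list", config@nSamples)
  pooledRows <- vector("list", config@nSamples)
  truthRows <- vector("list", config@nSamples)

  for (i in seq_len(config@nSamples)) {
    sid <- sprintf("S%03d", i)

    ## -- true somatic variants: all replicates, AF in trueAFRange ----------
    nTrue <- stats::rpois(1L, config@trueVariantRate)
    nTrue <- min(nTrue, nSites)
    true <- NULL
    if (nTrue > 0L) {
      info <- .siteInfo(sample.int(nSites, nTrue), nSites)
      alt <- vapply(info$ref,
                    function(r) sample(setdiff(BASES, r), 1L), "")
      true <- data.frame(
        info, alt = alt,
        function_class = sample(c("nonsynonymous", "stopgain", "frameshift",
                                  "splice_site", "other"),
                                nTrue, replace = TRUE,
                                prob = c(0.60, 0.12, 0.08, 0.12, 0.08)),
        pop_af = NA_real_, stringsAsFactors = FALSE)
    }

    ## -- artifacts: independent per replicate ------------------------------
    art <- vector("list", nReps)
    for (r in seq_len(nReps)) {
      m <- min(stats::rpois(1L, config@artifactRate), nSites)
      if (m == 0L) next
      info <- .siteInfo(sample.int(nSites, m), nSites)
      art[[r]] <- data.frame(
        info, alt = unname(TRANSITION[info$ref]),
        function_class = siteClass[info$site],
        pop_af = sitePopAF[info$site],
        replicate_id = repIds[r],
        af = 0.3 * stats::rbeta(m, config@artifactAFShape[1L],
                                config@artifactAFShape[2L]),
        qual = stats::runif(m, 20, 200),
        mapq = stats::runif(m, 20, 60),
        depth = rDepth(m), stringsAsFactors = FALSE)
    }
    art <- if (length(art)) do.call(rbind, art) else NULL

    ## drop artifacts colliding with a true variant of the same sample
    if (!is.null(art) && !is.null(true)) {
      art <- art[!paste(art$site, art$alt) %in% paste(true$site, true$alt), ,
                 drop = FALSE]
      if (nrow(art) == 0L) art <- NULL
    }

    trueRep <- NULL
    if (!is.null(true)) {
      k <- nrow(true)
      trueRep <- true[rep(seq_len(k), times = nReps), , drop = FALSE]
      trueRep$replicate_id <- rep(repIds, each = k)
      n <- nrow(trueRep)
      trueRep$af <- stats::runif(n, config@trueAFRange[1L],
                                 config@trueAFRange[2L])
      trueRep$qual <- stats::runif(n, 80, 1000)
      trueRep$mapq <- stats::runif(n, 42, 60)
      trueRep$depth <- rDepth(n)
    }

    calls <- rbind(trueRep, art)
    if (is.null(calls) || nrow(calls) == 0L) next
    calls$sample_id <- sid

    ## -- pooled (compiled-alignment) calls ---------------------------------
    key <- paste(calls$site, calls$alt)
    first <- !duplicated(key)
    uk <- key[first]
    nPresent <- as.vector(table(key)[uk])
    sumAD <- as.vector(tapply(calls$af * calls$depth, key, sum)[uk])
    sumD <- as.vector(tapply(calls$depth, key, sum)[uk])
    sumQD <- as.vector(tapply(calls$qual * calls$depth, key, sum)[uk])
    sumMD <- as.vector(tapply(calls$mapq * calls$depth, key, sum)[uk])
    ## replicates without the call still contribute reads at AF 0
    extraD <- vapply(nReps - nPresent,
                     function(k) if (k > 0L) sum(rDepth(k)) else 0, 0)
    pooled <- calls[first, , drop = FALSE]
    pooled$replicate_id <- "pooled"
    pooled$af <- sumAD / (sumD + extraD)
    pooled$qual <- sumQD / sumD
    pooled$mapq <- sumMD / sumD
    pooled$depth <- sumD + extraD

    isTrue <- if (is.null(true)) rep(FALSE, nrow(pooled)) else
      paste(pooled$site, pooled$alt) %in% paste(true$site, true$alt)

    repRows[[i]] <- calls
    pooledRows[[i]] <- pooled
    truthRows[[i]] <- data.frame(
      sample_id = sid, chrom = pooled$chrom, pos = pooled$pos,
      ref = pooled$ref, alt = pooled$alt,
      status = ifelse(isTrue, "true", "artifact"),
      stringsAsFactors = FALSE)
  }

  finish <- function(rows) {
    if (all(vapply(rows, is.null, TRUE))) {
      df <- data.frame(sample_id = character(0), replicate_id = character(0),
                       chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       qual = numeric(0), mapq = numeric(0), af = numeric(0),
                       function_class = character(0), pop_af = numeric(0),
                       gene = character(0), depth = numeric(0))
      return(variantCallSet(df))
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    df <- df[, c("sample_id", "replicate_id", "chrom", "pos", "ref", "alt",
                 "qual", "mapq", "af", "function_class", "pop_af", "gene",
                 "depth")]
    rownames(df) <- NULL
    variantCallSet(df)
  }

  truth <- truthRows[!vapply(truthRows, is.null, TRUE)]
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               status = character(0))
  rownames(truth) <- NULL

  list(replicates = finish(repRows), pooled = finish(pooledRows),
       truth = truth)
}

## Reserved, biologically anchored features always present in the simulated
## chip: TP53 (focal, 17p), GPS2 (17p13), PPM1D/WIP1 (17q), and non-chr17
## genes used by the subgroup comparisons.
RESERVED_FEATURES <- data.frame(
  gene = c("TP53", "GPS2", "PPM1D", "MLL3", "KDM6A", "ZMYM3", "ESRRG"),
  chrom = c("chr17", "chr17", "chr17", "chr7", "chrX", "chrX", "chr1"),
  pos = c(7571720, 7217225, 58711000, 151830000, 44900000, 70460000,
          216500000),
  stringsAsFactors = FALSE
)

#' Simulate an expression cohort with i17q dosage structure
#'
#' Generates a log2 expression matrix in which i17q-positive samples carry
#' `log2(hemizygousFold)` on chromosome 17 features telomeric to the
#' breakpoint (one copy retained), `log2(duplicatedFold)` on features at or
#' beyond it (three copies), an additional `-focalExcessLog2` on the focal
#' gene TP53, and Gaussian noise everywhere.  Half of the chromosome 17
#' features (including TP53 and GPS2) are placed below the breakpoint, the
#' rest (including PPM1D/WIP1) above it.  i17q-positive samples are labeled
#' group 4 with probability `group4Prob` and group 3 otherwise; negative
#' samples are spread over the four subgroups.
#'
#' @param config a [SimConfig-class].  `nChr17Features` must be at least 3
#'   and at least 4 features must remain off chromosome 17; `breakpoint`
#'   must lie inside chromosome 17 and beyond the fixed 17p gene positions.
#' @return an [ExpressionCohort-class].
#' @examples
#' cohort <- simulateExpressionCohort(simConfig(nSamples = 20, seed = 3))
#' cohort
#' @export
simulateExpressionCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@breakpoint < 1 || config@breakpoint > CHR17_LENGTH)
    stop(sprintf("breakpoint %.0f is outside the simulated chromosome 17 range [1, %d]",
                 config@breakpoint, CHR17_LENGTH), call. = FALSE)
  if (config@breakpoint <= max(RESERVED_FEATURES$pos[
        RESERVED_FEATURES$gene %in% c("TP53", "GPS2")]))
    stop("breakpoint must lie beyond the fixed 17p gene positions (> 7571720)",
         call. = FALSE)
  if (config@nChr17Features < 3L)
    stop("invalid 'nChr17Features': need at least 3 (TP53, GPS2, PPM1D)",
         call. = FALSE)
  if (config@nFeatures - config@nChr17Features < 4L)
    stop("invalid 'nFeatures': need at least 4 features off chromosome 17",
         call. = FALSE)
  set.seed(config@seed)

  nChr17 <- config@nChr17Features
  nHemi <- max(2L, round(nChr17 / 2))
  nOther <- config@nFeatures - nChr17

  res17 <- RESERVED_FEATURES[RESERVED_FEATURES$chrom == "chr17", ]
  resOther <- RESERVED_FEATURES[RESERVED_FEATURES$chrom != "chr17", ]

  extraHemi <- nHemi - 2L                      # beyond TP53, GPS2
  extraDup <- nChr17 - nHemi - 1L              # beyond PPM1D
  if (extraDup < 0L) { extraDup <- 0L; extraHemi <- nChr17 - 3L }
  hemiPos <- if (extraHemi > 0L)
    sample(seq(1e6, config@breakpoint - 1), extraHemi) else numeric(0)
  dupPos <- if (extraDup > 0L)
    sample(seq(ceiling(config@breakpoint), CHR17_LENGTH), extraDup) else
    numeric(0)
  chr17Extra <- data.frame(
    gene = sprintf("C17F%04d", seq_len(extraHemi + extraDup)),
    chrom = "chr17", pos = c(hemiPos, dupPos), stringsAsFactors = FALSE)

  otherExtraN <- nOther - nrow(resOther)
  otherExtra <- data.frame(
    gene = sprintf("FEAT%04d", seq_len(otherExtraN)),
    chrom = sample(paste0("chr", c(1:16, 18:22)), otherExtraN,
                   replace = TRUE),
    pos = sample.int(1e8, otherExtraN, replace = TRUE),
    stringsAsFactors = FALSE)

  features <- rbind(res17, chr17Extra, resOther, otherExtra)
  features$n_probes <- sample.int(10L, nrow(features), replace = TRUE)
  rownames(features) <- features$gene

  n <- config@nSamples
  nPos <- min(max(1L, round(n * config@i17qFraction)), n - 1L)
  status <- sample(c(rep(1L, nPos), rep(0L, n - nPos)))
  subgroup <- character(n)
  subgroup[status == 1L] <- ifelse(
    stats::runif(nPos) < config@group4Prob, "group4", "group3")
  subgroup[status == 0L] <- sample(MB_SUBGROUPS, n - nPos, replace = TRUE,
                                   prob = c(0.10, 0.35, 0.27, 0.28))
  sex <- ifelse(stats::runif(n) < ifelse(status == 1L, 0.84, 0.55),
                "M", "F")
  samples <- data.frame(subgroup = subgroup, i17q_status = status, sex = sex,
                        row.names = sprintf("S%03d", seq_len(n)),
                        stringsAsFactors = FALSE)

  baseline <- stats::rnorm(nrow(features), 8, 1.5)
  onChr17 <- .isChr17(features$chrom)
  dosage <- numeric(nrow(features))
  dosage[onChr17 & features$pos < config@breakpoint] <-
    log2(config@hemizygousFold)
  dosage[onChr17 & features$pos >= config@breakpoint] <-
    log2(config@duplicatedFold)
  focalShift <- ifelse(features$gene == "TP53", -config@focalExcessLog2, 0)

  mat <- matrix(baseline, nrow(features), n) +
    outer(dosage + focalShift, as.numeric(status)) +
    matrix(stats::rnorm(nrow(features) * n, 0, config@noiseSD),
           nrow(features), n)
  dimnames(mat) <- list(rownames(features), rownames(samples))

  expressionCohort(mat, features, samples)
}

#' Simulate a clinical survival cohort
#'
#' Event times are exponential with the per-stratum hazard from
#' `hazardByGroup`; death and relapse hazards are equal and independent, so
#' disease-free survival (first of relapse or death) never exceeds overall
#' survival.  All subjects are administratively censored at `censorTime`.
#' Molecular flags (`mutation_positive`, `i17q_positive`) and the clinical
#' risk group are drawn per patient; by default the hazard stratum is
#' `"high"` when either molecular flag is set and `"low"` otherwise.
#'
#' @param config a [SimConfig-class]; `hazardByGroup` must name every
#'   stratum used.
#' @param riskAssignment optional character vector (one stratum name per
#'   patient) overriding the default molecular-risk stratum.
#' @return data frame of clinical records: `patient_id`, `risk_group`
#'   (SR/HR), `mutation_positive`, `i17q_positive`, `stratum`, `os_time`,
#'   `os_event`, `dfs_time`, `dfs_event`.
#' @examples
#' clin <- simulateSurvivalCohort(simConfig(nSamples = 30, seed = 11))
#' head(clin)
#' @export
simulateSurvivalCohort <- function(config, riskAssignment = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples
  mutation <- stats::runif(n) < 0.18
  i17q <- stats::runif(n) < config@i17qFraction
  risk <- ifelse(stats::runif(n) < 0.6, "SR", "HR")
  stratum <- if (is.null(riskAssignment))
    ifelse(mutation | i17q, "high", "low") else as.character(riskAssignment)
  if (length(stratum) != n)
    stop(sprintf("riskAssignment must have length %d", n), call. = FALSE)
  h <- config@hazardByGroup
  unknown <- setdiff(unique(stratum), names(h))
  if (length(unknown))
    stop(sprintf("invalid 'hazardByGroup': no hazard for stratum %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  rate <- h[stratum]
  death <- stats::rexp(n, rate)
  relapse <- stats::rexp(n, rate)
  firstEvent <- pmin(death, relapse)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    risk_group = risk,
    mutation_positive = mutation,
    i17q_positive = i17q,
    stratum = stratum,
    os_time = pmin(death, config@censorTime),
    os_event = death <= config@censorTime,
    dfs_time = pmin(firstEvent, config@censorTime),
    dfs_event = firstEvent <= config@censorTime,
    stringsAsFactors = FALSE
  )
}

#' Load the packaged 57-tumor mutation table
#'
#' Reads the packaged fixture transcribing the 13 filtered mutations reported
#' in a 57-tumor consecutive medulloblastoma cohort (sample, gene, exonic
#' function, damage-predictor tally, coordinates and alleles).
#'
#' @param path fixture path; defaults to the copy shipped with the package.
#' @return data frame of 13 mutation records with columns `sample_id`,
#'   `location`, `gene`, `function_class`, `damaging_tally`, `chrom`,
#'   `start`, `ref`, `obs`.
#' @examples
#' tab1 <- loadTable1()
#' nrow(tab1)
#' @export
loadTable1 <- function(path = system.file("extdata", "table1_mutations.tsv",
                                          package = "iso17q")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("mutation-table fixture not found", call. = FALSE)
  tab <- tryCatch(
    suppressWarnings(
      utils::read.delim(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       damaging_tally = "character"))),
    error = function(e)
      stop(sprintf("mutation-table fixture is corrupt: %s", conditionMessage(e)),
           call. = FALSE))
  need <- c("sample_id", "gene", "function_class", "chrom", "start",
            "ref", "obs")
  missing <- setdiff(need, names(tab))
  if (length(missing) || nrow(tab) == 0L || anyNA(tab[, need[-5]]) ||
      !is.numeric(tab$start))
    stop("mutation-table fixture is corrupt", call. = FALSE)
  tab
}
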