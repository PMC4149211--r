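# Probe-normalized expression comparisons: one-way ANOVA across the four
# molecular medulloblastoma subgroups and two-group tests by i17q status,
# sex, or any binary grouping (optionally within one subgroup).

#' Normalize feature values by probe count
#'
#' Divides each feature's values by its number of microarray probes, putting
#' features with different probe counts on a directly comparable per-probe
#' scale.  Features already summarized from a single probe pass through
#' unchanged.  After normalization `n_probes` is reset to 1.
#'
#' @param cohort an [ExpressionCohort-class]; every feature needs
#'   `n_probes >= 1`.
#' @return a probe-normalized [ExpressionCohort-class].
#' @export
probeNormalize <- function(cohort) {
  stopifnot(is(cohort, "ExpressionCohort"))
  np <- probeCounts(cohort)
  if (anyNA(np) || any(np < 1L))
    stop("every feature needs n_probes >= 1", call. = FALSE)
  fd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  mat <- exprMatrix(cohort) / np
  fd$n_probes <- 1L
  expressionCohort(mat, fd,
                   as.data.frame(SummarizedExperiment::colData(cohort)))
}

.geneValues <- function(cohort, gene) {
  rd <- SummarizedExperiment::rowData(cohort)
  row <- which(rd$gene == gene)
  if (length(row) == 0L)
    stop(sprintf("gene %s is not in the cohort", gene), call. = FALSE)
  if (length(row) > 1L)
    stop(sprintf("gene %s matches %d features; aggregate first",
                 gene, length(row)), call. = FALSE)
  exprMatrix(cohort)[row, ]
}

.groupStats <- function(values, groups) {
  g <- split(values, groups, drop = TRUE)
  data.frame(group = names(g),
             n = vapply(g, length, 0L),
             mean = vapply(g, mean, 0),
             sd = vapply(g, stats::sd, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("%s test for %s\n", x$method, x$gene))
  print(x$groupStats, row.names = FALSE)
  cat(sprintf("  %s = %.4f (df %s), p = %.4g\n",
              if (x$method == "ANOVA") "F" else "t",
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$pValue))
  if (length(x$excluded))
    cat("  excluded groups (<2 samples):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' One-way ANOVA of a gene across molecular subgroups
#'
#' Fixed-effects one-way ANOVA of a gene's log2 expression across the
#' WNT / SHH / group3 / group4 subgroups.  Subgroups with fewer than 2
#' samples are excluded with a warning and recorded in the result.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param gene gene symbol (must match exactly one feature).
#' @return a `groupComparison` list: `gene`, `method = "ANOVA"`,
#'   `groupStats` (per-group n/mean/SD), `statistic` (F), `df`
#'   (between, within), `pValue`, `excluded`.
#' @examples
#' cohort <- simulateExpressionCohort(simConfig(nSamples = 40, seed = 4))
#' subgroupAnova(cohort, "MLL3")
#' @export
subgroupAnova <- function(cohort, gene) {
  values <- .geneValues(cohort, gene)
  groups <- factor(subgroups(cohort), levels = MB_SUBGROUPS)
  sizes <- table(groups)
  small <- names(sizes)[sizes > 0L & sizes < 2L]
  if (length(small)) {
    warning(sprintf("excluding subgroup(s) with <2 samples: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  } else groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 subgroups with >= 2 samples each", call. = FALSE)
  if (stats::sd(values) == 0) {
    ## degenerate constant input: no variance anywhere, F defined as 0
    fStat <- 0
    dfs <- c(nlevels(groups) - 1L, length(values) - nlevels(groups))
    pVal <- 1
  } else {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1L]]
    fStat <- tab[["F value"]][1L]
    dfs <- tab[["Df"]]
    pVal <- tab[["Pr(>F)"]][1L]
  }
  structure(list(gene = gene, method = "ANOVA",
                 groupStats = .groupStats(values, groups),
                 statistic = fStat,
                 df = dfs,
                 pValue = pVal,
                 excluded = small),
            class = "groupComparison")
}

#' Two-group expression test for a gene
#'
#' Welch (default) or pooled-variance t-test of a gene's log2 expression
#' between two classes: i17q-positive vs negative, male vs female, or any
#' user-supplied binary grouping, optionally restricted to one molecular
#' subgroup (e.g. the i17q contrast within group 4 only).
#'
#' @param cohort an [ExpressionCohort-class].
#' @param gene gene symbol (must match exactly one feature).
#' @param grouping `"i17q"`, `"sex"`, or a vector (factor/character/logical)
#'   with one entry per sample defining two classes.
#' @param within optional subgroup label; the test is run on samples of that
#'   subgroup only.
#' @param varEqual use the pooled-variance t-test instead of Welch.
#' @return a `groupComparison` list: `gene`, `method = "t-test"`,
#'   `groupStats`, `statistic` (t, first class minus second), `df`,
#'   `pValue`, `direction` (`"lower"`/`"higher"`/`"equal"` in the first
#'   class), `excluded`.
#' @examples
#' cohort <- simulateExpressionCohort(simConfig(nSamples = 40, seed = 4))
#' twoGroupTest(cohort, "TP53", grouping = "i17q")
#' @export
twoGroupTest <- function(cohort, gene, grouping = "i17q", within = NULL,
                         varEqual = FALSE) {
  values <- .geneValues(cohort, gene)
  g <- if (is.character(grouping) && length(grouping) == 1L) {
    switch(grouping,
      i17q = factor(ifelse(i17qStatus(cohort) == 1L, "i17q+", "i17q-"),
                    levels = c("i17q+", "i17q-")),
      sex = factor(SummarizedExperiment::colData(cohort)$sex),
      stop(sprintf("unknown grouping '%s'", grouping), call. = FALSE))
  } else factor(grouping)
  if (length(g) != length(values))
    stop("grouping must have one entry per sample", call. = FALSE)
  if (!is.null(within)) {
    keep <- subgroups(cohort) == within
    if (!any(keep))
      stop(sprintf("no samples in subgroup %s", within), call. = FALSE)
    values <- values[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) != 2L)
    stop(sprintf("grouping must define exactly 2 classes, found %d",
                 nlevels(g)), call. = FALSE)
  a <- values[g == levels(g)[1L]]
  b <- values[g == levels(g)[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop(sprintf("degenerate class: %s has %d sample(s)",
                 levels(g)[which.min(c(length(a), length(b)))],
                 min(length(a), length(b))), call. = FALSE)
  ht <- .safeTTest(a, b, varEqual = varEqual)
  d <- mean(a) - mean(b)
  structure(list(gene = gene, method = "t-test",
                 groupStats = .groupStats(values, g),
                 statistic = ht$statistic, df = ht$df,
                 pValue = ht$p.value,
                 direction = if (d < 0) "lower" else
                   if (d > 0) "higher" else "equal",
                 excluded = character(0)),
            class = "groupComparison")
}
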