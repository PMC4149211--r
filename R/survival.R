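# Kaplan-Meier estimation, the two-group log-rank test, and the combined
# molecular-risk stratification (mutation OR i17q).  The product-limit and
# log-rank computations are implemented here from their defining formulas;
# the test suite cross-checks them against the survival package.

.endpointCols <- function(endpoint) {
  switch(endpoint,
         OS = c(time = "os_time", event = "os_event"),
         DFS = c(time = "dfs_time", event = "dfs_event"),
         stop(sprintf("unknown endpoint '%s' (use OS or DFS)", endpoint),
              call. = FALSE))
}

#' Kaplan-Meier product-limit curve
#'
#' Estimates survival at every distinct observed time.  At tied times events
#' are processed before censorings: both event and censored subjects with
#' time `t` count in the risk set at `t`.
#'
#' @param records clinical table (see [simulateSurvivalCohort()] for the
#'   column layout), or any data frame carrying the endpoint's time/event
#'   columns.
#' @param endpoint `"OS"` or `"DFS"`.
#' @return a [SurvivalCurve-class].
#' @examples
#' clin <- simulateSurvivalCohort(simConfig(nSamples = 40, seed = 2))
#' kmCurve(clin, "OS")
#' @export
kmCurve <- function(records, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  cols <- .endpointCols(endpoint)
  .requireCols(records, unname(cols), "clinical table")
  time <- records[[cols["time"]]]
  event <- as.logical(records[[cols["event"]]])
  if (length(time) < 1L) stop("need at least one record", call. = FALSE)
  if (any(is.na(time)) || any(time < 0))
    stop("survival times must be non-negative", call. = FALSE)
  ts <- sort(unique(time))
  nRisk <- vapply(ts, function(t) sum(time >= t), 0)
  nEvent <- vapply(ts, function(t) sum(time == t & event), 0)
  nCensor <- vapply(ts, function(t) sum(time == t & !event), 0)
  surv <- cumprod(1 - nEvent / nRisk)
  new("SurvivalCurve", time = ts, surv = surv, nRisk = nRisk,
      nEvent = nEvent, nCensor = nCensor, endpoint = endpoint)
}

.resolveGrouping <- function(records, stratifier) {
  if (length(stratifier) == nrow(records) && nrow(records) > 1L)
    return(factor(stratifier))
  switch(as.character(stratifier),
    mutation = factor(ifelse(records$mutation_positive, "mutated",
                             "wild-type")),
    i17q = factor(ifelse(records$i17q_positive, "i17q+", "i17q-")),
    combined = factor(assignCombinedRisk(records)$molecular_risk,
                      levels = c("molecular-high", "molecular-low")),
    risk = factor(records$risk_group),
    factor(stratifier))
}

#' Two-group log-rank test
#'
#' Standard (unweighted, no continuity correction) log-rank comparison of
#' two survival distributions: at each distinct event time the observed
#' events in group 1 are compared with their hypergeometric expectation and
#' variance; the squared standardized sum is referred to a chi-square with
#' one degree of freedom.
#'
#' @param records clinical table.
#' @param grouping `"mutation"`, `"i17q"`, `"combined"`, `"risk"`, or a
#'   vector with one entry per record defining two non-empty groups.
#' @param endpoint `"OS"` or `"DFS"`.
#' @return list of class `logrankTest`: `chisq`, `df`, `pValue`, and the
#'   per-group `observed`/`expected` event counts and sizes `n`.
#' @examples
#' clin <- simulateSurvivalCohort(simConfig(nSamples = 60, seed = 8))
#' logrankTest(clin, grouping = "combined", endpoint = "DFS")
#' @export
logrankTest <- function(records, grouping, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  cols <- .endpointCols(endpoint)
  .requireCols(records, unname(cols), "clinical table")
  g <- droplevels(.resolveGrouping(records, grouping))
  if (nlevels(g) != 2L)
    stop(sprintf("log-rank needs exactly 2 groups, found %d", nlevels(g)),
         call. = FALSE)
  time <- records[[cols["time"]]]
  event <- as.logical(records[[cols["event"]]])
  if (any(table(g) == 0L))
    stop("a group has no subjects at risk", call. = FALSE)
  in1 <- g == levels(g)[1L]
  eventTimes <- sort(unique(time[event]))
  o1 <- e1 <- v <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & in1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & in1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1L)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  totalEvents <- sum(event)
  structure(list(
    chisq = chisq, df = 1L,
    pValue = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
    groups = levels(g),
    n = as.vector(table(g)),
    observed = c(o1, totalEvents - o1),
    expected = c(e1, totalEvents - e1)),
    class = "logrankTest")
}

#' @export
print.logrankTest <- function(x, ...) {
  cat("Two-group log-rank test\n")
  print(data.frame(group = x$groups, n = x$n, observed = x$observed,
                   expected = round(x$expected, 2)), row.names = FALSE)
  cat(sprintf("  chi-square = %.4f (1 df), p = %.4g\n", x$chisq, x$pValue))
  invisible(x)
}

#' Combined molecular risk label
#'
#' A patient is molecular-high risk when they carry a retained mutation in a
#' chromatin-remodeling gene (MLL3/KDM6A/GPS2/ZMYM3) OR are i17q-positive;
#' molecular-low otherwise.
#'
#' @param records clinical table with logical `mutation_positive` and
#'   `i17q_positive` columns (no missing values).
#' @return `records` with an added `molecular_risk` column
#'   (`"molecular-high"` / `"molecular-low"`).
#' @export
assignCombinedRisk <- function(records) {
  .requireCols(records, c("patient_id", "mutation_positive", "i17q_positive"),
               "clinical table")
  bad <- is.na(records$mutation_positive) | is.na(records$i17q_positive)
  if (any(bad))
    stop(sprintf("missing mutation/i17q flag for patient(s): %s",
                 paste(records$patient_id[bad], collapse = ", ")),
         call. = FALSE)
  records$molecular_risk <- ifelse(
    records$mutation_positive | records$i17q_positive,
    "molecular-high", "molecular-low")
  records
}

#' Survival analysis grid
#'
#' Runs the full grid of stratified survival analyses: each endpoint
#' (OS/DFS) crossed with each patient subset (standard-risk only / all
#' patients) and each stratifier (mutation status, i17q status, combined
#' molecular risk).  Each cell reports group sizes, the log-rank chi-square
#' and p-value, and the per-group Kaplan-Meier curves.
#'
#' @param records clinical table.
#' @param stratifiers subset of `"mutation"`, `"i17q"`, `"combined"`.
#' @param endpoints subset of `"OS"`, `"DFS"`.
#' @param subsets subset of `"SR"` (standard-risk patients only), `"all"`.
#' @return data frame of class `survivalReport`, one row per analysis cell
#'   (`stratifier`, `endpoint`, `subset`, `n`, `n1`, `n2`, `chisq`,
#'   `pValue`), with the per-cell curves in `attr(, "curves")`.
#' @examples
#' clin <- simulateSurvivalCohort(simConfig(nSamples = 60, seed = 8))
#' runSurvivalAnalysis(clin, stratifiers = "combined")
#' @export
runSurvivalAnalysis <- function(records,
                                stratifiers = c("mutation", "i17q",
                                                "combined"),
                                endpoints = c("OS", "DFS"),
                                subsets = c("SR", "all")) {
  stratifiers <- match.arg(stratifiers, several.ok = TRUE)
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  subsets <- match.arg(subsets, several.ok = TRUE)
  .checkClinical(records)
  cells <- list()
  curves <- list()
  for (sub in subsets) {
    recs <- if (sub == "SR")
      records[records$risk_group == "SR", , drop = FALSE] else records
    if (nrow(recs) == 0L)
      stop(sprintf("no patients left in subset '%s'", sub), call. = FALSE)
    for (strat in stratifiers) {
      g <- droplevels(.resolveGrouping(recs, strat))
      for (ep in endpoints) {
        lr <- logrankTest(recs, grouping = as.character(g), endpoint = ep)
        id <- sprintf("%s|%s|%s", strat, ep, sub)
        cells[[id]] <- data.frame(
          stratifier = strat, endpoint = ep, subset = sub,
          n = nrow(recs), n1 = lr$n[1L], n2 = lr$n[2L],
          group1 = lr$groups[1L], group2 = lr$groups[2L],
          chisq = lr$chisq, pValue = lr$pValue,
          stringsAsFactors = FALSE)
        curves[[id]] <- lapply(stats::setNames(levels(g), levels(g)),
          function(lv) kmCurve(recs[g == lv, , drop = FALSE], ep))
      }
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  class(out) <- c("survivalReport", class(out))
  out
}
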