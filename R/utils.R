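# Internal helpers shared across modules.

## chromosome-17 matching is tolerant of "chr" prefixes
.isChr17 <- function(chrom) sub("^chr", "", as.character(chrom)) == "17"

.variantKey <- function(df)
  paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = "\r")

.asCallDF <- function(x, what = "calls") {
  if (is(x, "VariantCallSet")) return(x@calls)
  if (is.data.frame(x)) return(x)
  stop(sprintf("'%s' must be a VariantCallSet or data frame", what),
       call. = FALSE)
}

## Welch (or pooled) two-sample t-test that tolerates zero-variance input:
## when both groups are constant the statistic is 0 (equal means, p = 1) or
## +/-Inf (p = 0).  stats::t.test() errors on such data.
.safeTTest <- function(x, y, varEqual = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                df = length(x) + length(y) - 2,
                p.value = if (d == 0) 1 else 0,
                estimate = c(mean(x), mean(y))))
  }
  ht <- stats::t.test(x, y, var.equal = varEqual)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, estimate = unname(ht$estimate))
}

.requireCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.checkClinical <- function(records) {
  .requireCols(records,
               c("patient_id", "os_time", "os_event", "dfs_time", "dfs_event"),
               "clinical table")
  if (any(records$os_time < 0 | records$dfs_time < 0, na.rm = TRUE))
    stop("survival times must be non-negative", call. = FALSE)
  if (any(records$dfs_time > records$os_time + 1e-9, na.rm = TRUE))
    stop("dfs_time must not exceed os_time", call. = FALSE)
  invisible(records)
}

#' Pool a set of printed proportions
#'
#' Combines several reported ratios (e.g. male counts among i17q-positive
#' tumors across independent studies) into a single pooled proportion by
#' summing numerators and denominators.
#'
#' @param successes integer vector of numerators.
#' @param totals integer vector of denominators, same length.
#' @return list with `successes`, `totals`, `fraction` and `percent`
#'   (`100 * fraction`).
#' @examples
#' # male fractions among i17q-positive medulloblastomas in three cohorts
#' pooledProportion(c(31, 16, 10), c(37, 18, 13))$percent
#' @export
pooledProportion <- function(successes, totals) {
  if (length(successes) != length(totals))
    stop("'successes' and 'totals' must have the same length", call. = FALSE)
  if (any(successes < 0) || any(totals <= 0) || any(successes > totals))
    stop("each ratio must satisfy 0 <= successes <= totals with totals > 0",
         call. = FALSE)
  frac <- sum(successes) / sum(totals)
  list(successes = sum(successes), totals = sum(totals),
       fraction = frac, percent = 100 * frac)
}
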