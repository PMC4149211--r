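#' Extract the call table from a VariantCallSet
#'
#' @param x a [VariantCallSet-class].
#' @return the underlying `data.frame` of calls.
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname variantCalls
#' @export
setMethod("variantCalls", "VariantCallSet", function(x) x@calls)

#' i17q status of the samples in a cohort
#'
#' @param x an [ExpressionCohort-class].
#' @return integer vector of 0/1 i17q flags, one per sample.
#' @export
setGeneric("i17qStatus", function(x) standardGeneric("i17qStatus"))

#' @rdname i17qStatus
#' @export
setMethod("i17qStatus", "ExpressionCohort", function(x)
  as.integer(SummarizedExperiment::colData(x)$i17q_status))

#' Molecular subgroup labels of a cohort
#'
#' @param x an [ExpressionCohort-class].
#' @return character vector of subgroup labels (WNT/SHH/group3/group4).
#' @export
setGeneric("subgroups", function(x) standardGeneric("subgroups"))

#' @rdname subgroups
#' @export
setMethod("subgroups", "ExpressionCohort", function(x)
  as.character(SummarizedExperiment::colData(x)$subgroup))

#' Probe counts per feature
#'
#' @param x an [ExpressionCohort-class].
#' @return integer vector of microarray probes per feature.
#' @export
setGeneric("probeCounts", function(x) standardGeneric("probeCounts"))

#' @rdname probeCounts
#' @export
setMethod("probeCounts", "ExpressionCohort", function(x)
  as.integer(SummarizedExperiment::rowData(x)$n_probes))

#' The log2 expression matrix of a cohort
#'
#' @param x an [ExpressionCohort-class].
#' @return numeric matrix, features x samples.
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname exprMatrix
#' @export
setMethod("exprMatrix", "ExpressionCohort", function(x)
  SummarizedExperiment::assay(x, "log2expr"))
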