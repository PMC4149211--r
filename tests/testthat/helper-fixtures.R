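# Shared builders for small in-code fixtures.

makeCalls <- function(n = 1, sample_id = "S001", replicate_id = "pooled",
                      chrom = "chr7", pos = seq_len(max(n, 1L)) + 100L,
                      ref = "G", alt = "A", qual = 100, mapq = 50,
                      af = 0.4, function_class = "nonsynonymous",
                      pop_af = NA_real_, gene = "MLL3", ...) {
  df <- data.frame(sample_id = sample_id, replicate_id = replicate_id,
                   chrom = chrom, pos = pos, ref = ref, alt = alt,
                   qual = qual, mapq = mapq, af = af,
                   function_class = function_class, pop_af = pop_af,
                   gene = gene, stringsAsFactors = FALSE, ...)
  df[seq_len(n), , drop = FALSE]
}

## tiny expression cohort built by hand: explicit matrix and metadata
makeCohort <- function(mat, chrom = NULL, pos = NULL, n_probes = NULL,
                       subgroup = NULL, i17q = NULL, sex = NULL) {
  nf <- nrow(mat); ns <- ncol(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("F%02d", seq_len(nf))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%02d", seq_len(ns))
  feat <- data.frame(
    gene = rownames(mat),
    chrom = if (is.null(chrom)) rep("chr1", nf) else chrom,
    pos = if (is.null(pos)) seq_len(nf) * 1000 else pos,
    n_probes = if (is.null(n_probes)) rep(1L, nf) else n_probes,
    row.names = rownames(mat))
  samp <- data.frame(
    subgroup = if (is.null(subgroup))
      rep(c("group3", "group4"), length.out = ns) else subgroup,
    i17q_status = if (is.null(i17q))
      rep(c(1L, 0L), length.out = ns) else i17q,
    sex = if (is.null(sex)) rep(c("M", "F"), length.out = ns) else sex,
    row.names = colnames(mat))
  expressionCohort(mat, feat, samp)
}

## clinical records from bare vectors
makeClinical <- function(time, event, group = NULL,
                         dfsTime = time, dfsEvent = event) {
  n <- length(time)
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    risk_group = rep("SR", n),
    mutation_positive = if (is.null(group)) rep(FALSE, n) else
      group == unique(group)[1L],
    i17q_positive = rep(FALSE, n),
    os_time = time, os_event = as.logical(event),
    dfs_time = dfsTime, dfs_event = as.logical(dfsEvent),
    stringsAsFactors = FALSE)
}
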