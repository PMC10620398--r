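#' Run the full differential methylation pipeline on a count matrix
#'
#' Chains the count stages in the assay's canonical order — library
#' standardization, coverage filter, relative methylation — then, per
#' pairwise timepoint comparison, DMP testing with FDR control and
#' width-optimized DMR calling, ending in the summary table.
#'
#' @param counts A [locus_counts] object.
#' @param chrom_lengths Named chromosome lengths (for window tiling).
#' @param min_reads Coverage filter threshold on normalized counts
#'   (default 10).
#' @param normalization `"median-scale"` or `"cpm"`.
#' @param alpha FDR threshold for DMPs (default 0.05).
#' @param diff_threshold Minimum |methylation difference| in percentage
#'   points (default 25).
#' @param widths DMR window-width grid (default `seq(100, 2000, 100)`).
#' @param comparisons Named list of [comparison]s (default all pairwise
#'   timepoint comparisons of the design).
#'
#' @return A list with `meth` (the `meth_matrix`), `comparisons`, `dmps`,
#'   `width_scans`, `dmrs` (all named by comparison), and `summary`
#'   (the per-comparison DMP/DMR table).
#' @export
run_pipeline <- function(counts, chrom_lengths, min_reads = 10,
                         normalization = "median-scale",
                         alpha = 0.05, diff_threshold = 25,
                         widths = seq(100, 2000, by = 100),
                         comparisons = NULL) {
  stopifnot(inherits(counts, "locus_counts"))
  if (is.null(comparisons)) comparisons <- default_comparisons(counts$design)
  x <- normalize_libraries(counts, normalization)
  x <- filter_coverage(x, min_reads = min_reads)
  m <- relative_methylation(x)
  dmps <- list(); scans <- list(); dmrs <- list()
  for (nm in names(comparisons)) {
    dmp <- call_dmps(m, comparisons[[nm]], alpha = alpha,
                     diff_threshold = diff_threshold)
    opt <- optimize_width(dmp, chrom_lengths, widths = widths)
    dmps[[nm]] <- dmp
    scans[[nm]] <- opt
    dmrs[[nm]] <- opt$dmrs
  }
  list(meth = m, comparisons = comparisons, dmps = dmps,
       width_scans = scans, dmrs = dmrs,
       summary = summarize_dmrs(dmps, dmrs))
}

#' Score recovery of planted clusters by called DMRs
#'
#' A planted cluster counts as recovered when some DMR of the matching
#' direction overlaps its span by at least 1 bp.
#'
#' @param cluster_spans Truth data.frame (`chrom`, `start`, `end`,
#'   `direction`).
#' @param dmrs Called DMR data.frame.
#'
#' @return A list with `n_planted`, `n_recovered`, `recovery` (fraction).
#' @export
score_recovery <- function(cluster_spans, dmrs) {
  n <- nrow(cluster_spans)
  if (n == 0) return(list(n_planted = 0L, n_recovered = 0L, recovery = NA_real_))
  rec <- vapply(seq_len(n), function(i) {
    any(dmrs$chrom == cluster_spans$chrom[i] &
          dmrs$direction == cluster_spans$direction[i] &
          dmrs$start < cluster_spans$end[i] &
          dmrs$end > cluster_spans$start[i])
  }, logical(1))
  list(n_planted = n, n_recovered = sum(rec), recovery = mean(rec))
}
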