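#' Locus-by-sample count matrix
#'
#' The central container of the pipeline: rows are methylation-affected loci
#' (methylation-sensitive cut sites), columns are samples. Raw counts are
#' integers; normalized counts appear after [normalize_libraries()].
#'
#' @param counts Non-negative integer matrix, one column per sample.
#' @param loci data.frame with columns `chrom`, `pos` (0-based), one row per
#'   matrix row; duplicates rejected.
#' @param design data.frame with at least `sample`, `bulk`, `timepoint`;
#'   `design$sample` must match `colnames(counts)`.
#'
#' @return An object of class `locus_counts` with fields `loci`, `design`,
#'   `raw`, and (after normalization) `norm`, `scale_factors`,
#'   `normalization`.
#' @export
locus_counts <- function(counts, loci, design) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(loci), ncol(counts) == nrow(design))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("raw counts must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(paste(loci$chrom, loci$pos))) {
    stop("duplicate (chrom, pos) locus", call. = FALSE)
  }
  if (!identical(colnames(counts), design$sample)) {
    counts <- counts[, design$sample, drop = FALSE]
  }
  ord <- order(loci$chrom, loci$pos)
  structure(
    list(loci = loci[ord, , drop = FALSE], design = design,
         raw = counts[ord, , drop = FALSE], norm = NULL,
         scale_factors = NULL, normalization = "none"),
    class = "locus_counts"
  )
}

#' @export
print.locus_counts <- function(x, ...) {
  cat(sprintf("<locus_counts> %d loci x %d samples (normalization: %s)\n",
              nrow(x$raw), ncol(x$raw), x$normalization))
  invisible(x)
}

#' @export
dim.locus_counts <- function(x) dim(x$raw)

#' Assemble a count matrix from per-sample locus counts
#'
#' Takes one `(chrom, pos, count)` table per sample and builds the union
#' matrix: a locus absent from a sample gets count 0; loci are sorted by
#' `(chrom, pos)` so input row order is irrelevant.
#'
#' @param per_sample Named list of data.frames (`chrom`, `pos`, `count`),
#'   one per sample; names must cover `design$sample`.
#' @param design Sample design data.frame (`sample`, `bulk`, `timepoint`).
#'
#' @return A [locus_counts] object.
#' @export
assemble_counts <- function(per_sample, design) {
  missing <- setdiff(design$sample, names(per_sample))
  if (length(missing) > 0) {
    stop("no count table for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (s in design$sample) {
    tab <- per_sample[[s]]
    dup <- which(duplicated(paste(tab$chrom, tab$pos)))
    if (length(dup) > 0) {
      stop("duplicate locus in counts for sample '", s, "' at row ", dup[1],
           " (", tab$chrom[dup[1]], ":", tab$pos[dup[1]], ")", call. = FALSE)
    }
  }
  keys <- unique(do.call(rbind, lapply(per_sample[design$sample],
                                       function(t) t[, c("chrom", "pos")])))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  rownames(keys) <- NULL
  id <- paste(keys$chrom, keys$pos)
  counts <- matrix(0L, nrow = nrow(keys), ncol = nrow(design),
                   dimnames = list(NULL, design$sample))
  for (s in design$sample) {
    tab <- per_sample[[s]]
    counts[match(paste(tab$chrom, tab$pos), id), s] <- as.integer(tab$count)
  }
  locus_counts(counts, keys, design)
}

#' Standardize library sizes
#'
#' `"median-scale"` (default) rescales each sample by
#' `median(library totals) / its total`, which is robust to a few unusually
#' deep libraries; `"cpm"` rescales to counts per million.
#'
#' @param x A [locus_counts] object.
#' @param method `"median-scale"` or `"cpm"`.
#'
#' @return `x` with `norm`, `scale_factors`, `normalization` filled in.
#' @export
normalize_libraries <- function(x, method = c("median-scale", "cpm")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "locus_counts"))
  totals <- colSums(x$raw)
  if (any(totals == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(x$raw)[totals == 0], collapse = ", "), call. = FALSE)
  }
  target <- if (method == "median-scale") stats::median(totals) else 1e6
  sf <- target / totals
  x$norm <- sweep(x$raw, 2, sf, `*`)
  x$scale_factors <- sf
  x$normalization <- method
  x
}

#' Coverage filter
#'
#' Retains loci whose normalized count reaches `min_reads` in every sample in
#' scope: all samples (default) or, for `scope = "per-comparison"`, only the
#' samples of the two groups being compared.
#'
#' @param x A normalized [locus_counts] object.
#' @param min_reads Minimum normalized count (default 10, the assay's
#'   standard registry filter).
#' @param scope `"all-samples"` or `"per-comparison"`.
#' @param comparison A [comparison] object; required when
#'   `scope = "per-comparison"`.
#'
#' @return The filtered `locus_counts`, with the dropped loci as a
#'   data.frame in `attr(, "drop_report")`.
#' @export
filter_coverage <- function(x, min_reads = 10,
                            scope = c("all-samples", "per-comparison"),
                            comparison = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "locus_counts"), min_reads >= 0)
  if (is.null(x$norm)) stop("normalize_libraries() first", call. = FALSE)
  cols <- if (scope == "per-comparison") {
    if (is.null(comparison)) {
      stop("per-comparison scope needs a comparison", call. = FALSE)
    }
    c(comparison$group_early, comparison$group_late)
  } else colnames(x$norm)
  keep <- rowSums(x$norm[, cols, drop = FALSE] >= min_reads) == length(cols)
  dropped <- x$norm[!keep, cols, drop = FALSE]
  drop_report <- cbind(x$loci[!keep, , drop = FALSE],
                       min_norm = if (nrow(dropped)) apply(dropped, 1, min)
                                  else numeric(0))
  rownames(drop_report) <- NULL
  if (!any(keep)) warning("coverage filter removed every locus")
  x$loci <- x$loci[keep, , drop = FALSE]
  rownames(x$loci) <- NULL
  x$raw <- x$raw[keep, , drop = FALSE]
  x$norm <- x$norm[keep, , drop = FALSE]
  attr(x, "drop_report") <- drop_report
  x
}

round_half_up <- function(x) floor(x + 0.5)

#' Relative methylation levels from normalized counts
#'
#' Because methylation blocks the methylation-sensitive cut, counts measure
#' the unmethylated fraction. Per locus, the most-cut sample anchors the
#' scale: with `M = max` normalized count in the row, the methylation level
#' is `1 - count / M`, the effective coverage is `round(M)`, and integer
#' pseudo meth/unmeth counts (`round half-up`) feed the logistic DMP test.
#' Consequence of the rowmax anchor: every locus has at least one sample at
#' methylation 0. All-zero loci carry no signal and are dropped with a
#' warning.
#'
#' @param x A normalized [locus_counts].
#'
#' @return An object of class `meth_matrix`: `loci`, `design`, `meth`
#'   (levels in `[0,1]`), `eff_coverage` (per-locus integer), `pseudo_meth`,
#'   `pseudo_unmeth` (integer matrices with
#'   `pseudo_meth + pseudo_unmeth = eff_coverage`).
#' @export
relative_methylation <- function(x) {
  stopifnot(inherits(x, "locus_counts"))
  if (is.null(x$norm)) stop("normalize_libraries() first", call. = FALSE)
  M <- apply(x$norm, 1, max)
  zero <- M == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero locus/loci dropped")
  }
  norm <- x$norm[!zero, , drop = FALSE]
  loci <- x$loci[!zero, , drop = FALSE]
  rownames(loci) <- NULL
  M <- M[!zero]
  meth <- 1 - sweep(norm, 1, M, `/`)
  meth[meth < 0] <- 0
  eff_cov <- as.integer(round_half_up(M))
  pseudo_meth <- round_half_up(meth * eff_cov)
  pseudo_unmeth <- sweep(-pseudo_meth, 1, eff_cov, `+`)
  structure(
    list(loci = loci, design = x$design, meth = meth,
         eff_coverage = eff_cov,
         pseudo_meth = pseudo_meth, pseudo_unmeth = pseudo_unmeth),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d loci x %d samples; median coverage %d\n",
              nrow(x$meth), ncol(x$meth),
              as.integer(stats::median(x$eff_coverage))))
  invisible(x)
}

#' PCA quality control of the methylation matrix
#'
#' Principal components of the sample-by-locus methylation matrix with loci
#' centered. In a sound design, samples cluster by group and the first
#' components absorb a large share of the variance.
#'
#' @param m A `meth_matrix` with at least 3 samples and 2 loci.
#'
#' @return A list with `coords` (samples x components), `var_explained`
#'   (fractions summing to 1), `design`, and `flag` (`"constant-matrix"`
#'   when there is no variance at all, else `NA`).
#' @export
pca_qc <- function(m) {
  stopifnot(inherits(m, "meth_matrix"))
  X <- t(m$meth)
  if (nrow(X) < 3 || ncol(X) < 2) {
    stop("pca_qc needs >= 3 samples and >= 2 loci", call. = FALSE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) {
    return(list(coords = matrix(0, nrow(X), 0), var_explained = numeric(0),
                design = m$design, flag = "constant-matrix"))
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  coords <- p$x
  rownames(coords) <- m$design$sample
  list(coords = coords, var_explained = ve, design = m$design, flag = NA)
}
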