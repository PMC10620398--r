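#' Define a two-group timepoint comparison
#'
#' @param name Comparison label, e.g. `"T30_vs_T0"` (late vs early).
#' @param group_late,group_early Disjoint, non-empty sample id vectors.
#'
#' @return An object of class `comparison`.
#' @export
comparison <- function(name, group_late, group_early) {
  stopifnot(length(group_late) > 0, length(group_early) > 0)
  if (length(intersect(group_late, group_early)) > 0) {
    stop("comparison groups must be disjoint", call. = FALSE)
  }
  structure(list(name = name, group_late = group_late,
                 group_early = group_early),
            class = "comparison")
}

#' All pairwise timepoint comparisons of a design
#'
#' For the default three-timepoint design this yields `T30_vs_T0`,
#' `T90_vs_T0`, `T90_vs_T30`. The first-named timepoint is the later one;
#' "methylated" direction means higher methylation at that later timepoint.
#'
#' @param design A [synthetic_design] or a design data.frame
#'   (`sample`, `timepoint`).
#'
#' @return Named list of [comparison] objects.
#' @export
default_comparisons <- function(design) {
  samples <- if (inherits(design, "synthetic_design")) design$samples else design
  tps <- unique(samples$timepoint)
  out <- list()
  for (i in seq_along(tps)) {
    for (j in seq_along(tps)) {
      if (j <= i) next
      nm <- paste0(tps[j], "_vs_", tps[i])
      out[[nm]] <- comparison(
        nm,
        group_late = samples$sample[samples$timepoint == tps[j]],
        group_early = samples$sample[samples$timepoint == tps[i]])
    }
  }
  out
}

# Vectorized binomial likelihood-ratio test on pooled group totals.
# With equal per-sample trials within a locus, the logistic regression of
# methylation proportion on a group indicator (weights = coverage) has the
# group-pooled proportions as MLE, so the 1-df LRT reduces to this closed
# form on sufficient statistics. xlogy handles the 0*log(0) limits.
binom_lrt <- function(y1, n1, y2, n2) {
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  ll <- function(y, n, p) xlogy(y, p) + xlogy(n - y, 1 - p)
  p1 <- y1 / n1
  p2 <- y2 / n2
  p0 <- (y1 + y2) / (n1 + n2)
  stat <- 2 * (ll(y1, n1, p1) + ll(y2, n2, p2) - ll(y1 + y2, n1 + n2, p0))
  stat <- pmax(stat, 0)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Test one locus for differential methylation
#'
#' Binomial logistic regression of the methylation proportion on the group
#' indicator with effective coverage as the number of trials, evaluated as a
#' 1-df likelihood-ratio test against the intercept-only model. The
#' methylation difference is in percentage points,
#' `100 * (weighted mean late - weighted mean early)`.
#'
#' @param meth_early,cov_early Integer pseudo methylated counts and
#'   coverages for the early group (one entry per sample).
#' @param meth_late,cov_late Same for the late group.
#'
#' @return A list with `p_value` and `meth_diff`.
#' @export
test_locus <- function(meth_early, cov_early, meth_late, cov_late) {
  stopifnot(all(cov_early >= 1), all(cov_late >= 1),
            length(meth_early) == length(cov_early),
            length(meth_late) == length(cov_late))
  y1 <- sum(meth_early); n1 <- sum(cov_early)
  y2 <- sum(meth_late); n2 <- sum(cov_late)
  list(p_value = binom_lrt(y1, n1, y2, n2),
       meth_diff = 100 * (y2 / n2 - y1 / n1))
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up with the usual monotonicity enforcement
#' (default), or Bonferroni. Stable under permutation of the input.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#'
#' @return Adjusted q-values, same order as the input.
#' @export
adjust_fdr <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = method)
}

#' Call differentially methylated positions (DMPs)
#'
#' Tests every locus of the matrix for one comparison, adjusts p-values
#' across loci, and keeps loci with `q < alpha` and
#' `|meth_diff| >= diff_threshold` percentage points. Direction is
#' "methylated" when the later timepoint is more methylated.
#'
#' @param m A `meth_matrix` (already coverage-filtered for this comparison).
#' @param comp A [comparison].
#' @param alpha FDR threshold (default 0.05).
#' @param diff_threshold Minimum absolute methylation difference in
#'   percentage points (default 25, the conventional effect-size filter;
#'   set 0 to disable).
#' @param fdr_method Passed to [adjust_fdr()].
#'
#' @return data.frame of DMP records (`chrom`, `pos`, `comparison`,
#'   `meth_diff`, `pvalue`, `qvalue`, `direction`) sorted by `(chrom, pos)`,
#'   with attributes `n_tested` (loci tested) and `n_significant` (loci with
#'   `q < alpha` before the effect-size threshold).
#' @export
call_dmps <- function(m, comp, alpha = 0.05, diff_threshold = 25,
                      fdr_method = "BH") {
  stopifnot(inherits(m, "meth_matrix"), inherits(comp, "comparison"))
  early <- comp$group_early
  late <- comp$group_late
  missing <- setdiff(c(early, late), colnames(m$meth))
  if (length(missing) > 0) {
    stop("samples absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_loci <- nrow(m$meth)
  if (n_loci == 0) {
    warning("no eligible loci for ", comp$name)
    out <- data.frame(chrom = character(0), pos = integer(0),
                      comparison = character(0), meth_diff = numeric(0),
                      pvalue = numeric(0), qvalue = numeric(0),
                      direction = character(0))
    attr(out, "n_tested") <- 0L
    attr(out, "n_significant") <- 0L
    return(out)
  }
  y1 <- rowSums(m$pseudo_meth[, early, drop = FALSE])
  n1 <- m$eff_coverage * length(early)
  y2 <- rowSums(m$pseudo_meth[, late, drop = FALSE])
  n2 <- m$eff_coverage * length(late)
  p <- binom_lrt(y1, n1, y2, n2)
  q <- adjust_fdr(p, fdr_method)
  diff <- 100 * (y2 / n2 - y1 / n1)
  keep <- q < alpha & abs(diff) >= diff_threshold
  out <- data.frame(
    chrom = m$loci$chrom[keep], pos = m$loci$pos[keep],
    comparison = rep(comp$name, sum(keep)), meth_diff = diff[keep],
    pvalue = p[keep], qvalue = q[keep],
    direction = ifelse(diff[keep] > 0, "methylated", "de-methylated"),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_loci
  attr(out, "n_significant") <- sum(q < alpha)
  out
}
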