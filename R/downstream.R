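#' Classify genes into early, mid, and continuous response sets
#'
#' Set algebra over the three pairwise-comparison gene lists of a
#' three-timepoint design:
#' * early = genes(T30 vs T0) not in genes(T90 vs T0) — affected only at the
#'   first stage;
#' * mid = (genes(T90 vs T0) and genes(T90 vs T30)) minus genes(T30 vs T0) —
#'   unaffected early, affected later;
#' * continuous = genes(T90 vs T0) minus early minus mid — progressive
#'   change across the whole period.
#'
#' Early and mid are disjoint by construction, and neither intersects
#' continuous.
#'
#' @param genes_t30_t0,genes_t90_t0,genes_t90_t30 Character vectors of gene
#'   ids, or data.frames with columns `gene_id` and `direction`.
#'
#' @return A list with character vectors `early`, `mid`, `continuous` and,
#'   when directions were supplied, a `directions` data.frame (direction
#'   taken from the latest comparison mentioning the gene).
#' @export
classify_response <- function(genes_t30_t0, genes_t90_t0, genes_t90_t30) {
  ids <- function(x) if (is.data.frame(x)) x$gene_id else as.character(x)
  a <- unique(ids(genes_t30_t0))
  b <- unique(ids(genes_t90_t0))
  c_ <- unique(ids(genes_t90_t30))
  early <- setdiff(a, b)
  mid <- setdiff(intersect(b, c_), a)
  continuous <- setdiff(b, union(early, mid))
  dirs <- NULL
  if (is.data.frame(genes_t30_t0) || is.data.frame(genes_t90_t0) ||
      is.data.frame(genes_t90_t30)) {
    tab <- rbind(
      if (is.data.frame(genes_t30_t0)) genes_t30_t0[, c("gene_id", "direction")],
      if (is.data.frame(genes_t90_t0)) genes_t90_t0[, c("gene_id", "direction")],
      if (is.data.frame(genes_t90_t30)) genes_t90_t30[, c("gene_id", "direction")])
    dirs <- tab[!duplicated(tab$gene_id, fromLast = TRUE), , drop = FALSE]
    rownames(dirs) <- NULL
  }
  list(early = sort(early), mid = sort(mid), continuous = sort(continuous),
       directions = dirs)
}

#' Hypergeometric term enrichment with dual-correction consensus
#'
#' For each term, the upper-tail hypergeometric probability of seeing `k` or
#' more selected genes with the term given `K` background genes with the
#' term, `n` selected and `N` background genes in total. P-values are
#' adjusted across terms twice — Benjamini-Hochberg and Bonferroni — and a
#' term is consensus-significant only when both adjusted values fall below
#' `alpha`, a conservative stand-in for agreement between two independent
#' enrichment tools.
#'
#' @param selected Character vector of selected genes; must be a subset of
#'   `background`.
#' @param background Character vector, the gene universe.
#' @param term_map data.frame with columns `gene` and `term`.
#' @param alpha Significance level (default 0.05).
#'
#' @return data.frame sorted by p: `term`, `k`, `K`, `n`, `N`, `p`, `q_bh`,
#'   `p_bonferroni`, `consensus_significant`.
#' @export
enrich_terms <- function(selected, background, term_map, alpha = 0.05) {
  selected <- unique(selected)
  background <- unique(background)
  stray <- setdiff(selected, background)
  if (length(stray) > 0) {
    stop("selected genes not in background: ", paste(stray, collapse = ", "),
         call. = FALSE)
  }
  term_map <- term_map[term_map$gene %in% background, , drop = FALSE]
  terms <- unique(term_map$term)
  if (length(terms) == 0) {
    stop("term_map covers no background gene", call. = FALSE)
  }
  N <- length(background)
  n <- length(selected)
  rows <- lapply(terms, function(tm) {
    with_term <- unique(term_map$gene[term_map$term == tm])
    K <- length(with_term)
    k <- length(intersect(with_term, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out$consensus_significant <- out$q_bh < alpha & out$p_bonferroni < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per record, `dCt = ct_target - mean(reference Cts)`; per gene,
#' `ddCt = dCt - mean(dCt of the calibrator timepoint)` and
#' `rel_expr = 2^-ddCt`, so the calibrator group has geometric-mean relative
#' expression 1 by construction. Records with a missing reference Ct are
#' skipped with a warning.
#'
#' @param qpcr data.frame with columns `gene`, `bulk`, `timepoint`,
#'   `ct_target`, and two reference columns (default `ct_sdha`, `ct_hprt`,
#'   the standard equine blood reference genes).
#' @param calibrator_timepoint Calibrator group label (default `"T0"`).
#' @param ref_cols Names of the reference Ct columns.
#'
#' @return The input with `delta_ct`, `delta_delta_ct`, and `rel_expr`
#'   columns appended.
#' @export
delta_delta_ct <- function(qpcr, calibrator_timepoint = "T0",
                           ref_cols = c("ct_sdha", "ct_hprt")) {
  stopifnot(all(ref_cols %in% names(qpcr)))
  refs <- as.matrix(qpcr[, ref_cols, drop = FALSE])
  bad <- rowSums(is.na(refs)) > 0 | is.na(qpcr$ct_target)
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped for missing Ct values")
    qpcr <- qpcr[!bad, , drop = FALSE]
    refs <- refs[!bad, , drop = FALSE]
  }
  qpcr$delta_ct <- qpcr$ct_target - rowMeans(refs)
  out <- lapply(split(qpcr, qpcr$gene), function(g) {
    cal <- g$delta_ct[g$timepoint == calibrator_timepoint]
    if (length(cal) == 0) {
      stop("gene ", g$gene[1], " has no calibrator (", calibrator_timepoint,
           ") records", call. = FALSE)
    }
    g$delta_delta_ct <- g$delta_ct - mean(cal)
    g$rel_expr <- 2^(-g$delta_delta_ct)
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-comparison differential expression outcome
#'
#' One-way ANOVA on `log2(rel_expr)` across timepoints; when the ANOVA
#' rejects at `alpha`, pairwise Welch t-tests with Holm correction decide
#' each comparison's outcome and sign, otherwise everything is N.S.
#' "Up-regulation" means higher expression at the later timepoint of the
#' comparison. Zero-variance identical groups are N.S. by definition.
#'
#' @param rel_expr Numeric vector of relative expression values (`> 0`).
#' @param timepoint Character vector of timepoint labels, ordered by
#'   `levels` (default the sorted unique labels, which orders T0 < T30 < T90
#'   for the standard design only by luck of naming; pass `levels`
#'   explicitly for other designs).
#' @param levels Ordered timepoint labels.
#' @param alpha Significance level (default 0.05).
#'
#' @return data.frame `comparison`, `outcome`
#'   (`Up-regulation`/`Down-regulation`/`N.S.`), `p_anova`, `p_pairwise`.
#' @export
test_expression <- function(rel_expr, timepoint,
                            levels = sort(unique(timepoint)), alpha = 0.05) {
  stopifnot(all(rel_expr > 0), length(rel_expr) == length(timepoint),
            length(levels) >= 2)
  y <- log2(rel_expr)
  g <- factor(timepoint, levels = levels)
  if (any(table(g) < 2)) stop("need >= 2 replicates per group", call. = FALSE)
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  comps <- vapply(pairs, function(p) paste0(p[2], "_vs_", p[1]), character(1))
  n_groups_var <- vapply(levels, function(l) stats::var(y[g == l]), numeric(1))
  if (all(n_groups_var < 1e-12) &&
      stats::var(tapply(y, g, mean)) < 1e-12) {
    return(data.frame(comparison = comps, outcome = "N.S.",
                      p_anova = 1, p_pairwise = NA_real_,
                      stringsAsFactors = FALSE))
  }
  p_anova <- stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
  if (is.na(p_anova) || p_anova >= alpha) {
    return(data.frame(comparison = comps, outcome = "N.S.",
                      p_anova = p_anova, p_pairwise = NA_real_,
                      stringsAsFactors = FALSE))
  }
  praw <- vapply(pairs, function(p) {
    y1 <- y[g == p[1]]; y2 <- y[g == p[2]]
    if (stats::var(y1) < 1e-12 && stats::var(y2) < 1e-12) {
      return(if (abs(mean(y1) - mean(y2)) < 1e-12) 1 else 0)
    }
    stats::t.test(y2, y1)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(praw, method = "holm")
  outcome <- vapply(seq_along(pairs), function(i) {
    if (padj[i] >= alpha) return("N.S.")
    d <- mean(y[g == pairs[[i]][2]]) - mean(y[g == pairs[[i]][1]])
    if (d > 0) "Up-regulation" else "Down-regulation"
  }, character(1))
  data.frame(comparison = comps, outcome = outcome, p_anova = p_anova,
             p_pairwise = padj, stringsAsFactors = FALSE)
}

#' Methylation/expression agreement call
#'
#' The agreement column is filled only when both outcomes are statistically
#' supported: `"Yes"` for the canonical inverse relationship
#' (de-methylation with up-regulation, or methylation with down-regulation),
#' `"No"` for a supported discordant pair, and blank (`""`) whenever either
#' outcome is `"N.S."`.
#'
#' @param meth_outcome Character vector over
#'   `{"De-methylation", "Methylation", "N.S."}`.
#' @param expr_outcome Character vector over
#'   `{"Up-regulation", "Down-regulation", "N.S."}`.
#'
#' @return Character vector over `{"Yes", "No", ""}`.
#' @export
agreement <- function(meth_outcome, expr_outcome) {
  meth_ok <- c("De-methylation", "Methylation", "N.S.")
  expr_ok <- c("Up-regulation", "Down-regulation", "N.S.")
  if (!all(meth_outcome %in% meth_ok)) {
    stop("unknown methylation outcome label(s): ",
         paste(setdiff(meth_outcome, meth_ok), collapse = ", "), call. = FALSE)
  }
  if (!all(expr_outcome %in% expr_ok)) {
    stop("unknown expression outcome label(s): ",
         paste(setdiff(expr_outcome, expr_ok), collapse = ", "), call. = FALSE)
  }
  ifelse(meth_outcome == "N.S." | expr_outcome == "N.S.", "",
         ifelse((meth_outcome == "De-methylation" &
                   expr_outcome == "Up-regulation") |
                  (meth_outcome == "Methylation" &
                     expr_outcome == "Down-regulation"),
                "Yes", "No"))
}
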