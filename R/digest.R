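#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
NULL

as_dna <- function(sequence) {
  if (is(sequence, "DNAString")) return(sequence)
  if (is.character(sequence) && length(sequence) == 1L) {
    return(Biostrings::DNAString(toupper(sequence)))
  }
  stop("sequence must be a single character string or a DNAString", call. = FALSE)
}

as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(genome)
  }
  if (is(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- "chr1"
    return(g)
  }
  if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(toupper(genome))
    if (is.null(names(genome))) names(g) <- paste0("chr", seq_along(g))
    else names(g) <- names(genome)
    return(g)
  }
  stop("genome must be a DNAStringSet, DNAString, or character vector",
       call. = FALSE)
}

#' Find cut positions of a restriction enzyme in a sequence
#'
#' Scans the forward strand for the recognition pattern (IUPAC codes in the
#' pattern act as wildcards; `N` in the subject never matches, so matches
#' containing `N` are skipped). For non-palindromic enzymes the reverse
#' strand is also scanned by matching the reverse complement of the pattern
#' on the forward axis; its cut is mapped back with the mirrored offset.
#' Double-strand cleavage is modeled as a single forward-axis coordinate,
#' sufficient for fragment length distributions.
#'
#' @param sequence Character string or `DNAString` over A/C/G/T/N.
#' @param enzyme A [restriction_enzyme].
#'
#' @return Sorted, deduplicated integer vector of 0-based cut coordinates.
#' @examples
#' find_sites("AAATTAACCGCAAATTAAA", get_enzyme("MseI")) # 4, 15
#' find_sites("AAATTAACCGCAAATTAAA", get_enzyme("AciI")) # 8
#' @export
find_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  subj <- as_dna(sequence)
  k <- nchar(enzyme$recognition)
  if (length(subj) < k) return(integer(0))
  fwd <- Biostrings::matchPattern(enzyme$recognition, subj, fixed = "subject")
  cuts <- BiocGenerics::start(fwd) - 1L + enzyme$cut_offset
  if (!enzyme$palindromic) {
    rcpat <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(enzyme$recognition)))
    rev <- Biostrings::matchPattern(rcpat, subj, fixed = "subject")
    # a site on the bottom strand at forward span [s, s+k) cuts at the
    # mirrored offset from the span's right edge
    cuts <- c(cuts, BiocGenerics::start(rev) - 1L + (k - enzyme$cut_offset))
  }
  sort(unique(as.integer(cuts)))
}

#' In-silico double digestion of a genome
#'
#' Merges the cut positions of a methylation-sensitive enzyme and its
#' companion per chromosome and emits the induced fragment tiling. Fragments
#' use 0-based half-open coordinates and tile each chromosome exactly.
#' Chromosome ends are labeled `"terminal"`; internal boundaries carry the
#' name of the cutting enzyme, or `"both"` when the two enzymes cut at the
#' same coordinate.
#'
#' @param genome `DNAStringSet` (or named character vector) of chromosomes.
#' @param ms_enzyme Methylation-sensitive [restriction_enzyme].
#' @param companion Companion [restriction_enzyme]; must differ from
#'   `ms_enzyme`.
#'
#' @return A data.frame with columns `chrom`, `start`, `end`, `left_end`,
#'   `right_end`, `length`.
#' @examples
#' frags <- double_digest("AAATTAACCGCAAATTAAA",
#'                        get_enzyme("AciI"), get_enzyme("MseI"))
#' frags
#' @export
double_digest <- function(genome, ms_enzyme, companion) {
  stopifnot(inherits(ms_enzyme, "restriction_enzyme"),
            inherits(companion, "restriction_enzyme"))
  if (identical(ms_enzyme$name, companion$name)) {
    stop("ms_enzyme and companion must be distinct enzymes", call. = FALSE)
  }
  g <- as_genome(genome)
  out <- lapply(seq_along(g), function(i) {
    chrom <- names(g)[i]
    L <- length(g[[i]])
    cuts_a <- find_sites(g[[i]], ms_enzyme)
    cuts_b <- find_sites(g[[i]], companion)
    both <- intersect(cuts_a, cuts_b)
    all_cuts <- sort(unique(c(cuts_a, cuts_b)))
    all_cuts <- all_cuts[all_cuts > 0 & all_cuts < L]
    labels <- ifelse(all_cuts %in% both, "both",
                     ifelse(all_cuts %in% cuts_a, ms_enzyme$name, companion$name))
    bounds <- c(0L, all_cuts, L)
    blabs <- c("terminal", labels, "terminal")
    n <- length(bounds) - 1L
    data.frame(
      chrom = rep(chrom, n),
      start = bounds[-length(bounds)],
      end = bounds[-1],
      left_end = blabs[-length(blabs)],
      right_end = blabs[-1],
      stringsAsFactors = FALSE
    )
  })
  frags <- do.call(rbind, out)
  frags$length <- frags$end - frags$start
  rownames(frags) <- NULL
  frags
}

#' Size-select double-digest fragments
#'
#' Keeps fragments inside a length window and, optionally, only those with
#' exactly one methylation-sensitive terminus and one companion terminus —
#' the configuration captured by ddRAD-style library preparation. A terminus
#' labeled `"both"` counts as either enzyme but a fragment still needs one
#' distinct terminus of each kind.
#'
#' @param fragments Fragment data.frame from [double_digest()].
#' @param ms_enzyme,companion Enzymes (or their names) defining the two
#'   terminus classes.
#' @param min_len,max_len Inclusive fragment length window in bp
#'   (defaults 200 and 700, the size-selection window of the assay).
#' @param require_mixed_ends Require one terminus of each enzyme
#'   (default `TRUE`).
#'
#' @return The selected subset of `fragments`.
#' @export
select_fragments <- function(fragments, ms_enzyme, companion,
                             min_len = 200, max_len = 700,
                             require_mixed_ends = TRUE) {
  stopifnot(min_len <= max_len)
  ms <- if (inherits(ms_enzyme, "restriction_enzyme")) ms_enzyme$name else ms_enzyme
  co <- if (inherits(companion, "restriction_enzyme")) companion$name else companion
  keep <- fragments$length >= min_len & fragments$length <= max_len
  if (require_mixed_ends) {
    is_ms <- function(x) x %in% c(ms, "both")
    is_co <- function(x) x %in% c(co, "both")
    mixed <- (is_ms(fragments$left_end) & is_co(fragments$right_end)) |
      (is_co(fragments$left_end) & is_ms(fragments$right_end))
    # "both/both" ends satisfy either orientation but must involve two cuts
    keep <- keep & mixed &
      fragments$left_end != "terminal" & fragments$right_end != "terminal"
  }
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate methylation-sensitive enzymes by selectable fragments
#'
#' Double-digests the genome with each candidate plus the fixed companion,
#' applies size selection, and counts the selectable fragments. The best
#' enzyme is the argmax; ties are broken alphabetically by enzyme name and
#' flagged.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param candidates List of candidate [restriction_enzyme]s.
#' @param companion Companion [restriction_enzyme].
#' @param min_len,max_len Size-selection window (default 200-700 bp).
#' @param require_mixed_ends Passed to [select_fragments()].
#'
#' @return A list with `table` (data.frame `enzyme`, `n_selectable`, sorted
#'   by decreasing count then name), `best` (enzyme name), and `tie`
#'   (logical flag).
#' @export
rank_enzymes <- function(genome, candidates, companion,
                         min_len = 200, max_len = 700,
                         require_mixed_ends = TRUE) {
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  g <- as_genome(genome)
  if (sum(lengths(g)) == 0) stop("empty genome", call. = FALSE)
  counts <- vapply(candidates, function(enz) {
    frags <- double_digest(g, enz, companion)
    nrow(select_fragments(frags, enz, companion, min_len, max_len,
                          require_mixed_ends))
  }, integer(1))
  nm <- vapply(candidates, `[[`, character(1), "name")
  tab <- data.frame(enzyme = nm, n_selectable = counts, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$n_selectable, tab$enzyme), , drop = FALSE]
  rownames(tab) <- NULL
  top <- tab$n_selectable[1]
  tie <- sum(tab$n_selectable == top) > 1
  list(table = tab, best = tab$enzyme[1], tie = tie)
}

#' Write fragments as BED
#'
#' BED uses the same 0-based half-open convention as the internal fragment
#' table. The name field is `left:right` end labels, score the length.
#'
#' @param fragments Fragment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    paste0(fragments$left_end, ":", fragments$right_end),
                    fragments$length)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
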