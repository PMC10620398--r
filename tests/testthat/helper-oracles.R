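# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no Biostrings matching, no window arithmetic reuse) so that
# agreement is evidence, not tautology.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_complement <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

oracle_revcomp_pattern <- function(pattern) {
  paste(rev(iupac_complement[strsplit(pattern, "")[[1]]]), collapse = "")
}

# all 0-based match starts of an IUPAC pattern; subject N never matches.
# vectorized over start positions: one logical sweep per pattern offset
oracle_match_starts <- function(seq_chars, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  k <- length(pat)
  L <- length(seq_chars)
  if (L < k) return(integer(0))
  ok <- rep(TRUE, L - k + 1)
  for (i in seq_len(k)) {
    ok <- ok & (seq_chars[i:(L - k + i)] %in% iupac_sets[[pat[i]]])
  }
  which(ok) - 1L
}

oracle_find_cuts <- function(sequence, enzyme) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  k <- nchar(enzyme$recognition)
  cuts <- oracle_match_starts(chars, enzyme$recognition) + enzyme$cut_offset
  if (!enzyme$palindromic) {
    rc <- oracle_revcomp_pattern(enzyme$recognition)
    cuts <- c(cuts, oracle_match_starts(chars, rc) + (k - enzyme$cut_offset))
  }
  sort(unique(cuts))
}

oracle_fragment_bounds <- function(sequence, enzymes) {
  L <- nchar(sequence)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e)
    oracle_find_cuts(sequence, e)))))
  cuts <- cuts[cuts > 0 & cuts < L]
  c(0, cuts, L)
}

# brute-force DMR enumeration over explicit tiles
oracle_dmrs <- function(dmps, width, chrom_lengths, phase = 0) {
  rows <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    starts <- seq(phase, L - 1, by = width)
    if (phase > 0) starts <- c(0, starts)
    ends <- pmin(c(starts[-1], L), L)
    for (i in seq_along(starts)) {
      idx <- which(dmps$chrom == chrom & dmps$pos >= starts[i] &
                     dmps$pos < ends[i])
      if (length(idx) == 0) next
      nm <- sum(dmps$direction[idx] == "methylated")
      nd <- sum(dmps$direction[idx] == "de-methylated")
      if (max(nm, nd) < 2 || nm == nd) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = starts[i], end = ends[i],
        direction = if (nm > nd) "methylated" else "de-methylated",
        n_conc = max(nm, nd), n_disc = min(nm, nd),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_conc = integer(0), n_disc = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# BH step-up by direct definition: q_i = min over j with p_(j) >= p_i of
# p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(adj[i:m])
  q[ord] <- pmin(adj, 1)
  q
}

oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

# all-pairs interval overlap in bp (0-based half-open)
oracle_overlap_bp <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

small_design <- function(n_bulks = 5, chrom_lengths = 5e4,
                         library_size = 50 * 100, seed = 1,
                         dispersion = 0.02) {
  synthetic_design(chrom_lengths = chrom_lengths, n_bulks = n_bulks,
                   library_size = library_size, dispersion = dispersion,
                   seed = seed)
}
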