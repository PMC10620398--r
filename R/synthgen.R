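#' Describe a synthetic bulked time-course design
#'
#' Captures the experimental layout the generator emulates: bulks of pooled
#' individuals sampled at ordered timepoints (default 5 bulks at T0, T30,
#' T90, the bulked training time-course the assay was designed around), plus
#' the count-model nuisance parameters.
#'
#' @param chrom_lengths Integer vector of chromosome lengths in bp.
#' @param n_bulks Number of bulks per timepoint (default 5). The same bulks
#'   appear at every timepoint.
#' @param timepoints Ordered character vector of timepoint labels
#'   (default `c("T0", "T30", "T90")`); at least two.
#' @param library_size Expected total read count per sample; recycled across
#'   samples (default 1e6).
#' @param dispersion Negative-binomial inverse-size parameter `phi >= 0`;
#'   `var = mu + phi * mu^2`, so 0 degenerates to Poisson (default 0.02:
#'   bulking four individuals per sample averages out most biological
#'   variability, leaving mild residual technical overdispersion).
#' @param seed Integer seed driving every stochastic stage.
#'
#' @return An object of class `synthetic_design` with a `samples` data.frame
#'   (`sample`, `bulk`, `timepoint`, `library_size`).
#' @examples
#' d <- synthetic_design(chrom_lengths = 50000, seed = 1)
#' head(d$samples)
#' @export
synthetic_design <- function(chrom_lengths = 1e5, n_bulks = 5,
                             timepoints = c("T0", "T30", "T90"),
                             library_size = 1e6, dispersion = 0.02,
                             seed = 1L) {
  stopifnot(all(chrom_lengths > 0), n_bulks >= 1, length(timepoints) >= 2,
            all(library_size > 0), dispersion >= 0)
  chrom_lengths <- as.integer(chrom_lengths)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  samples <- expand.grid(bulk = seq_len(n_bulks), timepoint = timepoints,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample <- paste0(samples$timepoint, "_", samples$bulk)
  samples$library_size <- rep_len(library_size, nrow(samples))
  samples <- samples[, c("sample", "bulk", "timepoint", "library_size")]
  structure(
    list(chrom_lengths = chrom_lengths, n_bulks = as.integer(n_bulks),
         timepoints = timepoints, samples = samples,
         dispersion = dispersion, seed = as.integer(seed)),
    class = "synthetic_design"
  )
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "<synthetic_design> %d chromosome(s), %s bp; %d bulks x %d timepoints (%s); dispersion %.3g; seed %d\n",
    length(x$chrom_lengths), format(sum(x$chrom_lengths), big.mark = ","),
    x$n_bulks, length(x$timepoints), paste(x$timepoints, collapse = ", "),
    x$dispersion, x$seed))
  invisible(x)
}

# Destroy every match of the patterns in `seq_chars` except those whose span
# is protected. Mutates one unprotected base per offending match and rescans.
scrub_patterns <- function(seq_chars, patterns, protected = NULL) {
  prot <- rep(FALSE, length(seq_chars))
  if (!is.null(protected) && nrow(protected) > 0) {
    for (i in seq_len(nrow(protected))) {
      prot[(protected$start[i] + 1):(protected$end[i])] <- TRUE
    }
  }
  bases <- c("A", "C", "G", "T")
  for (iter in 1:50) {
    subj <- Biostrings::DNAString(paste(seq_chars, collapse = ""))
    dirty <- FALSE
    for (pat in patterns) {
      m <- Biostrings::matchPattern(pat, subj, fixed = "subject")
      for (j in seq_along(m)) {
        s <- BiocGenerics::start(m)[j]; e <- BiocGenerics::end(m)[j]
        idx <- s:e
        free <- idx[!prot[idx]]
        if (length(free) == 0) next  # match lies inside a protected span
        pos <- free[ceiling(length(free) / 2)]
        seq_chars[pos] <- sample(setdiff(bases, seq_chars[pos]), 1L)
        dirty <- TRUE
      }
    }
    if (!dirty) return(seq_chars)
  }
  stop("could not scrub chance recognition sites after 50 passes", call. = FALSE)
}

# Concrete instantiation of an IUPAC pattern (random choice per ambiguity code)
instantiate_pattern <- function(pattern) {
  letters <- strsplit(pattern, "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# Both-strand pattern set an enzyme can match
enzyme_patterns <- function(enzyme) {
  pats <- enzyme$recognition
  if (!enzyme$palindromic) {
    pats <- c(pats, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(enzyme$recognition))))
  }
  pats
}

#' Simulate a genome with planted restriction sites
#'
#' Generates random nucleotide chromosomes, removes chance occurrences of the
#' recognition sites of `scrub_enzymes` (both strands), then plants sites for
#' the methylation-sensitive enzyme and the companion at approximately
#' `site_density` sites per kbp per enzyme. After planting, the sequence is
#' re-scrubbed so the only recognition sites of the scrubbed enzymes are the
#' planted ones; the methylation-sensitive cut sites define the locus
#' registry downstream stages consume.
#'
#' @param design A [synthetic_design] (chromosome lengths and seed).
#' @param site_density Planted sites per kbp per enzyme; `>= 0`.
#' @param ms_enzyme,companion Enzymes to plant (default AciI and MseI).
#' @param scrub_enzymes List of enzymes whose chance sites are removed
#'   (default the two planted enzymes; pass the full candidate list when the
#'   genome feeds enzyme ranking).
#' @param seed Seed (default `design$seed`).
#'
#' @return A list with `genome` (`DNAStringSet`), `loci` (data.frame
#'   `chrom`, `pos` of methylation-sensitive cut coordinates, 0-based), and
#'   `site_table` (planted site spans for both enzymes).
#' @export
simulate_genome <- function(design, site_density,
                            ms_enzyme = get_enzyme("AciI"),
                            companion = get_enzyme("MseI"),
                            scrub_enzymes = list(ms_enzyme, companion),
                            seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"), site_density >= 0)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  patterns <- unique(unlist(lapply(scrub_enzymes, enzyme_patterns)))
  k_ms <- nchar(ms_enzyme$recognition)
  k_co <- nchar(companion$recognition)
  min_sep <- max(k_ms, k_co) + 2L
  chroms <- vector("list", length(design$chrom_lengths))
  loci <- list(); sites <- list()
  for (ci in seq_along(design$chrom_lengths)) {
    L <- design$chrom_lengths[ci]
    chrom <- names(design$chrom_lengths)[ci]
    n_per_enz <- round(site_density * L / 1000)
    if (2 * n_per_enz * min_sep > 0.5 * L) {
      stop("site_density ", site_density, "/kbp is too high for chromosome ",
           chrom, " (", L, " bp): planted sites would overlap", call. = FALSE)
    }
    seq_chars <- sample(bases, L, replace = TRUE)
    seq_chars <- scrub_patterns(seq_chars, patterns)
    placed <- data.frame(start = integer(0), end = integer(0),
                         enzyme = character(0))
    if (n_per_enz > 0) {
      n_total <- 2L * n_per_enz
      # exact uniform placement with minimum separation: sorted uniforms in
      # the gap-shrunk interval plus cumulative separation offsets
      slack <- L - min_sep * (n_total + 1L)
      if (slack <= n_total) {
        stop("could not place ", n_total, " sites with ", min_sep,
             " bp separation on ", L, " bp", call. = FALSE)
      }
      pos <- sort(sample.int(slack, n_total)) +
        min_sep * seq_len(n_total)
      enz_of <- rep(c(ms_enzyme$name, companion$name), n_per_enz)[
        sample.int(n_total)]
      ends <- integer(n_total)
      for (i in seq_len(n_total)) {
        enz <- if (enz_of[i] == ms_enzyme$name) ms_enzyme else companion
        site <- instantiate_pattern(enz$recognition)
        k <- nchar(site)
        seq_chars[(pos[i] + 1):(pos[i] + k)] <- strsplit(site, "")[[1]]
        ends[i] <- pos[i] + k
      }
      placed <- data.frame(start = pos, end = ends, enzyme = enz_of,
                           stringsAsFactors = FALSE)
      # planting may create chance sites at junctions; remove them
      seq_chars <- scrub_patterns(seq_chars, patterns, protected = placed)
    }
    chroms[[ci]] <- paste(seq_chars, collapse = "")
    ms_rows <- placed[placed$enzyme == ms_enzyme$name, , drop = FALSE]
    if (nrow(ms_rows) > 0) {
      loci[[ci]] <- data.frame(chrom = chrom,
                               pos = ms_rows$start + ms_enzyme$cut_offset)
    }
    if (nrow(placed) > 0) {
      placed$chrom <- chrom
      sites[[ci]] <- placed[, c("chrom", "start", "end", "enzyme")]
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  names(genome) <- names(design$chrom_lengths)
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chrom = character(0), pos = integer(0))
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  site_table <- if (length(sites)) do.call(rbind, sites) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               enzyme = character(0))
  rownames(site_table) <- NULL
  list(genome = genome, loci = loci, site_table = site_table)
}

#' Plant methylation states and differential clusters
#'
#' Draws a baseline methylation level for every locus once per bulk from a
#' beta law (shared across timepoints, mimicking stable bulk identity), then
#' groups differential loci into clusters of `cluster_size` nearby loci and
#' shifts them by `+effect_size` (methylation gain) or `-effect_size`
#' (de-methylation), truncated to `[0, 1]`, at every timepoint from
#' `onset` onward. Non-differential loci are identical in expectation across
#' timepoints. Locus amplification propensities are drawn from a gamma law
#' with mean 1.
#'
#' @param loci Locus registry data.frame (`chrom`, `pos`), e.g. from
#'   [simulate_genome()].
#' @param design A [synthetic_design].
#' @param baseline_shape1,baseline_shape2 Beta parameters of the baseline
#'   methylation law (default `Beta(2, 2)`: partially methylated loci, the
#'   regime a methylation-sensitive digest can actually report on).
#' @param n_differential Number of differential loci; must be a multiple of
#'   `cluster_size`.
#' @param effect_size Methylation difference `Delta` in `[0, 1]`.
#' @param cluster_width Maximum span in bp of one planted cluster.
#' @param cluster_size Loci per cluster; `>= 2` so every cluster is a true
#'   region, not an isolated position.
#' @param onset Index into `design$timepoints` at which the shift first
#'   applies (default 2: every timepoint after baseline).
#' @param propensity_shape Gamma shape for locus propensities (rate equal, so
#'   mean 1; default 25, coefficient of variation 0.2 — a registry whose
#'   every locus must clear the same absolute read floor in every library
#'   cannot hold loci with much wider capture-efficiency spread).
#' @param diff_baseline_shape1,diff_baseline_shape2 Beta law of the
#'   *unmethylated-end* baseline of differential loci (default
#'   `Beta(2, 18)`, mean 0.1). A methylation gain is only observable when
#'   the site starts lowly methylated, and a loss only when it starts
#'   methylated by at least the effect size, so gaining clusters start at
#'   this law and losing clusters start at it plus `effect_size` — mirror
#'   trajectories that keep the planted effect inside the dynamic range a
#'   count-based readout can report on. Truncation to `[0, 1]` still
#'   applies.
#' @param seed Seed (default `design$seed + 1`).
#'
#' @return An object of class `synthetic_truth`: `loci`, `locus_propensity`,
#'   `methylation_state` (locus x sample matrix in `[0,1]`), `differential`
#'   (data.frame of shifted loci with direction and delta), `cluster_spans`
#'   (data.frame `chrom`, `start`, `end`, `direction`, 0-based half-open).
#' @export
plant_methylation <- function(loci, design,
                              baseline_shape1 = 2, baseline_shape2 = 2,
                              n_differential = 0, effect_size = 0,
                              cluster_width = 400, cluster_size = 3,
                              onset = 2, propensity_shape = 25,
                              diff_baseline_shape1 = 2,
                              diff_baseline_shape2 = 18,
                              seed = design$seed + 1L) {
  stopifnot(inherits(design, "synthetic_design"),
            abs(effect_size) <= 1, cluster_size >= 2 || n_differential == 0,
            cluster_width <= min(design$chrom_lengths))
  if (n_differential %% max(cluster_size, 1) != 0) {
    stop("n_differential must be a multiple of cluster_size", call. = FALSE)
  }
  set.seed(seed)
  n_loci <- nrow(loci)
  samples <- design$samples
  n_samp <- nrow(samples)
  propensity <- stats::rgamma(n_loci, shape = propensity_shape,
                              rate = propensity_shape)
  base <- matrix(stats::rbeta(n_loci * design$n_bulks,
                              baseline_shape1, baseline_shape2),
                 nrow = n_loci, ncol = design$n_bulks)
  m <- base[, samples$bulk, drop = FALSE]
  colnames(m) <- samples$sample
  differential <- data.frame(chrom = character(0), pos = integer(0),
                             cluster = integer(0), direction = character(0),
                             delta = numeric(0))
  spans <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0))
  if (n_differential > 0) {
    n_clusters <- n_differential / cluster_size
    ord <- order(loci$chrom, loci$pos)
    # candidate windows: runs of cluster_size consecutive loci within width
    cand <- integer(0)
    for (i in seq_len(n_loci - cluster_size + 1)) {
      idx <- ord[i:(i + cluster_size - 1)]
      if (length(unique(loci$chrom[idx])) == 1 &&
          (loci$pos[idx[cluster_size]] - loci$pos[idx[1]]) < cluster_width) {
        cand <- c(cand, i)
      }
    }
    chosen <- integer(0); used <- rep(FALSE, n_loci)
    for (i in sample(cand)) {
      idx <- ord[i:(i + cluster_size - 1)]
      if (!any(used[idx])) {
        chosen <- c(chosen, i)
        used[idx] <- TRUE
        if (length(chosen) == n_clusters) break
      }
    }
    if (length(chosen) < n_clusters) {
      stop("not enough loci to host ", n_clusters, " clusters of ",
           cluster_size, " loci within ", cluster_width, " bp; capacity is ",
           length(chosen), call. = FALSE)
    }
    affected <- samples$timepoint %in%
      design$timepoints[seq(onset, length(design$timepoints))]
    dirs <- sample(c("methylated", "de-methylated"), n_clusters, replace = TRUE)
    for (ci in seq_along(chosen)) {
      idx <- ord[chosen[ci]:(chosen[ci] + cluster_size - 1)]
      delta <- if (dirs[ci] == "methylated") effect_size else -effect_size
      # direction-conditional baseline: gains start at the low-methylation
      # law, losses at its mirror (law + Delta), so both trajectories are
      # realizable and symmetric
      b0 <- matrix(stats::rbeta(length(idx) * design$n_bulks,
                                diff_baseline_shape1, diff_baseline_shape2),
                   nrow = length(idx))
      start_m <- if (delta >= 0) b0 else pmin(b0 + effect_size, 1)
      m[idx, ] <- start_m[, samples$bulk, drop = FALSE]
      m[idx, affected] <- pmin(1, pmax(0, m[idx, affected] + delta))
      differential <- rbind(differential, data.frame(
        chrom = loci$chrom[idx], pos = loci$pos[idx], cluster = ci,
        direction = dirs[ci], delta = delta))
      spans <- rbind(spans, data.frame(
        chrom = loci$chrom[idx[1]], start = min(loci$pos[idx]),
        end = max(loci$pos[idx]) + 1L, direction = dirs[ci]))
    }
  }
  structure(
    list(loci = loci, locus_propensity = propensity, methylation_state = m,
         differential = differential, cluster_spans = spans,
         params = list(baseline = c(baseline_shape1, baseline_shape2),
                       effect_size = effect_size, onset = onset)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d loci x %d samples; %d differential loci in %d clusters\n",
    nrow(x$loci), ncol(x$methylation_state), nrow(x$differential),
    nrow(x$cluster_spans)))
  invisible(x)
}

#' Simulate per-locus read counts from a planted truth
#'
#' Reads arise from successful digestion at unmethylated sites, so the
#' expected count of locus i in sample j is `s_j * a_i * (1 - m_ij)`: library
#' scale times locus propensity times unmethylated fraction. Counts are
#' negative-binomial with the design's dispersion (`var = mu + phi mu^2`);
#' dispersion 0 gives Poisson draws. The library scale is
#' `library_size / n_loci`, so a fully unmethylated, unit-propensity locus
#' has expected coverage `library_size / n_loci`.
#'
#' @param truth A `synthetic_truth` from [plant_methylation()].
#' @param design The matching [synthetic_design].
#' @param seed Seed (default `design$seed + 2`).
#'
#' @return A [locus_counts] object carrying the truth in
#'   `attr(, "truth")`.
#' @export
simulate_counts <- function(truth, design, seed = design$seed + 2L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(design, "synthetic_design"))
  samples <- design$samples
  if (ncol(truth$methylation_state) != nrow(samples)) {
    stop("truth and design disagree on sample count", call. = FALSE)
  }
  set.seed(seed)
  n_loci <- nrow(truth$loci)
  s <- samples$library_size / max(n_loci, 1)
  mu <- outer(truth$locus_propensity, s) * (1 - truth$methylation_state)
  counts <- matrix(0L, nrow = n_loci, ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample))
  if (design$dispersion == 0) {
    counts[] <- as.integer(stats::rpois(length(mu), lambda = mu))
  } else {
    counts[] <- as.integer(stats::rnbinom(length(mu), mu = mu,
                                          size = 1 / design$dispersion))
  }
  x <- locus_counts(counts, truth$loci, samples)
  attr(x, "truth") <- truth
  x
}

#' Write synthetic fixtures to disk
#'
#' Writes the genome as 60-column wrapped FASTA, planted cluster spans as
#' BED (0-based half-open), the locus registry and counts as TSV
#' (`chrom pos <sample>...`), and the design table as TSV
#' (`sample bulk timepoint library_size`).
#'
#' @param dir Output directory (created if missing).
#' @param genome `DNAStringSet` or `NULL`.
#' @param truth `synthetic_truth` or `NULL`.
#' @param counts [locus_counts] or `NULL`.
#' @param design [synthetic_design] or `NULL`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixtures <- function(dir, genome = NULL, truth = NULL,
                                     counts = NULL, design = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(genome)) {
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"), width = 60)
  }
  if (!is.null(truth)) {
    utils::write.table(truth$cluster_spans[, c("chrom", "start", "end", "direction")],
                       file.path(dir, "truth_clusters.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(truth$loci, file.path(dir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(counts)) write_counts_tsv(counts, file.path(dir, "counts.tsv"))
  if (!is.null(design)) {
    utils::write.table(design$samples, file.path(dir, "design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
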