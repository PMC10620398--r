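#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

#' Load gene models from GFF3 or BED
#'
#' GFF3 `gene` features (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED intervals are taken as-is. The gene id
#' comes from the GFF3 `ID=` (or `gene_id=`) attribute, or BED column 4.
#' Duplicate gene ids and malformed lines are hard errors.
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed"` (default: guessed from the extension).
#'
#' @return A data.frame of gene models: `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`).
#' @export
load_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  format <- match.arg(format, c("gff3", "bed"))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  parse_line <- function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (format == "gff3") {
      if (length(f) < 9) {
        stop("malformed GFF3 line ", lineno[i], " in ", path, call. = FALSE)
      }
      if (tolower(f[3]) != "gene") return(NULL)
      start1 <- suppressWarnings(as.integer(f[4]))
      end1 <- suppressWarnings(as.integer(f[5]))
      if (is.na(start1) || is.na(end1) || start1 > end1) {
        stop("malformed coordinates at GFF3 line ", lineno[i], call. = FALSE)
      }
      if (!f[7] %in% c("+", "-")) {
        stop("unknown strand '", f[7], "' at GFF3 line ", lineno[i],
             call. = FALSE)
      }
      attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
      kv <- strsplit(attrs, "=", fixed = TRUE)
      keys <- vapply(kv, `[`, character(1), 1)
      vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
      id <- vals[match(c("ID", "gene_id"), keys)]
      id <- id[!is.na(id)][1]
      if (is.na(id)) {
        stop("no ID/gene_id attribute at GFF3 line ", lineno[i], call. = FALSE)
      }
      data.frame(gene_id = sub("^gene:", "", id), chrom = f[1],
                 start = start1 - 1L, end = end1, strand = f[7],
                 stringsAsFactors = FALSE)
    } else {
      if (length(f) < 4) {
        stop("malformed BED line ", lineno[i], " in ", path, call. = FALSE)
      }
      start0 <- suppressWarnings(as.integer(f[2]))
      end0 <- suppressWarnings(as.integer(f[3]))
      if (is.na(start0) || is.na(end0) || start0 >= end0) {
        stop("malformed coordinates at BED line ", lineno[i], call. = FALSE)
      }
      strand <- if (length(f) >= 6) f[6] else "+"
      if (!strand %in% c("+", "-")) {
        stop("unknown strand '", strand, "' at BED line ", lineno[i],
             call. = FALSE)
      }
      data.frame(gene_id = f[4], chrom = f[1], start = start0, end = end0,
                 strand = strand, stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(seq_along(lines), parse_line)
  genes <- do.call(rbind, rows)
  if (is.null(genes) || nrow(genes) == 0) {
    stop("no gene features found in ", path, call. = FALSE)
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  rownames(genes) <- NULL
  genes
}

#' Regulatory interval of a gene
#'
#' The promoter-anchored extension at the transcription-orientation 5' end:
#' `[start - extension, start)` for `+` genes, `[end, end + extension)` for
#' `-` genes, clipped to `[0, chrom_length)`. The regulatory interval never
#' overlaps the gene body.
#'
#' @param genes Gene model data.frame from [load_annotation()].
#' @param extension Extension in bp (default 2500).
#' @param chrom_lengths Named chromosome lengths; `Inf` assumed for
#'   chromosomes not listed.
#'
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open); zero-length intervals (fully clipped) get `start == end`.
#' @export
regulatory_interval <- function(genes, extension = 2500,
                                chrom_lengths = NULL) {
  stopifnot(extension >= 0)
  L <- function(chrom) {
    if (is.null(chrom_lengths) || !chrom %in% names(chrom_lengths)) Inf
    else chrom_lengths[[chrom]]
  }
  start <- ifelse(genes$strand == "+",
                  pmax(0, genes$start - extension), genes$end)
  end <- ifelse(genes$strand == "+", genes$start,
                pmin(vapply(genes$chrom, L, numeric(1)),
                     genes$end + extension))
  end <- pmax(end, start)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Intersect DMRs with gene bodies and regulatory regions
#'
#' A hit requires at least `min_overlap` bp of overlap between a DMR and the
#' gene body or its regulatory interval. A DMR touching both body and
#' regulatory region of the same gene reports `site = "body"` (body takes
#' precedence). One DMR may hit several genes and vice versa. DMRs on
#' chromosomes absent from the annotation are listed as unassigned with a
#' warning.
#'
#' @param dmrs DMR data.frame (`chrom`, `start`, `end`, `direction`,
#'   `comparison`).
#' @param genes Gene model data.frame from [load_annotation()].
#' @param extension Regulatory extension in bp (default 2500).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param chrom_lengths Optional named chromosome lengths for clipping
#'   regulatory intervals.
#'
#' @return A list with `hits` (data.frame `gene_id`, `chrom`, `dmr_start`,
#'   `dmr_end`, `comparison`, `direction`, `site`), `unassigned` (DMRs with
#'   no annotated chromosome), and `gene_summary` (per-gene direction:
#'   `methylated`, `de-methylated`, or `mixed`).
#' @export
intersect_dmrs <- function(dmrs, genes, extension = 2500, min_overlap = 1,
                           chrom_lengths = NULL) {
  reg <- regulatory_interval(genes, extension, chrom_lengths)
  no_chrom <- !(dmrs$chrom %in% genes$chrom)
  if (any(no_chrom)) {
    warning(sum(no_chrom), " DMR(s) on chromosome(s) absent from the ",
            "annotation: ", paste(unique(dmrs$chrom[no_chrom]), collapse = ", "))
  }
  hit_one <- function(iv, site) {
    if (nrow(dmrs) == 0 || nrow(iv) == 0) return(NULL)
    ok <- iv$end > iv$start
    ivv <- iv[ok, , drop = FALSE]
    if (nrow(ivv) == 0) return(NULL)
    q <- GenomicRanges::GRanges(dmrs$chrom,
                                IRanges::IRanges(dmrs$start + 1L, dmrs$end))
    s <- GenomicRanges::GRanges(ivv$chrom,
                                IRanges::IRanges(ivv$start + 1L, ivv$end))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(q, s, minoverlap = min_overlap))
    if (length(ov) == 0) return(NULL)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    data.frame(gene_id = ivv$gene_id[si], chrom = dmrs$chrom[qi],
               dmr_start = dmrs$start[qi], dmr_end = dmrs$end[qi],
               comparison = dmrs$comparison[qi], direction = dmrs$direction[qi],
               site = site, stringsAsFactors = FALSE)
  }
  body_hits <- hit_one(
    data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
               start = genes$start, end = genes$end), "body")
  reg_hits <- hit_one(reg, "regulatory")
  hits <- rbind(body_hits, reg_hits)
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(0), chrom = character(0),
                       dmr_start = integer(0), dmr_end = integer(0),
                       comparison = character(0), direction = character(0),
                       site = character(0))
  } else {
    # body precedence for a DMR hitting both intervals of the same gene
    key <- paste(hits$gene_id, hits$chrom, hits$dmr_start, hits$dmr_end,
                 hits$comparison)
    hits <- hits[order(key, hits$site), , drop = FALSE]  # "body" < "regulatory"
    hits <- hits[!duplicated(paste(hits$gene_id, hits$chrom, hits$dmr_start,
                                   hits$dmr_end, hits$comparison)), ,
                 drop = FALSE]
    hits <- hits[order(hits$gene_id, hits$chrom, hits$dmr_start), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  gene_summary <- if (nrow(hits) > 0) {
    agg <- tapply(hits$direction, hits$gene_id, function(d) {
      u <- unique(d)
      if (length(u) == 1) u else "mixed"
    })
    data.frame(gene_id = names(agg), direction = unname(as.character(agg)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), direction = character(0))
  }
  list(hits = hits, unassigned = dmrs[no_chrom, , drop = FALSE],
       gene_summary = gene_summary)
}

#' Per-comparison differentially methylated gene table
#'
#' Counts genes per comparison split by direction. A gene with hits of both
#' directions within a comparison is "mixed": included in the gene count but
#' in neither direction column. The `All` row is the union of genes across
#' comparisons (each gene counted once, direction aggregated over all its
#' hits).
#'
#' @param hits Hit data.frame from [intersect_dmrs()].
#'
#' @return data.frame `comparison`, `n_genes`, `n_demethylated`,
#'   `n_methylated`, with an `All` union row first.
#' @export
gene_table <- function(hits) {
  count_block <- function(h) {
    if (nrow(h) == 0) return(c(0L, 0L, 0L))
    agg <- tapply(h$direction, h$gene_id, function(d) {
      u <- unique(d); if (length(u) == 1) u else "mixed"
    })
    c(length(agg), sum(agg == "de-methylated"), sum(agg == "methylated"))
  }
  comps <- unique(hits$comparison)
  rows <- lapply(comps, function(nm) {
    v <- count_block(hits[hits$comparison == nm, , drop = FALSE])
    data.frame(comparison = nm, n_genes = v[1], n_demethylated = v[2],
               n_methylated = v[3], stringsAsFactors = FALSE)
  })
  all_v <- count_block(hits)
  rbind(data.frame(comparison = "All", n_genes = all_v[1],
                   n_demethylated = all_v[2], n_methylated = all_v[3],
                   stringsAsFactors = FALSE),
        do.call(rbind, rows))
}
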