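#' Read and write the counts TSV dialect
#'
#' Counts travel as TSV with header `chrom pos <sample>...`; positions are
#' 0-based. The design table is TSV with header
#' `sample bulk timepoint library_size`.
#'
#' @param x A [locus_counts] object.
#' @param path File path.
#' @return `path` invisibly for writers; parsed objects for readers.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "locus_counts"))
  tab <- cbind(x$loci, as.data.frame(x$raw))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param design Design data.frame matching the sample columns of the file.
#' @export
read_counts_tsv <- function(path, design) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", design$sample)
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("counts file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(tab[, design$sample, drop = FALSE])
  locus_counts(counts, tab[, c("chrom", "pos")], design)
}

#' @rdname write_counts_tsv
#' @export
read_design_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample", "bulk", "timepoint")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("design file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read a Ct table for qPCR analysis
#'
#' TSV with header `gene bulk timepoint ct_target ct_sdha ct_hprt`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_ct_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
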