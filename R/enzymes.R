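#' Restriction enzyme descriptions
#'
#' A `restriction_enzyme` describes the recognition sequence and top-strand
#' cut position of a restriction endonuclease. Recognition sequences may use
#' IUPAC ambiguity codes (e.g. `RCCGGY`). The cut offset is measured in bases
#' from the start of the recognition site on the forward strand, so `MseI`
#' (`T^TAA`) has `cut_offset = 1`.
#'
#' @param name Enzyme name, e.g. `"AciI"`.
#' @param recognition Recognition sequence as an IUPAC nucleotide string.
#' @param cut_offset Top-strand cut position, in bases from the start of the
#'   recognition site; must lie in `[0, nchar(recognition)]`.
#' @param palindromic Logical; if `NULL` (default) it is derived by comparing
#'   the recognition sequence with its reverse complement (IUPAC-aware).
#'
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("MseI", "TTAA", 1)
#' restriction_enzyme("AciI", "CCGC", 1) # non-palindromic, scanned both strands
#' @export
restriction_enzyme <- function(name, recognition, cut_offset, palindromic = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(recognition)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(recognition, "")[[1]], iupac)
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s) in recognition sequence of ", name, ": ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(cut_offset) || length(cut_offset) != 1L ||
      cut_offset < 0 || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie in [0, ", nchar(recognition), "] for ", name,
         call. = FALSE)
  }
  if (is.null(palindromic)) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
    palindromic <- identical(rc, recognition)
  }
  structure(
    list(name = name, recognition = recognition,
         cut_offset = as.integer(cut_offset), palindromic = isTRUE(palindromic)),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<restriction_enzyme> %s  %s  (%s)\n", x$name, site,
              if (x$palindromic) "palindromic" else "non-palindromic"))
  invisible(x)
}

#' Built-in enzyme registry
#'
#' The methylation-sensitive candidates evaluated for CG-context profiling
#' (AciI, AclI, AgeI, BsrFI, BstBI) plus the methylation-insensitive companion
#' MseI. Cut offsets follow the enzymes' documented top-strand cleavage
#' (AciI C^CGC, AclI AA^CGTT, AgeI A^CCGGT, BsrFI R^CCGGY, BstBI TT^CGAA,
#' MseI T^TAA). The registry ships as a plain TSV
#' (`system.file("extdata", "enzymes.tsv", package = "mcseedr")`) so offsets
#' can be edited without touching code; offsets shift fragment boundaries by
#' a few bp at most and never change fragment counts.
#'
#' @param path Optional path to a registry TSV with columns
#'   `name recognition cut_offset`; defaults to the packaged registry.
#'
#' @return A named list of [restriction_enzyme] objects.
#' @examples
#' names(enzyme_registry())
#' enzyme_registry()[["AciI"]]
#' @export
enzyme_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.tsv", package = "mcseedr")
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "integer"),
                           comment.char = "#")
  enz <- lapply(seq_len(nrow(tab)), function(i) {
    restriction_enzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i])
  })
  names(enz) <- tab$name
  enz
}

#' Fetch one enzyme from the registry by name
#'
#' @param name Enzyme name as in [enzyme_registry()].
#' @return A [restriction_enzyme].
#' @export
get_enzyme <- function(name) {
  reg <- enzyme_registry()
  if (!name %in% names(reg)) {
    stop("unknown enzyme '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}
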