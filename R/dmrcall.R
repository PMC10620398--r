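#' Tile a chromosome with adjacent fixed-width windows
#'
#' Windows `[phase + k*width, phase + (k+1)*width)` clipped to
#' `[0, chrom_length)`; together with the leading `[0, phase)` remainder
#' (when `phase > 0`) they cover every coordinate exactly once.
#'
#' @param chrom_length Chromosome length in bp.
#' @param width Window width in bp; `> 0`.
#' @param phase Anchor offset in `[0, width)` (default 0).
#'
#' @return data.frame with columns `start`, `end` (0-based half-open).
#' @export
tile_windows <- function(chrom_length, width, phase = 0) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  stopifnot(phase >= 0, phase < width, chrom_length > 0)
  starts <- seq(from = phase, to = chrom_length - 1, by = width)
  if (phase > 0) starts <- c(0, starts)
  ends <- pmin(c(starts[-1], chrom_length), chrom_length)
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Call DMRs at one window width
#'
#' Assigns each DMP to its unique tile and emits a DMR for every tile whose
#' majority direction holds at least two significant DMPs. Windows where both
#' directions reach two or more with an exact tie are skipped (and returned
#' in `attr(, "skipped_ties")`). DMR boundaries are the tile boundaries; the
#' member-DMP span is reported alongside (`span_start`, `span_end`).
#'
#' @param dmps DMP data.frame from [call_dmps()] (already FDR- and
#'   effect-size-filtered), columns `chrom`, `pos`, `direction`, optionally
#'   `comparison`.
#' @param width Window width in bp.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param phase Tiling anchor (default 0).
#'
#' @return data.frame of DMR records: `chrom`, `start`, `end`, `comparison`,
#'   `direction`, `n_dmps_concordant`, `n_dmps_discordant`, `span_start`,
#'   `span_end`, sorted by `(chrom, start)`.
#' @export
call_dmrs_at_width <- function(dmps, width, chrom_lengths, phase = 0) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), comparison = character(0),
                      direction = character(0),
                      n_dmps_concordant = integer(0),
                      n_dmps_discordant = integer(0),
                      span_start = integer(0), span_end = integer(0))
  if (nrow(dmps) == 0) {
    attr(empty, "skipped_ties") <- empty[0, 1:3]
    return(empty)
  }
  bad <- !(dmps$chrom %in% names(chrom_lengths)) |
    dmps$pos >= chrom_lengths[dmps$chrom] | dmps$pos < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop("DMP at ", dmps$chrom[i], ":", dmps$pos[i],
         " lies outside the chromosome", call. = FALSE)
  }
  comp <- if ("comparison" %in% names(dmps)) dmps$comparison else
    rep(NA_character_, nrow(dmps))
  win <- ifelse(dmps$pos < phase, -1L,
                as.integer(floor((dmps$pos - phase) / width)))
  key <- paste(dmps$chrom, win, sep = "\r")
  rows <- list(); ties <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    n_meth <- sum(dmps$direction[idx] == "methylated")
    n_de <- sum(dmps$direction[idx] == "de-methylated")
    if (max(n_meth, n_de) < 2) next
    chrom <- dmps$chrom[idx[1]]
    w <- win[idx[1]]
    start <- if (w < 0) 0L else as.integer(phase + w * width)
    end <- as.integer(min(if (w < 0) phase else phase + (w + 1) * width,
                          chrom_lengths[chrom]))
    if (n_meth == n_de) {
      ties[[length(ties) + 1]] <- data.frame(chrom = chrom, start = start,
                                             end = end)
      next
    }
    dir <- if (n_meth > n_de) "methylated" else "de-methylated"
    rows[[length(rows) + 1]] <- data.frame(
      chrom = chrom, start = start, end = end,
      comparison = comp[idx[1]], direction = dir,
      n_dmps_concordant = max(n_meth, n_de),
      n_dmps_discordant = min(n_meth, n_de),
      span_start = min(dmps$pos[idx]),
      span_end = max(dmps$pos[idx]) + 1L,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_ties") <- if (length(ties)) do.call(rbind, ties) else
    empty[0, 1:3]
  out
}

#' Optimize the DMR window width
#'
#' Evaluates [call_dmrs_at_width()] over a width grid (default 100 bp to
#' 2000 bp in 100 bp steps, the iterative procedure's search space) and
#' keeps the width maximizing the DMR count. Ties go to the smallest width
#' and are flagged.
#'
#' @param dmps Filtered DMP data.frame.
#' @param chrom_lengths Named chromosome lengths.
#' @param widths Width grid (default `seq(100, 2000, by = 100)`).
#' @param phase Tiling anchor (default 0).
#'
#' @return A list with `scan` (data.frame `width`, `n_dmrs`),
#'   `chosen_width`, `tie` flag, and `dmrs` at the chosen width.
#' @export
optimize_width <- function(dmps, chrom_lengths,
                           widths = seq(100, 2000, by = 100), phase = 0) {
  if (length(widths) == 0) stop("width grid is empty", call. = FALSE)
  widths <- sort(widths)
  if (nrow(dmps) == 0) {
    warning("no DMPs: width scan is all zeros")
    return(list(scan = data.frame(width = widths, n_dmrs = 0L),
                chosen_width = widths[1], tie = TRUE,
                dmrs = call_dmrs_at_width(dmps, widths[1], chrom_lengths, phase)))
  }
  per_width <- lapply(widths, function(w)
    call_dmrs_at_width(dmps, w, chrom_lengths, phase))
  n <- vapply(per_width, nrow, integer(1))
  best <- which.max(n)  # first maximum = smallest width on the sorted grid
  list(scan = data.frame(width = widths, n_dmrs = n),
       chosen_width = widths[best],
       tie = sum(n == n[best]) > 1,
       dmrs = per_width[[best]])
}

#' Per-comparison DMP/DMR summary table
#'
#' The standard reporting layout: per comparison and in total, the number of
#' DMPs and DMRs split by modulation direction.
#'
#' @param dmp_list Named list (by comparison) of DMP data.frames.
#' @param dmr_list Named list (by comparison) of DMR data.frames.
#'
#' @return data.frame with one row per comparison plus a `Total` row;
#'   columns `comparison`, `dmps`, `dmps_demethylated`, `dmps_methylated`,
#'   `dmrs`, `dmrs_demethylated`, `dmrs_methylated`.
#' @export
summarize_dmrs <- function(dmp_list, dmr_list) {
  comps <- union(names(dmp_list), names(dmr_list))
  rows <- lapply(comps, function(nm) {
    dmp <- dmp_list[[nm]]; dmr <- dmr_list[[nm]]
    data.frame(
      comparison = nm,
      dmps = if (is.null(dmp)) 0L else nrow(dmp),
      dmps_demethylated = if (is.null(dmp)) 0L else
        sum(dmp$direction == "de-methylated"),
      dmps_methylated = if (is.null(dmp)) 0L else
        sum(dmp$direction == "methylated"),
      dmrs = if (is.null(dmr)) 0L else nrow(dmr),
      dmrs_demethylated = if (is.null(dmr)) 0L else
        sum(dmr$direction == "de-methylated"),
      dmrs_methylated = if (is.null(dmr)) 0L else
        sum(dmr$direction == "methylated"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(comparison = "Total", t(colSums(tab[, -1, drop = FALSE])))
  names(total) <- names(tab)
  rbind(tab, total)
}

#' Write DMRs as BED6+
#'
#' `chrom start end comparison:direction n_concordant .` plus the extra
#' columns of the DMR table.
#'
#' @param dmrs DMR data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  bed <- data.frame(dmrs$chrom, dmrs$start, dmrs$end,
                    paste0(dmrs$comparison, ":", dmrs$direction),
                    dmrs$n_dmps_concordant, ".",
                    dmrs$n_dmps_discordant, dmrs$span_start, dmrs$span_end)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
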