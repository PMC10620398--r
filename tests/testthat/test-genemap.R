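write_gff3 <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("load_annotation converts GFF3 and BED coordinate conventions", {
  gff <- write_gff3(c(
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gene:G1;Name=foo",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=T1;Parent=G1",
    "chr2\tsrc\tgene\t500\t900\t.\t-\t.\tID=G2"))
  genes <- load_annotation(gff)
  expect_equal(nrow(genes), 2L)  # mRNA feature ignored
  expect_equal(genes$start[1], 1000L)
  expect_equal(genes$end[1], 2000L)
  expect_equal(genes$gene_id, c("G1", "G2"))
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t2000\tG1\t0\t+", "chr2\t499\t900\tG2\t0\t-"), bed)
  genes_b <- load_annotation(bed)
  expect_equal(genes_b$start, c(1000L, 499L))
  expect_equal(genes_b$strand, c("+", "-"))
})

test_that("load_annotation rejects malformed input with line numbers", {
  expect_error(load_annotation(write_gff3("chr1\tsrc\tgene\t10")),
               "line 2")
  expect_error(load_annotation(write_gff3(
    "chr1\tsrc\tgene\t100\t200\t.\t?\t.\tID=G1")), "strand")
  expect_error(load_annotation(write_gff3(c(
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=G1",
    "chr1\tsrc\tgene\t300\t400\t.\t+\t.\tID=G1"))), "duplicate")
})

test_that("regulatory_interval follows the strand-aware promoter rule", {
  genes <- data.frame(gene_id = c("P", "M", "EDGE"),
                      chrom = "chr1",
                      start = c(10000L, 10000L, 1000L),
                      end = c(12000L, 12000L, 3000L),
                      strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  reg <- regulatory_interval(genes, 2500, c(chr1 = 1e6))
  expect_equal(c(reg$start[1], reg$end[1]), c(7500L, 10000L))
  expect_equal(c(reg$start[2], reg$end[2]), c(12000L, 14500L))
  expect_equal(c(reg$start[3], reg$end[3]), c(0L, 1000L))
  # minus-strand gene near the chromosome end is clipped
  tail_gene <- data.frame(gene_id = "T", chrom = "chr1", start = 999000L,
                          end = 999500L, strand = "-")
  rt <- regulatory_interval(tail_gene, 2500, c(chr1 = 1e6))
  expect_equal(c(rt$start, rt$end), c(999500L, 1000000L))
  # regulatory interval never overlaps its own gene body
  for (i in seq_len(nrow(reg))) {
    expect_equal(oracle_overlap_bp(reg$start[i], reg$end[i],
                                   genes$start[i], genes$end[i]), 0)
  }
})

test_that("intersect_dmrs classifies body vs regulatory hits", {
  genes <- data.frame(gene_id = "G", chrom = "chr1", start = 10000L,
                      end = 12000L, strand = "+", stringsAsFactors = FALSE)
  dmr <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                   comparison = "T30_vs_T0",
                                   direction = "methylated",
                                   stringsAsFactors = FALSE)
  expect_equal(intersect_dmrs(dmr(10500, 11200), genes)$hits$site, "body")
  expect_equal(intersect_dmrs(dmr(8000, 8100), genes)$hits$site, "regulatory")
  expect_equal(nrow(intersect_dmrs(dmr(7000, 7400), genes)$hits), 0L)
  # spanning both: body precedence, single hit
  both <- intersect_dmrs(dmr(9000, 10500), genes)
  expect_equal(nrow(both$hits), 1L)
  expect_equal(both$hits$site, "body")
  # unknown chromosome: warned and unassigned
  expect_warning(
    un <- intersect_dmrs(data.frame(chrom = "chrX", start = 1L, end = 100L,
                                    comparison = "c", direction = "methylated"),
                         genes), "absent")
  expect_equal(nrow(un$unassigned), 1L)
  expect_equal(nrow(un$hits), 0L)
})

test_that("hits agree with an all-pairs overlap oracle on random fixtures", {
  set.seed(88)
  for (rep in 1:8) {
    n_genes <- sample(3:20, 1)
    n_dmrs <- sample(5:50, 1)
    L <- 2e5
    gs <- sort(sample.int(L - 5000, n_genes))
    genes <- data.frame(gene_id = paste0("G", seq_len(n_genes)),
                        chrom = "chr1", start = gs,
                        end = gs + sample(500:4000, n_genes, replace = TRUE),
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    ds <- sample.int(L - 3000, n_dmrs)
    dmrs <- data.frame(chrom = "chr1", start = ds,
                       end = ds + sample(100:2000, n_dmrs, replace = TRUE),
                       comparison = "c",
                       direction = sample(c("methylated", "de-methylated"),
                                          n_dmrs, replace = TRUE),
                       stringsAsFactors = FALSE)
    got <- intersect_dmrs(dmrs, genes, extension = 2500,
                          chrom_lengths = c(chr1 = L))$hits
    # oracle: all pairs, body takes precedence over regulatory
    want <- list()
    for (i in seq_len(n_dmrs)) {
      for (j in seq_len(n_genes)) {
        body <- oracle_overlap_bp(dmrs$start[i], dmrs$end[i],
                                  genes$start[j], genes$end[j]) >= 1
        if (genes$strand[j] == "+") {
          rs <- max(0, genes$start[j] - 2500); re <- genes$start[j]
        } else {
          rs <- genes$end[j]; re <- min(L, genes$end[j] + 2500)
        }
        regu <- oracle_overlap_bp(dmrs$start[i], dmrs$end[i], rs, re) >= 1
        if (body || regu) {
          want[[length(want) + 1]] <- data.frame(
            gene_id = genes$gene_id[j], dmr_start = dmrs$start[i],
            site = if (body) "body" else "regulatory",
            stringsAsFactors = FALSE)
        }
      }
    }
    want <- do.call(rbind, want)
    key <- function(df, s) paste(df$gene_id, df$dmr_start, df$site)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_setequal(key(got), key(want))
    }
  }
})

test_that("coordinate reflection maps hits onto hits (strand symmetry)", {
  set.seed(17)
  L <- 1e5
  gs <- sort(sample.int(L - 10000, 8))
  genes <- data.frame(gene_id = paste0("G", 1:8), chrom = "chr1", start = gs,
                      end = gs + 2000L,
                      strand = sample(c("+", "-"), 8, replace = TRUE),
                      stringsAsFactors = FALSE)
  ds <- sample.int(L - 3000, 25)
  dmrs <- data.frame(chrom = "chr1", start = ds, end = ds + 500L,
                     comparison = "c", direction = "methylated",
                     stringsAsFactors = FALSE)
  fwd <- intersect_dmrs(dmrs, genes, chrom_lengths = c(chr1 = L))$hits
  refl_genes <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                           start = L - genes$end, end = L - genes$start,
                           strand = ifelse(genes$strand == "+", "-", "+"),
                           stringsAsFactors = FALSE)
  refl_dmrs <- transform(dmrs, start = L - end, end = L - start)
  rev <- intersect_dmrs(refl_dmrs, refl_genes, chrom_lengths = c(chr1 = L))$hits
  expect_setequal(paste(fwd$gene_id, fwd$site),
                  paste(rev$gene_id, rev$site))
})

test_that("gene_table counts directions with mixed handling", {
  hits <- data.frame(
    gene_id = c("A", "B", "C", "C"),
    chrom = "chr1", dmr_start = 1:4, dmr_end = 2:5,
    comparison = "T30_vs_T0",
    direction = c("methylated", "methylated", "de-methylated", "methylated"),
    site = "body", stringsAsFactors = FALSE)
  tab <- gene_table(hits)
  row <- tab[tab$comparison == "T30_vs_T0", ]
  expect_equal(row$n_genes, 3L)
  expect_equal(row$n_methylated, 2L)   # C is mixed: counted in n_genes only
  expect_equal(row$n_demethylated, 0L)
  all_row <- tab[tab$comparison == "All", ]
  expect_equal(all_row$n_genes, 3L)
  empty <- gene_table(hits[0, ])
  expect_equal(empty$n_genes, 0L)
})
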