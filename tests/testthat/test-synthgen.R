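test_that("simulate_genome plants findable sites at the requested density", {
  d <- small_design(chrom_lengths = 10000, seed = 7)
  g <- simulate_genome(d, site_density = 2)
  # ~20 planted methylation-sensitive sites on 10 kbp at 2/kbp
  expect_equal(nrow(g$loci), 20L)
  found <- find_sites(as.character(g$genome[[1]]), get_enzyme("AciI"))
  expect_identical(sort(g$loci$pos), found)
  # companion sites also planted and exactly findable
  mse <- find_sites(as.character(g$genome[[1]]), get_enzyme("MseI"))
  planted_mse <- g$site_table[g$site_table$enzyme == "MseI", ]
  expect_identical(sort(planted_mse$start + 1L), mse)
})

test_that("simulate_genome zero density yields a site-free genome", {
  d <- small_design(chrom_lengths = 5000, seed = 3)
  g <- simulate_genome(d, site_density = 0)
  expect_equal(nrow(g$loci), 0L)
  expect_equal(find_sites(as.character(g$genome[[1]]), get_enzyme("AciI")),
               integer(0))
  expect_equal(find_sites(as.character(g$genome[[1]]), get_enzyme("MseI")),
               integer(0))
})

test_that("simulate_genome is byte-identical under the same seed", {
  d <- small_design(chrom_lengths = 8000, seed = 5)
  g1 <- simulate_genome(d, site_density = 2)
  g2 <- simulate_genome(d, site_density = 2)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$loci, g2$loci)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(g1$genome, f1, width = 60)
  Biostrings::writeXStringSet(g2$genome, f2, width = 60)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("excessive site density is rejected with a clear message", {
  d <- small_design(chrom_lengths = 1000, seed = 1)
  expect_error(simulate_genome(d, site_density = 100), "too high")
})

test_that("plant_methylation respects the null configuration", {
  d <- small_design(seed = 2)
  g <- simulate_genome(d, site_density = 2)
  tr <- plant_methylation(g$loci, d, n_differential = 0)
  expect_true(all(tr$methylation_state >= 0 & tr$methylation_state <= 1))
  expect_equal(nrow(tr$differential), 0L)
  expect_equal(nrow(tr$cluster_spans), 0L)
  # same bulk shares its baseline across timepoints: T0_1 == T30_1 == T90_1
  expect_identical(tr$methylation_state[, "T0_1"],
                   tr$methylation_state[, "T90_1"])
})

test_that("plant_methylation builds the requested cluster structure", {
  d <- small_design(chrom_lengths = 2e5, library_size = 50 * 400, seed = 9)
  g <- simulate_genome(d, site_density = 2)
  tr <- plant_methylation(g$loci, d, n_differential = 30, effect_size = 0.5,
                          cluster_width = 2000, cluster_size = 3)
  expect_equal(nrow(tr$cluster_spans), 10L)
  expect_equal(nrow(tr$differential), 30L)
  for (i in seq_len(nrow(tr$cluster_spans))) {
    sp <- tr$cluster_spans[i, ]
    inside <- tr$differential$chrom == sp$chrom &
      tr$differential$pos >= sp$start & tr$differential$pos < sp$end &
      tr$differential$direction == sp$direction
    expect_equal(sum(inside), 3L)
    expect_lte(sp$end - sp$start, 2000L)
  }
  # shifted loci move by ~+/- Delta at later timepoints
  aff <- d$samples$sample[d$samples$timepoint != "T0"]
  base <- d$samples$sample[d$samples$timepoint == "T0"]
  idx <- match(paste(tr$differential$chrom, tr$differential$pos),
               paste(tr$loci$chrom, tr$loci$pos))
  shift <- rowMeans(tr$methylation_state[idx, aff, drop = FALSE]) -
    rowMeans(tr$methylation_state[idx, base, drop = FALSE])
  gain <- tr$differential$direction == "methylated"
  expect_true(all(abs(shift[gain] - 0.5) < 0.05))
  expect_true(all(abs(shift[!gain] + 0.5) < 0.05))
})

test_that("plant_methylation errors when cluster capacity is exceeded", {
  d <- small_design(chrom_lengths = 20000, seed = 4)
  g <- simulate_genome(d, site_density = 1)
  expect_error(
    plant_methylation(g$loci, d, n_differential = 300, effect_size = 0.3,
                      cluster_width = 400, cluster_size = 3),
    "capacity")
  expect_error(
    plant_methylation(g$loci, d, n_differential = 10, cluster_size = 3),
    "multiple")
})

test_that("simulate_counts follows the stated count law", {
  # fully methylated locus at zero dispersion is never cut
  d0 <- synthetic_design(chrom_lengths = 5000, n_bulks = 2,
                         library_size = 1000, dispersion = 0, seed = 8)
  g <- simulate_genome(d0, site_density = 2)
  tr <- plant_methylation(g$loci, d0, n_differential = 0)
  tr$methylation_state[] <- 1
  cnt <- simulate_counts(tr, d0)
  expect_true(all(cnt$raw == 0))
  # m = 0, dispersion 0: empirical mean within 3 SE of s_j * a_i over many draws
  tr$methylation_state[] <- 0
  tr$locus_propensity[] <- 1
  n_draws <- nrow(tr$loci) * nrow(d0$samples)  # 10 loci x 6 samples = 60
  reps <- ceiling(1e4 / n_draws)
  draws <- unlist(lapply(seq_len(reps), function(r)
    as.vector(simulate_counts(tr, d0, seed = 1000 + r)$raw)))
  mu <- 1000 / nrow(tr$loci)
  se <- sqrt(mu / length(draws))  # Poisson
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("expected counts decrease monotonically in methylation", {
  d <- synthetic_design(chrom_lengths = 5000, n_bulks = 3,
                        library_size = 2000, dispersion = 0, seed = 6)
  g <- simulate_genome(d, site_density = 2)
  tr <- plant_methylation(g$loci, d, n_differential = 0)
  means <- vapply(c(0, 0.3, 0.6, 0.9), function(m) {
    tr$methylation_state[] <- m
    mean(simulate_counts(tr, d, seed = 99)$raw)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("identical seed and config give identical truth and counts", {
  d <- small_design(chrom_lengths = 3e4, seed = 12)
  g <- simulate_genome(d, site_density = 2)
  tr1 <- plant_methylation(g$loci, d, n_differential = 6, effect_size = 0.4,
                           cluster_width = 3000, cluster_size = 2)
  tr2 <- plant_methylation(g$loci, d, n_differential = 6, effect_size = 0.4,
                           cluster_width = 3000, cluster_size = 2)
  expect_identical(tr1$methylation_state, tr2$methylation_state)
  expect_identical(tr1$cluster_spans, tr2$cluster_spans)
  expect_identical(simulate_counts(tr1, d)$raw, simulate_counts(tr2, d)$raw)
})

test_that("fixture writer emits the documented plain-text formats", {
  d <- small_design(chrom_lengths = 2e4, seed = 13)
  g <- simulate_genome(d, site_density = 2)
  tr <- plant_methylation(g$loci, d, n_differential = 4, effect_size = 0.5,
                          cluster_width = 2000, cluster_size = 2)
  cnt <- simulate_counts(tr, d)
  dir <- tempfile()
  write_synthetic_fixtures(dir, genome = g$genome, truth = tr,
                           counts = cnt, design = d)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fa", "truth_clusters.bed", "loci.tsv", "counts.tsv",
           "design.tsv")))))
  rt <- read_counts_tsv(file.path(dir, "counts.tsv"),
                        read_design_tsv(file.path(dir, "design.tsv")))
  expect_identical(unname(rt$raw), unname(cnt$raw))
  expect_identical(rt$loci$pos, cnt$loci$pos)
})
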