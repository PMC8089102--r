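test_that("reads are assigned to windows by midpoint", {
  w <- data.frame(chrom = "chr1", start = 0, end = 200)
  expect_equal(count_reads_in_windows(toy_reads(100), w), 1L)
  # read (190, 250): midpoint 220 lies outside [0, 200)
  r <- data.frame(chrom = "chr1", start = 190, end = 250)
  expect_equal(count_reads_in_windows(r, w), 0L)
  g <- genome_def("chr1", 1000)
  w2 <- data.frame(chrom = "chrX", start = 0, end = 10)
  expect_error(count_reads_in_windows(toy_reads(100), w2, g),
               "unknown chromosome")
})

test_that("interval-index counts equal the brute-force midpoint scan", {
  for (i in 1:5) {
    set.seed(400 + i)
    L <- sample(1e5:1e6, 1)
    n <- sample(100:2000, 1)
    s <- sort(sample(0:(L - 60), n, replace = TRUE))
    reads <- toy_reads(s)
    wl <- sample(c(100, 1000, 10000), 20, replace = TRUE)
    ws <- sample(0:(L - max(wl)), 20, replace = TRUE)
    wins <- data.frame(chrom = "chr1", start = ws, end = ws + wl)
    expect_equal(count_reads_in_windows(reads, wins),
                 brute_force_counts(reads, wins))
  }
})

test_that("rpkm matches its closed form and scaling invariance", {
  expect_equal(rpkm(10, 2000, 1e6), 5.0)
  expect_equal(rpkm(0, 2000, 1e6), 0)
  expect_equal(rpkm(329, 10000, 2e7), 1.645)
  expect_equal(rpkm(10, 2000, 1e6), rpkm(30, 2000, 3e6))
  expect_error(rpkm(10, 2000, 0), "library_size")
  expect_error(rpkm(10, 0, 1e6), "window_length_bp")
})

test_that("promoter windows clip at chromosome ends and use clipped length", {
  g <- genome_def("chr1", 1e6)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 5000, is_housekeeping = FALSE)
  w <- promoter_windows(genes, g, 10000)
  expect_equal(c(w$start, w$end), c(0, 10000))
  # a TSS near the end is clipped and RPKM divides by the clipped width
  genes2 <- data.frame(gene_id = "g2", chrom = "chr1", strand = "+",
                       tss = 2000, is_housekeeping = FALSE)
  w2 <- promoter_windows(genes2, g, 10000)
  expect_equal(c(w2$start, w2$end), c(0, 7000))
  reads <- toy_reads(seq(0, 9000, by = 100))  # midpoints 25..9025
  em <- promoter_enrichment_matrix(genes2, list(s1 = reads), g, 10000)
  expect_equal(em$values["g2", "s1"],
               rpkm(70, 7000, nrow(reads)))
  genes$chrom <- "chrZ"
  expect_error(promoter_enrichment_matrix(genes, list(s1 = reads), g),
               "unknown chromosome")
})

test_that("zero-read samples yield all-zero columns", {
  g <- genome_def("chr1", 1e6)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(100000, 200000),
                      is_housekeeping = FALSE)
  empty <- toy_reads(integer(0))
  expect_warning(
    em <- promoter_enrichment_matrix(genes, list(a = toy_reads(100000),
                                                 b = empty), g),
    "zero-read")
  expect_true(all(em$values[, "b"] == 0))
})

test_that("genome bins tile chromosomes with a truncated last bin", {
  g <- genome_def("chr1", 25000)
  b <- genome_bins(g, 10000)
  expect_equal(b$start, c(0, 10000, 20000))
  expect_equal(b$end, c(10000, 20000, 25000))
  g2 <- genome_def(c("c1", "c2"), c(25000, 9999))
  expect_equal(nrow(genome_bins(g2, 10000)),
               sum(ceiling(g2$length / 10000)))
  expect_equal(nrow(genome_bins(genome_def("c", 10), 1)), 10L)
})

test_that("bin counts partition the library (midpoint conservation)", {
  g <- genome_def("chr1", 2e5)
  set.seed(11)
  reads <- toy_reads(sample(0:(2e5 - 60), 5000, replace = TRUE))
  em <- bin_enrichment_matrix(g, list(s1 = reads, s2 = reads), 10000)
  bins <- genome_bins(g, 10000)
  counts <- count_reads_in_windows(reads, bins, g)
  expect_equal(sum(counts), nrow(reads))
  expect_equal(counts, brute_force_counts(reads, bins))
  # identical read sets give identical columns
  expect_equal(em$values[, "s1"], em$values[, "s2"])
})

test_that("metagene profile is flat on uniform coverage and strand-aware", {
  g <- genome_def("chr1", 1e6)
  gene <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                     tss = 500000, is_housekeeping = TRUE)
  # deterministic uniform reads: one midpoint per 100-bp bin genome-wide
  reads <- toy_reads(seq(25, 999900, by = 100))
  hk_rpkm <- rpkm(100, 10000, nrow(reads))
  prof <- metagene_profile(gene, reads, g, hk_mean_rpkm = hk_rpkm)
  expect_equal(length(unique(prof$value)), 1L)  # flat
  expect_equal(mean(prof$value), 1.0)

  # an asymmetric domain downstream of a "-" gene appears at negative
  # offsets after strand reversal
  gm <- data.frame(gene_id = "gm", chrom = "chr1", strand = "-",
                   tss = 500000, is_housekeeping = FALSE)
  shifted <- toy_reads(seq(501000, 502975, by = 25))
  pm <- metagene_profile(gm, shifted, g, hk_mean_rpkm = 1)
  expect_true(all(pm$offset[pm$value > 0] < 0))
  gp <- gm; gp$strand <- "+"
  pp <- metagene_profile(gp, shifted, g, hk_mean_rpkm = 1)
  expect_equal(pm$value, rev(pp$value))
})

test_that("housekeeping self-normalized profile averages exactly 1", {
  cfg <- tiny_config(seed = 5)
  sim <- simulate_genome_and_genes(cfg)
  k4 <- simulate_chip_reads(sim$genes, sim$truth, cfg, "H3K4me3")
  hkg <- sim$genes[sim$genes$is_housekeeping, ]
  em <- promoter_enrichment_matrix(hkg, list(s = k4), sim$genome, 10000)
  hk_mean <- mean(em$values[, "s"])
  prof <- metagene_profile(hkg, k4, sim$genome, hk_mean_rpkm = hk_mean)
  expect_equal(mean(prof$value), 1.0, tolerance = 1e-9)
  expect_error(metagene_profile(hkg[0, ], k4, sim$genome, hk_mean_rpkm = 1),
               "empty gene subset")
})
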