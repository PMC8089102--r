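test_that("z-scores use the population standard deviation", {
  zv <- zscore(c(a = 1, b = 2, c = 3))
  expect_equal(unname(zv$z), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(zv$sd_raw, sqrt(2 / 3))
  # identity: mean 0, population sd 1
  set.seed(3)
  x <- stats::setNames(rexp(50), paste0("g", 1:50))
  z <- zscore(x)$z
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  expect_warning(zc <- zscore(c(a = 2, b = 2, c = 2)), "constant")
  expect_true(all(zc$z == 0))
  expect_error(zscore(c(a = 1)), ">= 2")
})

test_that("housekeeping baseline is the mean z over the housekeeping set", {
  zv <- zscore(c(g1 = 0, g2 = 2, g3 = 4, g4 = 6))
  expect_equal(housekeeping_baseline(zv, c("g2", "g3")),
               mean(zv$z[c("g2", "g3")]))
  # all genes housekeeping: baseline is the mean of all z, i.e. 0
  expect_equal(housekeeping_baseline(zv, names(zv$z)), 0)
  expect_error(housekeeping_baseline(zv, character(0)), "empty")
  expect_error(housekeeping_baseline(zv, c("g1", "gX")), "gX")
})

test_that("bivalent universe: fixed list honored, thresholds applied", {
  k4 <- matrix(c(5, 0.5, 2, 3), 4, 1,
               dimnames = list(paste0("g", 1:4), "s1"))
  k27 <- matrix(c(2, 2, 0.2, 1), 4, 1,
                dimnames = list(paste0("g", 1:4), "s1"))
  expect_equal(call_bivalent(k4, k27, "s1", 1, 1), c("g1", "g4"))
  expect_equal(call_bivalent(k4, k27, "s1", fixed_set = c("g3", "g9")), "g3")
  expect_equal(call_bivalent(k4, k27, "s1", 1, Inf), character(0))
  k27b <- k27; rownames(k27b) <- paste0("h", 1:4)
  expect_error(call_bivalent(k4, k27b, "s1"), "universe")
})

test_that("super-bivalency uses strict inequalities on both conditions", {
  zv <- zscore(c(g1 = 0, g2 = 2, g3 = 4, g4 = 6, g5 = 8))
  base <- zv$z[["g3"]]  # a gene sitting exactly at the baseline
  k27 <- c(g1 = 5, g2 = 5, g3 = 5, g4 = 5, g5 = 1)
  cs <- call_super_bivalent(paste0("g", 1:5), zv, base, k27, cutoff = 1)
  # g3 ties the K4 baseline, g5 ties the K27 cutoff: both excluded
  expect_equal(cs$super_bivalent_genes, c("g4"))
  expect_true(all(cs$super_bivalent_genes %in% cs$bivalent_genes))
  expect_error(call_super_bivalent(c("g1", "gZ"), zv, base, k27), "gZ")
})

test_that("raising the K27 cutoff never enlarges the super set", {
  cfg <- tiny_config(seed = 8)
  sim <- simulate_genome_and_genes(cfg)
  k4 <- simulate_chip_reads(sim$genes, sim$truth, cfg, "H3K4me3")
  k27 <- simulate_chip_reads(sim$genes, sim$truth, cfg, "H3K27me3")
  m4 <- promoter_enrichment_matrix(sim$genes, list(s = k4), sim$genome, 10000)
  m27 <- promoter_enrichment_matrix(sim$genes, list(s = k27), sim$genome,
                                    10000)
  zv <- zscore(m4$values[, "s"])
  base <- housekeeping_baseline(zv,
                                sim$genes$gene_id[sim$genes$is_housekeeping])
  biv <- sim$truth$gene_id[sim$truth$true_class %in%
                             c("bivalent", "super_bivalent")]
  prev <- NULL
  for (cut in c(0.5, 1, 5, 50, 1e6)) {
    cs <- call_super_bivalent(biv, zv, base, m27$values[, "s"], cutoff = cut)
    if (!is.null(prev))
      expect_true(all(cs$super_bivalent_genes %in% prev))
    prev <- cs$super_bivalent_genes
  }
  expect_equal(prev, character(0))  # cutoff above the maximum empties the set
})

test_that("adding H3K4me3 reads to a super gene's promoter keeps it super", {
  cfg <- tiny_config(seed = 13)
  sim <- simulate_genome_and_genes(cfg)
  k4 <- simulate_chip_reads(sim$genes, sim$truth, cfg, "H3K4me3")
  k27 <- simulate_chip_reads(sim$genes, sim$truth, cfg, "H3K27me3")
  call_from <- function(k4_reads) {
    m4 <- promoter_enrichment_matrix(sim$genes, list(s = k4_reads),
                                     sim$genome, 10000)
    m27 <- promoter_enrichment_matrix(sim$genes, list(s = k27),
                                      sim$genome, 10000)
    zv <- zscore(m4$values[, "s"])
    base <- housekeeping_baseline(
      zv, sim$genes$gene_id[sim$genes$is_housekeeping])
    biv <- sim$truth$gene_id[sim$truth$true_class %in%
                               c("bivalent", "super_bivalent")]
    call_super_bivalent(biv, zv, base, m27$values[, "s"])
  }
  before <- call_from(k4)
  target <- before$super_bivalent_genes[1]
  tss <- sim$genes$tss[sim$genes$gene_id == target]
  extra <- toy_reads(seq(tss - 1000, tss + 1000, by = 10),
                     chrom = sim$genome$chrom)
  after <- call_from(rbind(k4, extra))
  expect_true(target %in% after$super_bivalent_genes)
})

test_that("overlap statistics report the rounded percentage of set A", {
  a <- paste0("g", 1:329)
  b <- c(a[1:294], paste0("h", 1:200))
  ov <- overlap_sets(a, b, "fPSC", "E6.5")
  expect_equal(ov$n_a, 329)
  expect_equal(ov$n_shared, 294)
  expect_equal(ov$pct_of_a, 89)
  expect_equal(overlap_sets(a, a)$pct_of_a, 100)
  expect_equal(overlap_sets(a, paste0("x", 1:5))$pct_of_a, 0)
  expect_true(is.na(overlap_sets(character(0), a)$pct_of_a))
})

test_that("pipeline classification equals a brute-force re-derivation", {
  cfg <- tiny_config(seed = 21)
  sim <- simulate_genome_and_genes(cfg)
  k4 <- simulate_chip_reads(sim$genes, sim$truth, cfg, "H3K4me3")
  k27 <- simulate_chip_reads(sim$genes, sim$truth, cfg, "H3K27me3")
  m4 <- promoter_enrichment_matrix(sim$genes, list(s = k4), sim$genome, 10000)
  m27 <- promoter_enrichment_matrix(sim$genes, list(s = k27), sim$genome,
                                    10000)
  m4h <- promoter_enrichment_matrix(sim$genes, list(s = k4), sim$genome, 5000)
  m27h <- promoter_enrichment_matrix(sim$genes, list(s = k27), sim$genome,
                                     5000)
  zv <- zscore(m4$values[, "s"])
  hk <- sim$genes$gene_id[sim$genes$is_housekeeping]
  biv <- call_bivalent(m4h, m27h, "s", 1, 1)
  cs <- call_super_bivalent(biv, zv, housekeeping_baseline(zv, hk),
                            m27$values[, "s"])
  # independent re-derivation straight from the read tables
  mid4 <- (k4$start + k4$end) %/% 2
  mid27 <- (k27$start + k27$end) %/% 2
  cnt <- function(mids, tss, h) sum(mids >= tss - h & mids < tss + h)
  r4_10 <- sapply(sim$genes$tss, function(t) cnt(mid4, t, 5000)) /
    10 / (nrow(k4) / 1e6)
  r27_10 <- sapply(sim$genes$tss, function(t) cnt(mid27, t, 5000)) /
    10 / (nrow(k27) / 1e6)
  r4_5 <- sapply(sim$genes$tss, function(t) cnt(mid4, t, 2500)) /
    5 / (nrow(k4) / 1e6)
  r27_5 <- sapply(sim$genes$tss, function(t) cnt(mid27, t, 2500)) /
    5 / (nrow(k27) / 1e6)
  z <- (r4_10 - mean(r4_10)) / sqrt(mean((r4_10 - mean(r4_10))^2))
  base <- mean(z[sim$genes$is_housekeeping])
  biv_bf <- sort(sim$genes$gene_id[r4_5 >= 1 & r27_5 >= 1])
  super_bf <- sort(intersect(biv_bf,
                             sim$genes$gene_id[z > base & r27_10 > 1]))
  expect_equal(cs$bivalent_genes, biv_bf)
  expect_equal(cs$super_bivalent_genes, super_bf)
})
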