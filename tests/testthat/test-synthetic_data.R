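test_that("gene grid geometry: disjoint promoters, alternating strands", {
  cfg <- sim_config(seed = 2,
                    n_genes_per_class = c(housekeeping = 20L, bivalent = 20L,
                                          super_bivalent = 20L, active = 20L,
                                          silent = 20L),
                    chrom_length = 10e6, gene_spacing = 50000)
  sim <- simulate_genome_and_genes(cfg)
  expect_equal(nrow(sim$genes), 100L)
  w <- promoter_windows(sim$genes, sim$genome, 10000)
  w <- w[order(w$start), ]
  expect_true(all(w$start[-1] >= w$end[-nrow(w)]))  # disjoint
  expect_equal(unique(diff(sim$genes$tss)), 50000)
  expect_setequal(unique(sim$genes$strand), c("+", "-"))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 42)
  a <- simulate_genome_and_genes(cfg)
  b <- simulate_genome_and_genes(cfg)
  expect_identical(a, b)
  r1 <- simulate_chip_reads(a$genes, a$truth, cfg, "H3K4me3", "s1")
  r2 <- simulate_chip_reads(b$genes, b$truth, cfg, "H3K4me3", "s1")
  expect_identical(r1, r2)
  # a different sample id gives a different read stream
  r3 <- simulate_chip_reads(a$genes, a$truth, cfg, "H3K4me3", "s2")
  expect_false(identical(r1$start, r3$start))
  e1 <- simulate_expression(a$genes, a$truth, cfg)
  e2 <- simulate_expression(b$genes, b$truth, cfg)
  expect_identical(e1$fpkm, e2$fpkm)
})

test_that("config validation rejects impossible geometry and warns on overlap", {
  expect_error(sim_config(n_genes_per_class = c(housekeeping = 1000L),
                          chrom_length = 1e6, gene_spacing = 50000),
               "exceeds chrom_length")
  cfg <- sim_config(n_genes_per_class = c(housekeeping = 4L, silent = 4L),
                    chrom_length = 1e6, gene_spacing = 9000,
                    k4_broad_width = 4000, valley_width = 4000)
  expect_warning(simulate_genome_and_genes(cfg), "overlap")
  expect_error(sim_config(gene_spacing = 5000), "smaller than gene_spacing")
})

test_that("read counts follow the Poisson(depth x domain_kb) law", {
  # one housekeeping gene, 2-kb domain at 100 reads/kb, no background:
  # expected 200 reads; empirical mean over 200 draws within 3 SE.
  cfg <- sim_config(n_genes_per_class = c(housekeeping = 1L),
                    chrom_length = 1e6, gene_spacing = 50000,
                    k4_narrow_depth = 100, background_read_rate = 0)
  sim <- simulate_genome_and_genes(cfg)
  n <- vapply(1:200, function(i) {
    nrow(simulate_chip_reads(sim$genes, sim$truth, cfg, "H3K4me3",
                             seed = 50000 + i))
  }, numeric(1))
  se <- sqrt(200 / 200)  # sd of the mean of 200 Poisson(200) draws
  expect_lt(abs(mean(n) - 200), 3 * se)
})

test_that("degenerate depths give the stated degenerate read sets", {
  cfg <- tiny_config(k4_narrow_depth = 0, k4_bivalent_depth = 0,
                     k4_broad_depth = 0, k27_depth = 0,
                     background_read_rate = 0)
  sim <- simulate_genome_and_genes(cfg)
  expect_equal(nrow(simulate_chip_reads(sim$genes, sim$truth, cfg,
                                        "H3K4me3")), 0L)
  # silent genes carry no H3K4me3 domain: with background off, no K4 read
  # falls in a silent promoter
  cfg2 <- tiny_config(background_read_rate = 0)
  sim2 <- simulate_genome_and_genes(cfg2)
  k4 <- simulate_chip_reads(sim2$genes, sim2$truth, cfg2, "H3K4me3")
  silent <- sim2$genes[sim2$genes$true_class == "silent", ]
  w <- promoter_windows(silent, sim2$genome, 10000)
  expect_true(all(count_reads_in_windows(k4, w, sim2$genome) == 0L))
})

test_that("methylome has fixed coverage, exact extremes and the global level", {
  cfg <- tiny_config()
  sim <- simulate_genome_and_genes(cfg)
  me <- simulate_methylome(sim$genes, sim$truth, cfg)
  expect_true(all(me$total_count == 20L))

  # levels 0 and 1 are exact
  cfg01 <- tiny_config(meth_global_level = 1, meth_valley_level = 0)
  me01 <- simulate_methylome(sim$genes, sim$truth, cfg01)
  valley_cls <- sim$truth$true_class %in% c("bivalent", "super_bivalent")
  vg <- sim$genes[valley_cls, ]
  vw <- promoter_windows(vg, sim$genome, cfg01$valley_width)
  in_valley <- rep(FALSE, nrow(me01))
  for (i in seq_len(nrow(vw)))
    in_valley <- in_valley | (me01$pos >= vw$start[i] & me01$pos < vw$end[i])
  expect_true(all(me01$meth_count[in_valley] == 0L))
  expect_true(all(me01$meth_count[!in_valley] == 20L))

  # binomial expectation outside valleys: mean within 3 SE of 0.8
  frac <- me$meth_count[!in_valley] / 20
  se <- sqrt(0.8 * 0.2 / (20 * sum(!in_valley)))
  expect_lt(abs(mean(frac) - 0.8), 3 * se)
})

test_that("expression with CV 0 equals the mean table and passes the filter", {
  cfg <- tiny_config(expr_cv = 0)
  sim <- simulate_genome_and_genes(cfg)
  em <- simulate_expression(sim$genes, sim$truth, cfg)
  a_high <- sim$truth$gene_id[sim$truth$planted_expression_class == "A_high"]
  expect_true(all(em$fpkm[a_high, em$group_of_sample == "A"] == 9))
  expect_true(all(em$fpkm[a_high, em$group_of_sample == "B"] == 3))
  # planted means (9,3,3): FC 3 >= 1.5 and FPKM 9 >= 3, so the filter passes
  deg <- tripartite_deg(em)
  expect_true(all(deg$assigned_group[deg$gene_id %in% a_high] == "A"))
})

test_that("truth table covers every generated gene exactly once", {
  cfg <- tiny_config(seed = 9)
  sim <- simulate_genome_and_genes(cfg)
  expect_setequal(sim$truth$gene_id, sim$genes$gene_id)
  expect_false(any(duplicated(sim$truth$gene_id)))
  expect_equal(sim$truth$is_housekeeping,
               sim$truth$true_class == "housekeeping")
})
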