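#' Simulation configuration for the synthetic epigenome
#'
#' Defines the statistical structure the classification pipeline assumes:
#' five planted promoter classes on a single synthetic chromosome.
#' Housekeeping and active genes carry a narrow (2 kb), strong H3K4me3
#' domain; bivalent genes carry the same narrow H3K4me3 domain at lower
#' depth together with a broad H3K27me3 domain; super-bivalent genes carry
#' a broad (8 kb) H3K4me3 domain at housekeeping per-kb depth (hence a
#' stronger 10-kb promoter enrichment than housekeeping) plus broad
#' H3K27me3; silent genes carry H3K27me3 only.  The methylome is globally
#' methylated with hypomethylated valleys over bivalent-class promoters,
#' and expression is a three-group FPKM matrix with planted group-specific
#' genes.
#'
#' @param seed integer seed from which all generator seeds derive.
#' @param n_genes_per_class named integer vector over the classes
#'   `housekeeping`, `bivalent`, `super_bivalent`, `active`, `silent`.
#' @param chrom chromosome name of the synthetic genome.
#' @param chrom_length chromosome length (bp).
#' @param gene_spacing distance between consecutive TSSs (bp).
#' @param read_length simulated read length (bp).
#' @param background_read_rate background reads per kb, genome-wide.
#' @param k4_narrow_width,k4_broad_width H3K4me3 domain widths (bp) for
#'   narrow-promoter classes and for super-bivalent genes; the broad width
#'   is also used for every H3K27me3 domain.
#' @param k4_narrow_depth H3K4me3 reads/kb over housekeeping and active
#'   promoters.
#' @param k4_bivalent_depth H3K4me3 reads/kb over (non-super) bivalent
#'   promoters; lower than the housekeeping depth, since typical bivalent
#'   promoters carry weaker H3K4me3 than housekeeping promoters.
#' @param k4_broad_depth H3K4me3 reads/kb over super-bivalent promoters
#'   (>= the housekeeping depth).
#' @param k27_depth H3K27me3 reads/kb over bivalent, super-bivalent and
#'   silent promoters.
#' @param meth_global_level,meth_valley_level CpG methylation fraction
#'   outside / inside promoter valleys.
#' @param cpg_spacing distance between simulated CpGs (bp).
#' @param cpg_coverage fixed read coverage per CpG.
#' @param valley_width width of the hypomethylated valley centered on the
#'   TSS of bivalent-class genes (bp).
#' @param expr_group_means named list over planted expression classes
#'   (`A_high`, `B_high`, `C_high`, `uniform`), each a length-3 numeric of
#'   mean FPKM per expression group.
#' @param expr_cv coefficient of variation of the log-normal FPKM noise.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_class = c(housekeeping = 40L,
                                             bivalent = 40L,
                                             super_bivalent = 30L,
                                             active = 40L,
                                             silent = 40L),
                       chrom = "chrS",
                       chrom_length = 10e6,
                       gene_spacing = 50000,
                       read_length = 50,
                       background_read_rate = 0.02,
                       k4_narrow_width = 2000,
                       k4_broad_width = 8000,
                       k4_narrow_depth = 500,
                       k4_bivalent_depth = 150,
                       k4_broad_depth = 500,
                       k27_depth = 250,
                       meth_global_level = 0.8,
                       meth_valley_level = 0.1,
                       cpg_spacing = 100,
                       cpg_coverage = 20L,
                       valley_width = 10000,
                       expr_group_means = list(
                         A_high = c(9, 3, 3),
                         B_high = c(3, 9, 3),
                         C_high = c(3, 3, 9),
                         uniform = c(5, 5, 5)),
                       expr_cv = 0.2) {
  cfg <- list(seed = as.integer(seed),
              n_genes_per_class = n_genes_per_class,
              chrom = chrom, chrom_length = chrom_length,
              gene_spacing = gene_spacing, read_length = read_length,
              background_read_rate = background_read_rate,
              k4_narrow_width = k4_narrow_width,
              k4_broad_width = k4_broad_width,
              k4_narrow_depth = k4_narrow_depth,
              k4_bivalent_depth = k4_bivalent_depth,
              k4_broad_depth = k4_broad_depth,
              k27_depth = k27_depth,
              meth_global_level = meth_global_level,
              meth_valley_level = meth_valley_level,
              cpg_spacing = cpg_spacing,
              cpg_coverage = as.integer(cpg_coverage),
              valley_width = valley_width,
              expr_group_means = expr_group_means,
              expr_cv = expr_cv)
  known <- c("housekeeping", "bivalent", "super_bivalent", "active", "silent")
  if (is.null(names(n_genes_per_class)) ||
      any(!names(n_genes_per_class) %in% known))
    stop("n_genes_per_class must be named with classes among: ",
         paste(known, collapse = ", "))
  if (any(n_genes_per_class < 0)) stop("negative gene count")
  if (max(k4_narrow_width, k4_broad_width, valley_width) >= gene_spacing)
    stop("domain widths must be smaller than gene_spacing")
  depths <- c(background_read_rate, k4_narrow_depth, k4_bivalent_depth,
              k4_broad_depth, k27_depth)
  if (any(depths < 0)) stop("depths must be >= 0")
  for (m in c(meth_global_level, meth_valley_level))
    if (m < 0 || m > 1) stop("methylation levels must lie in [0, 1]")
  if (sum(n_genes_per_class) * gene_spacing > chrom_length)
    stop("total genes x gene_spacing exceeds chrom_length")
  if (expr_cv < 0) stop("expr_cv must be >= 0")
  stopifnot(all(vapply(expr_group_means, length, 0L) == 3L))
  structure(cfg, class = "sim_config")
}

# Deterministic per-stream seed: the base seed plus a stable, small label
# hash, so the K4 reads of sample "a" differ from the K27 reads of "b"
# while remaining reproducible.  Kept far below .Machine$integer.max.
stream_seed <- function(config, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100000L
  (config$seed %% 20000L) * 100000L + h
}

#' Simulate the genome, gene grid and truth table
#'
#' Genes are placed on a regular grid (`gene_spacing` apart, first TSS at
#' half a spacing) with alternating strands; the class labels are shuffled
#' over the grid so class is independent of position.  Each gene also
#' receives a planted expression class, assigned round-robin.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` ([genome_def()]), `genes`
#'   (gene-model `data.frame` with `true_class`), and `truth`
#'   (`gene_id`, `true_class`, `is_housekeeping`,
#'   `planted_expression_class`).
#' @export
simulate_genome_and_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- genome_def(config$chrom, config$chrom_length)
  counts <- config$n_genes_per_class[config$n_genes_per_class > 0]
  n <- sum(counts)
  if (n == 0L) stop("no genes requested")
  set.seed(stream_seed(config, "genes"))
  classes <- sample(rep(names(counts), counts))
  tss <- config$gene_spacing / 2 + (seq_len(n) - 1L) * config$gene_spacing
  if (any(tss >= config$chrom_length))
    stop("gene grid exceeds chromosome length")
  if (config$gene_spacing < 10000)
    warning("gene_spacing below 10 kb: 10-kb promoter windows will overlap")
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = config$chrom,
    strand = rep_len(c("+", "-"), n),
    tss = tss,
    is_housekeeping = classes == "housekeeping",
    true_class = classes,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    gene_id = genes$gene_id,
    true_class = classes,
    is_housekeeping = genes$is_housekeeping,
    planted_expression_class = rep_len(names(config$expr_group_means), n),
    stringsAsFactors = FALSE
  )
  list(genome = genome, genes = genes, truth = truth)
}

# Per-class K4/K27 domain width and depth (reads/kb); zero width = no domain.
chip_domain_spec <- function(config, mark) {
  if (mark == "H3K4me3") {
    list(housekeeping = c(config$k4_narrow_width, config$k4_narrow_depth),
         active = c(config$k4_narrow_width, config$k4_narrow_depth),
         bivalent = c(config$k4_narrow_width, config$k4_bivalent_depth),
         super_bivalent = c(config$k4_broad_width, config$k4_broad_depth),
         silent = c(0, 0))
  } else if (mark == "H3K27me3") {
    list(housekeeping = c(0, 0), active = c(0, 0),
         bivalent = c(config$k4_broad_width, config$k27_depth),
         super_bivalent = c(config$k4_broad_width, config$k27_depth),
         silent = c(config$k4_broad_width, config$k27_depth))
  } else stop("mark must be H3K4me3 or H3K27me3")
}

#' Simulate ChIP-seq read intervals for one mark and sample
#'
#' Per gene, the read count is Poisson with mean `depth x domain_kb` and
#' reads fall uniformly within the TSS-centered domain; background reads
#' fall uniformly genome-wide at `background_read_rate` reads/kb.  No
#' nucleosome or peak-shape structure is modeled: uniform placement is
#' sufficient for the RPKM and breadth statistics the pipeline computes.
#'
#' @param genes gene models from [simulate_genome_and_genes()].
#' @param truth matching truth table.
#' @param config a [sim_config()].
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @param sample_id sample label.
#' @param seed optional explicit seed; by default derived from
#'   `config$seed`, the mark and the sample label.
#' @return read `data.frame` (`chrom`, `start`, `end`, `mark`,
#'   `sample_id`) sorted by position.
#' @export
simulate_chip_reads <- function(genes, truth, config, mark,
                                sample_id = "sim", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  spec <- chip_domain_spec(config, mark)
  if (is.null(seed)) seed <- stream_seed(config, paste0(mark, ":", sample_id))
  set.seed(seed)
  L <- config$chrom_length
  rl <- config$read_length
  cls <- truth$true_class[match(genes$gene_id, truth$gene_id)]
  starts <- numeric(0)
  for (i in seq_len(nrow(genes))) {
    wd <- spec[[cls[i]]]
    width <- wd[1L]; depth <- wd[2L]
    if (width <= 0 || depth <= 0) next
    dom_start <- max(0, genes$tss[i] - width / 2)
    dom_end <- min(L, genes$tss[i] + width / 2)
    eff <- dom_end - dom_start
    if (eff <= rl) next
    k <- stats::rpois(1L, depth * eff / 1000)
    if (k > 0L)
      starts <- c(starts, floor(stats::runif(k, dom_start, dom_end - rl)))
  }
  nbg <- stats::rpois(1L, config$background_read_rate * L / 1000)
  if (nbg > 0L)
    starts <- c(starts, floor(stats::runif(nbg, 0, L - rl)))
  starts <- sort(starts)
  data.frame(chrom = rep(config$chrom, length(starts)),
             start = starts, end = starts + rl,
             mark = rep(mark, length(starts)),
             sample_id = rep(sample_id, length(starts)),
             stringsAsFactors = FALSE)
}

#' Simulate a bin-free CpG methylome
#'
#' CpGs are placed every `cpg_spacing` bp along the chromosome; each has a
#' fixed total coverage and a methylated count drawn from
#' `Binomial(cpg_coverage, p)`, where `p` is `meth_valley_level` inside
#' the valley windows (TSS +/- `valley_width/2` of valley genes, by
#' default the bivalent and super-bivalent classes, emulating DNA
#' methylation valleys at developmental promoters) and
#' `meth_global_level` elsewhere.
#'
#' @param genes,truth,config as in [simulate_chip_reads()].
#' @param valley_genes optional character vector of gene IDs carrying a
#'   valley; defaults to the bivalent plus super-bivalent classes.
#' @param sample_id sample label used in seed derivation.
#' @param seed optional explicit seed.
#' @return CpG `data.frame` (`chrom`, `pos`, `meth_count`, `total_count`).
#' @export
simulate_methylome <- function(genes, truth, config, valley_genes = NULL,
                               sample_id = "sim", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(valley_genes)) {
    cls <- truth$true_class[match(genes$gene_id, truth$gene_id)]
    valley_genes <- genes$gene_id[cls %in% c("bivalent", "super_bivalent")]
  }
  if (is.null(seed)) seed <- stream_seed(config, paste0("meth:", sample_id))
  set.seed(seed)
  pos <- seq(0, config$chrom_length - 1, by = config$cpg_spacing)
  p <- rep(config$meth_global_level, length(pos))
  vg <- genes[genes$gene_id %in% valley_genes, , drop = FALSE]
  if (nrow(vg)) {
    vs <- pmax(0, vg$tss - config$valley_width / 2)
    ve <- pmin(config$chrom_length, vg$tss + config$valley_width / 2)
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(pos + 1L, width = 1L),
      IRanges::IRanges(vs + 1L, ve))
    p[hit] <- config$meth_valley_level
  }
  data.frame(chrom = rep(config$chrom, length(pos)), pos = pos,
             meth_count = stats::rbinom(length(pos), config$cpg_coverage, p),
             total_count = rep(config$cpg_coverage, length(pos)),
             stringsAsFactors = FALSE)
}

#' Simulate a three-group FPKM expression matrix
#'
#' FPKM values are log-normal with the class/group mean from
#' `expr_group_means` and coefficient of variation `expr_cv`; with
#' `expr_cv = 0` the matrix equals the mean table exactly.  Planted
#' "one-group-high" classes have an own-group mean at least 1.5x the
#' other groups and at least 3 FPKM, so they satisfy the one-versus-rest
#' fold-change filter by construction.
#'
#' @param genes,truth,config as in [simulate_chip_reads()].
#' @param groups length-3 character vector of group labels, matched by
#'   position against the entries of `expr_group_means`.
#' @param n_reps replicates per group.
#' @param seed optional explicit seed.
#' @return an [expression_matrix()]: FPKM matrix (genes x samples) plus a
#'   sample-to-group map.
#' @export
simulate_expression <- function(genes, truth, config,
                                groups = c("A", "B", "C"), n_reps = 2L,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"), length(groups) == 3L)
  if (is.null(seed)) seed <- stream_seed(config, "expr")
  set.seed(seed)
  cls <- truth$planted_expression_class[match(genes$gene_id, truth$gene_id)]
  if (any(!cls %in% names(config$expr_group_means)))
    stop("expr_group_means lacks entries for some planted classes")
  mean_tab <- t(vapply(config$expr_group_means, as.numeric, numeric(3L)))
  colnames(mean_tab) <- groups
  mu <- mean_tab[cls, , drop = FALSE]  # genes x groups
  samples <- paste(rep(groups, each = n_reps), paste0("r", seq_len(n_reps)),
                   sep = "_")
  group_of_sample <- stats::setNames(rep(groups, each = n_reps), samples)
  cv <- config$expr_cv
  fpkm <- matrix(0, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    m <- mu[, group_of_sample[samples[j]]]
    if (cv == 0) {
      fpkm[, j] <- m
    } else {
      sdlog <- sqrt(log1p(cv^2))
      val <- stats::rlnorm(length(m), log(pmax(m, .Machine$double.xmin)) -
                             sdlog^2 / 2, sdlog)
      val[m == 0] <- 0
      fpkm[, j] <- val
    }
  }
  expression_matrix(fpkm, group_of_sample)
}
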