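#' Pipeline run configuration
#'
#' Collects every input path and tunable parameter of a classification
#' run.  Paths are checked at run time by [run_pipeline()]; a missing
#' file is reported with the field it belongs to.
#'
#' @param genome path to a chrom.sizes file.
#' @param genes path to a gene-model TSV or GTF.
#' @param hk_list path to the housekeeping gene list (one ID per line).
#' @param reads named list: sample id -> named list of BED paths per mark
#'   (`H3K4me3`, `H3K27me3`).
#' @param cpg optional named list: sample id -> CpG table path.
#' @param expression,groups optional FPKM matrix TSV and sample-to-group
#'   TSV.
#' @param truth optional truth-table TSV (synthetic runs); enables the
#'   recovery report.
#' @param bivalent_list optional path to a curated bivalent gene list;
#'   when given it is used verbatim instead of threshold-derived calls.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded in the manifest.
#' @param promoter_bp 10-kb classification promoter window.
#' @param heatmap_bp +/- 2.5 kb presence window used to derive the
#'   bivalent universe.
#' @param bin_bp genome bin width for methylome and mark clustering.
#' @param k27_cutoff H3K27me3 RPKM cutoff for super-bivalency.
#' @param k4_min_rpkm,k27_min_rpkm presence thresholds for the derived
#'   bivalent universe.
#' @param fc_min,fpkm_min one-versus-rest expression filter thresholds.
#' @param min_coverage minimum CpG coverage per methylation bin.
#' @return list of class `run_config`.
#' @export
run_config <- function(genome, genes, hk_list, reads, cpg = NULL,
                       expression = NULL, groups = NULL, truth = NULL,
                       bivalent_list = NULL, out_dir, seed = 1L,
                       promoter_bp = 10000, heatmap_bp = 5000,
                       bin_bp = 10000, k27_cutoff = 1,
                       k4_min_rpkm = 1, k27_min_rpkm = 1,
                       fc_min = 1.5, fpkm_min = 3, min_coverage = 3) {
  params <- c(promoter_bp, heatmap_bp, bin_bp, k27_cutoff, k4_min_rpkm,
              k27_min_rpkm, fc_min, fpkm_min, min_coverage)
  if (any(params <= 0)) stop("all parameters must be positive")
  structure(list(genome = genome, genes = genes, hk_list = hk_list,
                 reads = reads, cpg = cpg, expression = expression,
                 groups = groups, truth = truth,
                 bivalent_list = bivalent_list, out_dir = out_dir,
                 seed = as.integer(seed), promoter_bp = promoter_bp,
                 heatmap_bp = heatmap_bp, bin_bp = bin_bp,
                 k27_cutoff = k27_cutoff, k4_min_rpkm = k4_min_rpkm,
                 k27_min_rpkm = k27_min_rpkm, fc_min = fc_min,
                 fpkm_min = fpkm_min, min_coverage = min_coverage),
            class = "run_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

check_input <- function(path, field) {
  if (is.null(path)) return(invisible(NULL))
  if (!file.exists(path))
    stop("missing input file for field '", field, "': ", path)
  invisible(path)
}

#' Write a full synthetic dataset to disk
#'
#' Generates a genome, gene grid, per-sample ChIP-seq reads for both
#' marks, per-sample methylomes, and a three-group expression matrix,
#' all through the package's text formats, ready for [run_pipeline()].
#'
#' @param config a [sim_config()].
#' @param out_dir dataset directory (created).
#' @param chip_samples character vector of ChIP/WGBS sample labels.
#' @param expression_groups length-3 character vector of expression group
#'   labels.
#' @param n_reps expression replicates per group.
#' @return list with `paths` (all files written), `truth`, and
#'   `run_config` — a ready-to-run [run_config()] pointing at the files.
#' @export
simulate_command <- function(config, out_dir,
                             chip_samples = c("fPSC", "E65epi"),
                             expression_groups = c("A", "B", "C"),
                             n_reps = 2L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome_and_genes(config)
  p <- list(genome = file.path(out_dir, "genome.chrom.sizes"),
            genes = file.path(out_dir, "genes.tsv"),
            hk_list = file.path(out_dir, "housekeeping.txt"),
            truth = file.path(out_dir, "truth.tsv"),
            expression = file.path(out_dir, "fpkm.tsv"),
            groups = file.path(out_dir, "sample_groups.tsv"),
            config = file.path(out_dir, "sim_config.yaml"))
  writeLines(paste(sim$genome$chrom, format(sim$genome$length,
                                            scientific = FALSE, trim = TRUE),
                   sep = "\t"), p$genome)
  data.table::fwrite(sim$genes, p$genes, sep = "\t", showProgress = FALSE)
  writeLines(sim$genes$gene_id[sim$genes$is_housekeeping], p$hk_list)
  data.table::fwrite(sim$truth, p$truth, sep = "\t", showProgress = FALSE)
  reads <- list(); cpg <- list()
  for (s in chip_samples) {
    reads[[s]] <- list()
    for (mk in c("H3K4me3", "H3K27me3")) {
      rd <- simulate_chip_reads(sim$genes, sim$truth, config, mk,
                                sample_id = s)
      f <- file.path(out_dir, sprintf("%s_%s.bed", s, mk))
      data.table::fwrite(rd[, c("chrom", "start", "end")], f, sep = "\t",
                         col.names = FALSE, showProgress = FALSE)
      reads[[s]][[mk]] <- f
    }
    me <- simulate_methylome(sim$genes, sim$truth, config, sample_id = s)
    f <- file.path(out_dir, sprintf("%s_cpg.tsv", s))
    data.table::fwrite(me, f, sep = "\t", showProgress = FALSE)
    cpg[[s]] <- f
  }
  em <- simulate_expression(sim$genes, sim$truth, config,
                            groups = expression_groups, n_reps = n_reps)
  write_tsv_matrix(em$fpkm, p$expression, id_name = "gene_id")
  data.table::fwrite(data.frame(sample = names(em$group_of_sample),
                                group = unname(em$group_of_sample)),
                     p$groups, sep = "\t", showProgress = FALSE)
  cfg_out <- unclass(config)
  cfg_out$n_genes_per_class <- as.list(cfg_out$n_genes_per_class)
  yaml::write_yaml(cfg_out, p$config)
  rc <- run_config(genome = p$genome, genes = p$genes, hk_list = p$hk_list,
                   reads = reads, cpg = cpg, expression = p$expression,
                   groups = p$groups, truth = p$truth,
                   out_dir = file.path(out_dir, "results"),
                   seed = config$seed)
  list(paths = c(p, list(reads = reads, cpg = cpg)), truth = sim$truth,
       run_config = rc)
}

#' Run the full classification pipeline
#'
#' simulate -> quantify -> classify -> compare, as one reproducible run:
#' promoter and bin enrichment matrices for both marks, per-sample
#' bivalent and super-bivalent call sets, pairwise overlap of the super
#' sets, bin-level methylation with pairwise Pearson correlations and an
#' uncentered-correlation sample tree, the one-versus-rest expression
#' classifier, an optional recovery report against a truth table, and a
#' machine-readable manifest (parameters, input checksums, seed,
#' package version).  Outputs are plain text and deterministic, so two
#' runs from the same inputs are byte-identical.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  warnings_log <- character(0)
  withCallingHandlers({
  for (f in c("genome", "genes", "hk_list", "expression", "groups",
              "truth", "bivalent_list"))
    check_input(config[[f]], f)
  for (s in names(config$reads)) for (mk in names(config$reads[[s]]))
    check_input(config$reads[[s]][[mk]], paste0("reads$", s, "$", mk))
  for (s in names(config$cpg))
    check_input(config$cpg[[s]], paste0("cpg$", s))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  inputs <- stage("load", {
    genome <- read_chrom_sizes(config$genome)
    genes <- read_gene_models(config$genes, housekeeping = config$hk_list)
    samples <- names(config$reads)
    k4 <- lapply(samples, function(s)
      read_bed_reads(config$reads[[s]]$H3K4me3, "H3K4me3", s))
    k27 <- lapply(samples, function(s)
      read_bed_reads(config$reads[[s]]$H3K27me3, "H3K27me3", s))
    names(k4) <- names(k27) <- samples
    list(genome = genome, genes = genes, k4 = k4, k27 = k27,
         samples = samples)
  })

  mats <- stage("quantify", {
    m <- list(
      k4_10kb = promoter_enrichment_matrix(inputs$genes, inputs$k4,
                                           inputs$genome,
                                           config$promoter_bp, "H3K4me3"),
      k27_10kb = promoter_enrichment_matrix(inputs$genes, inputs$k27,
                                            inputs$genome,
                                            config$promoter_bp, "H3K27me3"),
      k4_heat = promoter_enrichment_matrix(inputs$genes, inputs$k4,
                                           inputs$genome,
                                           config$heatmap_bp, "H3K4me3"),
      k27_heat = promoter_enrichment_matrix(inputs$genes, inputs$k27,
                                            inputs$genome,
                                            config$heatmap_bp, "H3K27me3"),
      k4_bins = bin_enrichment_matrix(inputs$genome, inputs$k4,
                                      config$bin_bp, "H3K4me3"),
      k27_bins = bin_enrichment_matrix(inputs$genome, inputs$k27,
                                       config$bin_bp, "H3K27me3"))
    for (nm in names(m))
      write_tsv_matrix(m[[nm]]$values,
                       file.path(out, paste0(nm, "_rpkm.tsv")),
                       id_name = "id")
    m
  })

  calls <- stage("call-bivalency", {
    hk_ids <- inputs$genes$gene_id[inputs$genes$is_housekeeping]
    fixed <- if (!is.null(config$bivalent_list))
      read_gene_list(config$bivalent_list) else NULL
    res <- list()
    for (s in inputs$samples) {
      zv <- zscore(mats$k4_10kb$values[, s])
      base <- housekeeping_baseline(zv, hk_ids)
      biv <- call_bivalent(mats$k4_heat, mats$k27_heat, s,
                           config$k4_min_rpkm, config$k27_min_rpkm,
                           fixed_set = fixed)
      cs <- call_super_bivalent(biv, zv, base, mats$k27_10kb$values[, s],
                                cutoff = config$k27_cutoff, sample_id = s)
      res[[s]] <- cs
      summ <- data.frame(gene_id = inputs$genes$gene_id,
                         k4_z = zv$z[inputs$genes$gene_id],
                         k27_rpkm = mats$k27_10kb$values[
                           inputs$genes$gene_id, s],
                         bivalent = inputs$genes$gene_id %in%
                           cs$bivalent_genes,
                         super_bivalent = inputs$genes$gene_id %in%
                           cs$super_bivalent_genes,
                         stringsAsFactors = FALSE)
      data.table::fwrite(summ, file.path(out, sprintf("bivalency_%s.tsv", s)),
                         sep = "\t", showProgress = FALSE)
      writeLines(cs$bivalent_genes,
                 file.path(out, sprintf("bivalent_genes_%s.txt", s)))
      writeLines(cs$super_bivalent_genes,
                 file.path(out, sprintf("super_bivalent_genes_%s.txt", s)))
    }
    res
  })

  stage("overlap", {
    ss <- inputs$samples
    if (length(ss) >= 2L) {
      rows <- list()
      for (i in seq_along(ss)) for (j in seq_along(ss)) if (i != j)
        rows[[length(rows) + 1L]] <- overlap_sets(
          calls[[ss[i]]]$super_bivalent_genes,
          calls[[ss[j]]]$super_bivalent_genes, ss[i], ss[j])
      data.table::fwrite(do.call(rbind, rows), file.path(out, "overlap.tsv"),
                         sep = "\t", showProgress = FALSE)
    }
    if (length(ss) >= 2L) {
      for (mk in c("k4_bins", "k27_bins"))
        write_sample_tree(cluster_samples(mats[[mk]]),
                          file.path(out, paste0(mk, "_tree.nwk")))
    }
    NULL
  })

  if (!is.null(config$cpg)) stage("methylome", {
    cpgs <- lapply(config$cpg, read_cpg_table)
    bins <- genome_bins(inputs$genome, config$bin_bp)
    mm <- methyl_bin_matrix(cpgs, bins, config$min_coverage)
    write_tsv_matrix(mm$fraction, file.path(out, "methylation_bins.tsv"),
                     id_name = "bin_id")
    ss <- colnames(mm$fraction)
    if (length(ss) >= 2L) {
      rows <- list()
      for (i in seq_len(length(ss) - 1L)) for (j in (i + 1L):length(ss)) {
        pp <- pairwise_pearson(mm, ss[i], ss[j])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_a = ss[i], sample_b = ss[j], pearson_r = pp$r,
          n_bins = pp$n_bins, stringsAsFactors = FALSE)
      }
      data.table::fwrite(do.call(rbind, rows),
                         file.path(out, "methylation_correlation.tsv"),
                         sep = "\t", showProgress = FALSE)
      write_sample_tree(cluster_samples(mm),
                        file.path(out, "methylation_tree.nwk"))
    }
    NULL
  })

  if (!is.null(config$expression)) stage("deg", {
    em <- read_expression_matrix(config$expression, config$groups)
    deg <- tripartite_deg(em, fc_min = config$fc_min,
                          fpkm_min = config$fpkm_min)
    data.table::fwrite(deg, file.path(out, "deg.tsv"), sep = "\t",
                       showProgress = FALSE)
    if (ncol(em$fpkm) >= 2L)
      write_sample_tree(cluster_expression(em),
                        file.path(out, "expression_tree.nwk"))
    NULL
  })

  if (!is.null(config$truth)) stage("recovery", {
    truth <- data.table::fread(config$truth, header = TRUE, sep = "\t",
                               showProgress = FALSE, data.table = FALSE)
    biv_true <- truth$gene_id[truth$true_class %in%
                                c("bivalent", "super_bivalent")]
    sup_true <- truth$gene_id[truth$true_class == "super_bivalent"]
    rows <- list()
    for (s in inputs$samples) {
      mb <- recovery_metrics(calls[[s]]$bivalent_genes, biv_true)
      ms <- recovery_metrics(calls[[s]]$super_bivalent_genes, sup_true)
      rows[[s]] <- data.frame(sample = s,
                              bivalent_precision = mb["precision"],
                              bivalent_recall = mb["recall"],
                              super_precision = ms["precision"],
                              super_recall = ms["recall"],
                              row.names = NULL, stringsAsFactors = FALSE)
    }
    data.table::fwrite(do.call(rbind, rows), file.path(out, "recovery.tsv"),
                       sep = "\t", showProgress = FALSE)
    NULL
  })

  stage("manifest", {
    paths <- c(config$genome, config$genes, config$hk_list,
               unlist(config$reads), unlist(config$cpg),
               config$expression, config$groups, config$truth,
               config$bivalent_list)
    manifest <- list(
      package = "epibivalent",
      version = as.character(utils::packageVersion("epibivalent")),
      seed = config$seed,
      parameters = config[c("promoter_bp", "heatmap_bp", "bin_bp",
                            "k27_cutoff", "k4_min_rpkm", "k27_min_rpkm",
                            "fc_min", "fpkm_min", "min_coverage")],
      inputs = as.list(stats::setNames(unname(tools::md5sum(paths)), paths)),
      outputs = sort(list.files(out)),
      warnings = warnings_log)
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    NULL
  })
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  invisible(config$out_dir)
}
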