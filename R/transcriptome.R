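#' Expression matrix with a sample-to-group map
#'
#' @param fpkm numeric matrix of FPKM values (genes x samples,
#'   non-negative, with dimnames).
#' @param group_of_sample named character vector mapping every sample
#'   (column) to its group; every group must have at least one sample.
#' @return object of class `expression_matrix` (fields `fpkm`,
#'   `group_of_sample`).
#' @export
expression_matrix <- function(fpkm, group_of_sample) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
    stop("fpkm matrix needs gene rownames and sample colnames")
  if (any(fpkm < 0)) stop("negative FPKM values")
  miss <- setdiff(colnames(fpkm), names(group_of_sample))
  if (length(miss))
    stop("sample(s) without a group: ", paste(miss, collapse = ", "))
  group_of_sample <- group_of_sample[colnames(fpkm)]
  structure(list(fpkm = fpkm, group_of_sample = group_of_sample),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples; groups: %s\n",
              nrow(x$fpkm), ncol(x$fpkm),
              paste(unique(x$group_of_sample), collapse = ", ")))
  invisible(x)
}

#' Read an FPKM matrix and its sample-to-group map
#'
#' @param fpkm_path TSV written by [write_tsv_matrix()] (first column
#'   gene IDs).
#' @param groups_path two-column TSV with header `sample`, `group`.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(fpkm_path, groups_path) {
  fpkm <- read_tsv_matrix(fpkm_path)
  g <- data.table::fread(groups_path, header = TRUE, sep = "\t",
                         showProgress = FALSE, data.table = FALSE)
  expression_matrix(fpkm, stats::setNames(as.character(g$group),
                                          as.character(g$sample)))
}

#' Fragments per kilobase per million mapped fragments
#'
#' @param counts fragment count(s).
#' @param gene_length_bp gene length(s) in bp (> 0).
#' @param library_size total mapped fragments (> 0).
#' @return numeric FPKM value(s).
#' @export
fpkm_from_counts <- function(counts, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  counts / (gene_length_bp / 1000) / (library_size / 1e6)
}

#' One-versus-rest fold-change classifier for three groups
#'
#' A gene is assigned to group g iff its group-mean FPKM is at least
#' `fc_min` times the mean of each of the other two groups and at least
#' `fpkm_min`.  Group means are arithmetic means over replicates.  A
#' fold change against a zero mean counts as infinite, so the FC
#' condition holds whenever the own mean is positive.  For `fc_min > 1`
#' at most one group can win (mutual domination is impossible), so each
#' gene receives at most one label; genes passing for no group are
#' labelled `"none"`.
#'
#' @param em an [expression_matrix()] spanning exactly three groups.
#' @param groups optional explicit ordering of the three group labels.
#' @param fc_min minimum fold change versus each other group.
#' @param fpkm_min minimum own-group mean FPKM.
#' @return `data.frame` with `gene_id`, `assigned_group`, one
#'   `mean_<group>` column per group, `max_other_mean` and `fold_change`
#'   (own mean / max other mean, Inf when the other means are 0).
#' @export
tripartite_deg <- function(em, groups = NULL, fc_min = 1.5, fpkm_min = 3) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(groups)) groups <- unique(em$group_of_sample)
  if (length(groups) != 3L || !setequal(groups, unique(em$group_of_sample)))
    stop("exactly three groups are required")
  means <- vapply(groups, function(g) {
    rowMeans(em$fpkm[, em$group_of_sample == g, drop = FALSE])
  }, numeric(nrow(em$fpkm)))
  assigned <- rep("none", nrow(means))
  max_other <- fc <- rep(NA_real_, nrow(means))
  for (gi in seq_along(groups)) {
    own <- means[, gi]
    other <- means[, -gi, drop = FALSE]
    pass <- own >= fpkm_min &
      own >= fc_min * other[, 1L] & own >= fc_min * other[, 2L]
    if (fc_min > 1 && any(pass & assigned != "none"))
      stop("internal error: gene assigned to two groups with fc_min > 1")
    assigned[pass] <- groups[gi]
    mo <- pmax(other[, 1L], other[, 2L])
    max_other[pass] <- mo[pass]
    fc[pass] <- ifelse(mo[pass] == 0, Inf, own[pass] / mo[pass])
  }
  out <- data.frame(gene_id = rownames(em$fpkm), assigned_group = assigned,
                    stringsAsFactors = FALSE)
  for (gi in seq_along(groups)) out[[paste0("mean_", groups[gi])]] <- means[, gi]
  out$max_other_mean <- max_other
  out$fold_change <- fc
  out
}

#' Mean expression of marker panels per group
#'
#' Summarizes named marker panels (e.g. formative, naive, primed
#' pluripotency markers) as per-panel, per-group mean FPKM; panel genes
#' absent from the matrix are reported, not silently dropped.
#'
#' @param em an [expression_matrix()].
#' @param panels named list of non-empty character vectors of gene IDs.
#' @return list with `summary` (`panel`, `group`, `mean_fpkm`,
#'   `n_genes`), `genes` (per-gene group means with panel label) and
#'   `missing` (named list of absent gene IDs).
#' @export
marker_summary <- function(em, panels) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    stop("panels must be a named list")
  if (any(vapply(panels, length, 0L) == 0L))
    stop("empty panel: ",
         paste(names(panels)[vapply(panels, length, 0L) == 0L],
               collapse = ", "))
  groups <- unique(em$group_of_sample)
  gmeans <- vapply(groups, function(g) {
    rowMeans(em$fpkm[, em$group_of_sample == g, drop = FALSE])
  }, numeric(nrow(em$fpkm)))
  rownames(gmeans) <- rownames(em$fpkm)
  missing <- lapply(panels, setdiff, y = rownames(em$fpkm))
  rows <- list(); gene_rows <- list()
  for (p in names(panels)) {
    present <- intersect(panels[[p]], rownames(em$fpkm))
    if (length(present)) {
      sub <- gmeans[present, , drop = FALSE]
      rows[[p]] <- data.frame(panel = p, group = groups,
                              mean_fpkm = colMeans(sub),
                              n_genes = length(present),
                              stringsAsFactors = FALSE)
      gene_rows[[p]] <- data.frame(panel = p, gene_id = present,
                                   sub, check.names = FALSE,
                                   stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))),
       missing = missing[vapply(missing, length, 0L) > 0L])
}

#' Relative qPCR expression by the 2^-dCt method
#'
#' @param ct_gene Ct value(s) of the gene of interest.
#' @param ct_reference Ct value(s) of the reference gene.
#' @return `2^-(ct_gene - ct_reference)`.
#' @export
delta_ct_expression <- function(ct_gene, ct_reference) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_reference)))
    stop("non-finite Ct values")
  2^(-(ct_gene - ct_reference))
}

#' Hierarchical clustering of expression samples
#'
#' Applies `log2(FPKM + 1)` and clusters samples with
#' [cluster_samples()] (uncentered correlation, average linkage by
#' default).
#'
#' @param em an [expression_matrix()].
#' @param similarity,linkage passed to [cluster_samples()].
#' @return an [stats::hclust] tree.
#' @export
cluster_expression <- function(em, similarity = "uncentered",
                               linkage = "average") {
  stopifnot(inherits(em, "expression_matrix"))
  cluster_samples(log2(em$fpkm + 1), similarity = similarity,
                  linkage = linkage)
}
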