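#' Bin-level methylation for one sample
#'
#' The methylation fraction of a bin is the coverage-weighted mean over
#' its CpGs, `sum(meth_count) / sum(total_count)`; bins whose summed
#' coverage is below `min_coverage` are reported as missing.  Because the
#' fraction is computed from summed counts, splitting one CpG's counts
#' into two records leaves it unchanged.
#'
#' @param cpg CpG `data.frame` (`chrom`, `pos`, `meth_count`,
#'   `total_count`), e.g. from [read_cpg_table()] or
#'   [simulate_methylome()].
#' @param bins window `data.frame`, typically [genome_bins()] at 10 kb.
#' @param min_coverage minimum summed read coverage for a bin to be
#'   reported.
#' @return `data.frame` with `bin_id`, `meth_fraction` (NA when below
#'   coverage), `cpg_coverage`.
#' @export
bin_methylation <- function(cpg, bins, min_coverage = 3) {
  ids <- if ("bin_id" %in% names(bins)) bins$bin_id
         else sprintf("%s:%d-%d", bins$chrom, as.integer(bins$start),
                      as.integer(bins$end))
  meth <- tot <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    sub <- cpg[cpg$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sub$pos + 1L, width = 1L),
      IRanges::IRanges(bins$start[bi] + 1L, bins$end[bi]))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (length(s)) {
      meth_s <- tapply(sub$meth_count[q], s, sum)
      tot_s <- tapply(sub$total_count[q], s, sum)
      idx <- as.integer(names(meth_s))
      meth[bi[idx]] <- as.numeric(meth_s)
      tot[bi[idx]] <- as.numeric(tot_s)
    }
  }
  frac <- ifelse(tot >= min_coverage, meth / tot, NA_real_)
  data.frame(bin_id = ids, meth_fraction = frac, cpg_coverage = tot,
             stringsAsFactors = FALSE)
}

#' Bin methylation matrix across samples
#'
#' @param cpg_by_sample named list of per-sample CpG tables.
#' @param bins window `data.frame`.
#' @param min_coverage as in [bin_methylation()].
#' @return object of class `methyl_bin_matrix`: list with `fraction`
#'   (bins x samples, NA = missing), `coverage`, `bins`, `min_coverage`.
#' @export
methyl_bin_matrix <- function(cpg_by_sample, bins, min_coverage = 3) {
  if (is.null(names(cpg_by_sample)))
    stop("cpg_by_sample must be a named list")
  per <- lapply(cpg_by_sample, bin_methylation, bins = bins,
                min_coverage = min_coverage)
  frac <- vapply(per, `[[`, numeric(nrow(bins)), "meth_fraction")
  cov <- vapply(per, `[[`, numeric(nrow(bins)), "cpg_coverage")
  rownames(frac) <- rownames(cov) <- per[[1L]]$bin_id
  structure(list(fraction = frac, coverage = cov, bins = bins,
                 min_coverage = min_coverage),
            class = "methyl_bin_matrix")
}

fraction_matrix <- function(x) {
  if (inherits(x, "methyl_bin_matrix")) x$fraction
  else if (inherits(x, "enrichment_matrix")) x$values
  else as.matrix(x)
}

#' Pearson correlation between two samples over shared bins
#'
#' Bins missing in either sample are dropped (pairwise-complete); the
#' number of bins actually used is reported alongside the coefficient.
#'
#' @param mat a `methyl_bin_matrix`, `enrichment_matrix` or plain matrix
#'   (rows = bins, columns = samples).
#' @param sample_a,sample_b column names.
#' @return list with `r` and `n_bins`.
#' @export
pairwise_pearson <- function(mat, sample_a, sample_b) {
  m <- fraction_matrix(mat)
  x <- m[, sample_a]; y <- m[, sample_b]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("fewer than 3 shared non-missing bins")
  list(r = stats::cor(x[ok], y[ok]), n_bins = sum(ok))
}

#' Uncentered correlation between two vectors
#'
#' `s(x, y) = sum(x * y) / sqrt(sum(x^2) * sum(y^2))` over pairwise
#' complete entries — the cosine similarity classically used by Cluster
#' 3.0.  Unlike Pearson, it does not center, so it is invariant to
#' scaling but not to shifts.
#'
#' @param x,y numeric vectors of equal length (NAs dropped pairwise).
#' @return similarity in \[-1, 1\].
#' @export
uncentered_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0L) stop("no shared non-missing entries")
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) stop("zero-norm vector in uncentered correlation")
  sum(x * y) / den
}

#' Hierarchical clustering of samples by bin-level profiles
#'
#' Computes pairwise similarities (uncentered correlation by default,
#' pairwise-complete over missing bins), converts them to distances
#' `1 - s`, and clusters agglomeratively.  Average linkage is monotone,
#' so merge heights are non-decreasing.  Samples are ordered
#' lexicographically before clustering, making the result invariant to
#' input column order (deterministic tie-break).
#'
#' @param mat a `methyl_bin_matrix`, `enrichment_matrix` or plain matrix
#'   (rows = bins, columns = samples; >= 2 samples).
#' @param similarity `"uncentered"` or `"pearson"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return an [stats::hclust] tree with sample labels.
#' @export
cluster_samples <- function(mat, similarity = c("uncentered", "pearson"),
                            linkage = "average") {
  similarity <- match.arg(similarity)
  m <- fraction_matrix(mat)
  if (ncol(m) < 2L) stop("need >= 2 samples to cluster")
  m <- m[, order(colnames(m)), drop = FALSE]
  all_missing <- colSums(is.finite(m)) == 0L
  if (any(all_missing))
    stop("sample(s) with all bins missing: ",
         paste(colnames(m)[all_missing], collapse = ", "))
  n <- ncol(m)
  s <- diag(1, n)
  dimnames(s) <- list(colnames(m), colnames(m))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s[i, j] <- s[j, i] <- if (similarity == "uncentered")
      uncentered_correlation(m[, i], m[, j])
    else pairwise_pearson(m, colnames(m)[i], colnames(m)[j])$r
  }
  stats::hclust(stats::as.dist(1 - s), method = linkage)
}

#' Write an hclust tree as Newick text
#'
#' @param hc an [stats::hclust] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_tree <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
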