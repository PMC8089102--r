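#' Count reads whose midpoint falls in each window
#'
#' Reads are assigned to windows by their midpoint
#' (`floor((start + end) / 2)` in 0-based coordinates), so any tiling of a
#' chromosome partitions the reads and bin counts sum to the library
#' size.
#'
#' @param reads read `data.frame` (`chrom`, `start`, `end`).
#' @param windows window `data.frame` (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param genome optional [genome_def()]; if supplied, a window on an
#'   unknown chromosome is an error and reads must lie inside the genome.
#' @return integer vector of counts, one per window row.
#' @export
count_reads_in_windows <- function(reads, windows, genome = NULL) {
  if (any(windows$end <= windows$start)) stop("empty or inverted window")
  if (!is.null(genome)) {
    unk <- setdiff(unique(windows$chrom), genome$chrom)
    if (length(unk))
      stop("window on unknown chromosome: ", paste(unk, collapse = ", "))
    len <- genome$length[match(reads$chrom, genome$chrom)]
    if (anyNA(len) || any(reads$end > len) || any(reads$start < 0))
      stop("read interval outside genome")
  }
  counts <- integer(nrow(windows))
  mids <- (reads$start + reads$end) %/% 2
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    m <- mids[reads$chrom == ch]
    if (length(m) == 0L) next
    counts[wi] <- IRanges::countOverlaps(
      IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi]),
      IRanges::IRanges(m + 1L, width = 1L))
  }
  counts
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (window_length_bp / 1000) / (library_size / 1e6)` — the
#' enrichment unit used throughout: depth- and length-normalized
#' coverage.
#'
#' @param count read count(s).
#' @param window_length_bp window length(s), > 0.
#' @param library_size total mapped reads in the sample, > 0.
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(count, window_length_bp, library_size) {
  if (any(window_length_bp <= 0)) stop("window_length_bp must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count / (window_length_bp / 1000) / (library_size / 1e6)
}

#' TSS-centered promoter windows
#'
#' Windows are `TSS +/- window_bp/2`, clipped to the chromosome; the
#' clipped length is retained so downstream RPKM uses the true width.
#'
#' @param genes gene models.
#' @param genome a [genome_def()].
#' @param window_bp total window width (even).
#' @return `data.frame` with `chrom`, `start`, `end`, `gene_id`.
#' @export
promoter_windows <- function(genes, genome, window_bp = 10000) {
  if (window_bp %% 2 != 0) stop("window_bp must be even")
  len <- genome$length[match(genes$chrom, genome$chrom)]
  if (anyNA(len))
    stop("gene on unknown chromosome: ",
         paste(unique(genes$chrom[is.na(len)]), collapse = ", "))
  half <- window_bp / 2
  data.frame(chrom = genes$chrom,
             start = pmax(0, genes$tss - half),
             end = pmin(len, genes$tss + half),
             gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

new_enrichment_matrix <- function(values, windows, library_sizes, mark) {
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(list(values = values, windows = windows,
                 library_sizes = library_sizes, mark = mark),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d rows x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$mark)) "unknown mark" else x$mark))
  cat("library sizes:",
      paste(names(x$library_sizes), x$library_sizes, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

enrichment_over_windows <- function(windows, reads_by_sample, mark,
                                    genome, row_ids) {
  if (is.null(names(reads_by_sample)) || any(!nzchar(names(reads_by_sample))))
    stop("reads_by_sample must be a named list")
  lib <- vapply(reads_by_sample, nrow, integer(1))
  if (any(lib == 0L))
    warning("zero-read sample(s) yield all-zero columns: ",
            paste(names(lib)[lib == 0L], collapse = ", "))
  wlen <- windows$end - windows$start
  values <- vapply(reads_by_sample, function(rd) {
    if (nrow(rd) == 0L) return(numeric(nrow(windows)))
    rpkm(count_reads_in_windows(rd, windows, genome), wlen, nrow(rd))
  }, numeric(nrow(windows)))
  values <- matrix(values, nrow = nrow(windows),
                   dimnames = list(row_ids, names(reads_by_sample)))
  new_enrichment_matrix(values, windows, lib, mark)
}

#' Promoter RPKM enrichment matrix (genes x samples)
#'
#' One row per gene, with RPKM of the given mark in the TSS-centered
#' window of `window_bp` (clipped lengths used).  Library size is the
#' total number of reads supplied for the sample.
#'
#' @param genes gene models.
#' @param reads_by_sample named list (sample id -> read `data.frame`) for
#'   one mark.
#' @param genome a [genome_def()].
#' @param window_bp promoter window width; 10 kb for classification,
#'   5 kb (+/- 2.5 kb) for heatmap-style matrices.
#' @param mark mark label recorded on the matrix.
#' @return an `enrichment_matrix` (fields `values`, `windows`,
#'   `library_sizes`, `mark`).
#' @export
promoter_enrichment_matrix <- function(genes, reads_by_sample, genome,
                                       window_bp = 10000, mark = NULL) {
  w <- promoter_windows(genes, genome, window_bp)
  enrichment_over_windows(w, reads_by_sample, mark, genome, genes$gene_id)
}

#' Tile a genome into fixed-width bins
#'
#' @param genome a [genome_def()].
#' @param bin_bp bin width (>= 1); the last bin of each chromosome is
#'   truncated at the chromosome end.
#' @return `data.frame` with `chrom`, `start`, `end`, `bin_id`.
#' @export
genome_bins <- function(genome, bin_bp = 10000) {
  if (bin_bp < 1) stop("bin_bp must be >= 1")
  out <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    s <- seq(0, L - 1, by = bin_bp)
    data.frame(chrom = genome$chrom[i], start = s, end = pmin(s + bin_bp, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$bin_id <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                        as.integer(out$end))
  out
}

#' Genome-wide bin RPKM enrichment matrix (bins x samples)
#'
#' As [promoter_enrichment_matrix()] with tiling bins as rows; because
#' reads are assigned by midpoint, per-sample bin counts sum to the
#' library size.
#'
#' @inheritParams promoter_enrichment_matrix
#' @param bin_bp bin width in bp.
#' @return an `enrichment_matrix`.
#' @export
bin_enrichment_matrix <- function(genome, reads_by_sample, bin_bp = 10000,
                                  mark = NULL) {
  bins <- genome_bins(genome, bin_bp)
  enrichment_over_windows(bins, reads_by_sample, mark, genome, bins$bin_id)
}

#' Strand-aware TSS meta-profile, normalized to a housekeeping baseline
#'
#' For each gene in the subset, the window `TSS +/- window_bp/2` is cut
#' into `bin_bp` bins and per-bin read counts are converted to RPKM;
#' profiles of "-"-strand genes are reversed before averaging, and the
#' per-position mean over genes is divided by `hk_mean_rpkm` (the mean
#' window RPKM of housekeeping genes in the same sample), so profile
#' height is expressed relative to the housekeeping average.  The
#' housekeeping subset normalized by its own mean therefore averages
#' exactly 1 over the window.
#'
#' @param genes_subset gene models of the subset to average (non-empty;
#'   genes whose window would extend past a chromosome end are dropped
#'   with a warning).
#' @param reads read `data.frame` for one sample and mark.
#' @param genome a [genome_def()].
#' @param window_bp total window width.
#' @param bin_bp profile resolution.
#' @param hk_mean_rpkm housekeeping mean window RPKM (> 0).
#' @return `data.frame` with `offset` (bin center relative to the TSS)
#'   and `value`; attribute `bin_bp`.
#' @export
metagene_profile <- function(genes_subset, reads, genome,
                             window_bp = 10000, bin_bp = 100,
                             hk_mean_rpkm) {
  if (nrow(genes_subset) == 0L) stop("empty gene subset")
  if (hk_mean_rpkm <= 0) stop("hk_mean_rpkm must be > 0")
  if (window_bp %% bin_bp != 0) stop("window_bp must be a multiple of bin_bp")
  half <- window_bp / 2
  len <- genome$length[match(genes_subset$chrom, genome$chrom)]
  if (anyNA(len)) stop("gene on unknown chromosome")
  full <- genes_subset$tss - half >= 0 & genes_subset$tss + half <= len
  if (!all(full)) {
    warning(sum(!full), " gene(s) dropped: window extends past chromosome end")
    genes_subset <- genes_subset[full, , drop = FALSE]
    if (nrow(genes_subset) == 0L) stop("empty gene subset after clipping")
  }
  nb <- window_bp / bin_bp
  offs <- -half + (seq_len(nb) - 0.5) * bin_bp
  wins <- data.frame(
    chrom = rep(genes_subset$chrom, each = nb),
    start = rep(genes_subset$tss - half, each = nb) +
      rep((seq_len(nb) - 1L) * bin_bp, nrow(genes_subset)),
    stringsAsFactors = FALSE)
  wins$end <- wins$start + bin_bp
  cts <- matrix(count_reads_in_windows(reads, wins, genome),
                nrow = nb, ncol = nrow(genes_subset))
  rev_idx <- genes_subset$strand == "-"
  cts[, rev_idx] <- cts[nb:1, rev_idx, drop = FALSE]
  lib <- nrow(reads)
  vals <- rowMeans(rpkm(cts, bin_bp, lib)) / hk_mean_rpkm
  structure(data.frame(offset = offs, value = vals), bin_bp = bin_bp)
}

#' Full width at half maximum of a meta-profile
#'
#' Width (bp) of the region where the profile is at least half its
#' maximum — a simple breadth summary used to contrast broad and narrow
#' H3K4me3 domains.
#'
#' @param profile output of [metagene_profile()].
#' @return width in bp.
#' @export
profile_fwhm <- function(profile) {
  bin <- attr(profile, "bin_bp")
  if (is.null(bin)) bin <- diff(profile$offset[1:2])
  sum(profile$value >= max(profile$value) / 2) * bin
}
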