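#' Construct a genome definition
#'
#' A genome definition is the ordered set of chromosome names and lengths
#' against which all coordinates in the package are validated.  All
#' coordinates in this package are 0-based half-open (the BED convention);
#' a chromosome of length L therefore spans positions `[0, L)`.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths numeric vector of chromosome lengths in base pairs
#'   (each >= 1).
#' @return a `data.frame` with columns `chrom` and `length`, one row per
#'   chromosome, in the supplied order.
#' @export
genome_def <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) == 0L) stop("no chromosomes")
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  dup <- chroms[duplicated(chroms)]
  if (length(dup))
    stop("duplicate chromosome name(s): ", paste(unique(dup), collapse = ", "))
  bad <- !is.finite(lengths) | lengths < 1
  if (any(bad))
    stop("non-positive chromosome length for: ",
         paste(chroms[bad], collapse = ", "))
  data.frame(chrom = chroms, length = lengths, stringsAsFactors = FALSE)
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path path to a two-column whitespace-separated text file
#'   (chromosome name, length in bp).
#' @return a genome definition as from [genome_def()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- vapply(fields, length, integer(1))
  if (any(n != 2L))
    stop("malformed chrom.sizes line ", which(n != 2L)[1L], " in ", path)
  lens <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(lens))
    stop("malformed chrom.sizes line ", which(is.na(lens))[1L],
         " in ", path, ": length is not numeric")
  genome_def(vapply(fields, `[`, "", 1L), lens)
}

#' Read ChIP-seq read intervals from a BED3+ file
#'
#' Only the first three columns are used.  Coordinates are taken as
#' 0-based half-open, as BED defines them.  Reads are assumed to be
#' deduplicated, uniquely mapped fragments; validation against a genome
#' is deferred to quantification.
#'
#' @param path BED3+ file.
#' @param mark histone mark label, e.g. `"H3K4me3"` or `"H3K27me3"`.
#' @param sample_id sample label attached to every read.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `mark`,
#'   `sample_id`.
#' @export
read_bed_reads <- function(path, mark, sample_id) {
  dt <- data.table::fread(path, header = FALSE, select = 1:3,
                          col.names = c("chrom", "start", "end"),
                          colClasses = list(character = 1),
                          showProgress = FALSE, data.table = FALSE)
  if (nrow(dt) == 0L) {
    dt <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), stringsAsFactors = FALSE)
  }
  bad <- dt$end <= dt$start | dt$start < 0
  if (any(bad))
    stop("invalid read interval at line ", which(bad)[1L], " of ", path,
         " (need 0 <= start < end)")
  dt$mark <- as.character(mark)
  dt$sample_id <- as.character(sample_id)
  message(nrow(dt), " reads loaded from ", path)
  dt
}

#' Read gene models from TSV or GTF
#'
#' The TSV form requires a header with columns `gene_id`, `chrom`,
#' `strand`, `tss` (0-based), plus optional `is_housekeeping` and
#' `true_class`.  A GTF (detected by the `.gtf` extension) is parsed with
#' \pkg{rtracklayer}; the TSS of a "+"-strand gene is its start and of a
#' "-"-strand gene its last base (`end - 1` in 0-based coordinates).
#'
#' @param path gene-model file.
#' @param housekeeping optional character vector of housekeeping gene IDs,
#'   or a path to a text file with one ID per line; overrides any
#'   `is_housekeeping` column.
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `is_housekeeping` (and `true_class` if present).
#' @export
read_gene_models <- function(path, housekeeping = NULL) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md) && any(md$type == "gene"))
      gr <- gr[md$type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id
    if (is.null(ids)) stop("GTF records carry no gene_id attribute")
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand symbol in GTF: ",
           paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
    genes <- data.frame(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = strand,
      # import() is 1-based closed; 0-based TSS is start-1 (+) / end-1 (-)
      tss = ifelse(strand == "+",
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr) - 1L),
      stringsAsFactors = FALSE
    )
  } else {
    genes <- data.table::fread(path, header = TRUE, sep = "\t",
                               colClasses = list(character = "chrom"),
                               showProgress = FALSE, data.table = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    miss <- setdiff(need, names(genes))
    if (length(miss))
      stop("gene model file lacks column(s): ", paste(miss, collapse = ", "))
    genes$gene_id <- as.character(genes$gene_id)
    genes$chrom <- as.character(genes$chrom)
    genes$strand <- as.character(genes$strand)
  }
  if (any(!genes$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  if (any(genes$tss < 0)) stop("negative TSS coordinate")
  if (!is.null(housekeeping)) {
    if (length(housekeeping) == 1L && file.exists(housekeeping))
      housekeeping <- read_gene_list(housekeeping)
    genes$is_housekeeping <- genes$gene_id %in% housekeeping
  } else if (!"is_housekeeping" %in% names(genes)) {
    genes$is_housekeeping <- FALSE
  } else {
    genes$is_housekeeping <- as.logical(genes$is_housekeeping)
  }
  genes
}

#' Read a plain-text gene list (one ID per line)
#' @param path text file.
#' @return character vector of IDs (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a per-CpG methylation table
#'
#' Expects a TSV with header `chrom`, `pos` (0-based), `meth_count`,
#' `total_count`, as emitted by [simulate_methylome()] or converted from
#' bisulfite callers.
#'
#' @param path TSV file.
#' @return validated `data.frame`.
#' @export
read_cpg_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = "chrom"),
                          showProgress = FALSE, data.table = FALSE)
  need <- c("chrom", "pos", "meth_count", "total_count")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("CpG table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(dt$total_count < 1)) stop("non-positive total_count in ", path)
  if (any(dt$meth_count < 0 | dt$meth_count > dt$total_count))
    stop("meth_count outside [0, total_count] in ", path)
  dt
}

#' Write a bedGraph track
#'
#' @param track `data.frame` with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  need <- c("chrom", "start", "end", "value")
  miss <- setdiff(need, names(track))
  if (length(miss))
    stop("track lacks column(s): ", paste(miss, collapse = ", "))
  if (any(track$end <= track$start)) stop("empty or inverted interval")
  track <- track[order(track$chrom, track$start), need, drop = FALSE]
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping intervals on ", ch)
  }
  data.table::fwrite(track, path, sep = "\t", col.names = FALSE,
                     showProgress = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#' @param path bedGraph file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  data.table::fread(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "value"),
                    colClasses = list(character = 1),
                    showProgress = FALSE, data.table = FALSE)
}

#' Convert a 1-based closed interval to 0-based half-open
#'
#' The single place where the two genomic coordinate conventions meet:
#' a 1-based closed interval `[start, end]` becomes `[start - 1, end)`,
#' preserving its length.
#'
#' @param start,end 1-based closed coordinates.
#' @return list with elements `start` and `end` (0-based half-open).
#' @export
from_1based_closed <- function(start, end) {
  if (any(end < start)) stop("end < start")
  list(start = start - 1, end = end)
}

#' Write a numeric matrix as TSV with an id column
#' @param mat matrix with rownames and colnames.
#' @param path output file.
#' @param id_name header for the rowname column.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(mat, path, id_name = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  data.table::fwrite(df, path, sep = "\t", showProgress = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_tsv_matrix()]
#' @param path TSV file whose first column holds row ids.
#' @return numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  df <- data.table::fread(path, header = TRUE, sep = "\t",
                          showProgress = FALSE, data.table = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}
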