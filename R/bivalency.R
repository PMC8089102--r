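#' Z-score a vector of promoter enrichments
#'
#' Standardizes one sample's RPKM values across genes using the
#' population standard deviation, so `mean(z) = 0` and `sd_pop(z) = 1`.
#' A constant vector (sd 0) yields all-zero z-scores with a warning
#' rather than an error, so degenerate toy inputs do not crash the
#' pipeline.
#'
#' @param values named numeric vector (length >= 2) of raw enrichments.
#' @return object of class `zscored_vector`: list with `raw`, `z`,
#'   `mean_raw`, `sd_raw` (population sd).
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values to z-score")
  if (any(!is.finite(values))) stop("non-finite values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) {
    warning("constant vector: all z-scores set to 0")
    z <- values * 0
  } else {
    z <- (values - m) / s
  }
  structure(list(raw = values, z = z, mean_raw = m, sd_raw = s),
            class = "zscored_vector")
}

#' Housekeeping baseline on the z-score scale
#'
#' The arithmetic mean z-scored H3K4me3 enrichment over the housekeeping
#' genes; super-bivalent genes must exceed this baseline.
#'
#' @param zvec a [zscore()] result over all genes of one sample.
#' @param hk_ids non-empty character vector of housekeeping gene IDs, all
#'   present in `zvec`.
#' @return baseline value (numeric scalar).
#' @export
housekeeping_baseline <- function(zvec, hk_ids) {
  stopifnot(inherits(zvec, "zscored_vector"))
  if (length(hk_ids) == 0L) stop("empty housekeeping set")
  miss <- setdiff(hk_ids, names(zvec$z))
  if (length(miss))
    stop("housekeeping gene(s) missing from z-scored vector: ",
         paste(miss, collapse = ", "))
  mean(zvec$z[hk_ids])
}

matrix_values <- function(x) {
  if (inherits(x, "enrichment_matrix")) x$values else as.matrix(x)
}

#' Derive (or accept) the bivalent gene universe for one sample
#'
#' When a curated bivalent list is available it is taken as given
#' (intersected with the row universe); otherwise bivalent genes are
#' derived as those whose promoter carries both marks:
#' `K4_rpkm >= k4_min_rpkm` and `K27_rpkm >= k27_min_rpkm`, typically on
#' +/- 2.5 kb promoter matrices.
#'
#' @param k4_matrix,k27_matrix `enrichment_matrix` objects (or plain
#'   matrices) over the same gene universe.
#' @param sample sample (column) to use.
#' @param k4_min_rpkm,k27_min_rpkm presence thresholds.
#' @param fixed_set optional externally supplied bivalent gene list.
#' @return sorted character vector of bivalent gene IDs.
#' @export
call_bivalent <- function(k4_matrix, k27_matrix, sample,
                          k4_min_rpkm = 1, k27_min_rpkm = 1,
                          fixed_set = NULL) {
  k4 <- matrix_values(k4_matrix)
  k27 <- matrix_values(k27_matrix)
  if (!setequal(rownames(k4), rownames(k27)))
    stop("K4 and K27 matrices cover different gene universes")
  universe <- rownames(k4)
  if (!is.null(fixed_set)) return(sort(intersect(fixed_set, universe)))
  k27 <- k27[universe, , drop = FALSE]
  keep <- k4[, sample] >= k4_min_rpkm & k27[, sample] >= k27_min_rpkm
  sort(universe[keep])
}

#' Call super-bivalent genes
#'
#' Within the bivalent universe, super-bivalent genes are those whose
#' 10-kb-promoter H3K4me3 z-score is strictly higher than the averaged
#' housekeeping baseline and whose 10-kb-promoter H3K27me3 RPKM strictly
#' exceeds the cutoff (default 1).  Both inequalities are strict, so ties
#' with the baseline or the cutoff are excluded.
#'
#' @param bivalent_set character vector of bivalent gene IDs.
#' @param k4_10kb_zvec a [zscore()] result over all genes (10-kb promoter
#'   H3K4me3 RPKM) of the sample.
#' @param hk_baseline housekeeping baseline from
#'   [housekeeping_baseline()].
#' @param k27_10kb_rpkm named numeric vector of 10-kb promoter H3K27me3
#'   RPKM.
#' @param cutoff H3K27me3 RPKM cutoff (default 1).
#' @param sample_id optional sample label recorded on the result.
#' @return object of class `bivalency_calls`: `sample_id`,
#'   `bivalent_genes`, `super_bivalent_genes`, `hk_baseline_z`,
#'   `k27_cutoff_rpkm`, `thresholds_used`.
#' @export
call_super_bivalent <- function(bivalent_set, k4_10kb_zvec, hk_baseline,
                                k27_10kb_rpkm, cutoff = 1,
                                sample_id = NA_character_) {
  stopifnot(inherits(k4_10kb_zvec, "zscored_vector"))
  miss <- setdiff(bivalent_set,
                  intersect(names(k4_10kb_zvec$z), names(k27_10kb_rpkm)))
  if (length(miss))
    stop("bivalent gene(s) missing from enrichment vectors: ",
         paste(miss, collapse = ", "))
  z <- k4_10kb_zvec$z[bivalent_set]
  k27 <- k27_10kb_rpkm[bivalent_set]
  super <- sort(bivalent_set[z > hk_baseline & k27 > cutoff])
  structure(list(sample_id = sample_id,
                 bivalent_genes = sort(bivalent_set),
                 super_bivalent_genes = super,
                 hk_baseline_z = hk_baseline,
                 k27_cutoff_rpkm = cutoff,
                 thresholds_used = list(k4_rule = "z > housekeeping mean z",
                                        k27_rule = paste0("RPKM > ", cutoff))),
            class = "bivalency_calls")
}

#' @export
print.bivalency_calls <- function(x, ...) {
  cat(sprintf("bivalency_calls%s: %d bivalent, %d super-bivalent\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              length(x$bivalent_genes), length(x$super_bivalent_genes)))
  cat(sprintf("  housekeeping baseline z = %.4f; K27 cutoff RPKM = %g\n",
              x$hk_baseline_z, x$k27_cutoff_rpkm))
  invisible(x)
}

#' Overlap between two gene sets
#'
#' Reports the shared count and the percentage of set A that is also in
#' set B, rounded to the nearest integer percent (e.g. 294 of 329 shared
#' reports 89).
#'
#' @param set_a,set_b character vectors.
#' @param label_a,label_b labels for the report.
#' @return one-row `data.frame`: `set_a_label`, `set_b_label`, `n_a`,
#'   `n_b`, `n_shared`, `pct_of_a` (NA when `n_a` is 0).
#' @export
overlap_sets <- function(set_a, set_b, label_a = "A", label_b = "B") {
  a <- unique(set_a); b <- unique(set_b)
  shared <- length(intersect(a, b))
  data.frame(set_a_label = label_a, set_b_label = label_b,
             n_a = length(a), n_b = length(b), n_shared = shared,
             pct_of_a = if (length(a)) round(100 * shared / length(a))
                        else NA_real_,
             stringsAsFactors = FALSE)
}

#' Precision and recall of a called set against a planted truth set
#'
#' @param called character vector of called IDs.
#' @param truth_set character vector of true-positive IDs.
#' @return named numeric vector `precision`, `recall` (NA when
#'   undefined).
#' @export
recovery_metrics <- function(called, truth_set) {
  tp <- length(intersect(called, truth_set))
  c(precision = if (length(called)) tp / length(unique(called)) else NA_real_,
    recall = if (length(truth_set)) tp / length(unique(truth_set))
             else NA_real_)
}
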