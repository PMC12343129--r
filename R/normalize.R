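# Count normalization and detection filtering.

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples (genes with a zero anywhere drop
#' out of the reference), then normalized to geometric mean 1. If no gene
#' is positive in every sample, either an error is raised or, with
#' `pseudo_reference = TRUE`, the geometric mean is taken over positive
#' counts only.
#'
#' @param counts Non-negative genes-by-samples matrix.
#' @param pseudo_reference Fall back to a positive-counts pseudo-reference
#'   when no gene is positive in all samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos) && !pseudo_reference) {
    stop("no gene has positive counts in every sample; ",
         "consider pseudo_reference = TRUE", call. = FALSE)
  }
  log_geo <- if (any(all_pos) && !pseudo_reference) {
    rowMeans(log(counts[all_pos, , drop = FALSE]))
  } else {
    apply(counts, 1L, function(x) {
      if (!any(x > 0)) return(NA_real_)
      mean(log(x[x > 0]))
    })
  }
  use <- if (any(all_pos) && !pseudo_reference) {
    counts[all_pos, , drop = FALSE]
  } else counts
  sf <- vapply(seq_len(ncol(use)), function(j) {
    r <- log(use[, j]) - log_geo
    r <- r[is.finite(r)]
    if (!length(r)) stop("cannot compute a size factor for column ", j,
                         call. = FALSE)
    exp(stats::median(r))
  }, numeric(1))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Moderated log transform of normalized counts
#'
#' `y = log2(count / size_factor + 1)`: a monotone log-scale transform of
#' normalized counts on which the detection filter operates. Exact zeros
#' map to 0. This is a documented surrogate for regularized-log
#' transforms with shrinkage; pass/fail sets near the threshold may differ
#' slightly from theirs.
#'
#' @param counts Non-negative genes-by-samples matrix.
#' @param factors Positive per-sample size factors.
#' @return Transformed matrix of the same shape.
#' @export
moderated_log <- function(counts, factors = size_factors(counts)) {
  stopifnot(all(factors > 0), length(factors) == ncol(counts))
  log2(sweep(counts, 2L, factors, "/") + 1)
}

#' Detection filter across tissues
#'
#' A transcript is detected in a tissue when its moderated-log value is at
#' or above `threshold` in ALL samples of that tissue (the boundary is
#' inclusive). Also partitions transcripts into those common to every
#' tissue and the tissue-specific rest.
#'
#' @param transformed Matrix from [moderated_log()].
#' @param metadata Metadata `data.frame` with `sample_id` and `tissue`
#'   covering every column.
#' @param threshold Detection threshold on the moderated-log scale
#'   (default 7, i.e. a normalized count of 127).
#' @return A list: `detected` (transcripts x tissues logical matrix),
#'   `common` (ids detected in all tissues), `pattern` (per-transcript
#'   comma-separated detecting tissues), `n_detected_any`.
#' @export
detect <- function(transformed, metadata, threshold = 7) {
  miss <- setdiff(colnames(transformed), metadata$sample_id)
  if (length(miss)) stop("samples missing from metadata: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tissue <- metadata$tissue[match(colnames(transformed),
                                  metadata$sample_id)]
  tissues <- sort(unique(tissue))
  det <- vapply(tissues, function(tt) {
    cols <- which(tissue == tt)
    apply(transformed[, cols, drop = FALSE] >= threshold, 1L, all)
  }, logical(nrow(transformed)))
  rownames(det) <- rownames(transformed)
  common <- rownames(det)[rowSums(det) == length(tissues)]
  pattern <- apply(det, 1L, function(z)
    paste(tissues[z], collapse = ","))
  list(detected = det, common = common, pattern = pattern,
       n_detected_any = sum(rowSums(det) > 0))
}
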