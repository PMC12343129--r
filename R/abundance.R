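# Reading transcript-quantification output (kallisto-style abundance
# tables plus a run summary) and the sample metadata table.

HIBERNATION_STATES <- c("summer", "entrance", "torpor", "arousal", "IBA",
                        "spring")

#' Read one sample's abundance table and run summary
#'
#' Expects the quantifier's per-sample layout: `abundance.tsv` with columns
#' `target_id`, `length`, `eff_length`, `est_counts`, `tpm`, and
#' `run_info.json` carrying `n_processed` (total processed reads) and
#' optionally `n_pseudoaligned`. TPM is checked to sum to 1e6 (tolerance
#' 1); negative or non-finite counts are an error.
#'
#' @param dir Sample directory containing the two files.
#' @return A list: `table` (data frame), `total_reads`, `aligned_reads`
#'   (`NA` if absent).
#' @export
read_abundance <- function(dir) {
  tsv <- file.path(dir, "abundance.tsv")
  info <- file.path(dir, "run_info.json")
  if (!file.exists(tsv)) stop("missing abundance table: ", tsv, call. = FALSE)
  if (!file.exists(info)) {
    stop("missing run summary (run_info.json) for ", dir, call. = FALSE)
  }
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("target_id", "length", "eff_length", "est_counts", "tpm")
  if (!all(need %in% names(tab))) {
    stop("abundance table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(tab$est_counts)) || any(tab$est_counts < 0)) {
    stop("est_counts must be finite and non-negative", call. = FALSE)
  }
  if (nrow(tab) > 0L && abs(sum(tab$tpm) - 1e6) > 1) {
    warning("TPM column does not sum to 1e6 (got ", format(sum(tab$tpm)),
            ")", call. = FALSE)
  }
  ri <- jsonlite::fromJSON(info)
  if (is.null(ri$n_processed)) {
    stop("run summary lacks n_processed (total processed reads)",
         call. = FALSE)
  }
  list(table = tab, total_reads = as.numeric(ri$n_processed),
       aligned_reads = if (is.null(ri$n_pseudoaligned)) NA_real_ else
         as.numeric(ri$n_pseudoaligned))
}

#' Read all samples' abundances under a directory
#'
#' @param dir Directory whose sub-directories are sample ids.
#' @return Named list of [read_abundance()] results.
#' @export
read_abundances <- function(dir) {
  samples <- list.dirs(dir, recursive = FALSE)
  if (!length(samples)) stop("no sample sub-directories under ", dir,
                             call. = FALSE)
  out <- lapply(samples, read_abundance)
  names(out) <- basename(samples)
  out
}

#' Read the sample metadata table
#'
#' Tab-separated with columns `sample_id`, `tissue`, `state`, `sex`.
#' States must be drawn from the six hibernation-study labels (summer is
#' the reference level); sex from `F`/`M`.
#'
#' @param path TSV path.
#' @return Metadata `data.frame` with `state` as a factor with reference
#'   level `summer`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "state", "sex")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(md$state), HIBERNATION_STATES)
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!all(md$sex %in% c("F", "M"))) stop("sex must be F or M",
                                          call. = FALSE)
  md$state <- factor(md$state, levels = HIBERNATION_STATES)
  md$state <- stats::relevel(droplevels(md$state), ref = "summer")
  md
}

#' Mitochondrial fraction of total reads
#'
#' Per sample: the summed estimated counts over the manifest transcripts,
#' divided by the run summary's total processed reads (or pseudoaligned
#' reads with `denominator = "aligned"`), as a percentage. Also reports
#' the per-tissue mean and standard deviation.
#'
#' @param abundances Named list from [read_abundances()] (names = sample
#'   ids).
#' @param metadata Metadata `data.frame` (see [read_metadata()]).
#' @param transcripts Optional character vector restricting to manifest
#'   transcript ids (default: all rows of each table).
#' @param denominator `"total"` (processed reads) or `"aligned"`.
#' @return A list: `per_sample` (`data.frame` of `sample_id`, `tissue`,
#'   `percent`), `per_tissue` (`data.frame` of `tissue`, `mean`, `sd`,
#'   `n`).
#' @export
mito_fraction <- function(abundances, metadata, transcripts = NULL,
                          denominator = c("total", "aligned")) {
  denominator <- match.arg(denominator)
  miss <- setdiff(names(abundances), metadata$sample_id)
  if (length(miss)) stop("samples missing from metadata: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  per <- do.call(rbind, lapply(names(abundances), function(sid) {
    ab <- abundances[[sid]]
    tab <- ab$table
    if (!is.null(transcripts)) {
      tab <- tab[tab$target_id %in% transcripts, , drop = FALSE]
    }
    denom <- if (denominator == "total") ab$total_reads else ab$aligned_reads
    if (!is.finite(denom) || denom <= 0) {
      stop("invalid read denominator for sample ", sid, call. = FALSE)
    }
    data.frame(sample_id = sid,
               tissue = metadata$tissue[match(sid, metadata$sample_id)],
               percent = 100 * sum(tab$est_counts) / denom,
               stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(per, per$tissue), function(d) {
    data.frame(tissue = d$tissue[1L], mean = mean(d$percent),
               sd = stats::sd(d$percent), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(per_sample = per, per_tissue = agg)
}

#' Counts matrix from abundance tables
#'
#' Assembles the genes-by-samples estimated-count matrix, optionally
#' aggregating rows by a locus-grouping map (e.g. mt-Atp8 + mt-Atp6 ->
#' "mt-Atp6/8").
#'
#' @param abundances Named list from [read_abundances()].
#' @param grouping Optional named character vector mapping transcript id
#'   to group label (ids absent from the map keep their own id).
#' @return Numeric matrix (transcripts/groups x samples).
#' @export
counts_from_abundances <- function(abundances, grouping = NULL) {
  ids <- abundances[[1L]]$table$target_id
  mat <- vapply(abundances, function(ab) {
    if (!identical(ab$table$target_id, ids)) {
      stop("abundance tables disagree on transcript ids", call. = FALSE)
    }
    ab$table$est_counts
  }, numeric(length(ids)))
  rownames(mat) <- ids
  if (!is.null(grouping)) {
    grp <- ifelse(ids %in% names(grouping), grouping[ids], ids)
    mat <- rowsum(mat, grp)
  }
  mat
}
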