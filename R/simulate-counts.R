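# Negative-binomial count simulation with planted design effects.

#' Specify the truth of a simulated count experiment
#'
#' Defaults emulate the hibernation study design: six states (summer
#' reference plus entrance, torpor, arousal, IBA, spring) with three
#' replicates per state and sex alternating within state. Baseline means
#' are log-normal; dispersions default to 0.05; size factors log-normal
#' around 1.
#'
#' @param n_genes Number of genes.
#' @param states State labels (first = reference).
#' @param reps_per_state Biological replicates per state.
#' @param baseline_mu Per-gene baseline means (recycled); default
#'   log-normal draws around 200.
#' @param dispersion Per-gene NB dispersions (recycled; default 0.05).
#' @param size_factors Per-sample size factors (recycled; default
#'   log-normal, sd 0.15, normalized to geometric mean 1).
#' @param lfc Genes x (states - 1) matrix of planted log2 fold changes
#'   versus the reference (default all zero). Column names must match the
#'   non-reference states.
#' @param sex_lfc Per-gene log2 fold change of males versus females
#'   (recycled; default 0).
#' @param seed Integer seed.
#' @return A list of class `count_truth`.
#' @export
count_truth <- function(n_genes = 2000L,
                        states = HIBERNATION_STATES,
                        reps_per_state = 3L,
                        baseline_mu = NULL, dispersion = 0.05,
                        size_factors = NULL, lfc = NULL, sex_lfc = 0,
                        seed = 1L) {
  stopifnot(reps_per_state >= 2L, n_genes >= 1L, length(states) >= 2L)
  n_samp <- length(states) * reps_per_state
  .with_seed(seed, function() {
    if (is.null(baseline_mu)) {
      baseline_mu <- exp(stats::rnorm(n_genes, log(200), 1))
    }
    if (is.null(size_factors)) {
      size_factors <- exp(stats::rnorm(n_samp, 0, 0.15))
      size_factors <- size_factors / exp(mean(log(size_factors)))
    }
    alt <- states[-1L]
    if (is.null(lfc)) {
      lfc <- matrix(0, n_genes, length(alt),
                    dimnames = list(NULL, alt))
    }
    stopifnot(ncol(lfc) == length(alt))
    colnames(lfc) <- alt
    structure(list(
      n_genes = n_genes, states = states, reps_per_state = reps_per_state,
      baseline_mu = rep_len(baseline_mu, n_genes),
      dispersion = rep_len(dispersion, n_genes),
      size_factors = rep_len(size_factors, n_samp),
      lfc = lfc, sex_lfc = rep_len(sex_lfc, n_genes), seed = seed),
      class = "count_truth")
  })
}

#' Simulate a negative-binomial count matrix from a truth specification
#'
#' Draws `K[g, j] ~ NB(mean = s_j * mu_g * 2^(state lfc + sex lfc),
#' dispersion alpha_g)`. Sex alternates F/M within each state so sex is
#' never confounded with state.
#'
#' @param truth A [count_truth()].
#' @param tissue Tissue label written into the metadata.
#' @return A list: `counts` (genes x samples), `metadata` (`sample_id`,
#'   `tissue`, `state`, `sex`), `truth`.
#' @export
simulate_counts <- function(truth, tissue = "liver") {
  stopifnot(inherits(truth, "count_truth"))
  states <- truth$states
  reps <- truth$reps_per_state
  md <- data.frame(
    sample_id = paste0(rep(states, each = reps), "_",
                       rep(seq_len(reps), length(states))),
    tissue = tissue,
    state = rep(states, each = reps),
    sex = rep_len(c("F", "M"), length(states) * reps),
    stringsAsFactors = FALSE)
  n_genes <- truth$n_genes
  lfc_full <- cbind(matrix(0, n_genes, 1L,
                           dimnames = list(NULL, states[1L])), truth$lfc)
  .with_seed(truth$seed + 1L, function() {
    counts <- matrix(0, n_genes, nrow(md))
    for (j in seq_len(nrow(md))) {
      eff <- lfc_full[, md$state[j]] +
        if (md$sex[j] == "M") truth$sex_lfc else 0
      mu <- truth$size_factors[j] * truth$baseline_mu * 2^eff
      counts[, j] <- stats::rnbinom(n_genes, size = 1 / truth$dispersion,
                                    mu = mu)
    }
    rownames(counts) <- paste0("gene", seq_len(n_genes))
    colnames(counts) <- md$sample_id
    list(counts = counts, metadata = md, truth = truth)
  })
}

#' Write a simulated experiment as kallisto-style abundance directories
#'
#' Emits, per sample, `<dir>/<sample_id>/abundance.tsv` (columns
#' `target_id`, `length`, `eff_length`, `est_counts`, `tpm`) and
#' `run_info.json` with `n_processed` and `n_pseudoaligned`, plus a
#' `metadata.tsv` - the exact dialect the profiling side consumes.
#'
#' @param sim A [simulate_counts()] result.
#' @param dir Output directory (created).
#' @param lengths Per-gene transcript lengths (recycled; default 1000).
#' @param total_reads Per-sample total processed reads (recycled); default
#'   scales each sample's mitochondrial counts to 20% of the total.
#' @return `dir`, invisibly.
#' @export
write_abundance_dirs <- function(sim, dir, lengths = 1000L,
                                 total_reads = NULL) {
  counts <- sim$counts
  lengths <- rep_len(lengths, nrow(counts))
  if (is.null(total_reads)) total_reads <- round(colSums(counts) / 0.2)
  total_reads <- rep_len(total_reads, ncol(counts))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eff <- pmax(lengths - 100L, 1L)
  for (j in seq_len(ncol(counts))) {
    sd <- file.path(dir, colnames(counts)[j])
    dir.create(sd, showWarnings = FALSE)
    rate <- counts[, j] / eff
    tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rate
    tab <- data.frame(target_id = rownames(counts), length = lengths,
                      eff_length = eff, est_counts = counts[, j],
                      tpm = tpm)
    utils::write.table(tab, file.path(sd, "abundance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(n_processed = total_reads[j],
                              n_pseudoaligned = sum(counts[, j])),
                         file.path(sd, "run_info.json"), auto_unbox = TRUE)
  }
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
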