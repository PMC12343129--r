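# Mitochondrial-derived-peptide (MDP) panel handling and homology calls.

# normalize gene symbols for matching: "MT-ATP6", "mt-Atp6", "ATP6" all map
# to "atp6"
.norm_gene <- function(x) sub("^mt", "", gsub("[^a-z0-9]", "", tolower(x)))

#' Load an MDP peptide panel
#'
#' Reads a peptide FASTA plus a tab-separated metadata table (columns
#' `name`, `mode`, `anchor_gene`, `anchor_strand`, `expected_orf_len_nt`,
#' `source`). With no arguments, loads the bundled panel: the 13-name
#' roster MOTS-c, Humanin, SHLP1-6, SHMOOSE, MTALTND4, Gau, CYTB-187AA and
#' Rudel. In the bundled files only MOTS-c and Humanin carry the canonical
#' human peptides; the remaining homology entries are clearly marked
#' seeded synthetic surrogate sequences (for use with the bundled synthetic
#' reference), and Rudel is positional (no peptide; see [call_rudel()]).
#'
#' @param fasta,meta Paths to the peptide FASTA and metadata TSV; `NULL`
#'   for the bundled panel.
#' @return A `data.frame` with columns `name`, `mode`, `peptide` (`NA` for
#'   positional entries), `anchor_gene`, `anchor_strand`,
#'   `expected_orf_len_nt`, `source`.
#' @export
mdp_panel <- function(fasta = NULL, meta = NULL) {
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "mdp_panel_synthetic.fasta",
                         package = "mitotome", mustWork = TRUE)
  }
  if (is.null(meta)) {
    meta <- system.file("extdata", "mdp_panel_synthetic.tsv",
                        package = "mitotome", mustWork = TRUE)
  }
  aa <- Biostrings::readAAStringSet(fasta)
  names(aa) <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  tab <- utils::read.delim(meta, comment.char = "#", stringsAsFactors = FALSE)
  if (anyDuplicated(tab$name)) stop("panel names must be unique",
                                    call. = FALSE)
  idx <- match(tab$name, names(aa))
  tab$peptide <- ifelse(is.na(idx), NA_character_, as.character(aa)[idx])
  miss <- tab$mode == "homology" & is.na(tab$peptide)
  if (any(miss)) stop("homology panel entries lack peptides: ",
                      paste(tab$name[miss], collapse = ", "), call. = FALSE)
  tab[, c("name", "mode", "peptide", "anchor_gene", "anchor_strand",
          "expected_orf_len_nt", "source")]
}

#' Match candidate ORFs against an MDP panel
#'
#' For each homology-mode panel entry, scores every candidate ORF on the
#' required strand at the anchor locus (anchor interval plus `flank_nt`)
#' by Smith-Waterman local alignment of the panel peptide against the ORF
#' peptide, and reports the single best-scoring ORF passing the identity
#' and reference-coverage thresholds. Panel entries with no qualifying ORF
#' are reported absent (a result, not an error).
#'
#' @param orfs A [scan_orfs()] data frame of candidate ORFs.
#' @param panel A [mdp_panel()] data frame (positional entries ignored).
#' @param features A [gene_features()] data frame used to resolve anchors.
#' @param genome_length Genome length (nt), for circular overlap tests.
#' @param min_identity Minimum percent identity over aligned columns.
#' @param min_coverage Minimum aligned fraction of the panel peptide.
#' @param flank_nt Flank added to each side of the anchor interval.
#' @param matrix,gap_open,gap_extend Alignment parameters (BLOSUM62, 11, 1).
#' @return A `data.frame` with one row per homology panel entry: `name`,
#'   `present`, `orf_start`, `orf_end`, `strand`, `length_nt`, `score`,
#'   `identity`, `coverage`, `peptide`.
#' @export
match_mdps <- function(orfs, panel, features, genome_length,
                       min_identity = 50, min_coverage = 0.7,
                       flank_nt = 100L, matrix = blosum62(),
                       gap_open = 11, gap_extend = 1) {
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  hom <- panel[panel$mode == "homology", , drop = FALSE]
  L <- genome_length
  res <- lapply(seq_len(nrow(hom)), function(i) {
    p <- hom[i, ]
    absent <- data.frame(name = p$name, present = FALSE,
                         orf_start = NA_integer_, orf_end = NA_integer_,
                         strand = NA_character_, length_nt = NA_integer_,
                         score = NA_real_, identity = NA_real_,
                         coverage = NA_real_, peptide = NA_character_,
                         stringsAsFactors = FALSE)
    a <- features[.norm_gene(features$name) == .norm_gene(p$anchor_gene), ,
                  drop = FALSE]
    if (nrow(a) == 0L) return(absent)
    a <- a[1L, ]
    want_strand <- if (p$anchor_strand == "sense") a$strand else
      if (a$strand == "+") "-" else "+"
    a_len <- interval_length(a$start, a$end, L)
    w_start <- (a$start - flank_nt) %% L
    w_len <- a_len + 2L * flank_nt
    cand <- orfs[orfs$strand == want_strand, , drop = FALSE]
    if (nrow(cand) == 0L) return(absent)
    foot <- cand$length_nt + ifelse(grepl("^incomplete", cand$stop_kind),
                                    0L, 3L)
    ov <- vapply(seq_len(nrow(cand)), function(k)
      .circular_overlap(cand$start[k], foot[k], w_start, w_len, L),
      numeric(1))
    cand <- cand[ov > 0L, , drop = FALSE]
    if (nrow(cand) == 0L) return(absent)
    best <- NULL
    for (k in seq_len(nrow(cand))) {
      sw <- smith_waterman(p$peptide, cand$peptide[k], matrix = matrix,
                           gap_open = gap_open, gap_extend = gap_extend)
      if (sw$score <= 0) next
      cov <- (sw$query_span[2L] - sw$query_span[1L] + 1L) / nchar(p$peptide)
      if (sw$identity < min_identity || cov < min_coverage) next
      if (is.null(best) || sw$score > best$score) {
        best <- list(k = k, score = sw$score, identity = sw$identity,
                     coverage = cov)
      }
    }
    if (is.null(best)) return(absent)
    o <- cand[best$k, ]
    data.frame(name = p$name, present = TRUE, orf_start = o$start,
               orf_end = o$end, strand = o$strand, length_nt = o$length_nt,
               score = best$score, identity = best$identity,
               coverage = best$coverage, peptide = o$peptide,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Call the Rudel antisense ORF of the mt-Atp8/mt-Atp6 locus
#'
#' Rudel ("Russian doll of electron carrier and energy transducer ATPase
#' genes") is defined positionally, not by homology: the longest antisense
#' ORF across the combined mt-Atp8/mt-Atp6 locus. Returns `NULL` (absent)
#' when no antisense ORF meets `min_len_nt`.
#'
#' @param genome A [circular_genome()].
#' @param features A [gene_features()] data frame containing the mt-Atp8
#'   and mt-Atp6 CDS features (a missing locus is an error).
#' @param min_len_nt Minimum ORF coding length (nt).
#' @param overlap_fraction Minimum fraction of the ORF inside the locus.
#' @return A one-row `data.frame` (`name`, `start`, `end`, `strand`,
#'   `length_nt`, `peptide`, `host_gene`) or `NULL` when absent.
#' @export
call_rudel <- function(genome, features, min_len_nt = 60L,
                       overlap_fraction = 0.5) {
  key <- .norm_gene(features$name)
  locus <- features[key %in% c("atp8", "atp6") & features$kind == "CDS", ,
                    drop = FALSE]
  if (nrow(locus) < 2L) {
    stop("mt-Atp8/mt-Atp6 locus not found in the feature table",
         call. = FALSE)
  }
  hits <- find_antisense_orfs(genome, locus, min_len_nt = min_len_nt,
                              overlap_fraction = overlap_fraction)
  if (nrow(hits) == 0L) return(NULL)
  top <- hits[1L, ]  # sorted by decreasing length
  data.frame(name = "Rudel", start = top$start, end = top$end,
             strand = top$strand, length_nt = top$length_nt,
             peptide = top$peptide, host_gene = top$host_gene,
             stringsAsFactors = FALSE)
}
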