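#' Generate a circular genome with planted annotation truth
#'
#' Builds a seeded random circular genome and plants, without mutual
#' corruption: CDS features (random peptides, exact start/stop codons, an
#' adjacent upstream in-frame stop so ORF scanning recovers them exactly),
#' nested ORFs at caller-chosen coordinates (antisense or frameshifted,
#' free peptide), and MDP homologs (a reference peptide mutated to a target
#' identity, planted at an anchor feature). Host reading frames overlapping
#' a nested planting are constrained to stay stop-free. Regenerating with
#' the same seed is byte-identical.
#'
#' @param length_nt Genome length.
#' @param features A `data.frame` with columns `name`, `kind`, `start`,
#'   `length_nt` (genomic footprint; for CDS this includes the stop codon
#'   and must be divisible by 3), `strand`.
#' @param nested Optional `data.frame` with columns `name`, `g0` (0-based
#'   genome start of the ORF footprint), `n_aa` (peptide length including
#'   the initiator Met), `strand`.
#' @param homologs Optional `data.frame` with columns `name`, `peptide`
#'   (reference peptide), `anchor` (feature name), `strand_rule` (`"sense"`
#'   or `"antisense"` relative to the anchor), `identity` (target
#'   fractional identity in (0, 1]), `offset_nt` (offset of the ORF
#'   footprint from the anchor start).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param clean_min_len If non-`NULL`, iteratively remove every unplanted
#'   ORF of coding length >= `clean_min_len` (by start-codon knock-out,
#'   re-solving planted regions where necessary) so that [scan_orfs()] at
#'   this threshold returns exactly the planted truth.
#' @param rotate Rotate the finished genome by this many nucleotides
#'   (features and truth are shifted accordingly).
#' @param accession Accession string for the genome (marked synthetic).
#' @param max_tries Number of full regeneration attempts before giving up.
#' @return A list with `genome` (a [circular_genome()]), `features` (a
#'   [gene_features()] data frame) and `truth` (a `data.frame` of planted
#'   ORFs: `name`, `kind`, `start`, `end`, `strand`, `length_nt`,
#'   `peptide`, `anchor`, `target_identity`, `realized_identity`).
#' @export
make_genome <- function(length_nt, features, nested = NULL, homologs = NULL,
                        seed = 1L, clean_min_len = NULL, rotate = 0L,
                        accession = "synthetic-mito", max_tries = 25L) {
  stopifnot(length_nt >= 100L, nrow(features) >= 1L)
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (any(cds$length_nt %% 3L != 0L)) {
    stop("CDS footprint lengths must be divisible by 3", call. = FALSE)
  }
  .with_seed(seed, function() {
    for (try in seq_len(max_tries)) {
      res <- .make_genome_once(length_nt, features, nested, homologs,
                               clean_min_len)
      if (!is.null(res)) {
        if (rotate %% length_nt != 0L) {
          res$genome <- rotate_genome(res$genome, rotate)
          res$features <- rotate_features(res$features, rotate, length_nt)
          res$truth <- .rotate_truth(res$truth, rotate, length_nt)
        }
        res$genome$accession <- accession
        res$seed <- seed
        return(res)
      }
    }
    stop("infeasible planting specification (", max_tries,
         " attempts exhausted)", call. = FALSE)
  })
}

.rotate_truth <- function(truth, k, L) {
  truth$start <- (truth$start - k) %% L
  truth$end <- ((truth$end - 1L - k) %% L) + 1L
  truth
}

.make_genome_once <- function(L, features, nested, homologs, clean_min_len) {
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cons <- list()
  truth <- list()

  # nested free-peptide ORFs
  if (!is.null(nested)) {
    for (i in seq_len(nrow(nested))) {
      nd <- nested[i, ]
      cons <- c(cons, .orf_constraints(nd$g0, nd$n_aa, nd$strand, L))
      truth[[length(truth) + 1L]] <- data.frame(
        name = nd$name, kind = "nested", start = nd$g0 %% L,
        end = ((nd$g0 + 3L * (nd$n_aa + 1L) - 1L) %% L) + 1L,
        strand = nd$strand, length_nt = 3L * nd$n_aa,
        anchor = NA_character_, target_identity = NA_real_,
        stringsAsFactors = FALSE)
    }
  }

  # homologs of reference peptides at anchor features
  planted_peps <- character(0)
  if (!is.null(homologs)) {
    for (i in seq_len(nrow(homologs))) {
      h <- homologs[i, ]
      a <- features[features$name == h$anchor, , drop = FALSE]
      if (nrow(a) != 1L) stop("homolog anchor not found: ", h$anchor,
                              call. = FALSE)
      strand <- if (h$strand_rule == "sense") a$strand[1L] else
        if (a$strand[1L] == "+") "-" else "+"
      mut <- .mutate_peptide(h$peptide, h$identity)
      g0 <- (a$start[1L] + h$offset_nt) %% L
      n_aa <- nchar(mut)
      cons <- c(cons, .orf_constraints(g0, n_aa, strand, L, peptide = mut))
      planted_peps[h$name] <- mut
      truth[[length(truth) + 1L]] <- data.frame(
        name = h$name, kind = "homolog", start = g0,
        end = ((g0 + 3L * (n_aa + 1L) - 1L) %% L) + 1L, strand = strand,
        length_nt = 3L * n_aa, anchor = h$anchor,
        target_identity = h$identity, stringsAsFactors = FALSE)
    }
  }
  free_pos <- unique(unlist(lapply(cons, `[[`, "pos")))

  # host CDS features: exact random peptides outside planted windows
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (f$kind != "CDS") next
    n_aa <- f$length_nt %/% 3L - 1L
    pep <- .random_peptide(n_aa)
    cons <- c(cons, .host_constraints(f$start, n_aa, f$strand, L, pep,
                                      free_pos))
    # adjacent upstream in-frame stop so the scanner recovers the CDS exactly
    up_rel <- if (f$strand == "+") -3L else f$length_nt
    stop_allowed <- if (f$strand == "+") MITO_STOP_CODONS else
      .rc_codons(MITO_STOP_CODONS)
    cons <- c(cons, list(.cc((f$start + up_rel + 0:2) %% L, stop_allowed)))
    truth[[length(truth) + 1L]] <- data.frame(
      name = f$name, kind = "cds", start = f$start %% L,
      end = ((f$start + f$length_nt - 1L) %% L) + 1L, strand = f$strand,
      length_nt = f$length_nt - 3L, anchor = NA_character_,
      target_identity = NA_real_, stringsAsFactors = FALSE)
  }

  chars <- .solve_constraints(chars, cons)
  if (is.null(chars)) return(NULL)
  truth <- do.call(rbind, truth)

  if (!is.null(clean_min_len)) {
    chars <- .clean_background(chars, cons, truth, L, clean_min_len)
    if (is.null(chars)) return(NULL)
  }

  genome <- circular_genome(paste(chars, collapse = ""))
  truth$peptide <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    s <- extract_sequence(genome, tr$start, tr$end, tr$strand)
    translate_mito(substr(s, 1L, tr$length_nt))
  }, "")
  truth$realized_identity <- NA_real_
  if (!is.null(homologs)) {
    for (i in which(truth$kind == "homolog")) {
      ref <- homologs$peptide[match(truth$name[i], homologs$name)]
      got <- truth$peptide[i]
      if (nchar(ref) != nchar(got)) return(NULL)
      # global positional identity: the planting is full-length by design
      id <- 100 * mean(strsplit(ref, "")[[1L]] == strsplit(got, "")[[1L]])
      truth$realized_identity[i] <- id
      if (abs(id / 100 - truth$target_identity[i]) > 0.03) {
        return(NULL)  # realized identity off target: retry
      }
    }
  }
  feats <- features
  feats$end <- ((feats$start + feats$length_nt - 1L) %% L) + 1L
  feats <- gene_features(feats$name, feats$kind, feats$start %% L, feats$end,
                         feats$strand)
  list(genome = genome, features = feats, truth = truth)
}

# iteratively remove unplanted ORFs >= min_len: background start codons are
# knocked out directly; start codons inside planted regions are excluded by
# adding an anti-start constraint and re-solving
.clean_background <- function(chars, cons, truth, L, min_len) {
  constrained <- unique(unlist(lapply(cons, `[[`, "pos")))
  all64 <- names(MITO_GENETIC_CODE)
  truth_key <- paste(truth$start, truth$strand, truth$length_nt)
  for (round in seq_len(40L)) {
    g <- circular_genome(paste(chars, collapse = ""))
    orfs <- scan_orfs(g, min_len_nt = max(min_len, 12L))
    key <- paste(orfs$start, orfs$strand, orfs$length_nt)
    offend <- orfs[!(key %in% truth_key), , drop = FALSE]
    if (nrow(offend) == 0L) return(chars)
    dirty <- FALSE
    for (i in seq_len(nrow(offend))) {
      o <- offend[i, ]
      foot <- o$length_nt + 3L
      sc <- if (o$strand == "+") (o$start + 0:2) %% L else
        (o$start + foot - 3L + 0:2) %% L
      if (!any(sc %in% constrained)) {
        chars[sc[2L] + 1L] <- "C"  # no start codon has a C in position 2
      } else {
        banned <- if (o$strand == "+") MITO_START_CODONS else
          .rc_codons(MITO_START_CODONS)
        cons <- c(cons, list(.cc(sc, setdiff(all64, banned))))
        constrained <- unique(c(constrained, sc))
        dirty <- TRUE
      }
    }
    if (dirty) {
      chars <- .solve_constraints(chars, cons, prefer_current = TRUE)
      if (is.null(chars)) return(NULL)
    }
  }
  NULL
}
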