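# Six-frame ORF enumeration on a circular genome under the vertebrate
# mitochondrial genetic code.
#
# An ORF is defined by a start-codon position p on a strand and the first
# in-frame stop codon reached when reading forward (continuing across the
# origin). Its coding length (length_nt) excludes the stop codon; the
# stored interval (start, end) is the genomic footprint including the stop.
# ORFs whose footprint would exceed the genome length (no stop within one
# full turn) are discarded.

.codon_vector <- function(s) {
  # all overlapping 3-mers of string s, position i = s[i..i+2]
  n <- nchar(s)
  if (n < 3L) return(character(0))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  paste0(ch[1:(n - 2L)], ch[2:(n - 1L)], ch[3:n])
}

#' Scan a circular genome for open reading frames
#'
#' Enumerates, for each requested strand, every maximal ORF that begins at
#' an allowed start codon and ends at the first in-frame stop codon of
#' translation table 2 (`TAA`, `TAG`, `AGA`, `AGG`), reading across the
#' origin. By default only the longest ORF per (strand, stop codon) is
#' reported; `all_starts = TRUE` reports every qualifying start.
#'
#' Optionally, ORFs terminated by an incomplete stop (a trailing `T` or
#' `TA` completed by polyadenylation) are reported when their 3' end
#' coincides exactly with an annotated transcript boundary supplied via
#' `boundaries`.
#'
#' @param genome A [circular_genome()].
#' @param min_len_nt Minimum coding length in nucleotides (excluding the
#'   stop codon); must be >= 12.
#' @param strands Character vector, subset of `c("+", "-")`.
#' @param start_codons Allowed initiation codons (default
#'   `r paste(MITO_START_CODONS, collapse = ", ")`).
#' @param all_starts Report every start per stop instead of the longest.
#' @param allow_incomplete_stop Honour incomplete stops at `boundaries`.
#' @param boundaries Integer vector of 0-based genome coordinates at which
#'   annotated transcripts end (3' boundary on either strand).
#' @return A `data.frame` with one row per ORF: `start`, `end` (0-based
#'   half-open footprint including the stop codon), `strand`, `frame`,
#'   `wraps_origin`, `length_nt`, `start_codon`, `stop_kind`, `peptide`;
#'   sorted by (strand, start).
#' @export
scan_orfs <- function(genome, min_len_nt = 24L, strands = c("+", "-"),
                      start_codons = MITO_START_CODONS, all_starts = FALSE,
                      allow_incomplete_stop = FALSE, boundaries = integer()) {
  stopifnot(inherits(genome, "circular_genome"))
  if (length(strands) == 0L) stop("empty strand set", call. = FALSE)
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' or '-'",
                                           call. = FALSE)
  if (min_len_nt < 12L) stop("min_len_nt must be >= 12", call. = FALSE)
  L <- genome$length
  out <- list()
  for (strand in strands) {
    S <- if (strand == "+") genome$sequence else
      reverse_complement(genome$sequence)
    D <- paste0(S, S)
    cod <- .codon_vector(D)           # cod[p+1] = codon at 0-based p
    is_stop <- cod %in% MITO_STOP_CODONS
    is_start <- cod %in% start_codons
    stop_pos <- which(is_stop) - 1L   # 0-based positions on D
    start_pos <- which(is_start[seq_len(L)]) - 1L
    if (length(start_pos)) {
      # first in-frame stop at or after p+3, within one genome turn
      stops_by_class <- split(stop_pos, stop_pos %% 3L)
      rows <- lapply(start_pos, function(p) {
        cls <- as.character(p %% 3L)
        sp <- stops_by_class[[cls]]
        if (is.null(sp)) return(NULL)
        k <- findInterval(p + 3L - 1L, sp) + 1L  # first sp >= p + 3
        if (k > length(sp)) return(NULL)
        q <- sp[k]
        if (q + 3L - p > L) return(NULL)         # footprint exceeds one turn
        len_nt <- q - p
        if (len_nt < min_len_nt) return(NULL)
        c(p = p, q = q)
      })
      rows <- do.call(rbind, rows)
      if (!is.null(rows)) {
        p <- rows[, "p"]; q <- rows[, "q"]
        if (!all_starts) {
          # keep the longest ORF per circular stop position (a wrapping
          # start can be longer than a non-wrapping one for the same stop)
          ord <- order(q %% L, -(q - p))
          sel <- ord[!duplicated((q %% L)[ord])]
          p <- p[sel]; q <- q[sel]
        }
        for (i in seq_along(p)) {
          pi <- p[i]; qi <- q[i]
          len_nt <- qi - pi
          foot <- len_nt + 3L
          pep <- translate_mito(substr(D, pi + 1L, qi))
          out[[length(out) + 1L]] <- data.frame(
            start = .strand_to_genome(pi, foot, strand, L)["start"],
            end = .strand_to_genome(pi, foot, strand, L)["end"],
            strand = strand, frame = pi %% 3L,
            wraps_origin = pi + foot > L, length_nt = len_nt,
            start_codon = substr(D, pi + 1L, pi + 3L),
            stop_kind = substr(D, qi + 1L, qi + 3L), peptide = pep,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (allow_incomplete_stop && length(boundaries)) {
      out <- c(out, .incomplete_stop_orfs(D, L, strand, boundaries,
                                          start_codons, min_len_nt,
                                          stop_pos))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    start = integer(), end = integer(), strand = character(),
    frame = integer(), wraps_origin = logical(), length_nt = integer(),
    start_codon = character(), stop_kind = character(), peptide = character(),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$strand, res$start), , drop = FALSE]
}

# map a strand-coordinate footprint [p, p + foot) to genome coordinates
.strand_to_genome <- function(p, foot, strand, L) {
  if (strand == "+") {
    start <- p
    end <- ((p + foot - 1L) %% L) + 1L
  } else {
    start <- (L - p - foot) %% L
    end <- ((L - p - 1L) %% L) + 1L
  }
  c(start = start, end = end)
}

# ORFs ending in an incomplete stop (trailing T or TA) exactly at an
# annotated transcript 3' boundary
.incomplete_stop_orfs <- function(D, L, strand, boundaries, start_codons,
                                  min_len_nt, stop_pos) {
  cod <- NULL
  out <- list()
  for (b in boundaries) {
    # boundary in strand coordinates: position just past the last base
    bs <- if (strand == "+") b %% L else (L - (b %% L)) %% L
    if (bs == 0L) bs <- L
    for (trail in c(1L, 2L)) {
      tail_seq <- substr(D, bs - trail + 1L, bs)
      if (!(tail_seq %in% c("T", "TA"))) next
      # candidate starts in frame with the partial codon
      p_first <- (bs - trail) %% 3L
      cand <- seq.int(p_first, bs - trail - 3L, by = 3L)
      if (!length(cand)) next
      codons <- substring(D, cand + 1L, cand + 3L)
      ok_start <- codons %in% start_codons
      has_stop <- vapply(seq_along(cand), function(i) {
        any(stop_pos >= cand[i] & stop_pos < bs - trail &
              (stop_pos - cand[i]) %% 3L == 0L)
      }, logical(1))
      good <- which(ok_start & !has_stop)
      if (!length(good)) next
      p <- cand[good[1L]]  # longest: earliest start
      len_nt <- bs - p     # includes the trailing partial codon
      if (len_nt < min_len_nt || len_nt > L) next
      coding <- substr(D, p + 1L, bs - trail)
      g <- .strand_to_genome(p, len_nt, strand, L)
      out[[length(out) + 1L]] <- data.frame(
        start = g["start"], end = g["end"], strand = strand,
        frame = p %% 3L, wraps_origin = p + len_nt > L, length_nt = len_nt,
        start_codon = substr(D, p + 1L, p + 3L),
        stop_kind = if (trail == 1L) "incomplete_T" else "incomplete_TA",
        peptide = translate_mito(coding), stringsAsFactors = FALSE)
    }
  }
  out
}

# circular overlap (nt) between two 0-based half-open arcs given by
# (start, len) on a genome of length L
.circular_overlap <- function(s1, len1, s2, len2, L) {
  # unroll arc 1 at s1; consider arc 2 at its two possible unrolled offsets
  ov <- 0L
  for (off in c(s2, s2 - L, s2 + L)) {
    lo <- max(s1, off)
    hi <- min(s1 + len1, off + len2)
    ov <- max(ov, hi - lo)
  }
  ov
}

#' Find antisense ORFs nested in a gene locus
#'
#' Scans the strand opposite to `feature` and returns the ORFs whose
#' genomic footprint overlaps the feature interval by at least
#' `overlap_fraction` of the ORF ("Russian doll" nesting report). `feature`
#' may contain several rows (e.g. the adjacent mt-Atp8/mt-Atp6 genes),
#' which are merged into one locus interval.
#'
#' @param genome A [circular_genome()].
#' @param feature One or more rows of a [gene_features()] data frame, all
#'   on the same strand, of kind CDS.
#' @param min_len_nt Minimum ORF coding length (nt).
#' @param overlap_fraction Minimum fraction of the ORF footprint that must
#'   lie within the locus (default 0.5).
#' @param ... Passed to [scan_orfs()].
#' @return The [scan_orfs()] data frame restricted to qualifying ORFs, with
#'   extra columns `host_gene` and `overlap_nt`, sorted by decreasing
#'   `length_nt`.
#' @export
find_antisense_orfs <- function(genome, feature, min_len_nt = 24L,
                                overlap_fraction = 0.5, ...) {
  stopifnot(nrow(feature) >= 1L)
  if (!all(feature$kind == "CDS")) stop("feature must be of kind CDS",
                                        call. = FALSE)
  if (length(unique(feature$strand)) != 1L) {
    stop("locus features must share a strand", call. = FALSE)
  }
  L <- genome$length
  anti <- if (feature$strand[1L] == "+") "-" else "+"
  # merged locus arc: from the earliest start, spanning to the farthest end
  ls <- min(feature$start)
  lens <- interval_length(feature$start, feature$end, L)
  le <- max(feature$start + lens - ls) # relative extent
  orfs <- scan_orfs(genome, min_len_nt = min_len_nt, strands = anti, ...)
  if (nrow(orfs) == 0L) {
    orfs$host_gene <- character(0); orfs$overlap_nt <- integer(0)
    return(orfs)
  }
  foot <- orfs$length_nt + ifelse(grepl("^incomplete", orfs$stop_kind), 0L, 3L)
  ov <- vapply(seq_len(nrow(orfs)), function(i) {
    .circular_overlap(orfs$start[i], foot[i], ls, le, L)
  }, numeric(1))
  keep <- ov / foot >= overlap_fraction
  res <- orfs[keep, , drop = FALSE]
  res$host_gene <- rep(paste(feature$name, collapse = "/"), nrow(res))
  res$overlap_nt <- as.integer(ov[keep])
  res[order(-res$length_nt), , drop = FALSE]
}

#' Write ORF candidates as a BED file
#'
#' 0-based half-open BED6; origin-wrapping ORFs are split into two lines.
#' The name field carries the peptide length.
#'
#' @param orfs A [scan_orfs()] data frame.
#' @param genome_length Genome length (nt) for splitting wrapped ORFs.
#' @param path Output path.
#' @param chrom Chromosome/sequence name used in column 1.
#' @return `path`, invisibly.
#' @export
write_orf_bed <- function(orfs, genome_length, path, chrom = "mito") {
  lines <- character(0)
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    name <- sprintf("orf_pep%d", nchar(o$peptide))
    segs <- if (o$wraps_origin) {
      list(c(o$start, genome_length), c(0L, o$end))
    } else list(c(o$start, o$end))
    for (s in segs) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t0\t%s",
                                chrom, s[1L], s[2L], name, o$strand))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
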