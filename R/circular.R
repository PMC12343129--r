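#' Circular genome container
#'
#' Constructs a `circular_genome`: a mitochondrial sequence with circular
#' topology and an accession identifier. All internal coordinates in the
#' package are 0-based half-open and interpreted modulo the genome length.
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}`; stored uppercased.
#' @param accession Text identifier (e.g. a RefSeq accession).
#' @return An object of class `circular_genome` with fields `accession`,
#'   `sequence`, `length` and `topology` (always `"circular"`).
#' @export
circular_genome <- function(sequence, accession = "unnamed") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("genome sequence is empty", call. = FALSE)
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  structure(
    list(accession = accession, sequence = sequence, length = n,
         topology = "circular"),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("<circular_genome> ", x$accession, ": ", x$length, " nt (circular)\n",
      sep = "")
  invisible(x)
}

#' Gene feature table constructor
#'
#' Builds the feature `data.frame` used throughout the package: one row per
#' annotated feature with 0-based half-open coordinates. Features whose
#' interval crosses the origin carry `wraps_origin = TRUE` and have
#' `end < start`; their length is `(end - start) mod genome length`.
#'
#' @param name Gene symbols (e.g. `"mt-Atp6"`).
#' @param kind One of `"CDS"`, `"rRNA"`, `"tRNA"`, `"D-loop"`, `"other"`.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param wraps_origin Logical; default `end <= start`.
#' @return A `data.frame` with columns `name`, `kind`, `start`, `end`,
#'   `strand`, `wraps_origin`.
#' @export
gene_features <- function(name, kind, start, end, strand,
                          wraps_origin = end <= start) {
  kind <- match.arg(kind, c("CDS", "rRNA", "tRNA", "D-loop", "other"),
                    several.ok = TRUE)
  stopifnot(all(strand %in% c("+", "-")), all(start >= 0))
  data.frame(name = as.character(name), kind = kind,
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand),
             wraps_origin = as.logical(wraps_origin),
             stringsAsFactors = FALSE)
}

#' Length of a circular interval
#'
#' @param start,end 0-based half-open coordinates, interpreted modulo `len`.
#' @param len Genome length.
#' @return `(end - start) mod len` (an empty interval is disallowed upstream).
#' @export
interval_length <- function(start, end, len) {
  ((end - start) %% len)
}

#' Extract a (possibly origin-spanning) subsequence from a circular genome
#'
#' Returns the sense-strand subsequence for strand `"+"`, and its reverse
#' complement for `"-"`. Intervals with `end <= start` (after reduction
#' modulo the genome length) are interpreted as crossing the origin and are
#' concatenated across the junction.
#'
#' @param genome A [circular_genome()].
#' @param start,end 0-based half-open coordinates modulo the genome length.
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string of length `(end - start) mod length`.
#' @examples
#' g <- circular_genome("ACGTACGT")
#' extract_sequence(g, 6, 2, "+") # "GTAC"
#' @export
extract_sequence <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "circular_genome"), strand %in% c("+", "-"))
  L <- genome$length
  start <- start %% L
  end <- ((end - 1L) %% L) + 1L  # end in (0, L]
  if (end == start) {
    stop("empty interval: start == end (mod genome length)", call. = FALSE)
  }
  s <- if (end > start) {
    substr(genome$sequence, start + 1L, end)
  } else {
    paste0(substr(genome$sequence, start + 1L, L),
           substr(genome$sequence, 1L, end))
  }
  if (strand == "-") reverse_complement(s) else s
}

#' Rotate a circular genome and its features
#'
#' Moves the origin by `k` nucleotides: position `p` in the input becomes
#' `(p - k) mod length` in the output. Used for rotation-equivariance
#' checks; extracting any shifted feature from the rotated genome yields
#' the identical sequence.
#'
#' @param genome A [circular_genome()].
#' @param k Rotation offset in nucleotides.
#' @return The rotated `circular_genome`.
#' @export
rotate_genome <- function(genome, k) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  k <- k %% L
  if (k == 0L) return(genome)
  s <- paste0(substr(genome$sequence, k + 1L, L), substr(genome$sequence, 1L, k))
  circular_genome(s, accession = genome$accession)
}

#' @rdname rotate_genome
#' @param features A feature `data.frame` (see [gene_features()]).
#' @param len Genome length.
#' @export
rotate_features <- function(features, k, len) {
  k <- k %% len
  f <- features
  f$start <- (f$start - k) %% len
  f$end <- ((f$end - 1L - k) %% len) + 1L
  f$wraps_origin <- f$end <= f$start
  f
}
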