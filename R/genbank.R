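# GenBank flat-file input/output.
#
# No installed R package parses GenBank feature tables, so a minimal parser
# for single-record flat files is implemented here: LOCUS line, FEATURES
# table (location strings with complement()/join(), /gene and /product
# qualifiers) and the ORIGIN sequence block. Feature names key on /gene
# with /product as fallback.

.gb_feature_kinds <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                       `D-loop` = "D-loop")

# parse a GenBank location string into (start0, end, strand, wraps)
# handles: "a..b", "complement(a..b)", "join(a..b,c..d)" spanning the origin,
# and partial markers '<' / '>'
.parse_gb_location <- function(loc, genome_len) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  while (grepl("^complement\\(", loc)) {
    strand <- if (strand == "+") "-" else "+"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    rng <- lapply(parts, function(p) {
      m <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
      if (length(m) == 1L) m <- c(m, m)
      m
    })
    # origin-spanning join: last segment must continue at base 1
    if (length(rng) == 2L && rng[[2L]][1L] == 1L &&
        rng[[1L]][2L] == genome_len) {
      return(list(start = rng[[1L]][1L] - 1L, end = rng[[2L]][2L],
                  strand = strand, wraps = TRUE))
    }
    stop("unsupported join() location (only origin-spanning joins are handled): ",
         loc, call. = FALSE)
  }
  m <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
  if (length(m) == 1L) m <- c(m, m)
  if (anyNA(m)) stop("cannot parse GenBank location: ", loc, call. = FALSE)
  list(start = m[1L] - 1L, end = m[2L], strand = strand, wraps = FALSE)
}

#' Read a single-record GenBank flat file
#'
#' Parses the LOCUS line, feature table and ORIGIN sequence of a GenBank
#' flat file describing one circular mitochondrial genome. Coordinates are
#' converted from GenBank 1-based inclusive to the package's 0-based
#' half-open convention; `join()` locations spanning the origin are flagged
#' `wraps_origin`. Feature kinds other than CDS/rRNA/tRNA/D-loop are
#' retained as `kind = "other"` with a warning. Features are named from the
#' `/gene` qualifier, falling back to `/product`.
#'
#' @param path Path to a GenBank flat file with exactly one record.
#' @return A list with elements `genome` (a [circular_genome()]) and
#'   `features` (a [gene_features()] data frame).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0L) stop("not a GenBank flat file (no LOCUS line): ",
                                    path, call. = FALSE)
  if (length(locus_idx) > 1L) {
    stop("multi-record GenBank files are unsupported (", length(locus_idx),
         " LOCUS lines found)", call. = FALSE)
  }
  accession <- {
    acc_line <- grep("^(VERSION|ACCESSION)", lines, value = TRUE)
    if (length(acc_line)) strsplit(trimws(sub("^\\S+", "", acc_line[1L])),
                                   "\\s+")[[1L]][1L]
    else strsplit(lines[locus_idx], "\\s+")[[1L]][2L]
  }

  origin_idx <- grep("^ORIGIN", lines)
  if (length(origin_idx) == 0L) {
    stop("GenBank record has no ORIGIN sequence block", call. = FALSE)
  }
  end_idx <- grep("^//", lines)
  end_idx <- if (length(end_idx)) end_idx[1L] else length(lines) + 1L
  seq_lines <- lines[(origin_idx[1L] + 1L):(end_idx - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank record has an empty sequence",
                                  call. = FALSE)
  genome <- circular_genome(sequence, accession = accession)

  feat_idx <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_idx)) {
    block <- lines[(feat_idx[1L] + 1L):(origin_idx[1L] - 1L)]
    # feature headers start in column 6; qualifier/continuation lines at 22
    is_header <- grepl("^\\s{5}\\S", block)
    header_at <- which(is_header)
    for (i in seq_along(header_at)) {
      from <- header_at[i]
      to <- if (i < length(header_at)) header_at[i + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^\\s+(\\S+).*$", "\\1", chunk[1L])
      if (key == "source") next
      # location may continue over lines until the first qualifier ('/')
      qual_start <- grep("^\\s+/", chunk)
      loc_end <- if (length(qual_start)) qual_start[1L] - 1L else length(chunk)
      loc <- paste(trimws(sub("^\\s+\\S+\\s*", "", chunk[1L])),
                   if (loc_end >= 2L)
                     paste(trimws(chunk[2:loc_end]), collapse = "") else "",
                   sep = "")
      quals <- trimws(chunk[grepl("^\\s+/", chunk)])
      getq <- function(q) {
        hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^"|"$', "", sub(paste0("^/", q, "="), "", hit[1L]))
      }
      pos <- .parse_gb_location(loc, genome$length)
      kind <- .gb_feature_kinds[key]
      if (is.na(kind)) {
        warning("unknown GenBank feature kind '", key,
                "' retained as kind = 'other'", call. = FALSE)
        kind <- "other"
      }
      name <- getq("gene")
      if (is.na(name)) name <- getq("product")
      if (is.na(name)) name <- paste0(key, "_", length(feats) + 1L)
      feats[[length(feats) + 1L]] <- data.frame(
        name = name, kind = unname(kind), start = pos$start, end = pos$end,
        strand = pos$strand, wraps_origin = pos$wraps,
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    gene_features(character(), character(), integer(), integer(), character())
  list(genome = genome, features = features)
}

#' Write a circular genome and feature table as a GenBank flat file
#'
#' Emits a minimal single-record GenBank flat file (LOCUS, FEATURES with
#' `/gene` qualifiers, ORIGIN) that [read_genbank()] round-trips exactly.
#' Origin-spanning features are written as `join(a..length,1..b)`.
#'
#' @param genome A [circular_genome()].
#' @param features A [gene_features()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, features, path) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular     %s",
                     genome$accession, L, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("ACCESSION   %s", genome$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  kind_to_key <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                   `D-loop` = "D-loop", other = "misc_feature")
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    loc <- if (f$wraps_origin) {
      sprintf("join(%d..%d,1..%d)", f$start + 1L, L, f$end)
    } else {
      sprintf("%d..%d", f$start + 1L, f$end)
    }
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- kind_to_key[[f$kind]]
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  for (off in seq.int(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
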