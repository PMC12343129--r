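# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# the bundled synthetic squirrel-like reference (expensive: cache)
fixture_reference <- function() {
  cached("reference", function() synthetic_reference(seed = 1L))
}

# a small planted genome: 3 CDS + 1 antisense nested ORF + 1 homolog,
# background cleaned so that scanning at 150 nt returns exactly the truth
fixture_small_planted <- function() {
  cached("small_planted", function() {
    feats <- data.frame(
      name = c("geneA", "geneB", "geneC"), kind = "CDS",
      start = c(100L, 600L, 1200L), length_nt = c(300L, 360L, 450L),
      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
    nested <- data.frame(name = "asorf", g0 = 650L, n_aa = 80L,
                         strand = "-", stringsAsFactors = FALSE)
    hom <- data.frame(name = "homX",
                      peptide = "MAPRGFSCLLLLTSEIDLPVKRRA",
                      anchor = "geneC", strand_rule = "antisense",
                      identity = 0.85, offset_nt = 60L,
                      stringsAsFactors = FALSE)
    make_genome(2000L, feats, nested = nested, homologs = hom, seed = 1L,
                clean_min_len = 150L)
  })
}

# independent brute-force six-frame ORF oracle: for every start-codon
# position on each strand, walk codons (rotating across the origin via a
# doubled string) to the first in-frame stop; keep the longest ORF per
# (strand, stop); implemented position-by-position with substr, unlike
# the vectorized scanner
oracle_scan_orfs <- function(genome, min_len_nt,
                             start_codons = MITO_START_CODONS) {
  L <- genome$length
  stops <- c("TAA", "TAG", "AGA", "AGG")
  out <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") genome$sequence else
      reverse_complement(genome$sequence)
    D <- paste0(S, S)
    by_stop <- list()
    for (p in 0:(L - 1L)) {
      if (!(substr(D, p + 1L, p + 3L) %in% start_codons)) next
      q <- p + 3L
      repeat {
        if (q + 3L - p > L) { q <- NA_integer_; break }
        if (substr(D, q + 1L, q + 3L) %in% stops) break
        q <- q + 3L
      }
      if (is.na(q)) next
      if (q - p < min_len_nt) next
      key <- as.character(q %% L)
      if (is.null(by_stop[[key]]) || (q - p) > by_stop[[key]]$len) {
        by_stop[[key]] <- list(p = p, q = q, len = q - p)
      }
    }
    for (o in by_stop) {
      foot <- o$len + 3L
      gs <- if (strand == "+") o$p else (L - o$p - foot) %% L
      ge <- if (strand == "+") ((o$p + foot - 1L) %% L) + 1L else
        ((L - o$p - 1L) %% L) + 1L
      out[[length(out) + 1L]] <- data.frame(
        start = gs, end = ge, strand = strand, length_nt = o$len,
        peptide = translate_mito(substr(D, o$p + 1L, o$q)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length_nt = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  res[order(res$strand, res$start), , drop = FALSE]
}

random_genome <- function(len) {
  circular_genome(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""))
}

random_peptide_str <- function(n) {
  aa <- setdiff(unique(unname(MITO_GENETIC_CODE)), "*")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
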