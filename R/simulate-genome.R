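# Synthetic circular genomes with planted annotation truth.
#
# Planting works on a nucleotide-level constraint system: every planted ORF
# (a CDS, a nested antisense or frameshifted ORF, or an MDP homolog)
# contributes codon constraints - triples of genome positions with a set of
# allowed genome-orientation 3-mers (synonymous codons of a target amino
# acid, "any non-stop codon", a start-codon set, or a stop-codon set).
# Overlapping constraints (e.g. a host gene's reading frame and an
# antisense ORF inside it) are merged into regions and solved jointly by a
# seeded depth-first search over nucleotides, so planted reading frames
# never corrupt each other. Background positions are uniform random draws.

.NONSTOP_CODONS <- names(MITO_GENETIC_CODE)[MITO_GENETIC_CODE != "*"]

.rc_codons <- function(x) vapply(x, reverse_complement, "", USE.NAMES = FALSE)

# one codon constraint: genome positions (0-based, mod L) and allowed
# genome-orientation triples
.cc <- function(pos3, allowed) list(pos = pos3, allowed = allowed)

# constraints for an ORF with genome footprint [g0, g0 + 3*(n_aa + 1)),
# including its stop codon and an adjacent upstream in-frame stop.
# peptide = NULL plants a free ORF (any non-stop internal codons).
.orf_constraints <- function(g0, n_aa, strand, L, peptide = NULL,
                             start_set = "ATG") {
  foot <- 3L * (n_aa + 1L)
  cons <- list()
  allowed_at <- function(i) {  # i = amino-acid index 1..n_aa, or "stop"
    if (identical(i, "stop")) return(MITO_STOP_CODONS)
    if (i == 1L) return(start_set)
    if (is.null(peptide)) return(.NONSTOP_CODONS)
    .mito_synonyms[[substr(peptide, i, i)]]
  }
  for (i in seq_len(n_aa)) {
    rel <- if (strand == "+") 3L * (i - 1L) else foot - 3L * i
    allowed <- allowed_at(i)
    if (strand == "-") allowed <- .rc_codons(allowed)
    cons[[length(cons) + 1L]] <- .cc((g0 + rel + 0:2) %% L, allowed)
  }
  stop_rel <- if (strand == "+") 3L * n_aa else 0L
  stop_allowed <- if (strand == "+") MITO_STOP_CODONS else
    .rc_codons(MITO_STOP_CODONS)
  cons[[length(cons) + 1L]] <- .cc((g0 + stop_rel + 0:2) %% L, stop_allowed)
  up_rel <- if (strand == "+") -3L else foot
  cons[[length(cons) + 1L]] <- .cc((g0 + up_rel + 0:2) %% L, stop_allowed)
  cons
}

# reading-frame constraints for a host CDS whose codons must stay intact:
# exact synonymous codons of `peptide` outside `free_pos` (positions owned
# by a nested planting, where the host is only required to be non-stop),
# an exact start codon, and a stop codon at the end.
.host_constraints <- function(g0, n_aa, strand, L, peptide, free_pos) {
  foot <- 3L * (n_aa + 1L)
  cons <- list()
  for (i in seq_len(n_aa)) {
    rel <- if (strand == "+") 3L * (i - 1L) else foot - 3L * i
    pos <- (g0 + rel + 0:2) %% L
    inside <- any(pos %in% free_pos)
    allowed <- if (i == 1L) "ATG"
      else if (inside) .NONSTOP_CODONS
      else .mito_synonyms[[substr(peptide, i, i)]]
    if (strand == "-") allowed <- .rc_codons(allowed)
    cons[[length(cons) + 1L]] <- .cc(pos, allowed)
  }
  stop_rel <- if (strand == "+") 3L * n_aa else 0L
  stop_allowed <- if (strand == "+") MITO_STOP_CODONS else
    .rc_codons(MITO_STOP_CODONS)
  cons[[length(cons) + 1L]] <- .cc((g0 + stop_rel + 0:2) %% L, stop_allowed)
  cons
}

# merge codon constraints into connected regions (shared positions) and
# solve each region by seeded DFS over nucleotides; writes into chars.
# Returns the modified chars, or NULL if any region is infeasible.
.solve_constraints <- function(chars, cons, max_steps = 5e5,
                               prefer_current = FALSE) {
  if (!length(cons)) return(chars)
  # union-find over constraint indices via shared positions
  pos_owner <- new.env(hash = TRUE)
  parent <- seq_along(cons)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(cons)) {
    for (p in cons[[i]]$pos) {
      key <- as.character(p)
      j <- pos_owner[[key]]
      if (is.null(j)) pos_owner[[key]] <- i
      else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(cons), find, integer(1))
  for (r in unique(roots)) {
    idx <- which(roots == r)
    region <- cons[idx]
    sol <- .solve_region(region, max_steps,
                         current = if (prefer_current) chars else NULL)
    if (is.null(sol)) return(NULL)
    chars[sol$pos + 1L] <- sol$nt
  }
  chars
}

.solve_region <- function(region, max_steps = 5e5, current = NULL) {
  pos <- sort(unique(unlist(lapply(region, `[[`, "pos"))))
  n <- length(pos)
  idx_of <- new.env(hash = TRUE)
  for (i in seq_len(n)) idx_of[[as.character(pos[i])]] <- i
  tri_idx <- lapply(region, function(cc)
    vapply(as.character(cc$pos), function(k) idx_of[[k]], integer(1)))
  complete_at <- vapply(tri_idx, max, integer(1))
  by_complete <- split(seq_along(region), complete_at)
  nts <- c("A", "C", "G", "T")
  choice_order <- function(i) {
    # prefer the current assignment (minimal-change repair), then shuffle
    if (is.null(current)) return(sample(nts))
    cur <- current[pos[i] + 1L]
    c(cur, sample(setdiff(nts, cur)))
  }
  val <- character(n)
  opts <- vector("list", n)
  ptr <- integer(n)
  i <- 1L
  opts[[1L]] <- choice_order(1L)
  steps <- 0L
  while (i >= 1L && i <= n) {
    steps <- steps + 1L
    if (steps > max_steps) return(NULL)
    ptr[i] <- ptr[i] + 1L
    if (ptr[i] > 4L) { ptr[i] <- 0L; i <- i - 1L; next }
    val[i] <- opts[[i]][ptr[i]]
    ok <- TRUE
    for (k in by_complete[[as.character(i)]]) {
      tri <- paste(val[tri_idx[[k]]], collapse = "")
      if (!(tri %in% region[[k]]$allowed)) { ok <- FALSE; break }
    }
    if (ok) {
      i <- i + 1L
      if (i <= n) { opts[[i]] <- choice_order(i); ptr[i] <- 0L }
    }
  }
  if (i == 0L) return(NULL)
  list(pos = pos, nt = val)
}

# run body with a deterministic RNG state, restoring the caller's state
.with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(body())
}

.random_peptide <- function(n_aa) {
  aa20 <- setdiff(unique(unname(MITO_GENETIC_CODE)), "*")
  paste(c("M", sample(aa20, n_aa - 1L, replace = TRUE)), collapse = "")
}

# substitute positions of a peptide to reach a target fractional identity;
# position 1 (the initiator Met) is never touched
.mutate_peptide <- function(peptide, identity) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  aa20 <- setdiff(unique(unname(MITO_GENETIC_CODE)), "*")
  n <- length(aa)
  k <- round((1 - identity) * n)
  if (k > 0) {
    at <- sample(2:n, min(k, n - 1L))
    aa[at] <- vapply(aa[at], function(a) sample(setdiff(aa20, a), 1L), "")
  }
  paste(aa, collapse = "")
}
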