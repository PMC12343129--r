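# Local protein alignment with affine gaps, used to match candidate ORF
# peptides against the bundled MDP panel.

#' BLOSUM62 substitution matrix
#'
#' Convenience accessor for the BLOSUM62 matrix shipped with Biostrings.
#'
#' @return Integer substitution matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two peptides under a substitution matrix and
#' affine gap penalties. A gap of length `k` costs
#' `gap_open + k * gap_extend`. The traceback is deterministic, preferring
#' diagonal over up (gap in `target`) over left (gap in `query`). A score
#' of 0 means no positive-scoring local alignment exists and the aligned
#' span is empty.
#'
#' @param query,target Non-empty amino-acid strings.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Non-negative penalties with
#'   `gap_open >= gap_extend`.
#' @return A list: `score`; `query_span` and `target_span` (1-based
#'   inclusive `c(from, to)` of the aligned region, `c(0, -1)` when empty);
#'   `identity` (percent identity over aligned match/mismatch columns);
#'   `aligned_query`, `aligned_target` (gapped alignment strings);
#'   `n_columns` (alignment length).
#' @export
smith_waterman <- function(query, target, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(target)) {
    stop("query and target peptides must be non-empty", call. = FALSE)
  }
  if (!(gap_open >= gap_extend && gap_extend >= 0)) {
    stop("need gap_open >= gap_extend >= 0", call. = FALSE)
  }
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  t <- strsplit(target, "", fixed = TRUE)[[1L]]
  if (!all(q %in% rownames(matrix)) || !all(t %in% rownames(matrix))) {
    stop("peptide contains characters absent from the substitution matrix",
         call. = FALSE)
  }
  n <- length(q); m <- length(t)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)   # best local score ending at (i, j)
  E <- matrix(NEG, n + 1L, m + 1L) # gap in query (move left)
  F_ <- matrix(NEG, n + 1L, m + 1L) # gap in target (move up)
  sub <- matrix[q, t, drop = FALSE]
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - gap_open - gap_extend,
                               E[i + 1L, j] - gap_extend)
      F_[i + 1L, j + 1L] <- max(H[i, j + 1L] - gap_open - gap_extend,
                                F_[i, j + 1L] - gap_extend)
      h <- max(0, H[i, j] + sub[i, j], E[i + 1L, j + 1L], F_[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0) {
    return(list(score = 0, query_span = c(0L, -1L), target_span = c(0L, -1L),
                identity = NA_real_, aligned_query = "", aligned_target = "",
                n_columns = 0L))
  }
  # deterministic traceback: diagonal > up > left
  i <- bi; j <- bj
  aq <- character(0); at <- character(0)
  state <- "H"
  while (i > 0L && j > 0L) {
    h <- H[i + 1L, j + 1L]
    if (state == "H" && h == 0) break
    if (state == "H") {
      if (h == H[i, j] + sub[i, j]) {
        aq <- c(q[i], aq); at <- c(t[j], at); i <- i - 1L; j <- j - 1L
      } else if (h == F_[i + 1L, j + 1L]) {
        state <- "F"
      } else {
        state <- "E"
      }
    } else if (state == "F") {
      aq <- c(q[i], aq); at <- c("-", at)
      from_open <- H[i, j + 1L] - gap_open - gap_extend
      state <- if (F_[i + 1L, j + 1L] == from_open) "H" else "F"
      i <- i - 1L
    } else { # E
      aq <- c("-", aq); at <- c(t[j], at)
      from_open <- H[i + 1L, j] - gap_open - gap_extend
      state <- if (E[i + 1L, j + 1L] == from_open) "H" else "E"
      j <- j - 1L
    }
  }
  qs <- c(i + 1L, bi); ts <- c(j + 1L, bj)
  cols <- aq != "-" & at != "-"
  ident <- 100 * sum(aq == at & cols) / sum(cols)
  list(score = best, query_span = qs, target_span = ts, identity = ident,
       aligned_query = paste(aq, collapse = ""),
       aligned_target = paste(at, collapse = ""),
       n_columns = length(aq))
}
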