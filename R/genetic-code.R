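#' Vertebrate mitochondrial genetic code (NCBI translation table 2)
#'
#' Named character vector mapping each of the 64 codons to a one-letter
#' amino acid, with `*` for stop. Differs from the standard code in four
#' codons: `ATA` = Met, `TGA` = Trp, and `AGA`/`AGG` = stop.
#'
#' @format Named character vector of length 64.
#' @export
MITO_GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' @rdname MITO_GENETIC_CODE
#' @format `MITO_STOP_CODONS`: the four table-2 stop codons (includes
#'   `AGA`/`AGG`, unlike the standard code).
#' @export
MITO_STOP_CODONS <- names(MITO_GENETIC_CODE)[MITO_GENETIC_CODE == "*"]

#' @rdname MITO_GENETIC_CODE
#' @format `MITO_START_CODONS`: the default allowed initiation codons for
#'   mitochondrial ORF scanning (`ATG`, `ATA`, `ATT`, `ATC`, `GTG`).
#' @export
MITO_START_CODONS <- c("ATG", "ATA", "ATT", "ATC", "GTG")

# synonym sets per amino acid under table 2 (stops excluded from every set)
.mito_synonyms <- split(names(MITO_GENETIC_CODE), MITO_GENETIC_CODE)

#' Translate a nucleotide sequence under the vertebrate mitochondrial code
#'
#' Codon-wise translation under NCBI translation table 2. Stop codons
#' (`TAA`, `TAG`, `AGA`, `AGG`) are rendered as `*`; any codon containing a
#' character outside `{A,C,G,T}` (e.g. `N`) translates to `X`.
#'
#' @param seq Nucleotide string; length must be divisible by 3.
#' @return Amino-acid string of length `nchar(seq)/3`.
#' @examples
#' translate_mito("ATGTGAAGA") # "MW*"
#' @export
translate_mito <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, ") is not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(MITO_GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (case preserved).
#' @return The reverse complement as a string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}
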