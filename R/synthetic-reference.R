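# A synthetic stand-in for a sciurid mitochondrial genome, generated
# entirely in code. It reproduces the documented structure of the real
# molecule - 13 protein-coding genes, 2 rRNAs and 22 tRNAs in standard
# mammalian gene order, a control region (D-loop) spanning the origin, a
# planted 663-nt antisense ORF across the adjacent mt-Atp8/mt-Atp6 genes
# (the Rudel locus), and one planted homolog of every homology-mode panel
# entry at its anchor locus - but its sequence is synthetic, not the
# NC_027278.1 sequence.

.SYN_TRNA_LEN <- c(69L, 70L, 72L, 70L, 72L, 69L, 69L, 69L, 73L, 66L, 66L,
                   72L, 68L, 70L, 70L, 69L, 69L, 60L, 71L, 69L, 70L, 69L)

.syn_layout <- function() {
  # (name, kind, length_nt, strand) in standard mammalian mito gene order;
  # CDS lengths include the stop codon
  t_names <- paste0("tRNA-", c("Phe", "Val", "Leu1", "Ile", "Gln", "Met",
                               "Trp", "Ala", "Asn", "Cys", "Tyr", "Ser1",
                               "Asp", "Lys", "Gly", "Arg", "His", "Ser2",
                               "Leu2", "Glu", "Thr", "Pro"))
  t_strand <- c("+", "+", "+", "+", "-", "+", "+", "-", "-", "-", "-", "-",
                "+", "+", "+", "+", "+", "+", "+", "-", "+", "-")
  trna <- data.frame(name = t_names, kind = "tRNA", len = .SYN_TRNA_LEN,
                     strand = t_strand, stringsAsFactors = FALSE)
  tr <- function(i) trna[i, ]
  rbind(
    tr(1),
    data.frame(name = "mt-Rnr1", kind = "rRNA", len = 950L, strand = "+"),
    tr(2),
    data.frame(name = "mt-Rnr2", kind = "rRNA", len = 1560L, strand = "+"),
    tr(3),
    data.frame(name = "mt-Nd1", kind = "CDS", len = 957L, strand = "+"),
    tr(4), tr(5), tr(6),
    data.frame(name = "mt-Nd2", kind = "CDS", len = 1044L, strand = "+"),
    tr(7), tr(8), tr(9), tr(10), tr(11),
    data.frame(name = "mt-Co1", kind = "CDS", len = 1545L, strand = "+"),
    tr(12), tr(13),
    data.frame(name = "mt-Co2", kind = "CDS", len = 684L, strand = "+"),
    tr(14),
    data.frame(name = "mt-Atp8", kind = "CDS", len = 204L, strand = "+"),
    data.frame(name = "mt-Atp6", kind = "CDS", len = 681L, strand = "+"),
    data.frame(name = "mt-Co3", kind = "CDS", len = 783L, strand = "+"),
    tr(15),
    data.frame(name = "mt-Nd3", kind = "CDS", len = 348L, strand = "+"),
    tr(16),
    data.frame(name = "mt-Nd4l", kind = "CDS", len = 297L, strand = "+"),
    data.frame(name = "mt-Nd4", kind = "CDS", len = 1380L, strand = "+"),
    tr(17), tr(18), tr(19),
    data.frame(name = "mt-Nd5", kind = "CDS", len = 1812L, strand = "+"),
    data.frame(name = "mt-Nd6", kind = "CDS", len = 528L, strand = "-"),
    tr(20),
    data.frame(name = "mt-Cyb", kind = "CDS", len = 1140L, strand = "+"),
    tr(21), tr(22))
}

# offsets (nt from the anchor feature start) of the planted panel homologs
.SYN_HOMOLOG_OFFSET <- c("MOTS-c" = 200L, Humanin = 100L, SHLP1 = 300L,
                         SHLP2 = 500L, SHLP3 = 650L, SHLP4 = 850L,
                         SHLP5 = 1000L, SHLP6 = 1150L, SHMOOSE = 500L,
                         MTALTND4 = 301L, Gau = 400L, `CYTB-187AA` = 301L)

.SYN_RUDEL_AA <- 221L          # 663 nt coding length
.SYN_RUDEL_OFFSET <- 150L      # from the mt-Atp8 start, into mt-Atp6

#' Generate the bundled synthetic mitochondrial reference
#'
#' Builds a complete synthetic mitochondrial genome emulating the
#' thirteen-lined ground squirrel molecule's documented structure: 13 CDS,
#' 2 rRNA and 22 tRNA features in standard mammalian gene order with an
#' origin-spanning D-loop; a planted free 663-nt antisense ORF spanning
#' the adjacent mt-Atp8/mt-Atp6 genes (recovered by [call_rudel()]); and a
#' planted homolog of every homology-mode entry of `panel` at its anchor
#' locus and strand, mutated to `identity`. The sequence itself is
#' synthetic (generated, labelled as such in the accession); only the
#' structure follows the real annotation.
#'
#' @param seed Integer seed; output is byte-identical per seed.
#' @param panel An [mdp_panel()] data frame supplying homolog peptides.
#' @param identity Target fractional identity of planted homologs.
#' @param verify Re-scan the finished genome and stop unless every planted
#'   homolog and the Rudel ORF are recovered at their planted coordinates
#'   (retried internally with perturbed sub-seeds first).
#' @return As [make_genome()]: list with `genome`, `features`, `truth`.
#' @export
synthetic_reference <- function(seed = 1L, panel = mdp_panel(),
                                identity = 0.85, verify = TRUE) {
  lay <- .syn_layout()
  gap <- 5L
  starts <- integer(nrow(lay))
  pos <- 550L + gap
  for (i in seq_len(nrow(lay))) {
    starts[i] <- pos
    pos <- pos + lay$len[i] + if (lay$name[i] == "mt-Atp8") 0L else gap
  }
  L <- pos + 450L
  features <- data.frame(name = c(lay$name, "D-loop"),
                         kind = c(lay$kind, "D-loop"),
                         start = c(starts, L - 450L),
                         length_nt = c(lay$len, 1000L),
                         strand = c(lay$strand, "+"),
                         stringsAsFactors = FALSE)
  atp8_start <- starts[lay$name == "mt-Atp8"]
  nested <- data.frame(name = "Rudel", g0 = atp8_start + .SYN_RUDEL_OFFSET,
                       n_aa = .SYN_RUDEL_AA, strand = "-",
                       stringsAsFactors = FALSE)
  hom <- panel[panel$mode == "homology", , drop = FALSE]
  off <- .SYN_HOMOLOG_OFFSET[hom$name]
  if (anyNA(off)) stop("no planting offset for panel entries: ",
                       paste(hom$name[is.na(off)], collapse = ", "),
                       call. = FALSE)
  homologs <- data.frame(name = hom$name, peptide = hom$peptide,
                         anchor = hom$anchor_gene,
                         strand_rule = hom$anchor_strand,
                         identity = identity, offset_nt = unname(off),
                         stringsAsFactors = FALSE)
  for (try in seq_len(5L)) {
    sub_seed <- (seed * 131L + try - 1L) %% .Machine$integer.max
    gt <- make_genome(L, features, nested = nested, homologs = homologs,
                      seed = sub_seed,
                      accession = sprintf("SYNMT-%d", seed))
    if (!verify || .verify_reference(gt)) return(gt)
  }
  stop("failed to generate a verifiable synthetic reference", call. = FALSE)
}

.verify_reference <- function(gt) {
  tru <- gt$truth
  rud <- tryCatch(call_rudel(gt$genome, gt$features), error = function(e) NULL)
  trud <- tru[tru$name == "Rudel", ]
  if (is.null(rud) || rud$start != trud$start || rud$length_nt !=
        trud$length_nt) return(FALSE)
  orfs <- scan_orfs(gt$genome, min_len_nt = 24L)
  hom <- tru[tru$kind == "homolog", ]
  key <- paste(orfs$start, orfs$strand, orfs$length_nt)
  all(paste(hom$start, hom$strand, hom$length_nt) %in% key)
}
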