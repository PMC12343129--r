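# Assembly of the extended mitochondrial transcriptome manifest and its
# FASTA/GFF3 serialization.

#' Transcript record constructor
#'
#' @param id Unique transcript identifier.
#' @param gene_class One of `"mRNA"`, `"rRNA"`, `"MDP"`, `"lncRNA"`.
#' @param segments `data.frame` with columns `start`, `end` (0-based
#'   half-open genome coordinates), `strand`; one row per segment,
#'   several for chimeric transcripts.
#' @param sequence Transcript sequence (concatenated over segments).
#' @param anchor_gene Optional anchor/host gene symbol.
#' @return A list of class `transcript_record`.
#' @export
transcript_record <- function(id, gene_class, segments, sequence,
                              anchor_gene = NA_character_) {
  gene_class <- match.arg(gene_class, c("mRNA", "rRNA", "MDP", "lncRNA"))
  stopifnot(nrow(segments) >= 1L, nzchar(sequence))
  structure(list(id = id, gene_class = gene_class, segments = segments,
                 sequence = sequence, anchor_gene = anchor_gene),
            class = "transcript_record")
}

#' Build classical mRNA and rRNA transcript records
#'
#' One mRNA record per CDS feature and one rRNA record per rRNA feature,
#' strand-resolved. A feature table without any CDS is an input error.
#'
#' @param features A [gene_features()] data frame.
#' @param genome A [circular_genome()].
#' @return List of [transcript_record()]s.
#' @export
build_classical <- function(features, genome) {
  keep <- features[features$kind %in% c("CDS", "rRNA"), , drop = FALSE]
  if (!any(keep$kind == "CDS")) {
    stop("no CDS features in input: cannot build the classical transcriptome",
         call. = FALSE)
  }
  lapply(seq_len(nrow(keep)), function(i) {
    f <- keep[i, ]
    transcript_record(
      id = f$name, gene_class = if (f$kind == "CDS") "mRNA" else "rRNA",
      segments = data.frame(start = f$start, end = f$end, strand = f$strand,
                            stringsAsFactors = FALSE),
      sequence = extract_sequence(genome, f$start, f$end, f$strand))
  })
}

#' Exclude poly-A-incompatible features
#'
#' Transcripts that are not polyadenylated - the mt-tRNAs - cannot be
#' captured by a poly-A-selected sequencing library and are excluded from
#' the transcriptome, with the reason recorded.
#'
#' @param features A [gene_features()] data frame.
#' @return A list with `kept` (features data frame) and `excluded`
#'   (`data.frame` of `name`, `reason`).
#' @export
filter_polya_incompatible <- function(features) {
  is_trna <- features$kind == "tRNA"
  list(kept = features[!is_trna, , drop = FALSE],
       excluded = data.frame(
         name = features$name[is_trna],
         reason = rep("poly-A-incompatible", sum(is_trna)),
         stringsAsFactors = FALSE))
}

#' Assemble the transcriptome manifest
#'
#' Combines classical, MDP and lncRNA transcript records with the excluded
#' feature list into a `transcriptome_manifest`. Transcript ids must be
#' unique across all inputs (an id collision is an integrity error).
#'
#' @param classical,mdp_records,lncrnas Lists of [transcript_record()]s.
#' @param excluded `data.frame` of excluded features (`name`, `reason`).
#' @param genome_accession Accession of the source genome.
#' @param absent_mdps Character vector of panel entries with no qualifying
#'   ORF (recorded, not an error).
#' @return A `transcriptome_manifest` object.
#' @export
assemble_manifest <- function(classical, mdp_records = list(),
                              lncrnas = list(),
                              excluded = data.frame(name = character(),
                                                    reason = character()),
                              genome_accession = "unnamed",
                              absent_mdps = character()) {
  records <- c(classical, mdp_records, lncrnas)
  if (length(records) == 0L) stop("manifest would be empty", call. = FALSE)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(genome_accession = genome_accession, records = records,
                 excluded = excluded, absent_mdps = absent_mdps),
            class = "transcriptome_manifest")
}

#' @export
print.transcriptome_manifest <- function(x, ...) {
  cls <- vapply(x$records, `[[`, "", "gene_class")
  cat("<transcriptome_manifest> ", x$genome_accession, ": ",
      length(x$records), " transcripts\n", sep = "")
  tb <- table(factor(cls, levels = c("mRNA", "rRNA", "MDP", "lncRNA")))
  cat("  ", paste(names(tb), tb, sep = "=", collapse = "  "), "\n", sep = "")
  cat("  excluded: ", nrow(x$excluded), " feature(s)\n", sep = "")
  if (length(x$absent_mdps)) {
    cat("  absent panel members: ", paste(x$absent_mdps, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Per-class record counts of a manifest
#'
#' @param manifest A `transcriptome_manifest`.
#' @return Named integer vector: `mRNA`, `rRNA`, `MDP`, `lncRNA`, `total`,
#'   `excluded`.
#' @export
manifest_counts <- function(manifest) {
  cls <- vapply(manifest$records, `[[`, "", "gene_class")
  tb <- table(factor(cls, levels = c("mRNA", "rRNA", "MDP", "lncRNA")))
  c(as.vector(tb), total = length(manifest$records),
    excluded = nrow(manifest$excluded)) |>
    stats::setNames(c("mRNA", "rRNA", "MDP", "lncRNA", "total", "excluded"))
}

#' Build the full extended mitochondrial transcriptome
#'
#' End-to-end construction: excludes poly-A-incompatible tRNAs, builds
#' classical mRNA/rRNA records, scans ORFs and matches them against the
#' MDP panel, calls the positional Rudel ORF, places template lncRNAs,
#' and assembles the manifest. On the default synthetic reference this
#' yields 38 transcripts (13 mRNA + 2 rRNA + 13 MDP + 10 lncRNA) with the
#' 22 tRNAs excluded.
#'
#' @param genome A [circular_genome()].
#' @param features A [gene_features()] data frame.
#' @param panel An [mdp_panel()] data frame.
#' @param template A lncRNA template (see [default_lncrna_template()]).
#' @param min_identity,min_coverage Homology thresholds for [match_mdps()].
#' @param min_orf_len Minimum ORF coding length (nt) for the scan.
#' @return A `transcriptome_manifest`.
#' @export
build_transcriptome <- function(genome, features, panel = mdp_panel(),
                                template = default_lncrna_template(),
                                min_identity = 50, min_coverage = 0.7,
                                min_orf_len = 24L) {
  flt <- filter_polya_incompatible(features)
  classical <- build_classical(flt$kept, genome)
  orfs <- scan_orfs(genome, min_len_nt = min_orf_len)
  hits <- match_mdps(orfs, panel, features, genome$length,
                     min_identity = min_identity,
                     min_coverage = min_coverage)
  mdp_records <- list()
  for (i in which(hits$present)) {
    h <- hits[i, ]
    mdp_records[[length(mdp_records) + 1L]] <- transcript_record(
      id = h$name, gene_class = "MDP",
      segments = data.frame(start = h$orf_start, end = h$orf_end,
                            strand = h$strand, stringsAsFactors = FALSE),
      sequence = extract_sequence(genome, h$orf_start, h$orf_end, h$strand),
      anchor_gene = panel$anchor_gene[match(h$name, panel$name)])
  }
  absent <- hits$name[!hits$present]
  if ("Rudel" %in% panel$name[panel$mode == "positional"]) {
    rud <- call_rudel(genome, features)
    if (is.null(rud)) {
      absent <- c(absent, "Rudel")
    } else {
      mdp_records[[length(mdp_records) + 1L]] <- transcript_record(
        id = "Rudel", gene_class = "MDP",
        segments = data.frame(start = rud$start, end = rud$end,
                              strand = rud$strand, stringsAsFactors = FALSE),
        sequence = extract_sequence(genome, rud$start, rud$end, rud$strand),
        anchor_gene = rud$host_gene)
    }
  }
  lncrnas <- place_lncrnas(genome, features, template)
  assemble_manifest(classical, mdp_records, lncrnas, flt$excluded,
                    genome_accession = genome$accession,
                    absent_mdps = absent)
}

#' Write a transcriptome manifest to FASTA
#'
#' One 70-column-wrapped record per transcript; the header carries the
#' gene class, anchor gene and 1-based inclusive segment coordinates.
#'
#' @param manifest A `transcriptome_manifest` (non-empty, unique ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(manifest, path) {
  recs <- manifest$records
  if (length(recs) == 0L) stop("refusing to write an empty manifest",
                               call. = FALSE)
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(recs, `[[`, "", "sequence"))
  names(seqs) <- vapply(recs, function(r) {
    coords <- paste(sprintf("%d-%d(%s)", r$segments$start + 1L,
                            r$segments$end, r$segments$strand),
                    collapse = ",")
    sprintf("%s gene_class=%s anchor_gene=%s coords=%s", r$id, r$gene_class,
            r$anchor_gene, coords)
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write a transcriptome manifest to GFF3
#'
#' Emits a `##gff-version 3` file with 1-based inclusive coordinates.
#' Multi-segment transcripts produce one line per segment sharing an `ID`
#' attribute; origin-spanning segments are split at the junction.
#'
#' @param manifest A `transcriptome_manifest`.
#' @param path Output path.
#' @param genome_length Genome length (nt), used to split origin-spanning
#'   segments.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(manifest, path, genome_length) {
  recs <- manifest$records
  if (length(recs) == 0L) stop("refusing to write an empty manifest",
                               call. = FALSE)
  type_of <- c(mRNA = "mRNA", rRNA = "rRNA", MDP = "mRNA",
               lncRNA = "lnc_RNA")
  lines <- "##gff-version 3"
  for (r in recs) {
    attrs <- sprintf("ID=%s;Name=%s;gene_class=%s;anchor_gene=%s", r$id,
                     r$id, r$gene_class, r$anchor_gene)
    for (i in seq_len(nrow(r$segments))) {
      s <- r$segments[i, ]
      pieces <- if (s$end <= s$start) {
        list(c(s$start + 1L, genome_length), c(1L, s$end))
      } else list(c(s$start + 1L, s$end))
      for (p in pieces) {
        lines <- c(lines, sprintf("%s\tmitotome\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                  manifest$genome_accession,
                                  type_of[[r$gene_class]], p[1L], p[2L],
                                  s$strand, attrs))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the build report
#'
#' Tab-separated summary: per-class record counts, excluded features and
#' absent panel members.
#'
#' @param manifest A `transcriptome_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_build_report <- function(manifest, path) {
  cn <- manifest_counts(manifest)
  lines <- c("metric\tvalue",
             paste(names(cn), cn, sep = "\t"),
             paste0("absent_panel_members\t",
                    paste(manifest$absent_mdps, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
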