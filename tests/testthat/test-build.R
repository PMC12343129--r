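test_that("the default reference build partitions into 13+2+13+10 = 38", {
  ref <- fixture_reference()
  man <- cached("manifest", function()
    build_transcriptome(ref$genome, ref$features))
  cn <- manifest_counts(man)
  expect_equal(unname(cn["total"]), 38L)
  expect_equal(unname(cn[c("mRNA", "rRNA", "MDP", "lncRNA")]),
               c(13L, 2L, 13L, 10L))
  expect_equal(unname(cn["excluded"]), 22L)
  expect_true(all(man$excluded$reason == "poly-A-incompatible"))
  expect_length(man$absent_mdps, 0L)
})

test_that("the poly-A filter excludes exactly the tRNAs", {
  ref <- fixture_reference()
  flt <- filter_polya_incompatible(ref$features)
  expect_equal(nrow(flt$excluded), 22L)
  expect_false(any(flt$kept$kind == "tRNA"))
  empty <- filter_polya_incompatible(ref$features[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$excluded), 0L)
  mixed <- gene_features(letters[1:5], c("tRNA", "tRNA", "tRNA", "CDS",
                                         "CDS"),
                         start = (0:4) * 100L, end = (0:4) * 100L + 90L,
                         strand = "+")
  flt2 <- filter_polya_incompatible(mixed)
  expect_equal(nrow(flt2$excluded), 3L)
  expect_equal(nrow(flt2$kept), 2L)
})

test_that("classical builder needs CDS features and respects strand", {
  ref <- fixture_reference()
  only_trna <- ref$features[ref$features$kind == "tRNA", ]
  expect_error(build_classical(only_trna, ref$genome), "no CDS")
  recs <- build_classical(ref$features, ref$genome)
  expect_length(recs, 15L)  # 13 mRNA + 2 rRNA
  nd6 <- recs[[which(vapply(recs, `[[`, "", "id") == "mt-Nd6")]]
  f <- ref$features[ref$features$name == "mt-Nd6", ]
  expect_identical(nd6$sequence,
                   extract_sequence(ref$genome, f$start, f$end, "-"))
})

test_that("lncRNA placement follows the template rules", {
  ref <- fixture_reference()
  recs <- place_lncrnas(ref$genome, ref$features)
  expect_length(recs, 10L)
  ids <- vapply(recs, `[[`, "", "id")
  expect_setequal(ids, c("7SRNA", "LIPCAR", "lncCYB", "lncND5", "lncND6",
                         "MDL1", "MDL1AS", "SncmtRNA", "ASncmtRNA1",
                         "ASncmtRNA2"))
  by_id <- stats::setNames(recs, ids)
  # MDL1/MDL1AS: identical interval, opposite strands, reverse complement
  expect_equal(by_id$MDL1$segments$start, by_id$MDL1AS$segments$start)
  expect_identical(by_id$MDL1$sequence,
                   reverse_complement(by_id$MDL1AS$sequence))
  # LIPCAR is a two-segment chimera
  expect_equal(nrow(by_id$LIPCAR$segments), 2L)
  expect_equal(nchar(by_id$LIPCAR$sequence), 800L)
  # lncND6 is antisense of mt-Nd6 (itself on the light strand)
  expect_identical(by_id$lncND6$segments$strand, "+")
  # a template anchored to a missing gene names the anchor in its error
  broken <- default_lncrna_template()
  broken$anchor[broken$name == "lncND5"] <- "mt-Nd9"
  expect_error(place_lncrnas(ref$genome, ref$features, broken), "mt-Nd9")
})

test_that("manifest assembly enforces id uniqueness and class arithmetic", {
  ref <- fixture_reference()
  classical <- build_classical(ref$features, ref$genome)
  lnc <- place_lncrnas(ref$genome, ref$features)
  man <- assemble_manifest(classical, list(), lnc,
                           filter_polya_incompatible(ref$features)$excluded,
                           genome_accession = ref$genome$accession)
  cn <- manifest_counts(man)
  expect_equal(unname(cn["total"]), 25L)  # 13 + 2 + 0 + 10
  expect_equal(unname(cn["MDP"]), 0L)
  expect_equal(unname(cn["total"]),
               sum(cn[c("mRNA", "rRNA", "MDP", "lncRNA")]))
  dup <- c(classical, classical[1])
  expect_error(assemble_manifest(dup), "duplicate")
})

test_that("sense/antisense pairs reverse-complement over their overlap", {
  ref <- fixture_reference()
  man <- cached("manifest", function()
    build_transcriptome(ref$genome, ref$features))
  by_id <- stats::setNames(man$records,
                           vapply(man$records, `[[`, "", "id"))
  # Rudel lies antisense within mt-Atp8/mt-Atp6: its sequence must equal
  # the reverse complement of the corresponding sense-strand stretch
  rud <- by_id$Rudel$segments
  sense <- extract_sequence(ref$genome, rud$start, rud$end, "+")
  expect_identical(by_id$Rudel$sequence, reverse_complement(sense))
  gau <- by_id$Gau$segments
  co1 <- ref$features[ref$features$name == "mt-Co1", ]
  expect_true(gau$start >= co1$start && gau$end <= co1$end)
  expect_identical(gau$strand, "-")
})

test_that("FASTA and GFF3 serialization round-trip and are deterministic", {
  ref <- fixture_reference()
  man <- cached("manifest", function()
    build_transcriptome(ref$genome, ref$features))
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  gf1 <- withr::local_tempfile(fileext = ".gff3")
  write_fasta(man, fa1)
  write_fasta(man, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  seqs <- Biostrings::readDNAStringSet(fa1)
  expect_length(seqs, 38L)
  ids <- vapply(strsplit(names(seqs), " "), `[[`, "", 1L)
  by_id <- stats::setNames(man$records,
                           vapply(man$records, `[[`, "", "id"))
  for (i in seq_along(seqs)) {
    expect_identical(as.character(seqs[[i]]), by_id[[ids[i]]]$sequence)
  }
  write_gff3(man, gf1, ref$genome$length)
  lines <- readLines(gf1)
  expect_identical(lines[1], "##gff-version 3")
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(gf1)
  expect_true(all(ids %in% gr$ID))
  lip <- gr[gr$ID == "LIPCAR"]
  expect_length(lip, 2L)  # chimera: two lines, one ID
  # 1-based inclusive conversion
  rudf <- gr[gr$ID == "Rudel"]
  expect_equal(GenomicRanges::start(rudf), by_id$Rudel$segments$start + 1L)
  expect_equal(GenomicRanges::end(rudf), by_id$Rudel$segments$end)
})

test_that("writers refuse empty manifests and duplicate ids", {
  p <- withr::local_tempfile()
  empty <- structure(list(genome_accession = "x", records = list(),
                          excluded = data.frame()),
                     class = "transcriptome_manifest")
  expect_error(write_fasta(empty, p), "empty")
  expect_false(file.exists(p))
})
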