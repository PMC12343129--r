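test_that("the bundled panel carries the 13-name roster and key metadata", {
  p <- mdp_panel()
  expect_setequal(p$name, c("MOTS-c", "Humanin", paste0("SHLP", 1:6),
                            "SHMOOSE", "MTALTND4", "Gau", "CYTB-187AA",
                            "Rudel"))
  expect_equal(p$expected_orf_len_nt[p$name == "MOTS-c"], 36)
  expect_identical(p$mode[p$name == "Rudel"], "positional")
  expect_true(all(!is.na(p$peptide[p$mode == "homology"])))
  expect_true(all(grepl("synthetic", p$source[!(p$name %in%
    c("MOTS-c", "Humanin", "Rudel"))])))
})

test_that("panel matching recovers every planted homolog at its locus", {
  ref <- fixture_reference()
  panel <- mdp_panel()
  orfs <- scan_orfs(ref$genome, min_len_nt = 24L)
  hits <- match_mdps(orfs, panel, ref$features, ref$genome$length)
  expect_equal(nrow(hits), 12L)
  expect_true(all(hits$present))
  tru <- ref$truth[ref$truth$kind == "homolog", ]
  expect_equal(hits$orf_start[match(tru$name, hits$name)], tru$start)
  expect_true(all(hits$identity >= 50 & hits$coverage >= 0.7))
  # calls come only from panel names: no spurious entries
  expect_true(all(hits$name %in% panel$name))
})

test_that("sub-threshold homologs are reported absent, not errored", {
  gt <- fixture_small_planted()  # homX planted at 85% identity
  orfs <- scan_orfs(gt$genome, min_len_nt = 24L)
  panel <- data.frame(name = "homX", mode = "homology",
                      peptide = "MAPRGFSCLLLLTSEIDLPVKRRA",
                      anchor_gene = "geneC", anchor_strand = "antisense",
                      expected_orf_len_nt = 75, source = "test",
                      stringsAsFactors = FALSE)
  found <- match_mdps(orfs, panel, gt$features, gt$genome$length,
                      min_identity = 60)
  expect_true(found$present)
  strict <- match_mdps(orfs, panel, gt$features, gt$genome$length,
                       min_identity = 95)
  expect_false(strict$present)
  # an anchor with no qualifying ORF on the required strand
  panel2 <- panel
  panel2$anchor_gene <- "geneA"
  panel2$anchor_strand <- "antisense"
  miss <- match_mdps(scan_orfs(gt$genome, min_len_nt = 150L), panel2,
                     gt$features, gt$genome$length)
  expect_false(miss$present)
})

test_that("Rudel is the longest antisense ORF of the mt-Atp8/6 locus", {
  ref <- fixture_reference()
  rud <- call_rudel(ref$genome, ref$features)
  expect_equal(rud$length_nt, 663L)
  expect_identical(rud$strand, "-")
  tru <- ref$truth[ref$truth$name == "Rudel", ]
  expect_equal(rud$start, tru$start)
  # rotation equivariance: shifting the origin leaves the sequence fixed
  k <- 1000L
  gr <- rotate_genome(ref$genome, k)
  fr <- rotate_features(ref$features, k, ref$genome$length)
  rud2 <- call_rudel(gr, fr)
  expect_equal(rud2$length_nt, 663L)
  expect_identical(rud2$peptide, rud$peptide)
  expect_equal(rud2$start, (rud$start - k) %% ref$genome$length)
})

test_that("a missing ATP locus is a locus error; no antisense start is absent", {
  ref <- fixture_reference()
  no_locus <- ref$features[!grepl("Atp", ref$features$name), ]
  expect_error(call_rudel(ref$genome, no_locus), "locus")
  gt <- fixture_small_planted()
  f <- gt$features
  f$name[f$name == "geneA"] <- "mt-Atp8"
  f$name[f$name == "geneB"] <- "mt-Atp6"
  # geneA (now mt-Atp8) has no antisense ORF >= 600: absent at that bar
  expect_null(call_rudel(gt$genome, f, min_len_nt = 600L))
})
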