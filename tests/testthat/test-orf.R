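test_that("scanner recovers planted ORFs exactly on a cleaned genome", {
  gt <- fixture_small_planted()
  got <- scan_orfs(gt$genome, min_len_nt = 150L)
  tru <- gt$truth[gt$truth$length_nt >= 150L, ]
  expect_equal(nrow(got), nrow(tru))
  expect_setequal(paste(got$start, got$end, got$strand, got$length_nt),
                  paste(tru$start, tru$end, tru$strand, tru$length_nt))
  expect_setequal(got$peptide, tru$peptide)
})

test_that("a genome without start codons yields no ORFs", {
  g <- circular_genome(strrep("C", 400))
  expect_equal(nrow(scan_orfs(g, min_len_nt = 24L)), 0L)
})

test_that("an ORF spanning the origin is recovered with correct peptide", {
  gt <- fixture_small_planted()
  L <- gt$genome$length
  tru <- gt$truth[gt$truth$name == "geneA", ]
  # rotate so geneA crosses the origin
  k <- (tru$start + 100L) %% L
  gr <- rotate_genome(gt$genome, k)
  got <- scan_orfs(gr, min_len_nt = 150L)
  row <- got[got$peptide == tru$peptide, ]
  expect_equal(nrow(row), 1L)
  expect_true(row$wraps_origin)
  expect_equal(row$start, (tru$start - k) %% L)
})

test_that("scanning equals the brute-force six-frame oracle on random genomes", {
  set.seed(404)
  for (i in 1:6) {
    g <- random_genome(sample(300:1200, 1))
    got <- scan_orfs(g, min_len_nt = 60L)
    ora <- oracle_scan_orfs(g, min_len_nt = 60L)
    expect_identical(paste(got$start, got$end, got$strand, got$length_nt),
                     paste(ora$start, ora$end, ora$strand, ora$length_nt))
    expect_identical(got$peptide, ora$peptide)
  }
})

test_that("reverse-complementing the genome swaps strand labels only", {
  set.seed(77)
  g <- random_genome(800)
  grc <- circular_genome(reverse_complement(g$sequence))
  a <- scan_orfs(g, min_len_nt = 60L)
  b <- scan_orfs(grc, min_len_nt = 60L)
  expect_equal(nrow(a), nrow(b))
  expect_setequal(a$peptide[a$strand == "+"], b$peptide[b$strand == "-"])
  expect_setequal(a$peptide[a$strand == "-"], b$peptide[b$strand == "+"])
})

test_that("no candidate peptide contains an internal stop", {
  set.seed(88)
  g <- random_genome(1500)
  o <- scan_orfs(g, min_len_nt = 24L)
  expect_true(nrow(o) > 0)
  expect_false(any(grepl("*", o$peptide, fixed = TRUE)))
  expect_true(all(nchar(o$peptide) == o$length_nt / 3))
  expect_true(all(o$length_nt %% 3 == 0))
})

test_that("incomplete stops are honoured only at annotated boundaries", {
  # ATG + 8 full codons + partial 'TA' ending exactly at the boundary
  coding <- "ATGAAACCCGGGTTTAAACCCGGGTTT"
  s <- paste0(strrep("C", 30), "TAA", coding, "TA", strrep("C", 30))
  g <- circular_genome(s)
  b <- 33L + nchar(coding) + 2L  # 0-based end of the transcript
  none <- scan_orfs(g, min_len_nt = 24L, allow_incomplete_stop = FALSE)
  expect_false(any(none$stop_kind == "incomplete_TA"))
  got <- scan_orfs(g, min_len_nt = 24L, allow_incomplete_stop = TRUE,
                   boundaries = b)
  hit <- got[got$stop_kind == "incomplete_TA", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 33L)
  expect_equal(hit$length_nt %% 3L, 2L)
})

test_that("parameter validation rejects degenerate scans", {
  g <- random_genome(200)
  expect_error(scan_orfs(g, strands = character()), "empty strand")
  expect_error(scan_orfs(g, min_len_nt = 6L), ">= 12")
})

test_that("antisense ORF search respects strand, overlap and host naming", {
  gt <- fixture_small_planted()
  host <- gt$features[gt$features$name == "geneB", ]
  hits <- find_antisense_orfs(gt$genome, host, min_len_nt = 150L)
  tru <- gt$truth[gt$truth$name == "asorf", ]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, tru$start)
  expect_equal(hits$length_nt, tru$length_nt)
  expect_identical(hits$strand, "-")
  expect_identical(hits$host_gene, "geneB")
  # a locus with no qualifying antisense ORF returns an empty frame
  lone <- gt$features[gt$features$name == "geneA", ]
  expect_equal(nrow(find_antisense_orfs(gt$genome, lone,
                                        min_len_nt = 150L)), 0L)
})
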