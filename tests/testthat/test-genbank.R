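test_that("GenBank write/read round-trips coordinates and sequence exactly", {
  ref <- fixture_reference()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(ref$genome, ref$features, path)
  back <- read_genbank(path)
  expect_identical(back$genome$sequence, ref$genome$sequence)
  expect_identical(back$genome$accession, ref$genome$accession)
  a <- ref$features[order(ref$features$name), ]
  b <- back$features[order(back$features$name), ]
  expect_equal(b$start, a$start)
  expect_equal(b$end, a$end)
  expect_identical(b$strand, a$strand)
  expect_identical(b$kind, a$kind)
  expect_identical(b$wraps_origin, a$wraps_origin)
})

test_that("1-based inclusive GenBank coordinates become 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gb")
  g <- circular_genome(strrep("ACGT", 10), accession = "mini")
  f <- gene_features("x", "CDS", 0L, 9L, "+")
  write_genbank(g, f, path)
  lines <- readLines(path)
  expect_true(any(grepl("1\\.\\.9", lines)))  # written as 1..9
  back <- read_genbank(path)
  expect_equal(back$features$start, 0L)
  expect_equal(back$features$end, 9L)
  expect_identical(back$features$strand, "+")
})

test_that("origin-spanning join() locations are flagged wraps_origin", {
  path <- withr::local_tempfile(fileext = ".gb")
  g <- circular_genome(strrep("ACGT", 25))
  f <- gene_features("dl", "D-loop", 90L, 10L, "+")
  write_genbank(g, f, path)
  expect_true(any(grepl("join\\(91\\.\\.100,1\\.\\.10\\)", readLines(path))))
  back <- read_genbank(path)
  expect_true(back$features$wraps_origin)
  expect_equal(back$features$start, 90L)
  expect_equal(back$features$end, 10L)
})

test_that("malformed records give format errors, unknown kinds a warning", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       x 4 bp", "FEATURES             Location/Qualifiers",
               "ORIGIN", "        1 acgt", "//",
               "LOCUS       y 4 bp", "ORIGIN", "        1 acgt", "//"), p)
  expect_error(read_genbank(p), "multi-record")
  writeLines(c("LOCUS       x 4 bp",
               "FEATURES             Location/Qualifiers"), p)
  expect_error(read_genbank(p), "ORIGIN")
  writeLines(c("LOCUS       x 40 bp",
               "FEATURES             Location/Qualifiers",
               "     stem_loop       2..13",
               '                     /gene="weird"',
               "ORIGIN",
               paste("        1", strrep("acgtacgtac", 4)), "//"), p)
  expect_warning(res <- read_genbank(p), "unknown GenBank feature kind")
  expect_identical(res$features$kind, "other")
  expect_identical(res$features$name, "weird")
})
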