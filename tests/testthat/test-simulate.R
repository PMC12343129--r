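test_that("both generators are byte-identical under a fixed seed", {
  gt1 <- fixture_small_planted()
  gt2 <- make_genome(
    2000L,
    data.frame(name = c("geneA", "geneB", "geneC"), kind = "CDS",
               start = c(100L, 600L, 1200L),
               length_nt = c(300L, 360L, 450L),
               strand = c("+", "+", "-"), stringsAsFactors = FALSE),
    nested = data.frame(name = "asorf", g0 = 650L, n_aa = 80L,
                        strand = "-", stringsAsFactors = FALSE),
    homologs = data.frame(name = "homX",
                          peptide = "MAPRGFSCLLLLTSEIDLPVKRRA",
                          anchor = "geneC", strand_rule = "antisense",
                          identity = 0.85, offset_nt = 60L,
                          stringsAsFactors = FALSE),
    seed = 1L, clean_min_len = 150L)
  expect_identical(gt1$genome$sequence, gt2$genome$sequence)
  tr <- count_truth(n_genes = 50L, seed = 4L)
  expect_identical(simulate_counts(tr)$counts, simulate_counts(tr)$counts)
})

test_that("planted homolog identity lands within 3 points of target", {
  gt <- fixture_small_planted()
  hom <- gt$truth[gt$truth$kind == "homolog", ]
  expect_equal(hom$realized_identity / 100, 0.85, tolerance = 0.03)
  sw <- smith_waterman("MAPRGFSCLLLLTSEIDLPVKRRA", hom$peptide)
  expect_gt(sw$score, 0)
})

test_that("simulated counts match negative-binomial moments", {
  tr <- count_truth(n_genes = 10000L, states = c("summer", "torpor"),
                    reps_per_state = 2L, baseline_mu = 100,
                    dispersion = 0.1, size_factors = rep(1, 4), seed = 9L)
  sim <- simulate_counts(tr)
  x <- as.vector(sim$counts)
  expect_equal(mean(x), 100, tolerance = 0.02)
  expect_equal(stats::var(x), 100 + 0.1 * 100^2, tolerance = 0.05)
  # Poisson limit as dispersion -> 0
  tr0 <- count_truth(n_genes = 10000L, states = c("summer", "torpor"),
                     reps_per_state = 2L, baseline_mu = 100,
                     dispersion = 1e-8, size_factors = rep(1, 4),
                     seed = 10L)
  x0 <- as.vector(simulate_counts(tr0)$counts)
  expect_equal(stats::var(x0) / mean(x0), 1, tolerance = 0.05)
})

test_that("planted size factors shape the column sums", {
  tr <- count_truth(n_genes = 2000L, states = c("summer", "torpor"),
                    reps_per_state = 1L + 1L, size_factors = c(1, 2, 1, 2),
                    dispersion = 0.05, seed = 12L)
  sim <- simulate_counts(tr)
  cs <- colSums(sim$counts)
  expect_equal(unname(cs[2] / cs[1]), 2, tolerance = 0.05)
})

test_that("the synthetic reference reproduces its documented structure", {
  ref <- fixture_reference()
  expect_equal(sum(ref$features$kind == "CDS"), 13L)
  expect_equal(sum(ref$features$kind == "tRNA"), 22L)
  expect_equal(sum(ref$features$kind == "rRNA"), 2L)
  dl <- ref$features[ref$features$kind == "D-loop", ]
  expect_true(dl$wraps_origin)
  tru <- ref$truth[ref$truth$name == "Rudel", ]
  expect_equal(tru$length_nt, 663L)
  # regenerating with the same seed is byte-identical
  ref2 <- synthetic_reference(seed = 1L)
  expect_identical(ref2$genome$sequence, ref$genome$sequence)
})
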