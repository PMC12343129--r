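test_that("size factors satisfy the scaling identities", {
  set.seed(42)
  base <- matrix(rpois(200 * 2, 50), 200, 2)
  m <- cbind(base[, 1], base[, 1] * 2)
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  same <- cbind(base[, 1], base[, 1], base[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3))
  zero <- matrix(0:1, 2, 2)
  zero[1, ] <- 0; zero[2, 1] <- 0
  expect_error(size_factors(zero), "pseudo_reference")
})

test_that("planted size factors are recovered within 5 percent", {
  planted <- c(1, 1.5, 0.7, 1.2)
  tr <- count_truth(n_genes = 500L, states = c("summer", "torpor"),
                    reps_per_state = 2L, size_factors = planted,
                    dispersion = 0.05, seed = 3L)
  sim <- simulate_counts(tr)
  sf <- size_factors(sim$counts)
  ref <- planted / exp(mean(log(planted)))
  expect_true(all(abs(sf - ref) / ref < 0.05))
})

test_that("moderated log hits the detection boundary arithmetic", {
  m <- matrix(c(127, 0, 254), 3, 1)
  y <- moderated_log(m, factors = 1)
  expect_equal(y[1, 1], 7)
  expect_equal(y[2, 1], 0)
  # doubling counts and factors leaves the transform unchanged
  m2 <- matrix(rpois(40, 30), 20, 2)
  f <- c(0.8, 1.25)
  expect_equal(moderated_log(2 * m2, 2 * f), moderated_log(m2, f))
})

test_that("detection requires the threshold in ALL samples of a tissue", {
  md <- data.frame(sample_id = c("l1", "l2", "b1", "b2"),
                   tissue = c("liver", "liver", "BAT", "BAT"),
                   state = "summer", sex = "F", stringsAsFactors = FALSE)
  y <- rbind(at_boundary = c(7, 7, 7, 7),
             just_below = c(7, 6.99, 7, 7),
             liver_only = c(9, 8, 0, 0))
  colnames(y) <- md$sample_id
  det <- detect(y, md, threshold = 7)
  expect_true(all(det$detected["at_boundary", ]))
  expect_false(det$detected["just_below", "liver"])
  expect_true(det$detected["just_below", "BAT"])
  expect_identical(unname(det$detected["liver_only", ]),
                   c(FALSE, TRUE))
  expect_identical(det$common, "at_boundary")
  # permutation invariance
  perm <- sample(ncol(y))
  det2 <- detect(y[, perm], md, threshold = 7)
  expect_identical(det2$detected, det$detected)
})

test_that("a planted detection pattern is recovered exactly", {
  set.seed(14)
  states <- c("summer", "torpor")
  tissues <- c("liver", "BAT", "brain")
  n_genes <- 30L
  pattern <- matrix(runif(n_genes * 3) < 0.5, n_genes, 3,
                    dimnames = list(paste0("gene", 1:n_genes), tissues))
  counts <- NULL; md <- NULL
  for (tt in tissues) {
    tr <- count_truth(n_genes = n_genes, states = states,
                      reps_per_state = 2L,
                      baseline_mu = ifelse(pattern[, tt], 2000, 2),
                      dispersion = 0.02, size_factors = rep(1, 4),
                      seed = match(tt, tissues))
    sim <- simulate_counts(tr, tissue = tt)
    colnames(sim$counts) <- paste0(tt, "_", colnames(sim$counts))
    sim$metadata$sample_id <- paste0(tt, "_", sim$metadata$sample_id)
    counts <- cbind(counts, sim$counts)
    md <- rbind(md, sim$metadata)
  }
  y <- moderated_log(counts, factors = rep(1, ncol(counts)))
  det <- detect(y, md, threshold = 7)
  expect_identical(det$detected[, tissues], pattern)
})
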