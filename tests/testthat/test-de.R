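test_that("BH adjustment follows the step-up definition with NA passthrough", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  got <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone: smaller p never gets a larger adjusted value
  set.seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= 0))
})

test_that("a constant gene carries no state signal", {
  md <- data.frame(sample_id = paste0("s", 1:12), tissue = "liver",
                   state = rep(c("summer", "torpor", "arousal"), each = 4),
                   sex = rep(c("F", "M"), 6), stringsAsFactors = FALSE)
  counts <- rbind(flat = rep(100, 12),
                  noisy = rpois(12, 100))
  colnames(counts) <- md$sample_id
  de <- nb_lrt(counts, md, factors = rep(1, 12))
  expect_equal(de$table$lrt[1], 0, tolerance = 1e-8)
  expect_equal(de$table$p[1], 1)
})

test_that("design validation catches degenerate inputs", {
  md <- data.frame(sample_id = paste0("s", 1:4), tissue = "liver",
                   state = "torpor", sex = rep(c("F", "M"), 2),
                   stringsAsFactors = FALSE)
  counts <- matrix(rpois(40, 50), 10, 4,
                   dimnames = list(NULL, md$sample_id))
  expect_error(nb_lrt(counts, md), "at least two states|summer")
  md$state <- c("torpor", "torpor", "arousal", "arousal")
  expect_error(nb_lrt(counts, md), "summer")
})

test_that("planted per-state effects drive the direction calls", {
  states <- c("summer", "entrance", "torpor", "arousal")
  lfc <- matrix(0, 400, 3,
                dimnames = list(NULL, c("entrance", "torpor", "arousal")))
  lfc[1:30, "torpor"] <- 2      # up in torpor only
  lfc[31:60, "arousal"] <- -2   # down in arousal only
  tr <- count_truth(n_genes = 400L, states = states, reps_per_state = 3L,
                    baseline_mu = 500, dispersion = 0.05, seed = 11L,
                    lfc = lfc)
  sim <- simulate_counts(tr)
  de <- nb_lrt(sim$counts, sim$metadata)
  dirs <- state_directions(de, alpha = 0.05)
  expect_gte(mean(dirs[1:30, "torpor"] == "up"), 0.9)
  expect_gte(mean(dirs[31:60, "arousal"] == "down"), 0.9)
  # null genes stay quiet nearly everywhere
  expect_lte(mean(dirs[61:400, ] != "none"), 0.02)
  # the direction rule: a gene with padj above alpha is none in all states
  hi <- which(de$table$padj > 0.2)
  expect_true(all(dirs[hi, ] == "none"))
  # and the long-format table agrees with the matrix
  long <- directions_long(de)
  expect_equal(nrow(long), 400L * 3L)
  expect_identical(long$direction[long$gene == "gene1" &
                                    long$state == "torpor"],
                   dirs["gene1", "torpor"])
})

test_that("power grows with effect size and replication", {
  states <- c("summer", "torpor")
  power_at <- function(effect, reps) {
    lfc <- matrix(0, 300, 1, dimnames = list(NULL, "torpor"))
    lfc[1:60, 1] <- effect
    tr <- count_truth(n_genes = 300L, states = states,
                      reps_per_state = reps, baseline_mu = 300,
                      dispersion = 0.05,
                      seed = 900L + reps * 10L + round(effect * 10),
                      lfc = lfc)
    sim <- simulate_counts(tr)
    de <- nb_lrt(sim$counts, sim$metadata)
    mean(de$table$p[1:60] <= 0.05, na.rm = TRUE)
  }
  p_small <- power_at(0.5, 3L)
  p_large <- power_at(2.0, 3L)
  expect_gt(p_large, p_small)
  p_few <- power_at(1.0, 2L)
  p_many <- power_at(1.0, 5L)
  expect_gt(p_many, p_few)
  expect_gte(p_large, 0.8)
})
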