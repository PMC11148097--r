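test_that("jaccard distance matches hand-counted examples and edge cases", {
  expect_equal(jaccard_distance(c("A", "B"), c("A", "B")), 0)
  expect_equal(jaccard_distance(c("A", "B"), c("C", "D")), 1)
  expect_equal(jaccard_distance(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_true(is.na(jaccard_distance(character(0), character(0))))
  expect_equal(jaccard_distance(c("A", "A", "B"), c("A", "B")), 0)
})

test_that("jaccard distance is a metric on random finite sets", {
  set.seed(42)
  universe <- LETTERS
  for (i in 1:200) {
    a <- sample(universe, sample(1:10, 1))
    b <- sample(universe, sample(1:10, 1))
    c <- sample(universe, sample(1:10, 1))
    dab <- jaccard_distance(a, b)
    expect_equal(dab, jaccard_distance(b, a))
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(jaccard_distance(a, a), 0)
    expect_lte(dab, jaccard_distance(a, c) + jaccard_distance(c, b) + 1e-12)
  }
})

test_that("to_probability sum-normalises and rejects invalid profiles", {
  expect_equal(to_probability(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(to_probability(c(2, 0, 2)), c(0.5, 0, 0.5))
  p <- c(0.2, 0.3, 0.5)
  expect_equal(to_probability(p), p)  # idempotent on normalised input
  expect_error(to_probability(c(0, 0)), "all-zero")
  expect_error(to_probability(c(-1, 2)), "non-negative")
  expect_error(to_probability(c(1, Inf)), "finite")
})

test_that("Jensen-Shannon distance hits its analytic endpoints", {
  expect_equal(jensen_shannon_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jensen_shannon_distance(c(1, 0), c(0, 1)), 1)
  # frozen value verified against the term-by-term oracle
  expect_equal(jensen_shannon_distance(c(0.5, 0.5), c(0.25, 0.75)),
               0.2208957688, tolerance = 1e-9)
  expect_equal(jsd_oracle(c(0.5, 0.5), c(0.25, 0.75)),
               0.2208957688, tolerance = 1e-9)
  expect_error(jensen_shannon_distance(c(1, 0), c(0.5, 0.25, 0.25)),
               "length")
  expect_error(
    jensen_shannon_distance(stats::setNames(c(1, 0), c("a", "b")),
                            stats::setNames(c(0, 1), c("b", "a"))),
    "misaligned")
})

test_that("JSD is symmetric, bounded and agrees with the brute-force oracle", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(2:30, 1)
    p1 <- to_probability(stats::runif(n))
    p2 <- to_probability(stats::runif(n) * stats::rbinom(n, 1, 0.8))
    if (sum(p2) == 0) next
    d <- jensen_shannon_distance(p1, p2)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, jensen_shannon_distance(p2, p1))
    expect_equal(d, jsd_oracle(p1, p2), tolerance = 1e-9)
  }
})

test_that("pairwise_ith aggregates region pairs per layer", {
  sets <- list(R1 = c("a", "b"), R2 = c("a", "b"), R3 = c("a", "b"))
  res <- pairwise_ith(sets, "mutational", "P01")
  expect_s3_class(res, "ith_result")
  expect_equal(res$n_pairs, 3L)
  expect_equal(res$pairs$distance, rep(0, 3))
  expect_equal(res$mean_ith, 0)

  sets2 <- list(R1 = c("a", "b", "c", "d", "e"),
                R2 = c("d", "e", "f", "g", "h"),
                R3 = c("x", "y"))
  res2 <- pairwise_ith(sets2, "mutational")
  expect_equal(res2$mean_ith, mean(res2$pairs$distance))

  prof <- list(R1 = c(1, 1), R2 = c(1, 1))
  expect_equal(pairwise_ith(prof, "methylation")$mean_ith, 0)
  expect_error(pairwise_ith(list(R1 = c("a")), "mutational"),
               "insufficient regions")
})

test_that("mean mutational ITH decreases with the trunk fraction", {
  means <- vapply(c(0.2, 0.8), function(tf) {
    cfg <- simulation_config(n_patients_H = 4, n_patients_L = 0,
                             trunk_fraction_H = tf, n_mutations_mean = 80,
                             n_windows = 10, n_genes = 10, seed = 31)
    sim <- simulate_cohort(cfg)
    muts <- split(sim$bundle$mutations, sim$bundle$mutations$patient_id)
    mean(vapply(names(sim$truth$patients), function(p) {
      fake <- list(bundle = list(samples = sim$bundle$samples[
        sim$bundle$samples$patient_id == p, ], mutations = muts[[p]]))
      vs <- variant_sets_from_sim(fake)
      pairwise_ith(vs$sets, "mutational", p)$mean_ith
    }, numeric(1)))
  }, numeric(1))
  expect_gt(means[1], means[2])
})

test_that("median_split dichotomises at the median with ties going low", {
  sp <- median_split(c(P1 = 1, P2 = 2, P3 = 3, P4 = 4))
  expect_equal(unname(sp$group), c("low", "low", "high", "high"))
  expect_equal(sp$median, 2.5)
  # odd n: the value equal to the median is assigned low
  sp2 <- median_split(c(a = 1, b = 2, c = 3))
  expect_equal(unname(sp2$group), c("low", "low", "high"))
  expect_equal(unname(median_split(c(a = 1, b = 2, c = 3),
                                   ties = "high")$group),
               c("low", "high", "high"))
  expect_message(sp3 <- median_split(c(a = 2, b = 2, c = 2)), "degenerate")
  expect_true(sp3$degenerate)
  expect_true(all(sp3$group == "low"))
  expect_true(is.na(median_split(c(1, 2, 3, NA))$group[4]))
  expect_error(median_split(c(1, NA)), ">= 2")
})
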