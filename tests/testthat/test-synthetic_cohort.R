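small_cfg <- function(...) {
  simulation_config(n_patients_H = 2, n_patients_L = 2,
                    n_mutations_mean = 40, n_windows = 30, n_genes = 20,
                    ...)
}

test_that("configuration is validated", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_regions = 1), "n_regions")
  expect_error(simulation_config(trunk_fraction_H = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(purity_range = c(0, 0.5)), "purity_range")
  expect_error(simulation_config(tumor_depth = 0), "depths")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 101)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$bundle$mutations, s2$bundle$mutations)
  expect_identical(s1$bundle$methylation, s2$bundle$methylation)
  expect_identical(s1$bundle$expression, s2$bundle$expression)
  expect_identical(s1$truth$patients, s2$truth$patients)
  s3 <- simulate_cohort(small_cfg(seed = 102))
  expect_false(identical(s1$bundle$mutations, s3$bundle$mutations))
})

test_that("cohort composition follows the configured design", {
  cfg <- simulation_config(n_patients_H = 12, n_patients_L = 8,
                           n_regions = 3, n_mutations_mean = 10,
                           n_windows = 10, n_genes = 5, seed = 2)
  sim <- simulate_cohort(cfg)
  s <- sim$bundle$samples
  expect_equal(length(unique(s$patient_id)), 20L)
  expect_equal(nrow(s), 80L)  # 3 tumor + 1 normal per patient
  expect_equal(sum(s$tissue == "normal"), 20L)
  subtypes <- vapply(sim$truth$patients, `[[`, character(1), "subtype")
  expect_equal(as.integer(table(subtypes)[c("H", "L")]), c(12L, 8L))
  tum <- s[s$tissue == "tumor", ]
  expect_true(all(tum$purity >= 0.3 & tum$purity <= 0.8))
})

test_that("realized trunk proportion concentrates around the target", {
  cfg <- simulation_config(trunk_fraction_H = 0.7, n_mutations_mean = 200,
                           n_windows = 10, n_genes = 10, seed = 7)
  sim <- simulate_patient(cfg, 1, "H", seed = 7)
  tr <- sim$truth$mutations
  n <- sum(!tr$contaminant)
  sd3 <- 3 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(tr$trunk_fraction_true - 0.7), sd3)
})

test_that("fully truncal tumors give zero ITH; private branches give one", {
  cfg1 <- simulation_config(trunk_fraction_H = 1, error_rate = 0,
                            pop_contam_rate = 0, n_mutations_mean = 60,
                            n_windows = 10, n_genes = 10, seed = 15)
  sim1 <- simulate_patient(cfg1, 1, "H", seed = 15)
  vs1 <- variant_sets_from_sim(sim1)
  ith1 <- pairwise_ith(vs1$sets, "mutational")
  expect_equal(ith1$pairs$distance, rep(0, 3))

  # with 2 regions every proper subset is private, so ITH hits 1
  cfg0 <- simulation_config(trunk_fraction_H = 0, error_rate = 0,
                            pop_contam_rate = 0, n_regions = 2,
                            n_mutations_mean = 60, n_windows = 10,
                            n_genes = 10, seed = 16)
  sim0 <- simulate_patient(cfg0, 1, "H", seed = 16)
  vs0 <- variant_sets_from_sim(sim0)
  expect_equal(pairwise_ith(vs0$sets, "mutational")$pairs$distance, 1)
})

test_that("H-like patients carry more truncal mutations than L-like", {
  cfg <- simulation_config(n_patients_H = 12, n_patients_L = 8,
                           n_mutations_mean = 60, n_windows = 10,
                           n_genes = 10, seed = 23)
  sim <- simulate_cohort(cfg)
  tf <- vapply(sim$truth$patients, function(t)
    t$mutations$trunk_fraction_true, numeric(1))
  st <- vapply(sim$truth$patients, `[[`, character(1), "subtype")
  expect_gt(mean(tf[st == "H"]), mean(tf[st == "L"]))
})

test_that("population-frequency contaminants exercise the germline filter", {
  cfg <- simulation_config(pop_contam_rate = 0.3, n_mutations_mean = 150,
                           n_windows = 10, n_genes = 10, seed = 29)
  sim <- simulate_patient(cfg, 1, "H", seed = 29)
  muts <- sim$bundle$mutations
  expect_true(any(muts$pop_freq > 0.01))
  kept <- filter_calls(muts)
  expect_true(all(kept$pop_freq <= 0.01))
  # contaminants flagged in truth are exactly the high-frequency ones
  tr <- sim$truth$mutations
  high <- unique(muts$pop_freq[muts$pop_freq > 0.01])
  expect_equal(sum(tr$contaminant) > 0, length(high) > 0)
})

test_that("survival hazard groups follow the genetic-ITH class", {
  cfg <- small_cfg(seed = 37)
  sim <- simulate_cohort(cfg)
  grp <- vapply(sim$truth$patients, `[[`, character(1), "hazard_group")
  st <- vapply(sim$truth$patients, `[[`, character(1), "subtype")
  # L-like tumors (low trunk fraction) are the high-ITH hazard group
  expect_true(all(grp[st == "L"] == "high"))
  expect_true(all(grp[st == "H"] == "low"))
  cl <- sim$bundle$clinical
  expect_true(all(cl$os_months >= 0))
  expect_true(all(cl$os_event %in% 0:1))
})
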