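test_that("sample QC applies strict thresholds on the failing side", {
  s <- make_samples(k = 3)
  # boundary values pass: qscore 35, contamination 0.02, depth 30
  s$qscore <- c(35, 34.9, 40, 40)
  s$contamination <- c(0.02, 0.005, 0.021, 0.005)
  s$mean_depth <- c(30, 250, 250, 29.9)
  qc <- qc_filter_samples(s)
  expect_equal(qc$kept$region_id, "P01_R1")
  expect_setequal(qc$excluded$region_id, c("P01_R2", "P01_R3", "P01_N"))
  expect_equal(qc$excluded$reason[qc$excluded$region_id == "P01_R2"],
               "qscore<35")
  s$qscore[2] <- NA
  expect_equal(qc_filter_samples(s)$excluded$reason[1], "missing_metric")
  empty <- qc_filter_samples(s[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$excluded), 0L)
})

test_that("call filter enforces read-support and population-frequency rules", {
  calls <- rbind(
    make_calls("R1", 1, 6),                            # SNV at boundary
    make_calls("R1", 2, 5),                            # SNV below
    make_calls("R1", 3, 7, ref = "AT", alt = "A"),     # indel below
    make_calls("R1", 4, 8, ref = "AT", alt = "A"),     # indel at boundary
    make_calls("R1", 5, 50, pop_freq = 0.02),          # germline frequency
    make_calls("R1", 6, 50, pop_freq = 0.01)           # 1% is not > 1%
  )
  kept <- filter_calls(calls)
  expect_equal(kept$pos, c(1, 4, 6))
  expect_error(filter_calls(make_calls("R1", 1, -2)), "negative")
  expect_equal(nrow(filter_calls(calls[0, ])), 0L)
})

test_that("cross-region rescue adds regions with raw support only", {
  raw <- rbind(make_calls("P01_R1", 100, 10),
               make_calls("P01_R2", 100, 1),
               make_calls("P01_R3", 100, 0),
               make_calls("P01_R1", 200, 3),  # passes nowhere
               make_calls("P01_R2", 200, 2))
  passing <- filter_calls(raw)
  out <- rescue_across_regions(passing, raw)
  expect_setequal(out$region_id[out$pos == 100], c("P01_R1", "P01_R2"))
  expect_true(out$rescued[out$region_id == "P01_R2" & out$pos == 100])
  expect_false(any(out$pos == 200))
  # monotone: output contains every passing call
  expect_true(all(paste(passing$region_id, passing$pos) %in%
                    paste(out$region_id, out$pos)))
  # idempotent: rescuing the rescued set changes nothing
  out2 <- rescue_across_regions(out[, names(raw)], raw)
  expect_equal(sort(paste(out2$region_id, out2$pos)),
               sort(paste(out$region_id, out$pos)))
  # variant passing in all regions is untouched
  raw3 <- rbind(make_calls("P01_R1", 300, 10), make_calls("P01_R2", 300, 9))
  out3 <- rescue_across_regions(filter_calls(raw3), raw3)
  expect_equal(nrow(out3), 2L)
  expect_false(any(out3$rescued))
})

test_that("rescue never crosses patients", {
  raw <- rbind(make_calls("P01_R1", 100, 10, patient_id = "P01"),
               make_calls("P02_R1", 100, 3, patient_id = "P02"))
  out <- rescue_across_regions(filter_calls(raw), raw)
  expect_equal(out$region_id, "P01_R1")
})

test_that("trunk/branch classification counts all-region sharing", {
  calls <- rbind(make_calls("P01_R1", 1, 20), make_calls("P01_R2", 1, 20),
                 make_calls("P01_R3", 1, 20),
                 make_calls("P01_R1", 2, 20))
  pm <- patient_mutation_set(calls, c("P01_R1", "P01_R2", "P01_R3"))
  cls <- classify_trunk_branch(pm)
  expect_equal(unname(cls$labels), c("trunk", "branch"))
  expect_equal(cls$trunk_proportion, 0.5)
  expect_equal(cls$trunk_proportion + cls$branch_proportion, 1)

  # 6 trunk + 2 branch -> 0.75
  calls2 <- do.call(rbind, c(
    lapply(1:6, function(i) rbind(make_calls("P01_R1", i, 20),
                                  make_calls("P01_R2", i, 20))),
    lapply(7:8, function(i) make_calls("P01_R1", i, 20))))
  pm2 <- patient_mutation_set(calls2, c("P01_R1", "P01_R2"))
  expect_equal(classify_trunk_branch(pm2)$trunk_proportion, 0.75)

  # zero variants -> proportions missing, not 0/0
  pm0 <- patient_mutation_set(calls[0, ], c("P01_R1", "P01_R2"))
  cls0 <- classify_trunk_branch(pm0)
  expect_true(is.na(cls0$trunk_proportion))
  expect_error(classify_trunk_branch(
    patient_mutation_set(calls[0, ], "P01_R1")), ">= 2")
})

test_that("filter-rescue-classify recovers simulated clone labels exactly", {
  cfg <- simulation_config(error_rate = 0, pop_contam_rate = 0,
                           n_mutations_mean = 150, n_windows = 10,
                           n_genes = 10, seed = 5)
  sim <- simulate_patient(cfg, 1, "L", seed = 123)
  vs <- variant_sets_from_sim(sim)
  cls <- classify_trunk_branch(vs$pm)
  truth <- sim$truth$mutations
  expect_equal(unname(cls$labels[truth$key]),
               ifelse(truth$is_trunk, "trunk", "branch"))
  expect_equal(cls$trunk_proportion, truth$trunk_fraction_true)
})

test_that("TMB counts missense mutations over the covered exome", {
  calls <- rbind(make_calls("R1", 1:3, 20, variant_class = "missense"),
                 make_calls("R1", 4:5, 20, variant_class = "synonymous"))
  t <- compute_tmb(calls)
  expect_equal(t$missense_count, 3)
  expect_equal(t$exonic_per_mb, 5 / 39)
  expect_equal(compute_tmb(make_calls("R1", 1:78, 20,
                                      variant_class = "missense"))$missense_per_mb,
               2.0)
  t0 <- compute_tmb(calls[0, ])
  expect_equal(unlist(t0), c(missense_count = 0, missense_per_mb = 0,
                             exonic_per_mb = 0))
})

test_that("driver fractions are computed per side and compared cohort-wide", {
  calls <- rbind(
    make_calls("P01_R1", 1:2, 20, driver_role = "oncogene"),
    make_calls("P01_R2", 1:2, 20, driver_role = "oncogene"),
    make_calls("P01_R1", 3:4, 20, driver_role = "passenger"),
    make_calls("P01_R2", 3:4, 20, driver_role = "passenger"),
    make_calls("P01_R1", 5, 20, driver_role = "TSG"))
  de <- driver_enrichment(list(P01 = calls),
                          list(P01 = c("P01_R1", "P01_R2")))
  expect_equal(de$per_patient$trunk_driver_fraction, 0.5)
  expect_equal(de$per_patient$branch_driver_fraction, 1)
  # no drivers anywhere -> both 0
  calls2 <- rbind(make_calls("P01_R1", 1, 20), make_calls("P01_R2", 1, 20),
                  make_calls("P01_R1", 2, 20))
  de2 <- driver_enrichment(list(P01 = calls2),
                           list(P01 = c("P01_R1", "P01_R2")))
  expect_equal(de2$per_patient$trunk_driver_fraction, 0)
  expect_equal(de2$per_patient$branch_driver_fraction, 0)
})

test_that("trunk driver enrichment emerges from the configured odds boost", {
  hits <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_patients_H = 4, n_patients_L = 0,
                             n_mutations_mean = 100, driver_fraction = 0.05,
                             trunk_driver_enrichment = 3, n_windows = 10,
                             n_genes = 10, seed = 1000 + s)
    sim <- simulate_cohort(cfg)
    calls <- split(sim$bundle$mutations, sim$bundle$mutations$patient_id)
    calls <- lapply(calls, function(cl)
      rescue_across_regions(filter_calls(cl), cl))
    regions <- lapply(split(sim$bundle$samples,
                            sim$bundle$samples$patient_id),
                      function(s) s$region_id[s$tissue == "tumor"])
    de <- driver_enrichment(calls, regions)
    mean(de$per_patient$trunk_driver_fraction, na.rm = TRUE) >
      mean(de$per_patient$branch_driver_fraction, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("signature matching ranks by cosine with a strict threshold", {
  catalog <- cbind(SBS1 = c(1, 0, 0, 0), SBS2 = c(0, 1, 1, 0),
                   SBS3 = c(0, 0, 0, 1))
  m <- match_signature(catalog[, "SBS1"], catalog)
  expect_equal(m$signature[1], "SBS1")
  expect_equal(m$cosine[1], 1)
  expect_true(m$matched[1])
  # orthogonal to every reference -> no matches
  expect_false(any(match_signature(c(0, 1, 0, 0),
                                   catalog[, c("SBS1", "SBS3")])$matched))
  # equal mixture of two disjoint-support, equal-norm references
  refA <- c(1, 1, 0, 0) / sqrt(2); refB <- c(0, 0, 1, 1) / sqrt(2)
  mm <- match_signature(0.5 * refA + 0.5 * refB, cbind(A = refA, B = refB))
  expect_equal(mm$cosine[1], mm$cosine[2])
  expect_equal(mm$cosine[1], sqrt(0.5), tolerance = 1e-12)
  expect_true(all(mm$matched))
  expect_error(match_signature(c(0, 0, 0, 0), catalog), "zero-norm")
})
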