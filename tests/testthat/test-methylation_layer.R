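make_cpgs <- function(pos, meth, total, region = "R1") {
  data.frame(region_id = region, chrom = "chr1", pos = pos,
             methylated_count = meth, total_count = total,
             stringsAsFactors = FALSE)
}

test_that("window binning pools CpG counts into tiling windows", {
  w <- bin_windows(make_cpgs(50, 3, 10), window_size = 100, step = 100)
  expect_equal(nrow(w), 1L)
  expect_equal(w$beta, 0.3)
  expect_equal(c(w$start, w$end), c(0, 100))

  # two CpGs in one window pool to 6/20
  w2 <- bin_windows(make_cpgs(c(10, 90), c(2, 4), c(10, 10)))
  expect_equal(w2$beta, 0.3)
  expect_equal(w2$methylated_count, 6)

  # window with no CpGs is absent; low-coverage windows dropped
  w3 <- bin_windows(make_cpgs(c(10, 250), c(2, 1), c(10, 3)))
  expect_equal(w3$start, 0)   # window [200,300) has 3 < 5 reads
})

test_that("sliding windows assign CpGs to every covering window", {
  w <- bin_windows(make_cpgs(120, 5, 10), window_size = 100, step = 50)
  expect_setequal(w$start, c(50, 100))
  expect_true(all(w$beta == 0.5))
})

test_that("binning conserves total counts over retained CpGs", {
  set.seed(13)
  cpgs <- make_cpgs(sample(0:999, 60), stats::rbinom(60, 20, 0.3),
                    rep(20, 60))
  w <- bin_windows(cpgs, window_size = 100, step = 100, min_coverage = 0)
  expect_equal(sum(w$total_count), sum(cpgs$total_count))
  expect_equal(sum(w$methylated_count), sum(cpgs$methylated_count))
})

test_that("purity correction inverts the two-component mixture", {
  expect_equal(purity_correct(c(0.3, 0.9), 1, c(0.5, 0.1)), c(0.3, 0.9))
  expect_equal(purity_correct(0.6, 0.8, 0.2), 0.7)
  expect_equal(purity_correct(0.1, 0.5, 0.5), 0)   # raw -0.3 clamped
  expect_equal(purity_correct(5, 0.5, 2, layer = "expression"), 8)
  expect_error(purity_correct(0.5, 0, 0.5), "purity")
  expect_error(purity_correct(c(0.5, 0.2), 0.5, 0.5), "length")
})

test_that("correction exactly inverts the simulator's purity mixing", {
  cfg <- simulation_config(n_windows = 200, seed = 3, n_mutations_mean = 10,
                           n_genes = 10)
  sim <- simulate_patient(cfg, 1, "H", seed = 41)
  tm <- sim$truth$methylation
  purity <- sim$truth$purity
  for (r in names(purity)) {
    corrected <- purity_correct(tm$observed_beta[r, ], purity[[r]],
                                tm$normal_beta)
    expect_equal(corrected, tm$tumor_beta[r, ], tolerance = 1e-12)
  }
})

test_that("corrected window betas beat uncorrected ones on DMR windows", {
  cfg <- simulation_config(n_windows = 300, seed = 19,
                           n_mutations_mean = 10, n_genes = 10)
  sim <- simulate_patient(cfg, 1, "L", seed = 57)
  b <- sim$bundle$methylation
  tm <- sim$truth$methylation
  purity <- sim$truth$purity
  nid <- sim$bundle$samples$region_id[sim$bundle$samples$tissue == "normal"]
  nb <- b[b$region_id == nid, ]
  normal_obs <- nb$methylated_count / nb$total_count
  err_cor <- err_obs <- c()
  for (r in names(purity)) {
    rb <- b[b$region_id == r, ]
    obs <- rb$methylated_count / rb$total_count
    cor <- purity_correct(obs, purity[[r]], normal_obs)
    dmr <- tm$dmr
    err_cor <- c(err_cor, abs(cor[dmr] - tm$tumor_beta[r, dmr]))
    err_obs <- c(err_obs, abs(obs[dmr] - tm$tumor_beta[r, dmr]))
  }
  expect_lt(mean(err_cor), mean(err_obs))
})

test_that("the DMR caller applies both the effect-size and FDR rules", {
  win <- function(region, start, meth, total) {
    data.frame(region_id = region, chrom = "chr1", start = start,
               end = start + 100, methylated_count = meth,
               total_count = total, stringsAsFactors = FALSE)
  }
  # identical counts -> nothing called
  t0 <- rbind(win("T1", 0, 50, 100), win("T1", 100, 20, 100))
  expect_false(any(call_dmr_simple(t0, t0)$dmr))

  # large difference -> hypermethylated DMR; oracle via fisher.test
  tum <- win("T1", 0, 90, 100)
  nrm <- win("N1", 0, 10, 100)
  d <- call_dmr_simple(tum, nrm)
  expect_true(d$dmr)
  expect_equal(d$direction, "hyper")
  expect_equal(d$delta_beta, 0.8)
  p_oracle <- stats::fisher.test(matrix(c(90, 10, 10, 90), 2))$p.value
  expect_equal(d$p, p_oracle)
  expect_lt(d$p, 1e-6)

  # highly significant but delta 0.19: fails the minimum-difference rule
  t19 <- win("T1", 0, 3900, 10000)
  n19 <- win("N1", 0, 2000, 10000)
  d19 <- call_dmr_simple(t19, n19)
  expect_equal(d19$delta_beta, 0.19)
  expect_lt(d19$q, 0.001)
  expect_false(d19$dmr)

  # hypomethylated direction
  dh <- call_dmr_simple(win("T1", 0, 10, 100), win("N1", 0, 90, 100))
  expect_equal(dh$direction, "hypo")

  # counts pooled across samples within a group
  t2 <- rbind(win("T1", 0, 45, 50), win("T2", 0, 45, 50))
  d2 <- call_dmr_simple(t2, nrm)
  expect_equal(d2$beta_tumor, 0.9)
})
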