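# Independent oracles used to validate the package implementations.

# Jensen-Shannon distance computed term by term, base-2 logs, 0*log0 = 0.
jsd_oracle <- function(p1, p2) {
  r <- (p1 + p2) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) {
      if (a[i] > 0) s <- s + a[i] * (log(a[i] / b[i]) / log(2))
    }
    s
  }
  sqrt(0.5 * (kl(p1, r) + kl(p2, r)))
}

# Product-limit estimator computed by explicit looping over event times.
km_oracle <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (j in seq_along(ut)) {
    at_risk <- sum(times >= ut[j])
    d <- sum(times == ut[j] & events == 1)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    out$surv[j] <- s
  }
  out
}

# Random unrooted binary tree with strictly positive branch lengths and its
# additive (path) distance matrix.
random_additive_tree <- function(n_leaves, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_leaves, rooted = FALSE,
                    tip.label = paste0("L", seq_len(n_leaves)))
  phy$edge.length <- stats::runif(length(phy$edge.length), 0.5, 3)
  list(phy = phy, dm = stats::cophenetic(phy))
}

# Small valid samples table: k tumor regions + 1 normal for one patient.
make_samples <- function(pid = "P01", k = 3, purity = rep(0.6, k)) {
  data.frame(
    patient_id = pid,
    region_id = c(paste0(pid, "_R", seq_len(k)), paste0(pid, "_N")),
    tissue = c(rep("tumor", k), "normal"),
    purity = c(purity, NA),
    mean_depth = rep(250, k + 1),
    qscore = rep(40, k + 1),
    contamination = rep(0.005, k + 1),
    stringsAsFactors = FALSE
  )
}

# Minimal somatic call row(s).
make_calls <- function(region_id, pos, alt_reads, patient_id = "P01",
                       ref = "A", alt = "T", gene = "GENE1",
                       variant_class = "missense", pop_freq = 0,
                       driver_role = "passenger") {
  data.frame(patient_id = patient_id, region_id = region_id,
             chrom = "chr1", pos = pos, ref = ref, alt = alt, gene = gene,
             variant_class = variant_class, alt_reads = alt_reads,
             ref_reads = 250 - alt_reads, pop_freq = pop_freq,
             driver_role = driver_role, stringsAsFactors = FALSE)
}

# Post-rescue per-region variant sets for one simulated patient.
variant_sets_from_sim <- function(sim_patient) {
  b <- sim_patient$bundle
  regions <- b$samples$region_id[b$samples$tissue == "tumor"]
  raw <- b$mutations
  passing <- filter_calls(raw)
  rescued <- rescue_across_regions(passing, raw)
  pm <- patient_mutation_set(rescued, regions)
  list(pm = pm,
       sets = lapply(stats::setNames(regions, regions), function(r)
         pm$variants[pm$presence[r, ] == 1L]))
}
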