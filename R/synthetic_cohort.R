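#' Configuration for the synthetic multi-region cohort generator
#'
#' Collects and validates every knob of the generative model. Defaults
#' emulate the study design the package targets: two histological subtypes
#' with very different clonal architecture (H-like tumors mostly truncal,
#' median trunk fraction 0.663; L-like tumors mostly branched, trunk
#' fraction 0.172), three sampled tumor regions plus one matched normal per
#' patient, exome-like mutation counts, 250x/75x tumor/normal sequencing
#' depth, purity-mixed methylation and expression profiles, and survival
#' with a group-dependent hazard tied to the genetic-ITH class.
#'
#' @param n_patients_H,n_patients_L patients per subtype.
#' @param n_regions tumor regions per patient (>= 2).
#' @param trunk_fraction_H,trunk_fraction_L probability that a somatic
#'   mutation is truncal (present in every region) in each subtype.
#' @param n_mutations_mean Poisson mean of somatic mutations per patient.
#' @param driver_fraction baseline probability a mutation hits a driver
#'   gene; on the trunk its odds are multiplied by
#'   \code{trunk_driver_enrichment}.
#' @param trunk_driver_enrichment odds multiplier for drivers on the trunk.
#' @param purity_range tumor purity drawn uniformly from this interval.
#' @param tumor_depth,normal_depth mean sequencing depth (x).
#' @param error_rate per-site probability parameter of sporadic
#'   alt-supporting reads in non-carrying regions (residual artifact rate in
#'   candidate call tables); exercises the cross-region rescue rule.
#' @param pop_contam_rate fraction of mutations given population frequency
#'   above 1% to exercise the germline filter.
#' @param n_windows methylation windows per patient.
#' @param dmr_fraction fraction of windows differentially methylated in
#'   tumor.
#' @param dmr_shift absolute beta-value shift of tumor DMR windows.
#' @param meth_window_depth mean pooled reads per window (CpGs pooled).
#' @param n_genes expression genes.
#' @param de_fraction fraction of genes with a tumor fold-change.
#' @param n_cnv_events_mean Poisson mean of arm-level CNV events per
#'   patient.
#' @param segments_per_arm segments simulated per chromosome arm and
#'   region.
#' @param cnv_noise_rate per-segment probability of a sporadic state flip.
#' @param hazard_ratio_highITH hazard ratio of the high-genetic-ITH group
#'   relative to the low group (values below 1 give high-ITH patients
#'   better outcomes).
#' @param base_hazard baseline event hazard per month.
#' @param censor_rate target fraction of censored observations.
#' @param seed master seed; per-patient substreams are derived from it.
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_patients_H = 12, n_patients_L = 8,
                              n_regions = 3,
                              trunk_fraction_H = 0.663,
                              trunk_fraction_L = 0.172,
                              n_mutations_mean = 100,
                              driver_fraction = 0.05,
                              trunk_driver_enrichment = 3,
                              purity_range = c(0.3, 0.8),
                              tumor_depth = 250, normal_depth = 75,
                              error_rate = 1e-4,
                              pop_contam_rate = 0.02,
                              n_windows = 300, dmr_fraction = 0.1,
                              dmr_shift = 0.3, meth_window_depth = 300,
                              n_genes = 500, de_fraction = 0.1,
                              n_cnv_events_mean = 4, segments_per_arm = 10,
                              cnv_noise_rate = 0.05,
                              hazard_ratio_highITH = 0.5,
                              base_hazard = 0.02, censor_rate = 0.2,
                              seed = 1) {
  cfg <- as.list(environment())
  fr <- c("trunk_fraction_H", "trunk_fraction_L", "driver_fraction",
          "pop_contam_rate", "dmr_fraction", "de_fraction",
          "cnv_noise_rate", "censor_rate", "error_rate")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must be in [0, 1]")
  }
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (tumor_depth < 1 || normal_depth < 1) stop("depths must be >= 1")
  if (length(purity_range) != 2L || purity_range[1] <= 0 ||
      purity_range[2] > 1 || purity_range[1] > purity_range[2]) {
    stop("purity_range must be an interval within (0, 1]")
  }
  if (hazard_ratio_highITH <= 0 || base_hazard <= 0) {
    stop("hazards must be positive")
  }
  class(cfg) <- "simulation_config"
  cfg
}

# deterministic per-patient substream seed, kept below 2^31
.patient_seed <- function(master_seed, patient_index) {
  as.integer((as.numeric(master_seed) %% 65011 + 1) * 20011 +
               patient_index * 104729) %% 2147483647L
}

# uniformly chosen non-empty proper subset of 1..k (bitmask over 1..2^k-2)
.random_proper_subset <- function(k) {
  m <- sample.int(2L^k - 2L, 1L)
  which(bitwAnd(m, 2L^(seq_len(k) - 1L)) > 0L)
}

.variant_classes <- c(missense = 0.55, synonymous = 0.20, nonsense = 0.05,
                      splice = 0.05, frameshift_indel = 0.07,
                      inframe_indel = 0.03, other = 0.05)

# censoring window upper bound m with P(censor) = target for Exp(hazard)
# event times and U(0, m) censoring: (1 - exp(-h m)) / (h m) = target.
.censor_bound <- function(hazard, target) {
  if (target <= 0) return(Inf)
  f <- function(u) (1 - exp(-u)) / u - target
  u <- stats::uniroot(f, c(1e-8, 500))$root
  u / hazard
}

#' Simulate one patient's multi-region multi-omic data
#'
#' Draws one patient under the generative model: region purities uniform in
#' \code{purity_range}; a Poisson number of somatic mutations, each truncal
#' with the subtype's trunk probability or else assigned a uniformly chosen
#' non-empty proper subset of regions; binomial read counts at the sample's
#' depth with success probability purity/2 in carrying regions and
#' \code{error_rate} elsewhere; arm-level CNV events with the same
#' trunk/branch structure; methylation windows whose observed beta is the
#' purity mixture of the tumor and normal components with binomial read
#' sampling; purity-mixed log-normal expression; and exponential survival
#' with the hazard scaled for the high-genetic-ITH group, censored
#' uniformly.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param patient_index integer used for ids and the derived substream.
#' @param subtype \code{"H"} or \code{"L"}.
#' @param seed substream seed (derived from the master seed by
#'   \code{\link{simulate_cohort}}).
#' @return List with \code{bundle} (per-patient slice: \code{samples},
#'   \code{mutations}, \code{segments}, \code{methylation},
#'   \code{expression}, \code{clinical}) and \code{truth} (clone labels,
#'   true betas, true ITH, hazard group).
#' @export
simulate_patient <- function(config, patient_index, subtype = c("H", "L"),
                             seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  subtype <- match.arg(subtype)
  if (is.null(seed)) seed <- .patient_seed(config$seed, patient_index)
  set.seed(seed)
  k <- config$n_regions
  pid <- sprintf("P%02d", patient_index)
  regions <- paste0(pid, "_R", seq_len(k))
  normal_id <- paste0(pid, "_N")
  trunk_fraction <- if (subtype == "H") config$trunk_fraction_H else
    config$trunk_fraction_L

  purity <- stats::runif(k, config$purity_range[1], config$purity_range[2])
  depth_t <- pmax(1, round(stats::rnorm(k, config$tumor_depth,
                                        0.05 * config$tumor_depth)))
  depth_n <- max(1, round(stats::rnorm(1, config$normal_depth,
                                       0.05 * config$normal_depth)))
  samples <- data.frame(
    patient_id = pid,
    region_id = c(regions, normal_id),
    tissue = c(rep("tumor", k), "normal"),
    purity = c(purity, NA_real_),
    mean_depth = c(depth_t, depth_n),
    qscore = stats::runif(k + 1, 36, 45),
    contamination = stats::runif(k + 1, 0, 0.01),
    stringsAsFactors = FALSE
  )

  ## --- somatic mutations -------------------------------------------------
  n_mut <- stats::rpois(1, config$n_mutations_mean)
  mut_rows <- list()
  truth_mut <- NULL
  if (n_mut > 0) {
    is_trunk <- stats::runif(n_mut) < trunk_fraction
    carriers <- lapply(seq_len(n_mut), function(i) {
      if (is_trunk[i]) seq_len(k) else .random_proper_subset(k)
    })
    # driver assignment: odds multiplied on the trunk, then renormalised
    p0 <- config$driver_fraction
    odds <- p0 / (1 - p0) * config$trunk_driver_enrichment
    p_trunk_driver <- odds / (1 + odds)
    p_driver <- ifelse(is_trunk, p_trunk_driver, p0)
    is_driver <- stats::runif(n_mut) < p_driver
    driver_role <- ifelse(
      is_driver, sample(c("oncogene", "TSG"), n_mut, replace = TRUE),
      "passenger")
    vclass <- sample(names(.variant_classes), n_mut, replace = TRUE,
                     prob = .variant_classes)
    is_indel_class <- vclass %in% c("frameshift_indel", "inframe_indel")
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_mut, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                  character(1))
    ins <- stats::runif(n_mut) < 0.5
    ref[is_indel_class & !ins] <- paste0(ref[is_indel_class & !ins], "T")
    alt[is_indel_class & ins] <- paste0(ref[is_indel_class & ins], "G")
    alt[is_indel_class & !ins] <- substr(ref[is_indel_class & !ins], 1, 1)
    chrom <- paste0("chr", sample(1:4, n_mut, replace = TRUE))
    pos <- patient_index * 10^6 + sample.int(9 * 10^5, n_mut)
    gene <- ifelse(is_driver,
                   sprintf("DRV%03d", sample.int(50, n_mut, replace = TRUE)),
                   sprintf("GENE%04d",
                           sample.int(5000, n_mut, replace = TRUE)))
    contaminant <- stats::runif(n_mut) < config$pop_contam_rate
    pop_freq <- ifelse(contaminant, stats::runif(n_mut, 0.02, 0.3), 0)

    for (r in seq_len(k)) {
      carrying <- vapply(carriers, function(s) r %in% s, logical(1))
      alt_reads <- integer(n_mut)
      alt_reads[carrying] <- stats::rbinom(sum(carrying), depth_t[r],
                                           purity[r] / 2)
      alt_reads[!carrying] <- stats::rbinom(sum(!carrying), depth_t[r],
                                            config$error_rate)
      mut_rows[[r]] <- data.frame(
        patient_id = pid, region_id = regions[r], chrom = chrom, pos = pos,
        ref = ref, alt = alt, gene = gene, variant_class = vclass,
        alt_reads = alt_reads, ref_reads = depth_t[r] - alt_reads,
        pop_freq = pop_freq, driver_role = driver_role,
        stringsAsFactors = FALSE
      )
    }
    key <- paste(chrom, pos, ref, alt, sep = ":")
    real <- !contaminant
    presence <- vapply(seq_len(k), function(r)
      vapply(carriers, function(s) r %in% s, logical(1)), logical(n_mut))
    presence <- matrix(presence, nrow = n_mut)
    true_pairs <- utils::combn(k, 2L)
    true_jaccard <- apply(true_pairs, 2L, function(ij) {
      a <- key[real & presence[, ij[1]]]
      b <- key[real & presence[, ij[2]]]
      jaccard_distance(a, b)
    })
    truth_mut <- list(
      key = key,
      clone = ifelse(is_trunk, "trunk",
                     vapply(carriers, paste, character(1), collapse = ",")),
      is_trunk = is_trunk, contaminant = contaminant,
      trunk_fraction_true = if (any(real)) mean(is_trunk[real]) else
        NA_real_,
      pairwise_jaccard = data.frame(
        region_a = regions[true_pairs[1L, ]],
        region_b = regions[true_pairs[2L, ]],
        distance = true_jaccard, stringsAsFactors = FALSE),
      mean_jaccard = mean(true_jaccard, na.rm = TRUE)
    )
  } else {
    truth_mut <- list(key = character(0), clone = character(0),
                      is_trunk = logical(0), contaminant = logical(0),
                      trunk_fraction_true = NA_real_,
                      pairwise_jaccard = NULL, mean_jaccard = NA_real_)
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    .empty_mutations()

  ## --- copy number -------------------------------------------------------
  arms <- synthetic_arm_table()
  n_ev <- min(stats::rpois(1, config$n_cnv_events_mean), nrow(arms))
  ev_arm <- if (n_ev > 0) sample(arms$arm, n_ev) else character(0)
  ev_dir <- sample(c("gain", "loss"), n_ev, replace = TRUE)
  ev_trunk <- stats::runif(n_ev) < trunk_fraction
  ev_carriers <- lapply(seq_len(n_ev), function(i) {
    if (ev_trunk[i]) seq_len(k) else .random_proper_subset(k)
  })
  spa <- config$segments_per_arm
  seg_rows <- list()
  for (r in seq_len(k)) {
    for (a in seq_len(nrow(arms))) {
      bounds <- round(seq(arms$start[a], arms$end[a], length.out = spa + 1))
      state <- rep("neutral", spa)
      hit <- which(ev_arm == arms$arm[a] &
                     vapply(ev_carriers, function(s) r %in% s, logical(1)))
      if (length(hit)) {
        n_set <- ceiling(0.8 * spa)
        state[seq_len(n_set)] <-
          ifelse(ev_dir[hit[1L]] == "gain", "amp", "del")
      }
      flip <- state == "neutral" & stats::runif(spa) < config$cnv_noise_rate
      state[flip] <- sample(c("amp", "del"), sum(flip), replace = TRUE)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        region_id = regions[r], chrom = arms$chrom[a],
        start = bounds[-(spa + 1)], end = bounds[-1], state = state,
        arm = arms$arm[a], stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_rows)
  ev_key <- paste(ev_arm, ev_dir, sep = ":")
  truth_cnv <- list(
    events = data.frame(arm = ev_arm, direction = ev_dir,
                        trunk = ev_trunk, stringsAsFactors = FALSE),
    carriers = ev_carriers,
    region_events = lapply(seq_len(k), function(r)
      ev_key[vapply(ev_carriers, function(s) r %in% s, logical(1))])
  )

  ## --- methylation -------------------------------------------------------
  nw <- config$n_windows
  normal_beta <- stats::rbeta(nw, 2, 8)
  dmr <- stats::runif(nw) < config$dmr_fraction
  shift_sign <- sample(c(1, -1), nw, replace = TRUE)
  shifted <- pmin(pmax(normal_beta + shift_sign * config$dmr_shift, 0.02),
                  0.98)
  dmr_trunk <- stats::runif(nw) < trunk_fraction
  dmr_carriers <- lapply(seq_len(nw), function(i) {
    if (!dmr[i]) integer(0) else
      if (dmr_trunk[i]) seq_len(k) else .random_proper_subset(k)
  })
  tumor_beta <- matrix(rep(normal_beta, k), nrow = k, byrow = TRUE)
  for (i in which(dmr)) tumor_beta[dmr_carriers[[i]], i] <- shifted[i]
  observed_beta <- purity * tumor_beta +
    (1 - purity) * matrix(rep(normal_beta, k), nrow = k, byrow = TRUE)
  meth_rows <- list()
  win_start <- (seq_len(nw) - 1L) * 100
  for (r in seq_len(k)) {
    total <- stats::rpois(nw, config$meth_window_depth)
    meth <- stats::rbinom(nw, total, observed_beta[r, ])
    meth_rows[[r]] <- data.frame(
      region_id = regions[r], chrom = "chr1", start = win_start,
      end = win_start + 100, methylated_count = meth, total_count = total,
      stringsAsFactors = FALSE)
  }
  total_n <- stats::rpois(nw, config$meth_window_depth)
  meth_rows[[k + 1L]] <- data.frame(
    region_id = normal_id, chrom = "chr1", start = win_start,
    end = win_start + 100,
    methylated_count = stats::rbinom(nw, total_n, normal_beta),
    total_count = total_n, stringsAsFactors = FALSE)
  methylation <- do.call(rbind, meth_rows)
  rownames(tumor_beta) <- regions
  rownames(observed_beta) <- regions
  truth_meth <- list(normal_beta = normal_beta, tumor_beta = tumor_beta,
                     observed_beta = observed_beta, dmr = dmr)

  ## --- expression --------------------------------------------------------
  ng <- config$n_genes
  genes <- sprintf("G%04d", seq_len(ng))
  baseline <- stats::rlnorm(ng, log(10), 1)
  de <- stats::runif(ng) < config$de_fraction
  fold <- rep(1, ng)
  fold[de] <- 2^stats::rnorm(sum(de), 0, 1.5)
  de_trunk <- stats::runif(ng) < trunk_fraction
  de_carriers <- lapply(seq_len(ng), function(i) {
    if (!de[i]) integer(0) else
      if (de_trunk[i]) seq_len(k) else .random_proper_subset(k)
  })
  expr <- matrix(0, nrow = ng, ncol = k + 1,
                 dimnames = list(genes, c(regions, normal_id)))
  for (r in seq_len(k)) {
    tum <- baseline
    for (i in which(de)) if (r %in% de_carriers[[i]]) tum[i] <-
        baseline[i] * fold[i]
    mixed <- purity[r] * tum + (1 - purity[r]) * baseline
    expr[, r] <- mixed * stats::rlnorm(ng, 0, 0.05)
  }
  expr[, k + 1] <- baseline * stats::rlnorm(ng, 0, 0.05)

  ## --- clinical / survival ----------------------------------------------
  high_ith <- trunk_fraction <
    mean(c(config$trunk_fraction_H, config$trunk_fraction_L))
  hazard_os <- config$base_hazard *
    ifelse(high_ith, config$hazard_ratio_highITH, 1)
  hazard_rfs <- 1.5 * hazard_os
  draw_endpoint <- function(h) {
    t_event <- stats::rexp(1, h)
    cmax <- .censor_bound(h, config$censor_rate)
    c_time <- if (is.finite(cmax)) stats::runif(1, 0, cmax) else Inf
    list(time = min(t_event, c_time), event = as.integer(t_event <= c_time))
  }
  os <- draw_endpoint(hazard_os)
  rfs <- draw_endpoint(hazard_rfs)
  clinical <- data.frame(
    patient_id = pid, subtype = subtype,
    purity_class = if (subtype == "H")
      sample(c("pure", "mixed"), 1, prob = c(1 / 3, 2 / 3)) else
        NA_character_,
    stage = sample(c("I", "II", "III"), 1, prob = c(0.7, 0.15, 0.15)),
    os_months = os$time, os_event = os$event,
    rfs_months = rfs$time, rfs_event = rfs$event,
    stringsAsFactors = FALSE
  )

  list(
    bundle = list(samples = samples, mutations = mutations,
                  segments = segments, methylation = methylation,
                  expression = expr, clinical = clinical),
    truth = list(patient_id = pid, subtype = subtype, seed = seed,
                 purity = stats::setNames(purity, regions),
                 mutations = truth_mut, cnv = truth_cnv,
                 methylation = truth_meth,
                 hazard_group = if (high_ith) "high" else "low")
  )
}

.empty_mutations <- function() {
  data.frame(patient_id = character(), region_id = character(),
             chrom = character(), pos = numeric(), ref = character(),
             alt = character(), gene = character(),
             variant_class = character(), alt_reads = numeric(),
             ref_reads = numeric(), pop_freq = numeric(),
             driver_role = character(), stringsAsFactors = FALSE)
}

#' Simulate a full multi-region cohort
#'
#' Concatenates independent per-patient simulations (H-subtype patients
#' first, then L). Each patient draws from a substream seeded
#' deterministically from the master seed, so the cohort is bit-identical
#' under a fixed seed and per-patient output does not depend on cohort
#' composition.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return List with \code{bundle} (a \code{\link{cohort_bundle}}) and
#'   \code{truth} (list with per-patient ground truth under
#'   \code{patients}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients_H + config$n_patients_L
  subtypes <- c(rep("H", config$n_patients_H),
                rep("L", config$n_patients_L))
  sims <- lapply(seq_len(n), function(i) {
    simulate_patient(config, i, subtypes[i],
                     seed = .patient_seed(config$seed, i))
  })
  bind <- function(field) do.call(rbind, lapply(sims, function(s)
    s$bundle[[field]]))
  expr <- do.call(cbind, lapply(sims, function(s) s$bundle$expression))
  bundle <- cohort_bundle(
    samples = bind("samples"), mutations = bind("mutations"),
    segments = bind("segments"), methylation = bind("methylation"),
    expression = expr, clinical = bind("clinical"),
    arms = synthetic_arm_table()
  )
  truth <- list(config = config,
                patients = stats::setNames(lapply(sims, `[[`, "truth"),
                                           vapply(sims, function(s)
                                             s$truth$patient_id,
                                             character(1))))
  list(bundle = bundle, truth = truth)
}
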