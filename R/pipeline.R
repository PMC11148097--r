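#' Run the full multi-layer ITH analysis
#'
#' Orchestrates the analysis end-to-end on a \code{\link{cohort_bundle}}:
#' sample QC, somatic-call filtering and cross-region rescue, trunk/branch
#' classification, TMB, arm-level CNV calls, purity correction of
#' methylation and expression, pairwise ITH per layer (Jaccard for
#' mutations/CNV, Jensen-Shannon for methylation/expression),
#' minimum-evolution trees per patient and layer with phylo/phyloepigenetic
#' concordance, cross-layer Spearman correlations of pairwise ITH per
#' subtype, driver trunk/branch enrichment, subtype ITH comparison, and
#' median-split survival stratification. The analysis is deterministic:
#' identical inputs give identical reports.
#'
#' @param bundle a \code{\link{cohort_bundle}}.
#' @param min_qscore,max_contamination,min_depth sample QC thresholds
#'   (see \code{\link{qc_filter_samples}}).
#' @param snv_min_reads,indel_min_reads,max_pop_freq call filter thresholds
#'   (see \code{\link{filter_calls}}).
#' @param arm_threshold arm-level call threshold
#'   (see \code{\link{call_arm_level}}).
#' @param min_window_coverage minimum pooled reads for a methylation window
#'   to enter profiles.
#' @param coverage_mb exome size for TMB.
#' @param verbose log one line per stage with record counts.
#' @return Object of class \code{ith_report}: a named list of per-stage
#'   results (see the package vignette); \code{report} holds the
#'   JSON-serialisable summary written by \code{\link{save_report}}.
#' @export
run_pipeline <- function(bundle,
                         min_qscore = 35, max_contamination = 0.02,
                         min_depth = 30,
                         snv_min_reads = 6, indel_min_reads = 8,
                         max_pop_freq = 0.01,
                         arm_threshold = 0.60,
                         min_window_coverage = 5,
                         coverage_mb = 39,
                         verbose = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  log_stage <- function(...) if (verbose) message("[ithlayers] ",
                                                  sprintf(...))

  ## --- sample QC ---------------------------------------------------------
  qc <- qc_filter_samples(bundle$samples, min_qscore, max_contamination,
                          min_depth)
  samples <- qc$kept
  log_stage("qc: %d/%d samples kept", nrow(samples), nrow(bundle$samples))
  tumor <- samples[samples$tissue == "tumor", , drop = FALSE]
  normal <- samples[samples$tissue == "normal", , drop = FALSE]
  region_patient <- stats::setNames(samples$patient_id, samples$region_id)
  patients <- unique(tumor$patient_id)
  regions_of <- lapply(stats::setNames(patients, patients), function(p)
    tumor$region_id[tumor$patient_id == p])
  analysable <- patients[vapply(regions_of, length, integer(1)) >= 2L &
                           patients %in% normal$patient_id]
  if (length(analysable) < length(patients)) {
    log_stage("qc: %d patient(s) dropped (fewer than 2 tumor regions or no normal)",
              length(patients) - length(analysable))
  }

  ## --- somatic calls: filter then rescue ---------------------------------
  raw <- bundle$mutations[bundle$mutations$region_id %in% tumor$region_id, ,
                          drop = FALSE]
  passing <- filter_calls(raw, snv_min_reads, indel_min_reads, max_pop_freq)
  rescued <- rescue_across_regions(passing, raw)
  log_stage("calls: %d raw -> %d pass -> %d after rescue",
            nrow(raw), nrow(passing), nrow(rescued))

  patient_calls <- split(rescued, rescued$patient_id)
  trunk_rows <- list()
  mut_sets <- list()
  for (p in analysable) {
    calls <- patient_calls[[p]]
    if (is.null(calls)) calls <- rescued[0, , drop = FALSE]
    pm <- patient_mutation_set(calls, regions_of[[p]])
    mut_sets[[p]] <- pm
    cls <- classify_trunk_branch(pm)
    trunk_rows[[p]] <- data.frame(
      patient_id = p, n_trunk = cls$n_trunk, n_branch = cls$n_branch,
      trunk_proportion = cls$trunk_proportion,
      branch_proportion = cls$branch_proportion, stringsAsFactors = FALSE)
  }
  trunk_branch <- do.call(rbind, c(trunk_rows, list(make.row.names = FALSE)))

  tmb <- do.call(rbind, lapply(split(rescued, rescued$region_id),
                               function(calls) {
    t <- compute_tmb(calls, coverage_mb)
    data.frame(region_id = calls$region_id[1L],
               missense_count = t$missense_count,
               missense_per_mb = t$missense_per_mb,
               exonic_per_mb = t$exonic_per_mb, stringsAsFactors = FALSE)
  }))
  rownames(tmb) <- NULL

  driver <- driver_enrichment(
    patient_calls[intersect(names(patient_calls), analysable)],
    regions_of)
  log_stage("trunk/branch + drivers: %d patients", length(analysable))

  ## --- CNV layer ---------------------------------------------------------
  arm_calls <- NULL
  cnv_sets <- list()
  if (!is.null(bundle$segments) && nrow(bundle$segments) > 0L) {
    segs <- bundle$segments[bundle$segments$region_id %in% tumor$region_id,
                            , drop = FALSE]
    arm_calls <- call_arm_level(segs, bundle$arms, arm_threshold)
    events <- arm_calls_to_events(arm_calls)
    for (p in analysable) {
      ev <- events[region_patient[events$region_id] == p, , drop = FALSE]
      cnv_sets[[p]] <- build_cnv_matrix(ev, regions_of[[p]])
    }
    log_stage("cnv: %d arm calls, %d events",
              nrow(arm_calls), nrow(events))
  }

  ## --- methylation layer -------------------------------------------------
  meth_profiles <- list()   # per patient: list(corrected matrix, normal)
  if (!is.null(bundle$methylation) && nrow(bundle$methylation) > 0L) {
    mw <- bundle$methylation
    mw <- mw[mw$total_count >= min_window_coverage &
               mw$region_id %in% samples$region_id, , drop = FALSE]
    mw$beta <- mw$methylated_count / mw$total_count
    mw$key <- paste(mw$chrom, mw$start, mw$end, sep = ":")
    for (p in analysable) {
      nid <- normal$region_id[normal$patient_id == p][1L]
      rids <- regions_of[[p]]
      sub <- mw[mw$region_id %in% c(rids, nid), , drop = FALSE]
      keys <- Reduce(intersect, split(sub$key, sub$region_id))
      if (length(keys) < 2L) next
      prof <- vapply(c(rids, nid), function(r) {
        s <- sub[sub$region_id == r, ]
        s$beta[match(keys, s$key)]
      }, numeric(length(keys)))
      rownames(prof) <- keys
      corrected <- vapply(rids, function(r) {
        purity_correct(prof[, r],
                       tumor$purity[tumor$region_id == r],
                       prof[, nid], layer = "methylation")
      }, numeric(length(keys)))
      meth_profiles[[p]] <- list(corrected = corrected,
                                 normal = prof[, nid])
    }
    log_stage("methylation: profiles for %d patients",
              length(meth_profiles))
  }

  ## --- expression layer --------------------------------------------------
  expr_profiles <- list()
  if (!is.null(bundle$expression) && NCOL(bundle$expression) > 0L) {
    ex <- bundle$expression
    for (p in analysable) {
      nid <- normal$region_id[normal$patient_id == p][1L]
      rids <- intersect(regions_of[[p]], colnames(ex))
      if (length(rids) < 2L || !(nid %in% colnames(ex))) next
      corrected <- vapply(rids, function(r) {
        purity_correct(ex[, r], tumor$purity[tumor$region_id == r],
                       ex[, nid], layer = "expression")
      }, numeric(nrow(ex)))
      rownames(corrected) <- rownames(ex)
      expr_profiles[[p]] <- list(corrected = corrected,
                                 normal = ex[, nid])
    }
    log_stage("expression: profiles for %d patients",
              length(expr_profiles))
  }

  ## --- pairwise ITH ------------------------------------------------------
  ith_results <- list()
  add_ith <- function(res) ith_results[[length(ith_results) + 1L]] <<- res
  for (p in analysable) {
    pm <- mut_sets[[p]]
    if (length(pm$variants) > 0L) {
      sets <- lapply(stats::setNames(regions_of[[p]], regions_of[[p]]),
                     function(r) pm$variants[pm$presence[r, ] == 1L])
      add_ith(pairwise_ith(sets, "mutational", p))
    }
    cm <- cnv_sets[[p]]
    if (!is.null(cm) && ncol(cm) > 0L) {
      sets <- lapply(stats::setNames(rownames(cm), rownames(cm)),
                     function(r) colnames(cm)[cm[r, ] == 1L])
      if (any(vapply(sets, length, integer(1)) > 0L)) {
        add_ith(pairwise_ith(sets, "cnv", p))
      }
    }
    mp <- meth_profiles[[p]]
    if (!is.null(mp)) {
      prof <- lapply(stats::setNames(colnames(mp$corrected),
                                     colnames(mp$corrected)),
                     function(r) mp$corrected[, r])
      add_ith(pairwise_ith(prof, "methylation", p))
    }
    ep <- expr_profiles[[p]]
    if (!is.null(ep)) {
      prof <- lapply(stats::setNames(colnames(ep$corrected),
                                     colnames(ep$corrected)),
                     function(r) ep$corrected[, r])
      add_ith(pairwise_ith(prof, "transcriptional", p))
    }
  }
  ith_pairs <- do.call(rbind, lapply(ith_results, function(r)
    cbind(patient_id = r$patient_id, layer = r$layer, r$pairs,
          stringsAsFactors = FALSE)))
  ith_means <- do.call(rbind, lapply(ith_results, function(r)
    data.frame(patient_id = r$patient_id, layer = r$layer,
               mean_ith = r$mean_ith, n_pairs = r$n_pairs,
               stringsAsFactors = FALSE)))
  log_stage("ith: %d patient-layer results", length(ith_results))

  ## --- trees -------------------------------------------------------------
  trees <- list()
  concordance_rows <- list()
  for (p in analysable) {
    nid <- normal$region_id[normal$patient_id == p][1L]
    ptrees <- list()
    pm <- mut_sets[[p]]
    if (length(pm$variants) > 0L && length(regions_of[[p]]) + 1L >= 3L) {
      m <- rbind(pm$presence, matrix(0L, 1L, ncol(pm$presence),
                                     dimnames = list(nid, NULL)))
      ptrees$mutation <- minimum_evolution_tree(euclidean_distances(m),
                                                root_label = nid)
    }
    cm <- cnv_sets[[p]]
    if (!is.null(cm) && ncol(cm) > 0L) {
      m <- rbind(cm, matrix(0L, 1L, ncol(cm), dimnames = list(nid, NULL)))
      ptrees$cnv <- minimum_evolution_tree(euclidean_distances(m),
                                           root_label = nid)
    }
    mp <- meth_profiles[[p]]
    if (!is.null(mp)) {
      m <- t(cbind(mp$corrected,
                   stats::setNames(data.frame(mp$normal), nid)))
      ptrees$methylation <- minimum_evolution_tree(euclidean_distances(m),
                                                   root_label = nid)
    }
    if (!is.null(ptrees$mutation) && !is.null(ptrees$methylation)) {
      cc <- tree_concordance(ptrees$mutation, ptrees$methylation)
      concordance_rows[[p]] <- data.frame(
        patient_id = p, rf_distance = cc$rf_distance,
        aligned = cc$aligned, stringsAsFactors = FALSE)
    }
    if (length(ptrees)) trees[[p]] <- ptrees
  }
  concordance <- if (length(concordance_rows))
    do.call(rbind, c(concordance_rows, list(make.row.names = FALSE)))
  log_stage("trees: %d patients, %d phylo/phyloepigenetic comparisons",
            length(trees), NROW(concordance))

  ## --- cross-layer correlations (pairwise values, per subtype) ----------
  correlations <- NULL
  subtype_of <- if (!is.null(bundle$clinical))
    stats::setNames(bundle$clinical$subtype, bundle$clinical$patient_id)
  if (!is.null(ith_pairs) && !is.null(subtype_of)) {
    ith_pairs$pair_key <- paste(ith_pairs$patient_id, ith_pairs$region_a,
                                ith_pairs$region_b, sep = "|")
    layers <- unique(ith_pairs$layer)
    rows <- list()
    for (st in unique(stats::na.omit(subtype_of))) {
      st_pairs <- ith_pairs[subtype_of[ith_pairs$patient_id] %in% st, ,
                            drop = FALSE]
      if (length(layers) >= 2L) {
        for (i in seq_len(length(layers) - 1L)) {
          for (j in (i + 1L):length(layers)) {
            a <- st_pairs[st_pairs$layer == layers[i], ]
            b <- st_pairs[st_pairs$layer == layers[j], ]
            common <- intersect(a$pair_key, b$pair_key)
            if (length(common) < 3L) next
            sp <- spearman(a$distance[match(common, a$pair_key)],
                           b$distance[match(common, b$pair_key)])
            rows[[length(rows) + 1L]] <- data.frame(
              subtype = st, layer_a = layers[i], layer_b = layers[j],
              rho = sp$rho, p = sp$p, n = sp$n, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(rows)) correlations <- do.call(rbind, rows)
    ith_pairs$pair_key <- NULL
  }

  ## --- subtype comparison of pairwise ITH -------------------------------
  subtype_comparison <- NULL
  if (!is.null(ith_pairs) && !is.null(subtype_of) &&
      length(unique(stats::na.omit(subtype_of))) == 2L) {
    rows <- lapply(unique(ith_pairs$layer), function(ly) {
      sub <- ith_pairs[ith_pairs$layer == ly, , drop = FALSE]
      st <- subtype_of[sub$patient_id]
      x <- sub$distance[st == "H" & !is.na(sub$distance)]
      y <- sub$distance[st == "L" & !is.na(sub$distance)]
      if (length(x) == 0L || length(y) == 0L) return(NULL)
      wt <- wilcoxon_rank_sum(x, y)
      data.frame(layer = ly, mean_H = mean(x), mean_L = mean(y),
                 U = wt$U, p = wt$p, n_H = length(x), n_L = length(y),
                 stringsAsFactors = FALSE)
    })
    subtype_comparison <- do.call(rbind, rows)
  }

  ## --- survival ----------------------------------------------------------
  survival_res <- NULL
  if (!is.null(bundle$clinical) && !is.null(ith_means)) {
    survival_res <- suppressMessages(
      stratified_survival_analysis(ith_means, bundle$clinical))
    log_stage("survival: %d layers stratified", length(survival_res))
  }

  ## --- serialisable report ----------------------------------------------
  surv_summary <- lapply(survival_res, function(sr) {
    out <- list(median_ith = sr$median_ith, evaluable = sr$evaluable,
                group = as.list(sr$group))
    for (ep in c("os", "rfs")) {
      if (is.null(sr[[ep]])) next
      out[[ep]] <- list(
        median_high = sr[[ep]]$medians[["high"]],
        median_low = sr[[ep]]$medians[["low"]],
        chi_square = sr[[ep]]$logrank$chi_square,
        p = sr[[ep]]$logrank$p)
    }
    out
  })
  newicks <- lapply(trees, function(pt) lapply(pt, write_newick))
  report <- list(
    n_patients = length(analysable),
    qc_excluded = qc$excluded,
    trunk_branch = trunk_branch,
    tmb = tmb,
    driver = list(per_patient = driver$per_patient,
                  p = if (!is.null(driver$test)) driver$test$p),
    ith_pairs = ith_pairs,
    ith_means = ith_means,
    trees = newicks,
    tree_concordance = concordance,
    correlations = correlations,
    subtype_comparison = subtype_comparison,
    survival = surv_summary
  )
  res <- list(report = report, qc = qc, mutations = rescued,
              mutation_sets = mut_sets, arm_calls = arm_calls,
              cnv_sets = cnv_sets, meth_profiles = meth_profiles,
              expr_profiles = expr_profiles, ith_results = ith_results,
              ith_pairs = ith_pairs, ith_means = ith_means, trees = trees,
              concordance = concordance, correlations = correlations,
              subtype_comparison = subtype_comparison,
              driver = driver, survival = survival_res)
  class(res) <- "ith_report"
  res
}

#' @export
print.ith_report <- function(x, ...) {
  cat(sprintf("ITH analysis: %d patients\n", x$report$n_patients))
  if (!is.null(x$ith_means)) {
    agg <- stats::aggregate(mean_ith ~ layer, data = x$ith_means, FUN = mean)
    for (i in seq_len(nrow(agg))) {
      cat(sprintf("  %-15s cohort mean ITH = %.4f\n",
                  agg$layer[i], agg$mean_ith[i]))
    }
  }
  if (!is.null(x$concordance)) {
    cat(sprintf("  phyloepigenetic trees aligned with phylogenetic: %d/%d\n",
                sum(x$concordance$aligned), nrow(x$concordance)))
  }
  invisible(x)
}

#' @export
summary.ith_report <- function(object, ...) {
  print(object)
  if (!is.null(object$subtype_comparison)) {
    cat("Subtype comparison of pairwise ITH (Wilcoxon rank-sum):\n")
    print(object$subtype_comparison, row.names = FALSE)
  }
  for (ly in names(object$survival)) {
    sr <- object$survival[[ly]]
    if (!is.null(sr$os)) {
      cat(sprintf("Survival, %s ITH median split: OS log-rank p = %.4g\n",
                  ly, sr$os$logrank$p))
    }
  }
  invisible(object)
}

#' Write pipeline outputs to a directory
#'
#' Writes the JSON report (stable sorted keys, full precision), per-stage
#' TSVs and one Newick file per patient and layer.
#'
#' @param result an \code{ith_report} from \code{\link{run_pipeline}}.
#' @param dir output directory.
#' @return Invisibly, the report path.
#' @export
save_report <- function(result, dir) {
  stopifnot(inherits(result, "ith_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "report.json")
  write_report(result$report, path)
  put <- function(tbl, fn) {
    if (is.null(tbl) || nrow(tbl) == 0L) return(invisible())
    utils::write.table(tbl, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  put(result$report$trunk_branch, "trunk_branch.tsv")
  put(result$report$ith_pairs, "ith_pairs.tsv")
  put(result$report$ith_means, "ith_means.tsv")
  put(result$report$tmb, "tmb.tsv")
  put(result$report$tree_concordance, "tree_concordance.tsv")
  for (p in names(result$trees)) {
    for (ly in names(result$trees[[p]])) {
      writeLines(write_newick(result$trees[[p]][[ly]]),
                 file.path(dir, sprintf("tree_%s_%s.nwk", p, ly)))
    }
  }
  invisible(path)
}
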