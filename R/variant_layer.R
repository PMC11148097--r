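#' Sample-level quality control
#'
#' Excludes sequenced samples failing library QC: a sample is kept iff its
#' total QScore is at least \code{min_qscore}, its estimated contamination
#' rate is at most \code{max_contamination}, and its mean depth is at least
#' \code{min_depth}. All three thresholds are strict on the failing side
#' ("smaller than 35", "greater than 0.02", "< 30X"), so boundary values
#' pass. A sample with a missing metric is excluded with reason
#' \code{"missing_metric"}.
#'
#' @param samples data frame with columns \code{patient_id},
#'   \code{region_id}, \code{qscore}, \code{contamination},
#'   \code{mean_depth}.
#' @param min_qscore,max_contamination,min_depth QC thresholds.
#' @return List with \code{kept} (data frame of passing samples) and
#'   \code{excluded} (data frame with columns \code{region_id},
#'   \code{reason}).
#' @export
qc_filter_samples <- function(samples, min_qscore = 35,
                              max_contamination = 0.02, min_depth = 30) {
  if (nrow(samples) == 0L) {
    return(list(kept = samples,
                excluded = data.frame(region_id = character(),
                                      reason = character(),
                                      stringsAsFactors = FALSE)))
  }
  reason <- character(nrow(samples))
  missing <- is.na(samples$qscore) | is.na(samples$contamination) |
    is.na(samples$mean_depth)
  reason[missing] <- "missing_metric"
  low_q <- !missing & samples$qscore < min_qscore
  reason[low_q] <- sprintf("qscore<%g", min_qscore)
  contam <- !missing & !low_q & samples$contamination > max_contamination
  reason[contam] <- sprintf("contamination>%g", max_contamination)
  shallow <- !missing & !low_q & !contam & samples$mean_depth < min_depth
  reason[shallow] <- sprintf("depth<%g", min_depth)
  fail <- nzchar(reason)
  list(
    kept = samples[!fail, , drop = FALSE],
    excluded = data.frame(region_id = samples$region_id[fail],
                          reason = reason[fail],
                          stringsAsFactors = FALSE)
  )
}

# indel iff ref/alt allele lengths differ
.is_indel <- function(calls) nchar(calls$ref) != nchar(calls$alt)

#' Filter somatic calls on supporting reads and population frequency
#'
#' Keeps an SNV iff it has at least \code{snv_min_reads} alt-supporting
#' reads and a small indel iff it has at least \code{indel_min_reads}
#' (thresholds are strict: "supporting reads < 6" fails, 6 passes). Any call
#' observed at more than \code{max_pop_freq} population frequency is removed
#' as likely germline. A call is an indel iff its ref and alt allele lengths
#' differ. Input order is preserved.
#'
#' @param calls data frame of somatic calls with at least \code{ref},
#'   \code{alt}, \code{alt_reads}, \code{pop_freq}.
#' @param snv_min_reads,indel_min_reads,max_pop_freq thresholds.
#' @return The passing subset of \code{calls}.
#' @export
filter_calls <- function(calls, snv_min_reads = 6, indel_min_reads = 8,
                         max_pop_freq = 0.01) {
  if (nrow(calls) == 0L) return(calls)
  if (any(calls$alt_reads < 0)) stop("negative alt_reads in call table")
  min_reads <- ifelse(.is_indel(calls), indel_min_reads, snv_min_reads)
  keep <- calls$alt_reads >= min_reads & calls$pop_freq <= max_pop_freq
  calls[keep, , drop = FALSE]
}

.variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Rescue low-frequency calls across regions of the same tumor
#'
#' Multi-region sequencing is prone to false negatives: a subclonal mutation
#' confidently called in one region may sit just below the calling
#' thresholds in another. The rescue rule repairs this: if a variant passed
#' filtering in at least one region of a patient and has at least one
#' alt-supporting read in the raw calls of another region of the same
#' patient, it is called in that region too. The output is a superset of
#' \code{passing}; a variant passing nowhere is never added, and the
#' operation is idempotent.
#'
#' @param passing data frame of calls that passed \code{\link{filter_calls}}.
#' @param raw data frame of all pre-filter calls (superset of
#'   \code{passing}), used to look up raw read support.
#' @return Data frame of calls: \code{passing} plus rescued rows taken from
#'   \code{raw}, with a logical column \code{rescued}.
#' @export
rescue_across_regions <- function(passing, raw) {
  cols <- names(raw)
  passing <- passing[, cols, drop = FALSE]
  if (nrow(passing) == 0L) {
    passing$rescued <- logical(0)
    return(passing)
  }
  pass_id <- paste(passing$patient_id, .variant_key(passing), sep = "|")
  raw_id <- paste(raw$patient_id, .variant_key(raw), sep = "|")
  pass_reg <- paste(pass_id, passing$region_id, sep = "|")
  raw_reg <- paste(raw_id, raw$region_id, sep = "|")
  rescue <- raw_id %in% pass_id &       # variant passed somewhere in patient
    !(raw_reg %in% pass_reg) &          # but not in this region
    raw$alt_reads >= 1L                 # and has raw support here
  add <- raw[rescue, , drop = FALSE]
  passing$rescued <- rep(FALSE, nrow(passing))
  add$rescued <- rep(TRUE, nrow(add))
  out <- rbind(passing, add)
  rownames(out) <- NULL
  out
}

#' Build a per-patient mutation presence structure
#'
#' Collects the post-rescue calls of one patient into the region-by-variant
#' presence matrix underlying trunk/branch classification, the mutational
#' Jaccard ITH and the phylogenetic distance matrix.
#'
#' @param calls post-rescue calls of a single patient.
#' @param region_ids tumor region identifiers to include (regions with zero
#'   calls still get a row).
#' @return List of class \code{patient_mutation_set}: \code{patient_id},
#'   \code{region_ids}, \code{variants} (character keys),
#'   \code{presence} (binary region x variant matrix).
#' @export
patient_mutation_set <- function(calls, region_ids) {
  pid <- unique(calls$patient_id)
  if (length(pid) > 1L) stop("calls span more than one patient")
  if (length(pid) == 0L) pid <- NA_character_
  variants <- unique(.variant_key(calls))
  presence <- matrix(0L, nrow = length(region_ids), ncol = length(variants),
                     dimnames = list(region_ids, variants))
  if (nrow(calls) > 0L) {
    idx <- cbind(match(calls$region_id, region_ids),
                 match(.variant_key(calls), variants))
    if (any(is.na(idx[, 1L]))) {
      stop("call references a region not in region_ids")
    }
    presence[idx] <- 1L
  }
  structure(list(patient_id = pid, region_ids = region_ids,
                 variants = variants, presence = presence),
            class = "patient_mutation_set")
}

#' Classify mutations as trunk or branch
#'
#' A somatic alteration shared by all sampled tumor regions of a patient is
#' a trunk mutation; anything present in only a subset is a branch mutation.
#' Classification runs on the post-rescue presence matrix, since the rescue
#' rule exists precisely to repair false-negative sharing.
#'
#' @param pm a \code{\link{patient_mutation_set}} with >= 2 tumor regions.
#' @return List with \code{labels} (named character vector,
#'   \code{"trunk"}/\code{"branch"} per variant key), \code{trunk_proportion}
#'   and \code{branch_proportion} (both \code{NA} when the patient has zero
#'   variants), \code{n_trunk}, \code{n_branch}.
#' @export
classify_trunk_branch <- function(pm) {
  stopifnot(inherits(pm, "patient_mutation_set"))
  if (length(pm$region_ids) < 2L) {
    stop("trunk/branch classification needs >= 2 tumor regions")
  }
  n_var <- length(pm$variants)
  if (n_var == 0L) {
    return(list(labels = character(0), trunk_proportion = NA_real_,
                branch_proportion = NA_real_, n_trunk = 0L, n_branch = 0L))
  }
  shared_by_all <- colSums(pm$presence) == nrow(pm$presence)
  labels <- ifelse(shared_by_all, "trunk", "branch")
  names(labels) <- pm$variants
  n_trunk <- sum(shared_by_all)
  list(labels = labels,
       trunk_proportion = n_trunk / n_var,
       branch_proportion = 1 - n_trunk / n_var,
       n_trunk = n_trunk,
       n_branch = n_var - n_trunk)
}

#' Tumor mutation burden
#'
#' TMB is defined as the total number of missense mutations; per-megabase
#' values are scaled by the covered exome size (default 39 Mb).
#'
#' @param calls calls of one region (or one patient, as desired).
#' @param coverage_mb covered exome size in megabases.
#' @return List with \code{missense_count}, \code{missense_per_mb},
#'   \code{exonic_per_mb} (all calls per Mb).
#' @export
compute_tmb <- function(calls, coverage_mb = 39) {
  stopifnot(coverage_mb > 0)
  n_missense <- sum(calls$variant_class == "missense")
  list(missense_count = n_missense,
       missense_per_mb = n_missense / coverage_mb,
       exonic_per_mb = nrow(calls) / coverage_mb)
}

#' Driver enrichment on trunk versus branch
#'
#' For each patient, the fraction of trunk mutations and of branch mutations
#' hitting a driver gene (annotated oncogene or tumor-suppressor role).
#' Patients with zero trunk (or branch) mutations contribute a missing value
#' on that side. The cohort-level comparison of the two fraction vectors
#' uses \code{\link{wilcoxon_rank_sum}} after dropping missing values.
#'
#' @param patient_calls named list (by patient) of post-rescue call data
#'   frames; \code{driver_role} column holds the role annotation.
#' @param region_ids named list (by patient) of tumor region ids.
#' @return List with \code{per_patient} (data frame: \code{patient_id},
#'   \code{trunk_driver_fraction}, \code{branch_driver_fraction}) and
#'   \code{test} (Wilcoxon comparison, or NULL when either side is empty).
#' @export
driver_enrichment <- function(patient_calls, region_ids) {
  rows <- lapply(names(patient_calls), function(pid) {
    calls <- patient_calls[[pid]]
    pm <- patient_mutation_set(calls, region_ids[[pid]])
    cls <- classify_trunk_branch(pm)
    key <- .variant_key(calls)
    is_driver <- calls$driver_role %in% c("oncogene", "TSG")
    driver_keys <- unique(key[is_driver])
    frac <- function(label) {
      keys <- names(cls$labels)[cls$labels == label]
      if (length(keys) == 0L) return(NA_real_)
      mean(keys %in% driver_keys)
    }
    data.frame(patient_id = pid,
               trunk_driver_fraction = frac("trunk"),
               branch_driver_fraction = frac("branch"),
               stringsAsFactors = FALSE)
  })
  per_patient <- do.call(rbind, rows)
  x <- per_patient$trunk_driver_fraction
  y <- per_patient$branch_driver_fraction
  test <- if (sum(!is.na(x)) > 0L && sum(!is.na(y)) > 0L) {
    wilcoxon_rank_sum(x[!is.na(x)], y[!is.na(y)])
  }
  list(per_patient = per_patient, test = test)
}

#' Match a mutational spectrum against reference signatures
#'
#' Cosine similarity of a 96-channel trinucleotide substitution spectrum
#' against each column of a reference signature catalog; references with
#' similarity strictly above \code{threshold} are reported as matches,
#' sorted by decreasing similarity.
#'
#' @param candidate non-negative numeric vector (one spectrum).
#' @param catalog numeric matrix, one reference signature per column, rows
#'   aligned with \code{candidate}.
#' @param threshold minimum cosine similarity for a match (strict).
#' @return Data frame with columns \code{signature}, \code{cosine},
#'   \code{matched}, sorted by decreasing \code{cosine}.
#' @export
match_signature <- function(candidate, catalog, threshold = 0.6) {
  catalog <- as.matrix(catalog)
  if (length(candidate) != nrow(catalog)) {
    stop("candidate length does not match catalog rows")
  }
  if (any(candidate < 0) || any(catalog < 0)) {
    stop("spectra must be non-negative")
  }
  cnorm <- sqrt(sum(candidate^2))
  rnorm <- sqrt(colSums(catalog^2))
  if (cnorm == 0 || any(rnorm == 0)) stop("zero-norm spectrum")
  cosine <- as.numeric(crossprod(catalog, candidate)) / (rnorm * cnorm)
  out <- data.frame(signature = colnames(catalog), cosine = cosine,
                    matched = cosine > threshold, stringsAsFactors = FALSE)
  out[order(-out$cosine), , drop = FALSE]
}
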