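#' Aggregate CpG counts into fixed-width methylation windows
#'
#' Sums methylated and total read counts of individual CpG records into
#' tiling windows (0-based half-open, a CpG at position \code{pos} falls in
#' the window with \code{start <= pos < start + window_size}) and computes
#' the window methylation level as total methylated reads over total reads.
#' Windows with zero covered CpGs, or with pooled coverage below
#' \code{min_coverage}, are dropped. With \code{step < window_size} the
#' windows overlap (sliding windows); counts are then assigned to every
#' window covering the CpG.
#'
#' @param cpg_records data frame with \code{region_id}, \code{chrom},
#'   \code{pos} (0-based), \code{methylated_count}, \code{total_count}.
#' @param window_size,step window width and slide step in bp.
#' @param min_coverage minimum pooled reads for a window to be reported.
#' @return Data frame with \code{region_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{methylated_count}, \code{total_count}, \code{beta}.
#' @export
bin_windows <- function(cpg_records, window_size = 100, step = 100,
                        min_coverage = 5) {
  stopifnot(window_size > 0, step > 0)
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      methylated_count = numeric(), total_count = numeric(),
                      beta = numeric(), stringsAsFactors = FALSE)
  if (nrow(cpg_records) == 0L) return(empty)
  # window start indices covering a position
  rows <- lapply(seq_len(nrow(cpg_records)), function(i) {
    pos <- cpg_records$pos[i]
    k_max <- pos %/% step
    k_min <- ceiling((pos - window_size + 1) / step)
    k <- seq(max(k_min, 0), k_max)
    k <- k[k * step + window_size > pos]
    data.frame(region_id = cpg_records$region_id[i],
               chrom = cpg_records$chrom[i],
               start = k * step,
               methylated_count = cpg_records$methylated_count[i],
               total_count = cpg_records$total_count[i],
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(
    cbind(methylated_count, total_count) ~ region_id + chrom + start,
    data = long, FUN = sum)
  agg <- agg[agg$total_count >= min_coverage, , drop = FALSE]
  if (nrow(agg) == 0L) return(empty)
  agg$end <- agg$start + window_size
  agg$beta <- agg$methylated_count / agg$total_count
  agg <- agg[order(agg$region_id, agg$chrom, agg$start), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, names(empty)]
}

#' Tumor-purity correction of methylation or expression profiles
#'
#' A bulk tumor-region profile is modelled as a two-component mixture of the
#' tumor-cell profile and the normal-cell profile weighted by tumor purity:
#' \deqn{observed_i = purity \cdot tumor_i + (1 - purity) \cdot normal_i.}
#' The correction inverts this linearly against the matched-normal profile,
#' \eqn{(observed_i - (1-purity) normal_i)/purity}, and clamps the result to
#' the valid range of the layer: \[0, 1\] for methylation beta values,
#' \[0, Inf) for expression abundances.
#'
#' @param observed numeric profile of the tumor region.
#' @param purity tumor purity in (0, 1].
#' @param normal_reference matched-normal profile, same features and order.
#' @param layer \code{"methylation"} (cap at 1) or \code{"expression"}
#'   (no cap).
#' @return Corrected numeric profile, names preserved.
#' @export
purity_correct <- function(observed, purity, normal_reference,
                           layer = c("methylation", "expression")) {
  layer <- match.arg(layer)
  if (!is.numeric(purity) || length(purity) != 1L || is.na(purity) ||
      purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]")
  }
  if (length(observed) != length(normal_reference)) {
    stop("observed and normal profiles have different lengths")
  }
  corrected <- (observed - (1 - purity) * normal_reference) / purity
  corrected <- pmax(corrected, 0)
  if (layer == "methylation") corrected <- pmin(corrected, 1)
  names(corrected) <- names(observed)
  corrected
}

#' Simple differential methylation caller
#'
#' Compares tumor against normal methylation per window on pooled counts.
#' For each window the methylated/unmethylated read counts pooled within
#' each group form a 2x2 table tested with Fisher's exact test (two-sided);
#' p-values are Benjamini-Hochberg adjusted across windows. A window is a
#' DMR iff the absolute pooled beta difference is at least \code{min_diff}
#' and the adjusted q-value is below \code{fdr}; direction is
#' hypermethylated (tumor above normal) or hypomethylated by the sign of
#' the difference.
#'
#' @param tumor_windows,normal_windows window data frames as produced by
#'   \code{\link{bin_windows}} (possibly several samples per group; counts
#'   are pooled per window). Windows are matched on
#'   \code{chrom:start:end}.
#' @param min_diff minimum absolute pooled beta difference.
#' @param fdr q-value significance level.
#' @return Data frame with one row per matched window: \code{chrom},
#'   \code{start}, \code{end}, \code{beta_tumor}, \code{beta_normal},
#'   \code{delta_beta}, \code{p}, \code{q}, \code{dmr} (logical),
#'   \code{direction} (\code{hyper}/\code{hypo}/\code{NA}).
#' @export
call_dmr_simple <- function(tumor_windows, normal_windows, min_diff = 0.2,
                            fdr = 0.05) {
  pool <- function(w) {
    agg <- stats::aggregate(
      cbind(methylated_count, total_count) ~ chrom + start + end,
      data = w, FUN = sum)
    agg$key <- paste(agg$chrom, agg$start, agg$end, sep = ":")
    agg
  }
  tum <- pool(tumor_windows)
  nrm <- pool(normal_windows)
  common <- intersect(tum$key, nrm$key)
  tum <- tum[match(common, tum$key), , drop = FALSE]
  nrm <- nrm[match(common, nrm$key), , drop = FALSE]
  n <- length(common)
  p <- numeric(n)
  for (i in seq_len(n)) {
    tab <- matrix(c(tum$methylated_count[i],
                    tum$total_count[i] - tum$methylated_count[i],
                    nrm$methylated_count[i],
                    nrm$total_count[i] - nrm$methylated_count[i]),
                  nrow = 2L)
    p[i] <- stats::fisher.test(tab)$p.value
  }
  q <- stats::p.adjust(p, method = "BH")
  beta_tumor <- tum$methylated_count / tum$total_count
  beta_normal <- nrm$methylated_count / nrm$total_count
  delta <- beta_tumor - beta_normal
  dmr <- abs(delta) >= min_diff & q < fdr
  direction <- rep(NA_character_, n)
  direction[dmr & delta > 0] <- "hyper"
  direction[dmr & delta < 0] <- "hypo"
  out <- data.frame(chrom = tum$chrom, start = tum$start, end = tum$end,
                    beta_tumor = beta_tumor, beta_normal = beta_normal,
                    delta_beta = delta, p = p, q = q, dmr = dmr,
                    direction = direction, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}
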