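#' Jaccard distance between two alteration sets
#'
#' Distance between the somatic alteration sets of two tumor regions,
#' defined as one minus the Jaccard coefficient:
#' \deqn{d_J(V_i, V_j) = 1 - |V_i \cap V_j| / |V_i \cup V_j|}
#' It ranges from 0 (identical sets, lowest heterogeneity) to 1 (disjoint
#' sets, highest heterogeneity). Used for the mutational and CNV layers,
#' where each region is summarised by the set of alterations it carries.
#'
#' @param v_i,v_j character vectors of alteration keys (e.g.
#'   \code{"chr1:123:A:T"} or \code{"1p:gain"}). Duplicates are ignored.
#' @return A single number in \[0, 1\], or \code{NA_real_} when both sets
#'   are empty (the distance is undefined and reported as missing).
#' @examples
#' jaccard_distance(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
#' @export
jaccard_distance <- function(v_i, v_j) {
  v_i <- unique(as.character(v_i))
  v_j <- unique(as.character(v_j))
  n_union <- length(union(v_i, v_j))
  if (n_union == 0L) return(NA_real_)
  1 - length(intersect(v_i, v_j)) / n_union
}

#' Convert a non-negative profile to a probability distribution
#'
#' Sum-normalises a purity-corrected methylation or expression profile so it
#' can enter the Jensen-Shannon distance. No pseudocount is added: the
#' divergence is always taken against the mixture distribution, which is
#' positive wherever either input is, so zeros are harmless.
#'
#' @param values numeric vector, finite and non-negative, with at least one
#'   positive entry.
#' @return Numeric vector of the same length summing to 1; names preserved.
#' @export
to_probability <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("profile values must be finite")
  if (any(values < 0)) stop("profile values must be non-negative")
  s <- sum(values)
  if (s <= 0) stop("cannot normalise an all-zero profile")
  values / s
}

#' Jensen-Shannon distance between two probability distributions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms:
#' \deqn{JSD(P_1, P_2) = \sqrt{\tfrac{1}{2}[D_{KL}(P_1 \| R) +
#'   D_{KL}(P_2 \| R)]}, \quad R = (P_1 + P_2)/2}
#' with the convention \eqn{0 \log 0 = 0}. With base-2 logs the distance is
#' bounded in \[0, 1\]: 0 iff the distributions are identical, 1 iff their
#' supports are disjoint. Used for the methylation and transcriptional
#' layers on sum-normalised, purity-corrected profiles.
#'
#' @param p1,p2 numeric probability vectors of equal length, each summing to
#'   1 (tolerance 1e-9). If both are named the names must agree.
#' @return A single number in \[0, 1\].
#' @examples
#' jensen_shannon_distance(c(1, 0), c(0, 1))  # 1
#' @export
jensen_shannon_distance <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("distributions have different lengths")
  if (!is.null(names(p1)) && !is.null(names(p2)) &&
      !identical(names(p1), names(p2))) {
    stop("distribution features are misaligned")
  }
  .check_prob(p1)
  .check_prob(p2)
  r <- (p1 + p2) / 2
  jsd2 <- 0.5 * (.kl_div(p1, r) + .kl_div(p2, r))
  # guard tiny negative rounding before the square root
  sqrt(max(jsd2, 0))
}

.check_prob <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("probabilities must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  invisible(p)
}

# Kullback-Leibler divergence in bits; terms with p == 0 contribute 0.
.kl_div <- function(p, q) {
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / q[keep]))
}

#' Pairwise ITH for one patient and one molecular layer
#'
#' Computes the distance between every pair of tumor regions of one patient
#' and the per-patient mean. Mutational and CNV layers use
#' \code{\link{jaccard_distance}} on per-region alteration sets; the
#' methylation and transcriptional layers use
#' \code{\link{jensen_shannon_distance}} on sum-normalised profiles.
#'
#' @param region_data for layers \code{"mutational"} and \code{"cnv"}, a
#'   named list of character vectors (one alteration set per tumor region);
#'   for \code{"methylation"} and \code{"transcriptional"}, a named list of
#'   non-negative numeric profile vectors over a common feature set
#'   (purity-corrected upstream).
#' @param layer one of \code{"mutational"}, \code{"cnv"},
#'   \code{"methylation"}, \code{"transcriptional"}.
#' @param patient_id patient identifier carried into the result.
#' @return An object of class \code{ith_result}: a list with
#'   \code{patient_id}, \code{layer}, \code{pairs} (data frame with columns
#'   \code{region_a}, \code{region_b}, \code{distance}), \code{mean_ith} and
#'   \code{n_pairs}.
#' @export
pairwise_ith <- function(region_data, layer, patient_id = NA_character_) {
  layer <- match.arg(layer,
                     c("mutational", "cnv", "methylation", "transcriptional"))
  regions <- names(region_data)
  if (is.null(regions) || any(!nzchar(regions))) {
    stop("region_data must be a named list of regions")
  }
  if (length(regions) < 2L) {
    stop("insufficient regions: pairwise ITH needs >= 2 tumor regions")
  }
  set_layer <- layer %in% c("mutational", "cnv")
  if (!set_layer) {
    probs <- lapply(region_data, to_probability)
  }
  pair_idx <- utils::combn(length(regions), 2L)
  dist <- apply(pair_idx, 2L, function(ij) {
    if (set_layer) {
      jaccard_distance(region_data[[ij[1L]]], region_data[[ij[2L]]])
    } else {
      jensen_shannon_distance(probs[[ij[1L]]], probs[[ij[2L]]])
    }
  })
  pairs <- data.frame(
    region_a = regions[pair_idx[1L, ]],
    region_b = regions[pair_idx[2L, ]],
    distance = as.numeric(dist),
    stringsAsFactors = FALSE
  )
  mean_ith <- mean(pairs$distance, na.rm = TRUE)  # NA pairs are undefined
  res <- list(
    patient_id = patient_id,
    layer = layer,
    pairs = pairs,
    mean_ith = if (is.nan(mean_ith)) NA_real_ else mean_ith,
    n_pairs = nrow(pairs)
  )
  class(res) <- "ith_result"
  res
}

#' @export
print.ith_result <- function(x, ...) {
  cat(sprintf("ITH result: patient %s, %s layer\n", x$patient_id, x$layer))
  cat(sprintf("  %d region pairs, mean ITH = %.4f\n", x$n_pairs, x$mean_ith))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Split patients into high/low groups at the median
#'
#' Dichotomises per-patient mean ITH values at the cohort median: values
#' strictly above the median are \code{"high"}, values at or below it are
#' \code{"low"} (the tie rule is fixed so the split is deterministic;
#' \code{ties} switches it). Missing values stay unassigned.
#'
#' @param values named numeric vector of per-patient summary values.
#' @param ties where a value equal to the median goes (default
#'   \code{"low"}).
#' @return A list with \code{group} (character vector \code{"high"}/
#'   \code{"low"}/\code{NA}, named as \code{values}), \code{median} and
#'   \code{degenerate} (TRUE when all non-missing values are equal, so one
#'   group is empty).
#' @export
median_split <- function(values, ties = c("low", "high")) {
  ties <- match.arg(ties)
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("median split needs >= 2 non-missing values")
  med <- stats::median(values[ok])
  group <- rep(NA_character_, length(values))
  if (ties == "low") {
    group[ok] <- ifelse(values[ok] > med, "high", "low")
  } else {
    group[ok] <- ifelse(values[ok] >= med, "high", "low")
  }
  names(group) <- names(values)
  degenerate <- length(unique(group[ok])) < 2L
  if (degenerate) {
    message("median_split: degenerate split (all values in one group)")
  }
  list(group = group, median = med, degenerate = degenerate)
}
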