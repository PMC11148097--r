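#' Arm-level copy-number calls from segment tables
#'
#' Calls a chromosome-arm gain for a region when the segments in the
#' amplified state account for more than 60% of all segments on that arm
#' (strictly more: 60.0% exactly is not called); losses analogously. By
#' default the fraction is computed over segment counts; \code{by =
#' "length"} weights segments by their genomic length instead. An arm with
#' zero segments is reported as \code{none} with missing fractions.
#'
#' @param segments data frame with columns \code{region_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{state}
#'   (\code{amp}/\code{del}/\code{neutral}), \code{arm}.
#' @param arms data frame defining the arms (\code{chrom}, \code{arm},
#'   \code{start}, \code{end}); every arm gets a call for every region.
#' @param threshold fraction of the arm's segments that must share a state.
#' @param by weight segments by \code{"count"} (default) or \code{"length"}.
#' @return Data frame with one row per (region, arm): \code{region_id},
#'   \code{arm}, \code{call} (\code{gain}/\code{loss}/\code{none}),
#'   \code{gain_fraction}, \code{loss_fraction}.
#' @export
call_arm_level <- function(segments, arms, threshold = 0.60,
                           by = c("count", "length")) {
  by <- match.arg(by)
  if (nrow(segments) > 0L) {
    bad <- !(segments$arm %in% arms$arm)
    if (any(bad)) {
      stop("segments reference undefined arms: ",
           paste(unique(segments$arm[bad]), collapse = ", "))
    }
    if (any(segments$end <= segments$start)) {
      stop("segment end must exceed start")
    }
  }
  regions <- unique(segments$region_id)
  grid <- expand.grid(region_id = regions, arm = arms$arm,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) {
    return(data.frame(region_id = character(), arm = character(),
                      call = character(), gain_fraction = numeric(),
                      loss_fraction = numeric(), stringsAsFactors = FALSE))
  }
  w <- if (by == "count") rep(1, nrow(segments)) else
    segments$end - segments$start
  key <- paste(segments$region_id, segments$arm, sep = "|")
  gkey <- paste(grid$region_id, grid$arm, sep = "|")
  total <- vapply(gkey, function(k) sum(w[key == k]), numeric(1))
  amp <- vapply(gkey, function(k)
    sum(w[key == k & segments$state == "amp"]), numeric(1))
  del <- vapply(gkey, function(k)
    sum(w[key == k & segments$state == "del"]), numeric(1))
  gain_fraction <- ifelse(total > 0, amp / total, NA_real_)
  loss_fraction <- ifelse(total > 0, del / total, NA_real_)
  call <- rep("none", nrow(grid))
  call[!is.na(gain_fraction) & gain_fraction > threshold] <- "gain"
  call[!is.na(loss_fraction) & loss_fraction > threshold] <- "loss"
  data.frame(region_id = grid$region_id, arm = grid$arm, call = call,
             gain_fraction = gain_fraction, loss_fraction = loss_fraction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Binary CNV event matrix for one patient
#'
#' Collects arm-level (and optionally focal) copy-number events of one
#' patient's tumor regions into the binary region-by-event matrix that
#' feeds the CNV Jaccard ITH and the phylo-CNV tree. Event keys take the
#' form \code{"arm:direction"} (e.g. \code{"1p:gain"}). Duplicate
#' (region, event) pairs collapse to a single presence.
#'
#' @param events data frame with columns \code{region_id} and \code{event}
#'   (pre-built keys), e.g. from \code{\link{arm_calls_to_events}}.
#' @param region_ids tumor regions to include (rows kept even with zero
#'   events).
#' @return Binary integer matrix, rows = regions, columns = sorted union of
#'   event keys.
#' @export
build_cnv_matrix <- function(events, region_ids) {
  keys <- sort(unique(events$event))
  m <- matrix(0L, nrow = length(region_ids), ncol = length(keys),
              dimnames = list(region_ids, keys))
  if (nrow(events) > 0L) {
    idx <- cbind(match(events$region_id, region_ids),
                 match(events$event, keys))
    if (any(is.na(idx[, 1L]))) {
      stop("event references a region not in region_ids")
    }
    m[idx] <- 1L
  }
  m
}

#' Convert arm-level calls to event keys
#'
#' @param arm_calls output of \code{\link{call_arm_level}}.
#' @return Data frame with \code{region_id}, \code{event} rows for every
#'   non-\code{none} call.
#' @export
arm_calls_to_events <- function(arm_calls) {
  hit <- arm_calls$call != "none"
  data.frame(region_id = arm_calls$region_id[hit],
             event = paste(arm_calls$arm[hit], arm_calls$call[hit],
                           sep = ":"),
             stringsAsFactors = FALSE)
}
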