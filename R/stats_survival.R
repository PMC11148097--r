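#' Wilcoxon rank-sum test
#'
#' Two-sided comparison of two independent samples. With a combined sample
#' size of at most 12 and no ties the exact null distribution of the
#' Mann-Whitney U statistic is used; otherwise the normal approximation
#' with mid-ranks, tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples, each non-empty.
#' @return List with \code{U} (Mann-Whitney statistic of \code{x}),
#'   \code{p} (two-sided), \code{exact} (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; the two-sided p-value comes from the
#' t approximation with n - 2 degrees of freedom. When either variable has
#' zero rank variance the coefficient is undefined and reported missing.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped),
#'   at least 3 complete pairs.
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("spearman needs >= 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, with the median
#' survival time defined as the first time at which the estimate drops to
#' 0.5 or below ("not reached", \code{NA}, when it never does, e.g. with
#' censored-only data).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = death/recurrence, 0 = censored).
#' @return List of class \code{km_curve}: \code{time}, \code{n_risk},
#'   \code{n_event}, \code{surv} (all at observed event/censoring times),
#'   \code{median} (time or \code{NA}), \code{n}, \code{n_events}.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(times < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  surv <- fit$surv
  med <- if (any(surv <= 0.5)) fit$time[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = surv, median = med,
                 n = length(times), n_events = sum(events)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test
#'
#' Standard log-rank comparison of two or more survival curves over pooled
#' event times; the p-value comes from the chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param times,events follow-up times and event indicators.
#' @param group group membership (factor or character), every level
#'   non-empty.
#' @return List with \code{chi_square}, \code{df}, \code{p}.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (any(table(group) == 0L)) stop("empty group")
  if (nlevels(group) < 2L) stop("log-rank needs >= 2 groups")
  if (sum(events) < 1L) stop("log-rank needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  list(chi_square = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median-split survival stratification
#'
#' For each ITH layer, splits patients into high/low groups at the median
#' of their per-patient mean ITH (\code{\link{median_split}}), then runs a
#' Kaplan-Meier estimate and log-rank test per survival endpoint (OS and
#' RFS, when present in \code{clinical}). A degenerate split (one group
#' empty) is reported as not evaluable for that layer.
#'
#' @param ith_means data frame with columns \code{patient_id}, \code{layer},
#'   \code{mean_ith} (one row per patient and layer).
#' @param clinical data frame with \code{patient_id}, \code{os_months},
#'   \code{os_event}, \code{rfs_months}, \code{rfs_event} (endpoints with
#'   all-missing columns are skipped).
#' @return Named list (by layer) of lists with \code{group} (named
#'   character vector), \code{median_ith}, \code{evaluable}, and per
#'   endpoint (\code{os}, \code{rfs}) the two \code{km_curve}s, group
#'   medians and the log-rank result.
#' @export
stratified_survival_analysis <- function(ith_means, clinical) {
  out <- list()
  for (layer in unique(ith_means$layer)) {
    sub <- ith_means[ith_means$layer == layer, , drop = FALSE]
    vals <- stats::setNames(sub$mean_ith, sub$patient_id)
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L) {
      message("stratified_survival_analysis: layer ", layer,
              " skipped (too few patients with ITH)")
      next
    }
    split <- suppressMessages(median_split(vals))
    res <- list(group = split$group, median_ith = split$median,
                evaluable = !split$degenerate)
    if (!split$degenerate) {
      cl <- clinical[match(names(split$group), clinical$patient_id), ,
                     drop = FALSE]
      for (ep in c("os", "rfs")) {
        tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
        if (!all(c(tcol, ecol) %in% names(cl))) next
        ok <- !is.na(cl[[tcol]]) & !is.na(cl[[ecol]])
        if (sum(ok) < 4L || sum(cl[[ecol]][ok]) < 1L) next
        tm <- cl[[tcol]][ok]; ev <- cl[[ecol]][ok]
        grp <- split$group[ok]
        if (length(unique(grp)) < 2L) next
        curves <- lapply(c(high = "high", low = "low"), function(g)
          km_estimate(tm[grp == g], ev[grp == g]))
        res[[ep]] <- list(
          curves = curves,
          medians = vapply(curves, `[[`, numeric(1), "median"),
          logrank = logrank_test(tm, ev, grp)
        )
      }
    }
    out[[layer]] <- res
  }
  out
}

#' Two-by-two exact test utility
#'
#' Fisher's exact test for comparing two proportions given as
#' successes/totals, e.g. cohort alteration frequencies.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return List with \code{p} (two-sided), \code{prop1}, \code{prop2}.
#' @export
proportion_exact_test <- function(k1, n1, k2, n2) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L)
  list(p = stats::fisher.test(tab)$p.value,
       prop1 = k1 / n1, prop2 = k2 / n2)
}
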