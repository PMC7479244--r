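#' Methylation percentage from read counts
#'
#' `100 * count_M / count_total`, the fraction of bisulfite reads reporting
#' a "C" at the site.  Zero-total cells are undefined and returned as NA,
#' never as 0.
#'
#' @param count_M methylated ("C") read count(s).
#' @param count_total total read count(s).
#' @return percentage(s) in \[0, 100\]; NA where `count_total` is 0 or NA.
#' @export
methylation_percent <- function(count_M, count_total) {
  if (any(count_M > count_total, na.rm = TRUE))
    stop("count_M exceeds count_total")
  if (any(count_M < 0 | count_total < 0, na.rm = TRUE))
    stop("negative counts")
  out <- ifelse(!is.na(count_total) & count_total >= 1,
                100 * count_M / count_total, NA_real_)
  out
}

#' Apply the CpG10 coverage filter
#'
#' Cells covered by fewer than `min_reads` reads are set missing, and sites
#' left missing in every sample are dropped.  With the default of 10 this is
#' the "CpGs10" filter: only CpGs covered by at least 10 uniquely mapped
#' reads enter the analysis.  The operation is idempotent.
#'
#' @param x a [CountMatrix].
#' @param min_reads minimum total reads per cell (inclusive).
#' @return a filtered [CountMatrix].
#' @export
filter_cpg10 <- function(x, min_reads = 10L) {
  stopifnot(inherits(x, "CountMatrix"))
  if (min_reads < 1) stop("min_reads must be >= 1")
  low <- !is.na(x$total) & x$total < min_reads
  x$meth[low] <- NA_integer_
  x$total[low] <- NA_integer_
  keep <- rowSums(!is.na(x$total)) > 0
  subset_matrix(x, sites = keep)
}

#' Classify sites by methylation level
#'
#' Hypomethylated below 20%, hypermethylated above 80%, intermediate in the
#' closed interval \[20, 80\].
#'
#' @param percentages numeric vector in \[0, 100\] (NAs allowed and
#'   ignored in the fractions).
#' @return list with `class` (factor hypo/intermediate/hyper, NA preserved)
#'   and `fractions` (named percentages over non-missing values, summing to
#'   100).
#' @export
classify_sites <- function(percentages) {
  ok <- !is.na(percentages)
  if (any(percentages[ok] < 0 | percentages[ok] > 100))
    stop("methylation percentages must lie in [0, 100]")
  cls <- rep(NA_character_, length(percentages))
  cls[ok & percentages < 20] <- "hypo"
  cls[ok & percentages >= 20 & percentages <= 80] <- "intermediate"
  cls[ok & percentages > 80] <- "hyper"
  cls <- factor(cls, levels = c("hypo", "intermediate", "hyper"))
  fr <- 100 * table(cls) / sum(ok)
  list(class = cls,
       fractions = c(hypo = unname(fr["hypo"]),
                     intermediate = unname(fr["intermediate"]),
                     hyper = unname(fr["hyper"])))
}

#' Bisulfite conversion rate from the spike-in control
#'
#' The conversion rate is estimated as the percentage of unmethylated
#' spike-in cytosines read as converted ("T").
#'
#' @param spikein_converted converted spike-in count.
#' @param spikein_total total spike-in cytosines.
#' @return percentage; NA with a warning when `spikein_total` is 0.
#' @export
estimate_conversion_rate <- function(spikein_converted, spikein_total) {
  out <- rep(NA_real_, length(spikein_total))
  zero <- is.na(spikein_total) | spikein_total < 1
  if (any(zero)) warning("spike-in total of 0: conversion rate undefined")
  out[!zero] <- 100 * spikein_converted[!zero] / spikein_total[!zero]
  out
}

#' Per-sample quality-control summary
#'
#' Computes, for each sample, every library statistic derivable from the
#' counts: number of covered CpGs, mean coverage, percentage of CpGs
#' passing the CpG10 filter, bisulfite conversion rate (from the spike-in
#' table), mean methylation at CpGs10, and the hypo / intermediate / hyper
#' class fractions.
#'
#' @param x a [CountMatrix] (unfiltered; the CpG10 filter is applied
#'   internally for the CpG10-conditional rows).
#' @param spikeins optional data.frame(sample_id, converted, total).
#' @param min_reads the CpG10 threshold.
#' @return data.frame, one row per sample.
#' @export
qc_summary <- function(x, spikeins = NULL, min_reads = 10L) {
  stopifnot(inherits(x, "CountMatrix"))
  m <- nrow(x$samples)
  if (nrow(x$sites) == 0) {
    return(data.frame(sample_id = x$samples$sample_id, n_covered = 0L,
                      mean_coverage = NA_real_, pct_cpgs10 = NA_real_,
                      conversion_rate = NA_real_,
                      mean_methylation_cpgs10 = NA_real_,
                      pct_hypo = NA_real_, pct_intermediate = NA_real_,
                      pct_hyper = NA_real_))
  }
  out <- data.frame(sample_id = x$samples$sample_id,
                    n_covered = NA_integer_, mean_coverage = NA_real_,
                    pct_cpgs10 = NA_real_, conversion_rate = NA_real_,
                    mean_methylation_cpgs10 = NA_real_, pct_hypo = NA_real_,
                    pct_intermediate = NA_real_, pct_hyper = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    tot <- x$total[, j]; meth <- x$meth[, j]
    cov <- !is.na(tot) & tot > 0
    out$n_covered[j] <- sum(cov)
    out$mean_coverage[j] <- mean(tot[cov])
    ten <- cov & tot >= min_reads
    out$pct_cpgs10[j] <- 100 * sum(ten) / sum(cov)
    pct10 <- methylation_percent(meth[ten], tot[ten])
    out$mean_methylation_cpgs10[j] <- mean(pct10)
    fr <- classify_sites(pct10)$fractions
    out$pct_hypo[j] <- fr[["hypo"]]
    out$pct_intermediate[j] <- fr[["intermediate"]]
    out$pct_hyper[j] <- fr[["hyper"]]
  }
  if (!is.null(spikeins)) {
    idx <- match(out$sample_id, spikeins$sample_id)
    out$conversion_rate <- estimate_conversion_rate(
      spikeins$converted[idx], spikeins$total[idx])
  }
  if ("group_label" %in% names(x$samples))
    out$group_label <- x$samples$group_label
  out
}
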