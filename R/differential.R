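#' Comparison specification for DMC calling
#'
#' Bundles the thresholds of a two-group differential methylation
#' comparison: a site is a DMC when it is covered in at least
#' `min_samples_per_group` samples of each group, its weighted-FDR adjusted
#' p-value is strictly below `alpha_adj`, and the absolute between-group
#' methylation difference is at least `min_diff` percentage points.
#'
#' @param group1,group2 group labels; `group1` is the reference orientation
#'   (positive difference = hypermethylated in `group1`).
#' @param min_samples_per_group coverage requirement (inclusive).
#' @param alpha_adj adjusted-p threshold (strict).
#' @param min_diff minimum |difference| in percentage points (inclusive).
#' @param ihw_alpha nominal FDR level recorded for the weighting step.
#' @param ihw_bins number of covariate bins for [ihw_adjust()].
#' @return list of class `comparison_spec`.
#' @export
comparison_spec <- function(group1, group2, min_samples_per_group = 4L,
                            alpha_adj = 0.1, min_diff = 10,
                            ihw_alpha = 0.05, ihw_bins = 10L) {
  if (identical(group1, group2)) stop("group labels must be distinct")
  if (alpha_adj <= 0 || min_diff <= 0 || ihw_alpha <= 0)
    stop("thresholds must be positive")
  out <- list(group1 = group1, group2 = group2,
              min_samples_per_group = as.integer(min_samples_per_group),
              alpha_adj = alpha_adj, min_diff = min_diff,
              ihw_alpha = ihw_alpha, ihw_bins = as.integer(ihw_bins))
  class(out) <- "comparison_spec"
  out
}

#' Shrunk beta-binomial dispersion estimates
#'
#' Per-site method-of-moments estimate of the beta-binomial dispersion phi
#' (the across-replicate overdispersion of methylated counts beyond
#' binomial sampling), shrunk toward the genome-wide mean of log
#' dispersions by empirical-Bayes weighting.  For sample j with coverage
#' n_j and proportion p_j in a group with pooled proportion p, the moment
#' identity `E[(p_j - p)^2] = p(1-p) (1/n_j + phi (1 - 1/n_j))` is solved
#' for phi per sample and averaged; the shrinkage weight grows with the
#' number of informative samples at the site.
#'
#' @param meth1,total1 matrices (sites x samples) for group 1.
#' @param meth2,total2 matrices for group 2.
#' @param prior_df prior "sample size": the shrinkage weight of the site
#'   estimate is `J / (J + prior_df)` with J the number of covered samples.
#' @param phi_range final clipping range for phi.
#' @return list with `phi` (shrunk, per site), `phi_raw` (unshrunk
#'   method-of-moments, truncated at 0) and `prior_phi` (the genome-wide
#'   shrinkage target).
#' @export
estimate_dispersion_shrunk <- function(meth1, total1, meth2, total2,
                                       prior_df = 20,
                                       phi_range = c(1e-6, 0.999)) {
  site_phi <- function(meth, total) {
    p_hat <- rowSums(meth, na.rm = TRUE) / rowSums(total, na.rm = TRUE)
    pj <- meth / total
    denom <- p_hat * (1 - p_hat)
    denom[denom <= 0] <- NA_real_          # degenerate (all 0 / all 1)
    resid <- (pj - p_hat)^2 / denom
    phi_j <- (resid - 1 / total) / (1 - 1 / total)
    phi_j[!is.finite(phi_j)] <- NA_real_
    list(est = rowMeans(phi_j, na.rm = TRUE),
         n = rowSums(!is.na(phi_j)))
  }
  g1 <- site_phi(meth1, total1)
  g2 <- site_phi(meth2, total2)
  n_info <- g1$n + g2$n
  est <- ifelse(n_info > 0,
                (ifelse(is.na(g1$est), 0, g1$est) * g1$n +
                 ifelse(is.na(g2$est), 0, g2$est) * g2$n) / pmax(n_info, 1),
                NA_real_)
  # genome-wide target: mean of the truncated per-site moment estimates
  # (individually very noisy and possibly negative at realistic replicate
  # numbers; the truncated mean is a stable, slightly conservative centre)
  prior_phi <- max(mean(pmax(est, 0), na.rm = TRUE), phi_range[1])
  if (!is.finite(prior_phi)) prior_phi <- phi_range[1]
  w <- n_info / (n_info + prior_df)
  shrunk <- ifelse(is.na(est), prior_phi,
                   w * pmax(est, 0) + (1 - w) * prior_phi)
  phi <- pmin(pmax(shrunk, phi_range[1]), phi_range[2])
  list(phi = phi, phi_raw = pmax(est, 0), prior_phi = prior_phi)
}

#' Beta-binomial Wald test for a group difference in methylation
#'
#' For each site, the group methylation proportion is the coverage-weighted
#' pooled proportion `sum(M) / sum(N)`; its variance under a beta-binomial
#' model with dispersion phi is
#' `p(1-p) * sum(n_j (1 + (n_j - 1) phi)) / (sum n_j)^2`.
#' The Wald statistic is the difference of the two group proportions over
#' the square root of the summed variances, referred to the standard
#' normal (two-sided).  For the variance (only), the proportion is
#' moderated by half a pseudo-read so that saturated sites (all 0% or all
#' 100%) keep a finite, nonzero standard error.
#'
#' @param meth1,total1,meth2,total2 count matrices (sites x samples).
#' @param phi per-site dispersion from [estimate_dispersion_shrunk()].
#' @return data.frame with n1, n2, mean1, mean2 (percent), diff
#'   (percentage points, group1 - group2), se, wald, p.
#' @export
wald_test <- function(meth1, total1, meth2, total2, phi) {
  group_stats <- function(meth, total) {
    M <- rowSums(meth, na.rm = TRUE)
    N <- rowSums(total, na.rm = TRUE)
    p_hat <- ifelse(N > 0, M / N, NA_real_)
    p_mod <- (M + 0.5) / (N + 1)
    var_num <- rowSums(total * (1 + (total - 1) * phi), na.rm = TRUE)
    v <- p_mod * (1 - p_mod) * var_num / N^2
    list(p = p_hat, v = v, n = rowSums(!is.na(total)))
  }
  g1 <- group_stats(meth1, total1)
  g2 <- group_stats(meth2, total2)
  diff <- g1$p - g2$p
  se <- sqrt(g1$v + g2$v)
  wald <- ifelse(se > 0, diff / se, 0)
  p <- ifelse(abs(diff) < 1e-12, 1, 2 * pnorm(-abs(wald)))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(n1 = g1$n, n2 = g2$n, mean1 = 100 * g1$p, mean2 = 100 * g2$p,
             diff = 100 * diff, se = 100 * se, wald = wald, p = p)
}

#' Site-level differential methylation tests for one comparison
#'
#' Runs the dispersion-shrunk beta-binomial Wald test at every CpG covered
#' in at least `min_samples_per_group` samples of both groups, then applies
#' covariate-weighted FDR adjustment ([ihw_adjust()]) with the per-site
#' average methylation across both groups as the covariate.
#'
#' @param x a [CountMatrix] (CpG10-filtered).
#' @param spec a [comparison_spec()].
#' @param prior_df dispersion-shrinkage prior strength.
#' @return data.frame of site tests: chrom, pos, n1, n2, mean1, mean2,
#'   diff, phi, wald, p, covariate, weight, p_adj.
#' @export
dm_test <- function(x, spec, prior_df = 20) {
  stopifnot(inherits(x, "CountMatrix"), inherits(spec, "comparison_spec"))
  labs <- x$samples$group_label
  j1 <- which(labs == spec$group1)
  j2 <- which(labs == spec$group2)
  if (!length(j1) || !length(j2))
    stop("comparison groups not present in the sample sheet")
  m1 <- x$meth[, j1, drop = FALSE]; t1 <- x$total[, j1, drop = FALSE]
  m2 <- x$meth[, j2, drop = FALSE]; t2 <- x$total[, j2, drop = FALSE]
  n1 <- rowSums(!is.na(t1)); n2 <- rowSums(!is.na(t2))
  keep <- n1 >= spec$min_samples_per_group & n2 >= spec$min_samples_per_group
  m1 <- m1[keep, , drop = FALSE]; t1 <- t1[keep, , drop = FALSE]
  m2 <- m2[keep, , drop = FALSE]; t2 <- t2[keep, , drop = FALSE]
  disp <- estimate_dispersion_shrunk(m1, t1, m2, t2, prior_df = prior_df)
  wt <- wald_test(m1, t1, m2, t2, disp$phi)
  covariate <- (wt$mean1 + wt$mean2) / 2
  adj <- ihw_adjust(wt$p, covariate, n_bins = spec$ihw_bins,
                    alpha = spec$ihw_alpha)
  out <- data.frame(x$sites[keep, , drop = FALSE], wt,
                    phi = disp$phi, covariate = covariate,
                    weight = adj$weights, p_adj = adj$p_adj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

# Storey pi0 estimate at a fixed lambda, clipped away from 0
storey_pi0 <- function(p, lambda = 0.5, clip = c(0.05, 1)) {
  pi0 <- sum(p > lambda) / (length(p) * (1 - lambda))
  min(max(pi0, clip[1]), clip[2])
}

#' Covariate-weighted FDR adjustment (binned weighted Benjamini-Hochberg)
#'
#' An independent-hypothesis-weighting style adjustment: the covariate is
#' split into quantile bins, each bin receives a weight proportional to its
#' estimated non-null fraction (1 - pi0, Storey's estimator at lambda =
#' 0.5, clipped to \[0.05, 1\]), weights are normalised to mean 1 over all
#' hypotheses, and Benjamini-Hochberg is applied to `p / weight`.  With a
#' single bin (or a constant covariate) the procedure reduces exactly to
#' unweighted Benjamini-Hochberg.
#'
#' @param p raw p-values.
#' @param covariate per-hypothesis covariate (finite), independent of p
#'   under the null — e.g. the average methylation across both groups.
#' @param n_bins number of quantile bins (>= 1).
#' @param alpha nominal FDR level (recorded; the weights do not depend on
#'   it in this binned implementation).
#' @param min_bin bins smaller than this are merged with their neighbour.
#' @param weight_smooth regularisation added to each bin's estimated
#'   non-null fraction before normalisation; pulls the weights toward
#'   uniform, which stabilises the finite-sample FDR of the weighted
#'   procedure (0 recovers fully data-driven weights).
#' @return list with `weights` (mean 1), `p_adj`, `bins` (factor) and
#'   `pi0` (per retained bin).
#' @export
ihw_adjust <- function(p, covariate = NULL, n_bins = 10L, alpha = 0.05,
                       min_bin = 200L, weight_smooth = 0.05) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  m <- length(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  if (is.null(covariate)) covariate <- rep(0, m)
  if (any(!is.finite(covariate)))
    stop("covariate must be finite for every hypothesis")
  # quantile bins; degenerate covariates collapse to one bin
  brk <- unique(quantile(covariate, probs = seq(0, 1, length.out =
                                                  n_bins + 1)))
  bins <- if (length(brk) <= 2) factor(rep(1L, m)) else
    cut(covariate, breaks = brk, include.lowest = TRUE)
  # merge undersized bins into the previous level
  repeat {
    tab <- table(bins)
    small <- which(tab < min_bin & tab > 0)
    if (!length(small) || nlevels(droplevels(bins)) <= 1) break
    lv <- levels(bins)[small[1]]
    others <- setdiff(levels(bins)[table(bins) > 0], lv)
    target <- others[which.min(abs(match(others, levels(bins)) -
                                     match(lv, levels(bins))))]
    bins[bins == lv] <- target
    bins <- droplevels(bins)
  }
  bins <- droplevels(bins)
  pi0 <- vapply(levels(bins), function(b) storey_pi0(p[bins == b]),
                numeric(1))
  wraw <- (1 - pi0) + weight_smooth
  if (all(wraw <= 0)) wraw[] <- 1          # uninformative: uniform weights
  w_bin <- wraw[as.character(bins)]
  weights <- w_bin * m / sum(w_bin)        # budget: mean weight exactly 1
  pw <- ifelse(weights > 0, pmin(p / weights, 1), 1)
  p_adj <- p.adjust(pw, method = "BH")
  p_adj[weights == 0] <- 1
  list(weights = unname(weights), p_adj = unname(p_adj), bins = bins,
       pi0 = pi0)
}

#' Call differentially methylated cytosines
#'
#' Applies the three DMC thresholds to a table of site tests: coverage in
#' at least `min_samples_per_group` bulls of each group, adjusted p
#' strictly below `alpha_adj`, and |difference| of at least `min_diff`
#' percentage points.  Every emitted row is re-checked against the
#' thresholds before returning.
#'
#' @param tests output of [dm_test()].
#' @param spec the [comparison_spec()] (defaults to the one stored on
#'   `tests`).
#' @return data.frame of DMCs with a `direction` column
#'   (hyper_in_group1 / hypo_in_group1).
#' @export
call_dmcs <- function(tests, spec = attr(tests, "spec")) {
  stopifnot(inherits(spec, "comparison_spec"))
  pass <- tests$n1 >= spec$min_samples_per_group &
    tests$n2 >= spec$min_samples_per_group &
    tests$p_adj < spec$alpha_adj &
    abs(tests$diff) >= spec$min_diff
  out <- tests[pass, , drop = FALSE]
  out$direction <- ifelse(out$diff > 0, "hyper_in_group1", "hypo_in_group1")
  stopifnot(all(out$p_adj < spec$alpha_adj),
            all(abs(out$diff) >= spec$min_diff),
            all(out$n1 >= spec$min_samples_per_group &
                  out$n2 >= spec$min_samples_per_group))
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

#' Merge DMCs into differentially methylated regions
#'
#' Greedy chaining: consecutive DMCs on the same chromosome whose positions
#' are at most `max_gap` bp apart (inclusive) are joined; maximal chains
#' with at least `min_dmcs` members become DMRs.  A DMR spans the positions
#' of its first and last member DMC.
#'
#' @param dmcs data.frame with chrom, pos (and optionally diff/direction).
#' @param min_dmcs minimum member count.
#' @param max_gap maximum inter-DMC distance in bp (position-to-position,
#'   inclusive).
#' @return data.frame: chrom, start, end, n_dmcs, mean_diff, direction
#'   (majority vote of member signs), member_pos (comma-separated).
#' @export
call_dmrs <- function(dmcs, min_dmcs = 3L, max_gap = 100L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_dmcs = integer(0),
                      mean_diff = numeric(0), direction = character(0),
                      member_pos = character(0), stringsAsFactors = FALSE)
  if (!nrow(dmcs)) return(empty)
  dmcs <- dmcs[order(dmcs$chrom, dmcs$pos), , drop = FALSE]
  new_chain <- c(TRUE, diff(dmcs$pos) > max_gap |
                   dmcs$chrom[-nrow(dmcs)] != dmcs$chrom[-1])
  chain <- cumsum(new_chain)
  out <- lapply(split(seq_len(nrow(dmcs)), chain), function(idx) {
    if (length(idx) < min_dmcs) return(NULL)
    d <- dmcs[idx, , drop = FALSE]
    diffs <- if ("diff" %in% names(d)) d$diff else rep(NA_real_,
                                                       length(idx))
    data.frame(chrom = d$chrom[1], start = min(d$pos), end = max(d$pos),
               n_dmcs = length(idx), mean_diff = mean(diffs),
               direction = if (all(is.na(diffs))) NA_character_ else
                 ifelse(mean(diffs > 0) >= 0.5, "hyper_in_group1",
                        "hypo_in_group1"),
               member_pos = paste(d$pos, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Compare two DMC sets
#'
#' Set arithmetic over DMCs keyed by (chrom, pos): sizes, intersection,
#' union (by inclusion-exclusion), the shared percentage
#' `100 * |A intersect B| / |A union B|`, and the per-set fraction of DMCs
#' hypermethylated in group 1.
#'
#' @param dmcs_a,dmcs_b DMC data.frames with chrom, pos and optionally
#'   direction.
#' @param label_a,label_b names used in the output.
#' @return list of class `dmc_set_comparison`.
#' @export
compare_dmc_sets <- function(dmcs_a, dmcs_b, label_a = "A", label_b = "B") {
  key <- function(d) paste(d$chrom, d$pos)
  ka <- unique(key(dmcs_a)); kb <- unique(key(dmcs_b))
  n_int <- length(intersect(ka, kb))
  n_union <- length(ka) + length(kb) - n_int
  hyper_pct <- function(d) if ("direction" %in% names(d) && nrow(d))
    100 * mean(d$direction == "hyper_in_group1") else NA_real_
  out <- list(label_a = label_a, label_b = label_b,
              size_a = length(ka), size_b = length(kb),
              intersection = n_int, union = n_union,
              shared_pct = if (n_union > 0) 100 * n_int / n_union else
                NA_real_,
              hyper_pct_a = hyper_pct(dmcs_a),
              hyper_pct_b = hyper_pct(dmcs_b))
  class(out) <- "dmc_set_comparison"
  out
}

#' @export
print.dmc_set_comparison <- function(x, ...) {
  cat(sprintf("DMC sets: |%s| = %d, |%s| = %d\n", x$label_a, x$size_a,
              x$label_b, x$size_b))
  cat(sprintf("  intersection %d, union %d, shared %.1f%%\n",
              x$intersection, x$union, x$shared_pct))
  invisible(x)
}

#' Export table for volcano plots
#'
#' One row per tested site: the methylation difference (group1 - group2
#' orientation), -log10 of the raw p-value, a pass/fail DMC flag and, for
#' failures, the first threshold missed ("coverage", "p_adj" or "diff").
#'
#' @param tests output of [dm_test()].
#' @param spec the [comparison_spec()].
#' @return data.frame: chrom, pos, diff, neg_log10_p, is_dmc, fail_reason.
#' @export
volcano_table <- function(tests, spec = attr(tests, "spec")) {
  stopifnot(inherits(spec, "comparison_spec"))
  cov_ok <- tests$n1 >= spec$min_samples_per_group &
    tests$n2 >= spec$min_samples_per_group
  p_ok <- tests$p_adj < spec$alpha_adj
  d_ok <- abs(tests$diff) >= spec$min_diff
  reason <- rep(NA_character_, nrow(tests))
  reason[!d_ok] <- "diff"
  reason[!p_ok] <- "p_adj"
  reason[!cov_ok] <- "coverage"
  data.frame(chrom = tests$chrom, pos = tests$pos, diff = tests$diff,
             neg_log10_p = -log10(tests$p), is_dmc = cov_ok & p_ok & d_ok,
             fail_reason = reason, stringsAsFactors = FALSE)
}
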