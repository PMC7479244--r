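#' Consolidate pyrosequencing replicates
#'
#' Each CpG is assayed at least in duplicate; a duplicate differing by more
#' than `max_diff` percentage points is inconsistent and triggers repeat
#' measurements.  The consolidation rule: keep the largest subset of
#' replicates whose pairwise range is at most `max_diff` (ties broken
#' toward including the earliest replicates) and report its mean; if no
#' consistent subset of size >= 2 exists the measurement is missing and
#' flagged.
#'
#' @param measurements long data.frame: region_id, cpg_index, sample_id,
#'   replicate, percentage.
#' @param max_diff consistency threshold in percentage points.
#' @return data.frame: region_id, cpg_index, sample_id, percentage (NA if
#'   unresolvable), n_replicates, n_used, flag ("ok", "inconsistent",
#'   "single_replicate").
#' @export
consolidate_replicates <- function(measurements, max_diff = 5) {
  need <- c("region_id", "cpg_index", "sample_id", "replicate",
            "percentage")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (any(measurements$percentage < 0 | measurements$percentage > 100,
          na.rm = TRUE))
    stop("percentages must lie in [0, 100]")
  key <- interaction(measurements$region_id, measurements$cpg_index,
                     measurements$sample_id, drop = TRUE)
  rows <- lapply(split(measurements, key), function(d) {
    d <- d[order(d$replicate), ]
    v <- d$percentage
    out <- data.frame(region_id = d$region_id[1],
                      cpg_index = d$cpg_index[1],
                      sample_id = d$sample_id[1],
                      percentage = NA_real_,
                      n_replicates = length(v), n_used = 0L,
                      flag = "inconsistent", stringsAsFactors = FALSE)
    if (length(v) < 2) { out$flag <- "single_replicate"; return(out) }
    best <- integer(0)
    # largest consistent subset; subset count is tiny (<= 2^6)
    for (size in seq(length(v), 2)) {
      combos <- utils::combn(seq_along(v), size, simplify = FALSE)
      ok <- Filter(function(ix) diff(range(v[ix])) <= max_diff, combos)
      if (length(ok)) {
        # ties: lexicographically smallest index set = earliest replicates
        best <- ok[[which.min(vapply(ok, function(ix)
          sum(2^(-ix)) * -1, numeric(1)))]]
        break
      }
    }
    if (length(best) >= 2) {
      out$percentage <- mean(v[best])
      out$n_used <- length(best)
      out$flag <- "ok"
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$region_id, res$cpg_index, res$sample_id), ]
}

#' RRBS vs pyrosequencing concordance per region
#'
#' For each region (typically a DMR), the per-sample RRBS value is the mean
#' methylation percentage of the member CpGs, the pyrosequencing value is
#' the mean of the consolidated assay percentages over the region's CpGs,
#' and concordance is Spearman's rank correlation over the paired samples.
#'
#' @param rrbs data.frame: region_id, sample_id, percentage (per-sample
#'   RRBS region means, e.g. from [dmr_sample_means()]).
#' @param pyro consolidated measurements from [consolidate_replicates()].
#' @param min_pairs minimum paired samples per region.
#' @return data.frame: region_id, n, rho, p (NA when a vector is
#'   constant).
#' @export
spearman_concordance <- function(rrbs, pyro, min_pairs = 5L) {
  pyro_region <- aggregate(percentage ~ region_id + sample_id, data = pyro,
                           FUN = mean, na.action = stats::na.omit)
  regions <- sort(unique(rrbs$region_id))
  out <- lapply(regions, function(rg) {
    a <- rrbs[rrbs$region_id == rg, ]
    b <- pyro_region[pyro_region$region_id == rg, ]
    merged <- merge(a, b, by = "sample_id", suffixes = c("_rrbs", "_pyro"))
    merged <- merged[complete.cases(merged[, c("percentage_rrbs",
                                               "percentage_pyro")]), ]
    if (nrow(merged) < min_pairs)
      stop(sprintf("region '%s' has %d paired samples (< %d)", rg,
                   nrow(merged), min_pairs))
    if (sd(merged$percentage_rrbs) == 0 || sd(merged$percentage_pyro) == 0)
      return(data.frame(region_id = rg, n = nrow(merged), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(merged$percentage_rrbs,
                                    merged$percentage_pyro,
                                    method = "spearman"))
    data.frame(region_id = rg, n = nrow(merged),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample RRBS means over DMR member CpGs
#'
#' @param x a [CountMatrix].
#' @param dmrs output of [call_dmrs()] (uses `chrom` and `member_pos`).
#' @return data.frame: region_id, sample_id, percentage.
#' @export
dmr_sample_means <- function(x, dmrs) {
  stopifnot(inherits(x, "CountMatrix"))
  pct <- percent_matrix(x)
  key <- paste(x$sites$chrom, x$sites$pos)
  out <- list()
  for (k in seq_len(nrow(dmrs))) {
    pos <- as.integer(strsplit(dmrs$member_pos[k], ",")[[1]])
    idx <- match(paste(dmrs$chrom[k], pos), key)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    vals <- colMeans(pct[idx, , drop = FALSE], na.rm = TRUE)
    out[[k]] <- data.frame(
      region_id = sprintf("%s:%d-%d", dmrs$chrom[k], dmrs$start[k],
                          dmrs$end[k]),
      sample_id = names(vals), percentage = unname(vals),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-CpG group tests of pyrosequencing percentages
#'
#' Runs the age-stratified two-group permutation test at each assayed CpG
#' and marks significance at `alpha`.
#'
#' @param pyro consolidated measurements from [consolidate_replicates()].
#' @param sample_sheet sample sheet with sample_id, group and age.
#' @param n_perm Monte-Carlo permutations per CpG.
#' @param seed base seed (offset per CpG for independence).
#' @param alpha significance mark threshold.
#' @return data.frame: region_id, cpg_index, n, observed (group mean
#'   difference), p, significant.
#' @export
pyro_group_tests <- function(pyro, sample_sheet, n_perm = 10000L,
                             seed = 1L, alpha = 0.05) {
  idx <- match(pyro$sample_id, sample_sheet$sample_id)
  pyro$group <- sample_sheet$group[idx]
  pyro$age <- sample_sheet$age[idx]
  # drop age strata that carry a single diet group once, up front
  mixed <- vapply(split(pyro$group, pyro$age),
                  function(g) length(unique(g)) >= 2, logical(1))
  if (!all(mixed)) {
    warning("age stratum/strata without both diet groups dropped: ",
            paste(names(mixed)[!mixed], collapse = ", "))
    pyro <- pyro[pyro$age %in% names(mixed)[mixed], ]
  }
  key <- interaction(pyro$region_id, pyro$cpg_index, drop = TRUE)
  i <- 0L
  out <- lapply(split(pyro, key), function(d) {
    i <<- i + 1L
    d <- d[!is.na(d$percentage), ]
    res <- stratified_permutation_test(
      d$percentage, factor(d$group, levels = c("HM", "MM")),
      strata = d$age, n_perm = n_perm, seed = seed + i)
    data.frame(region_id = d$region_id[1], cpg_index = d$cpg_index[1],
               n = nrow(d), observed = res$observed, p = res$p,
               significant = res$p < alpha, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
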