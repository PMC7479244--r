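new_permutation_result <- function(observed, n_perm, p, seed, statistic,
                                   extra = list()) {
  out <- c(list(observed = observed, n_perm = n_perm, p = p, seed = seed,
                statistic = statistic), extra)
  class(out) <- "permutation_result"
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo permutation test (%s)\n", x$statistic))
  cat(sprintf("  observed = %.6g, n_perm = %d, p = %.6g (add-one)\n",
              x$observed, x$n_perm, x$p))
  invisible(x)
}

#' k-sample Monte-Carlo permutation test
#'
#' Tests whether k groups share a common location by permuting group labels
#' uniformly over all observations.  The statistic is the variance of the
#' group means (any location-sensitive choice works; this one is recorded
#' in the result).  The p-value uses the add-one estimator
#' `(1 + #\{permuted >= observed\}) / (n_perm + 1)`, so it can never be 0.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, each non-empty).
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed integer seed.
#' @return a `permutation_result` with observed statistic, n_perm, p, seed.
#' @export
ksample_permutation_test <- function(values, groups, n_perm = 100000L,
                                     seed = 1L) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  if (length(values) != length(groups)) stop("length mismatch")
  if (length(values) < 2) stop("need >= 2 observations")
  idx <- split(seq_along(values), groups)
  gm <- function(v) vapply(idx, function(ii) mean(v[ii]), numeric(1))
  obs <- var(gm(values))
  n <- length(values)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm),
                   function(i) var(gm(values[sample.int(n)])),
                   numeric(1))
    p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
    new_permutation_result(obs, as.integer(n_perm), p, seed,
                           "between-group variance of group means")
  })
}

#' Stratified two-sample Monte-Carlo permutation test
#'
#' Two-group test of a difference in means with correction for a stratified
#' population: group labels are permuted independently *within* each
#' stratum, preserving the per-stratum group counts in every draw, so a
#' stratum main effect (e.g. age) cannot masquerade as a group effect.
#' Strata containing only one of the two groups carry no information and
#' are dropped with a warning.  The two-sided p doubles the smaller
#' add-one tail, capped at 1.
#'
#' @param values numeric vector.
#' @param groups two-level label per observation (first level minus second
#'   defines the sign of the statistic; pass a factor to control order).
#' @param strata stratum label per observation, or NULL for an unstratified
#'   test.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed integer seed.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return a `permutation_result`.
#' @export
stratified_permutation_test <- function(values, groups, strata = NULL,
                                        n_perm = 100000L, seed = 1L,
                                        alternative = c("two.sided",
                                                        "greater", "less")) {
  alternative <- match.arg(alternative)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2)
    stop("need exactly 2 groups with observations, got ", nlevels(groups))
  if (is.null(strata)) strata <- rep(1L, length(values))
  if (length(values) != length(groups) || length(values) != length(strata))
    stop("length mismatch")
  strata <- as.factor(strata)
  keep <- rep(TRUE, length(values))
  for (s in levels(strata)) {
    in_s <- strata == s
    if (length(unique(groups[in_s])) < 2) {
      warning("stratum '", s, "' contains a single group; dropped")
      keep[in_s] <- FALSE
    }
  }
  values <- values[keep]; groups <- droplevels(groups[keep])
  strata <- droplevels(strata[keep])
  if (nlevels(groups) != 2) stop("no stratum retains both groups")
  g1 <- levels(groups)[1]
  stat <- function(v) mean(v[groups == g1]) - mean(v[groups != g1])
  obs <- stat(values)
  str_idx <- split(seq_along(values), strata)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      v <- values
      for (idx in str_idx) v[idx] <- v[idx][sample.int(length(idx))]
      stat(v)
    }, numeric(1))
    tol <- 1e-12
    p_ge <- (1 + sum(perm >= obs - tol)) / (n_perm + 1)
    p_le <- (1 + sum(perm <= obs + tol)) / (n_perm + 1)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge, less = p_le)
    new_permutation_result(obs, as.integer(n_perm), p, seed,
                           sprintf("difference of group means (%s - %s)",
                                   g1, levels(groups)[2]),
                           extra = list(alternative = alternative,
                                        n_strata = nlevels(strata)))
  })
}
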