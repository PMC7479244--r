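#' Per-CpG, per-sample bisulfite count matrix
#'
#' The pipeline's central container: an ordered set of CpG sites (forward
#' strand C position, 1-based), a sample sheet, and two aligned integer
#' matrices of methylated and total read counts.  `NA` marks a site with no
#' coverage in a sample.
#'
#' @param sites data.frame with `chrom` and `pos`; (chrom, pos) must be
#'   unique.
#' @param samples data.frame with at least `sample_id`; typically also
#'   `bull_id`, `group`, `age`, `group_label`.
#' @param meth,total integer matrices, sites x samples, with
#'   `meth <= total` cell-wise.
#' @return an object of class `CountMatrix`.
#' @export
CountMatrix <- function(sites, samples, meth, total) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)),
            is.data.frame(samples), "sample_id" %in% names(samples),
            is.matrix(meth), is.matrix(total),
            nrow(meth) == nrow(sites), ncol(meth) == nrow(samples),
            all(dim(meth) == dim(total)))
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicate (chrom, pos) in sites")
  bad <- !is.na(meth) & !is.na(total) & (meth > total | meth < 0)
  if (any(bad)) stop("count_methylated must satisfy 0 <= meth <= total")
  colnames(meth) <- colnames(total) <- samples$sample_id
  ord <- order(sites$chrom, sites$pos)
  x <- list(sites = sites[ord, , drop = FALSE],
            samples = samples,
            meth = meth[ord, , drop = FALSE],
            total = total[ord, , drop = FALSE])
  rownames(x$sites) <- NULL
  class(x) <- "CountMatrix"
  x
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d CpG sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  cov <- mean(x$total, na.rm = TRUE)
  cat(sprintf("  mean coverage %.1f, %.1f%% cells covered\n",
              cov, 100 * mean(!is.na(x$total))))
  if ("group_label" %in% names(x$samples))
    cat("  groups:", paste(sprintf("%s=%d",
        names(table(x$samples$group_label)),
        table(x$samples$group_label)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a CountMatrix by site and/or sample
#'
#' @param x a [CountMatrix].
#' @param sites logical/integer index over sites.
#' @param samples logical/integer index over samples, or sample ids.
#' @return a [CountMatrix].
#' @export
subset_matrix <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  if (is.null(samples)) sj <- seq_len(nrow(x$samples))
  else if (is.character(samples)) sj <- match(samples,
                                              x$samples$sample_id)
  else sj <- samples
  CountMatrix(x$sites[si, , drop = FALSE],
              x$samples[sj, , drop = FALSE],
              x$meth[si, sj, drop = FALSE],
              x$total[si, sj, drop = FALSE])
}

#' Methylation percentage matrix
#'
#' @param x a [CountMatrix].
#' @return numeric matrix (sites x samples) of methylation percentages;
#'   uncovered cells are NA.
#' @export
percent_matrix <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  100 * x$meth / x$total
}
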