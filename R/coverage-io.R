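#' Read a bisulfite coverage file
#'
#' Parses the standard 6-column tab-separated coverage dialect (chrom,
#' 1-based start, 1-based end, methylation percentage, count methylated,
#' count unmethylated).  The percentage column is ignored and recomputed
#' downstream from the counts; malformed count fields are reported with
#' their line number.
#'
#' @param path file path.
#' @param sample_id optional id attached to the result.
#' @return data.frame with chrom, pos, count_M, count_U (and the sample id
#'   as attribute `"sample_id"`); zero rows with a warning for an empty
#'   file.
#' @export
read_coverage_file <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such coverage file: ", path)
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, colClasses = "character",
               quote = "", comment.char = ""),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    warning("empty coverage file: ", path)
    out <- data.frame(chrom = character(0), pos = integer(0),
                      count_M = integer(0), count_U = integer(0))
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  if (ncol(raw) != 6)
    stop(sprintf("coverage file %s: expected 6 tab-separated columns, got %d",
                 path, ncol(raw)))
  to_int <- function(col, name) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("coverage file %s: non-integer %s at line %d (value '%s')",
                   path, name, bad[1], raw[[col]][bad[1]]))
    v
  }
  pos <- to_int(2, "position")
  count_m <- to_int(5, "count-methylated")
  count_u <- to_int(6, "count-unmethylated")
  if (any(count_m < 0 | count_u < 0))
    stop("coverage file ", path, ": negative counts")
  out <- data.frame(chrom = raw[[1]], pos = pos, count_M = count_m,
                    count_U = count_u, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  out
}

#' Merge CpG dyad strand counts
#'
#' A coverage file may report the two cytosines of one CpG dyad separately:
#' the forward-strand C at position p and the reverse-strand C at p+1.  In
#' `merged` mode, records at adjacent positions on the same chromosome are
#' summed into the forward (lower) position, pairing greedily from the left;
#' `forward_only` leaves records untouched.
#'
#' @param records data.frame(chrom, pos, count_M, count_U).
#' @param mode "merged" or "forward_only".
#' @return data.frame in the same shape, keyed by forward-strand positions.
#' @export
merge_strand_counts <- function(records, mode = c("merged", "forward_only")) {
  mode <- match.arg(mode)
  if (mode == "forward_only" || nrow(records) < 2) return(records)
  records <- records[order(records$chrom, records$pos), ]
  same_dyad <- c(diff(records$pos) == 1L &
                   records$chrom[-nrow(records)] == records$chrom[-1], FALSE)
  # greedy left-to-right: a record already consumed as the +1 partner of the
  # previous one cannot start a new pair
  take <- logical(nrow(records))
  i <- 1L
  while (i <= nrow(records)) {
    if (same_dyad[i]) { take[i] <- TRUE; i <- i + 2L } else i <- i + 1L
  }
  partner <- which(take) + 1L
  records$count_M[take] <- records$count_M[take] + records$count_M[partner]
  records$count_U[take] <- records$count_U[take] + records$count_U[partner]
  out <- records[-partner, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a CountMatrix from per-sample coverage files
#'
#' Reads one coverage file per row of the sample sheet, optionally merges
#' dyad strands, and aligns all samples on the union of observed CpG sites.
#'
#' @param paths named character vector of coverage files; names must match
#'   `sample_sheet$sample_id` (unnamed paths are taken in sheet order).
#' @param sample_sheet data.frame with at least `sample_id`.
#' @param strand_mode passed to [merge_strand_counts()]; default
#'   "forward_only" (simulated files are already dyad-merged).
#' @return a [CountMatrix].
#' @export
build_count_matrix <- function(paths, sample_sheet,
                               strand_mode = c("forward_only", "merged")) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(names(paths))) names(paths) <- sample_sheet$sample_id
  missing <- setdiff(sample_sheet$sample_id, names(paths))
  if (length(missing))
    stop("no coverage file for sample(s): ", paste(missing, collapse = ", "))
  recs <- lapply(sample_sheet$sample_id, function(sid)
    merge_strand_counts(read_coverage_file(paths[[sid]], sid),
                        mode = strand_mode))
  all_sites <- unique(do.call(rbind,
    lapply(recs, function(r) r[, c("chrom", "pos")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), ]
  rownames(all_sites) <- NULL
  key <- paste(all_sites$chrom, all_sites$pos)
  n <- nrow(all_sites); m <- nrow(sample_sheet)
  meth <- tot <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    idx <- match(paste(recs[[j]]$chrom, recs[[j]]$pos), key)
    meth[idx, j] <- recs[[j]]$count_M
    tot[idx, j] <- recs[[j]]$count_M + recs[[j]]$count_U
  }
  CountMatrix(all_sites, sample_sheet, meth, tot)
}

#' Read a sample sheet CSV
#'
#' @param path CSV with columns sample_id, bull_id, group, age and
#'   optionally group_label (derived from group+age when absent).
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "bull_id", "group", "age")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!"group_label" %in% names(sheet))
    sheet$group_label <- paste0(sheet$group, sheet$age)
  if (anyDuplicated(sheet[, c("bull_id", "age")]))
    stop("sample sheet: duplicated (bull_id, age)")
  sheet
}
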