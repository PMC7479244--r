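# Independent brute-force oracles used by the annotation and DMR tests.
# They share no code with the implementations they check: everything is
# computed by per-base painting or exhaustive window enumeration.

# Per-base gene-feature labels on [1, L] for one chromosome.  windows_df:
# data.frame(start, end, type).  Paint lowest-precedence first so that the
# highest-precedence feature ends up on top, mirroring the documented rule.
oracle_feature_vector <- function(L, windows_df) {
  precedence <- c("tss", "tts", "five_prime_utr", "three_prime_utr",
                  "exon", "intron", "promoter", "upstream_10kb",
                  "downstream_10kb")
  lab <- rep("intergenic", L)
  for (ft in rev(precedence)) {
    w <- windows_df[windows_df$type == ft, , drop = FALSE]
    for (k in seq_len(nrow(w))) {
      s <- max(1L, w$start[k]); e <- min(L, w$end[k])
      if (s <= e) lab[s:e] <- ft
    }
  }
  lab
}

# Per-base island/shore/shelf membership on [1, L] from raw island
# intervals (data.frame start, end), by distance bands.
oracle_context_vector <- function(L, islands) {
  in_island <- rep(FALSE, L)
  for (k in seq_len(nrow(islands))) {
    s <- max(1L, islands$start[k]); e <- min(L, islands$end[k])
    in_island[s:e] <- TRUE
  }
  near <- function(mask, d) {
    # TRUE within d bases of any TRUE in mask
    idx <- which(mask)
    out <- rep(FALSE, L)
    for (i in idx) out[max(1L, i - d):min(L, i + d)] <- TRUE
    out
  }
  # distance bands computed from the island mask
  isl_idx <- which(in_island)
  dist <- rep(Inf, L)
  if (length(isl_idx)) {
    # nearest island base distance, linear scan both directions
    dist[isl_idx] <- 0
    for (i in 2:L) dist[i] <- min(dist[i], dist[i - 1] + 1)
    for (i in (L - 1):1) dist[i] <- min(dist[i], dist[i + 1] + 1)
  }
  lab <- rep("open_sea", L)
  lab[dist <= 4000] <- "shelf"
  lab[dist <= 2000] <- "shore"
  lab[dist == 0] <- "island"
  lab
}

# Exhaustive DMR oracle: every contiguous window of sorted positions is a
# candidate; valid iff >= min_dmcs members, all consecutive gaps <= max_gap,
# and maximal (cannot be extended on either side).
oracle_dmrs <- function(pos, min_dmcs = 3L, max_gap = 100L) {
  pos <- sort(unique(pos))
  n <- length(pos)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_dmcs) next
      gaps <- diff(pos[i:j])
      if (length(gaps) && any(gaps > max_gap)) next
      left_ext <- i > 1 && (pos[i] - pos[i - 1]) <= max_gap
      right_ext <- j < n && (pos[j + 1] - pos[j]) <= max_gap
      if (!left_ext && !right_ext)
        out[[length(out) + 1L]] <- c(start = pos[i], end = pos[j],
                                     n = j - i + 1)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      n = integer(0)))
  unique(as.data.frame(do.call(rbind, out)))
}
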