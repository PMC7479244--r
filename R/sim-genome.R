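BASES <- c("A", "C", "G", "T")

# Rejection-sample non-overlapping intervals of the given lengths on [1, L].
# Returns a data.frame(start, end), 1-based closed, sorted; may place fewer
# than requested if the chromosome is crowded.
place_intervals <- function(L, lengths, max_tries = 50L) {
  placed <- data.frame(start = integer(0), end = integer(0))
  for (len in lengths) {
    if (len >= L) next
    for (try in seq_len(max_tries)) {
      s <- sample.int(L - len, 1L)
      e <- s + len - 1L
      if (!nrow(placed) || all(e < placed$start - 1L | s > placed$end + 1L)) {
        placed <- rbind(placed, data.frame(start = s, end = e))
        break
      }
    }
  }
  placed[order(placed$start), , drop = FALSE]
}

#' Generate a toy genome with annotation tracks
#'
#' Draws i.i.d. nucleotide sequences at the configured GC content, places
#' CpG islands (GC-enriched, CpG-preserving segments), depletes CpG
#' dinucleotides everywhere else, and scatters gene models and repeat
#' intervals.  The result is a self-consistent genome in which CpG islands
#' have a higher observed/expected CpG ratio than the background and MspI
#' (C^CGG) sites are dense enough for a reduced-representation digest.
#'
#' @param config a [sim_config()]; the RNG is seeded from `config$seed`.
#' @return an object of class `genome_bundle`: a list with `sequences`
#'   (named character vector), `cgis`, `repeats`, `genes`, `exons`, `utrs`
#'   (data.frames, 1-based closed coordinates) and `config`.
#' @export
generate_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$chrom_length
    gc <- config$gc_content
    chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
    seqs <- vector("list", config$n_chroms)
    names(seqs) <- chrom_names
    cgi_list <- list(); rep_list <- list()
    gene_list <- list(); exon_list <- list(); utr_list <- list()

    # distribute islands and genes over chromosomes
    cgi_chrom <- if (config$n_cgis > 0)
      sort(sample.int(config$n_chroms, config$n_cgis, replace = TRUE))
    else integer(0)
    gene_chrom <- if (config$n_genes > 0)
      sort(sample.int(config$n_chroms, config$n_genes, replace = TRUE))
    else integer(0)
    gene_counter <- 0L

    for (ci in seq_len(config$n_chroms)) {
      base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
      x <- sample(BASES, L, replace = TRUE, prob = base_prob)

      # CpG islands: GC-rich redraw plus planted CG dinucleotides
      n_cgi_here <- sum(cgi_chrom == ci)
      cgis <- place_intervals(L, sample(seq(config$cgi_length[1],
                                            config$cgi_length[2]),
                                        n_cgi_here, replace = TRUE))
      in_cgi <- rep(FALSE, L)
      if (nrow(cgis)) {
        for (k in seq_len(nrow(cgis))) {
          idx <- cgis$start[k]:cgis$end[k]
          x[idx] <- sample(BASES, length(idx), replace = TRUE,
                           prob = c(0.175, 0.325, 0.325, 0.175))
          # plant extra CpG dyads to guarantee island-level CpG enrichment
          cand <- idx[idx < cgis$end[k]]
          plant <- cand[runif(length(cand)) < 0.05]
          if (length(plant)) { x[plant] <- "C"; x[plant + 1L] <- "G" }
          in_cgi[idx] <- TRUE
        }
        cgi_list[[ci]] <- data.frame(chrom = chrom_names[ci],
                                     start = cgis$start, end = cgis$end,
                                     stringsAsFactors = FALSE)
      }

      # genome-wide CpG depletion outside islands
      cg <- which(x[-L] == "C" & x[-1] == "G")
      cg <- cg[!in_cgi[cg]]
      destroy <- cg[runif(length(cg)) < config$cpg_depletion]
      if (length(destroy))
        x[destroy + 1L] <- sample(c("A", "T"), length(destroy),
                                  replace = TRUE)

      seqs[[ci]] <- paste(x, collapse = "")

      # repeats: placement independent of other tracks, overlaps allowed
      rep_len_range <- list(LINE = c(500L, 6000L), SINE = c(80L, 300L),
                            LTR = c(300L, 5000L), satellite = c(200L, 2000L),
                            simple = c(20L, 200L))
      reps <- list()
      for (cls in names(config$repeat_fraction)) {
        target <- config$repeat_fraction[[cls]] * L
        rng <- rep_len_range[[cls]] %||% c(100L, 1000L)
        covered <- 0; k <- 0L
        starts <- integer(0); ends <- integer(0)
        while (covered < target) {
          len <- sample(seq(rng[1], rng[2]), 1L)
          s <- sample.int(max(L - len, 1L), 1L)
          starts <- c(starts, s); ends <- c(ends, min(s + len - 1L, L))
          covered <- covered + len; k <- k + 1L
          if (k > 10000L) break
        }
        if (length(starts))
          reps[[cls]] <- data.frame(chrom = chrom_names[ci], start = starts,
                                    end = ends, class = cls,
                                    stringsAsFactors = FALSE)
      }
      if (length(reps)) rep_list[[ci]] <- do.call(rbind, reps)

      # gene models: non-overlapping spans with exons and terminal UTRs
      n_gene_here <- sum(gene_chrom == ci)
      if (n_gene_here > 0) {
        spans <- place_intervals(L, sample(5000:40000, n_gene_here,
                                           replace = TRUE))
        if (nrow(spans)) {
          for (k in seq_len(nrow(spans))) {
            gene_counter <- gene_counter + 1L
            gid <- sprintf("G%04d", gene_counter)
            strand <- sample(c("+", "-"), 1L)
            gs <- spans$start[k]; ge <- spans$end[k]
            n_ex <- sample(3:8, 1L)
            # exon starts spread over the span; first exon anchored at the
            # gene start and last ends at the gene end so TSS/TTS are real
            bounds <- sort(sample(seq(gs + 200L, ge - 200L),
                                  2L * (n_ex - 1L)))
            ex_s <- c(gs, bounds[seq(2, length(bounds), by = 2)])
            ex_e <- c(bounds[seq(1, length(bounds), by = 2)], ge)
            gene_list[[gene_counter]] <- data.frame(
              gene_id = gid, chrom = chrom_names[ci], start = gs, end = ge,
              strand = strand, stringsAsFactors = FALSE)
            exon_list[[gene_counter]] <- data.frame(
              gene_id = gid, chrom = chrom_names[ci], start = ex_s,
              end = ex_e, strand = strand, stringsAsFactors = FALSE)
            # terminal UTRs: first/last 150 bp of the terminal exons
            utr_len <- 150L
            first_ex <- c(ex_s[1], min(ex_e[1], ex_s[1] + utr_len - 1L))
            last_ex <- c(max(ex_s[n_ex], ex_e[n_ex] - utr_len + 1L),
                         ex_e[n_ex])
            five <- if (strand == "+") first_ex else last_ex
            three <- if (strand == "+") last_ex else first_ex
            utr_list[[gene_counter]] <- data.frame(
              gene_id = gid, chrom = chrom_names[ci],
              start = c(five[1], three[1]), end = c(five[2], three[2]),
              strand = strand,
              type = c("five_prime_utr", "three_prime_utr"),
              stringsAsFactors = FALSE)
          }
        }
      }
    }

    bundle <- list(
      sequences = unlist(seqs),
      cgis = if (length(cgi_list)) do.call(rbind, cgi_list) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), stringsAsFactors = FALSE),
      repeats = if (length(rep_list)) do.call(rbind, rep_list) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), class = character(0),
                   stringsAsFactors = FALSE),
      genes = do.call(rbind, gene_list),
      exons = do.call(rbind, exon_list),
      utrs = do.call(rbind, utr_list),
      config = config)
    rownames(bundle$cgis) <- rownames(bundle$repeats) <- NULL
    class(bundle) <- "genome_bundle"
    bundle
  })
}

#' In-silico MspI digest with size selection
#'
#' Cuts a sequence at every CCGG occurrence between the first C and the CGG
#' (C^CGG) and returns the fragments that pass the genomic size-selection
#' window.  Coordinates are 0-based half-open, so the boundaries of the
#' returned fragments are exactly the cut coordinates and the pre-filter
#' fragment set partitions the sequence.
#'
#' @param sequence uppercase ACGTN string.
#' @param frag_min,frag_max retained genomic fragment length range (bp),
#'   both inclusive.
#' @param require_cut_ends if TRUE, fragments touching a chromosome end are
#'   discarded even if they pass the size filter (a true
#'   reduced-representation library: both fragment ends must be MspI cuts).
#' @return data.frame with `start`, `end` (0-based half-open), `length`, and
#'   `both_cut_ends`.
#' @export
digest_mspi <- function(sequence, frag_min = 40L, frag_max = 290L,
                        require_cut_ends = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (frag_min > frag_max) stop("frag_min must be <= frag_max")
  L <- nchar(sequence)
  m <- gregexpr("CCGG", sequence, fixed = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer(0) else as.integer(m)  # half-open coords
  if (!length(cuts))                        # undigestible sequence
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), both_cut_ends = logical(0)))
  bounds <- unique(c(0L, cuts, L))
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  both <- start %in% cuts & end %in% cuts
  out <- data.frame(start = start, end = end, length = end - start,
                    both_cut_ends = both)
  out <- out[out$length >= frag_min & out$length <= frag_max, , drop = FALSE]
  if (require_cut_ends) out <- out[out$both_cut_ends, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CpG positions within retained fragments
#'
#' Finds forward-strand CpG dyads (position of the C) that fall entirely
#' inside the given fragments of each chromosome.
#'
#' @param bundle a `genome_bundle`.
#' @param fragments named list (per chromosome) of `digest_mspi()` outputs,
#'   or NULL to digest with the bundle's own config.
#' @return data.frame(chrom, pos) with 1-based CpG positions, sorted.
#' @export
cpg_sites_in_fragments <- function(bundle, fragments = NULL) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (is.null(fragments)) fragments <- digest_bundle(bundle)
  out <- list()
  for (chrom in names(bundle$sequences)) {
    fr <- fragments[[chrom]]
    if (is.null(fr) || !nrow(fr)) next
    seq <- bundle$sequences[[chrom]]
    m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    pos <- as.integer(m)                        # 1-based C of the dyad
    # dyad [pos, pos+1] inside a 0-based half-open fragment [s, e)
    fr_ir <- IRanges::IRanges(fr$start + 1L, fr$end)
    keep <- IRanges::overlapsAny(IRanges::IRanges(pos, pos + 1L), fr_ir,
                                 type = "within")
    if (any(keep))
      out[[chrom]] <- data.frame(chrom = chrom, pos = pos[keep],
                                 stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Digest every chromosome of a genome bundle
#'
#' @param bundle a `genome_bundle`.
#' @param require_cut_ends passed to [digest_mspi()]; defaults to TRUE as in
#'   a real reduced-representation library.
#' @return named list of per-chromosome fragment data.frames.
#' @export
digest_bundle <- function(bundle, require_cut_ends = TRUE) {
  cfg <- bundle$config
  lapply(setNames(nm = names(bundle$sequences)), function(chrom)
    digest_mspi(bundle$sequences[[chrom]], cfg$frag_min, cfg$frag_max,
                require_cut_ends = require_cut_ends))
}

#' Write a genome bundle to standard files
#'
#' Emits the genome FASTA, gene models as GTF (exon and UTR features with
#' gene_id/transcript_id attributes), CpG islands as BED and repeats as BED4
#' with the class in the name column.
#'
#' @param bundle a `genome_bundle`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "genes.gtf"),
             cgi = file.path(dir, "cgi.bed"),
             repeats = file.path(dir, "repeats.bed"))
  seqs <- Biostrings::DNAStringSet(bundle$sequences)
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])

  feat <- rbind(
    data.frame(gene_id = bundle$exons$gene_id, chrom = bundle$exons$chrom,
               start = bundle$exons$start, end = bundle$exons$end,
               strand = bundle$exons$strand, type = "exon",
               stringsAsFactors = FALSE),
    data.frame(gene_id = bundle$utrs$gene_id, chrom = bundle$utrs$chrom,
               start = bundle$utrs$start, end = bundle$utrs$end,
               strand = bundle$utrs$strand, type = bundle$utrs$type,
               stringsAsFactors = FALSE))
  feat <- feat[order(feat$chrom, feat$start), ]
  gr <- GenomicRanges::GRanges(feat$chrom,
                               IRanges::IRanges(feat$start, feat$end),
                               strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$source <- "rrbsmeth"
  S4Vectors::mcols(gr)$gene_id <- feat$gene_id
  S4Vectors::mcols(gr)$transcript_id <- paste0(feat$gene_id, ".t1")
  rtracklayer::export(gr, paths[["gtf"]], format = "gtf")

  cgi_gr <- GenomicRanges::GRanges(
    bundle$cgis$chrom, IRanges::IRanges(bundle$cgis$start, bundle$cgis$end))
  rtracklayer::export(cgi_gr, paths[["cgi"]], format = "bed")

  rep_gr <- GenomicRanges::GRanges(
    bundle$repeats$chrom,
    IRanges::IRanges(bundle$repeats$start, bundle$repeats$end))
  if (length(rep_gr)) S4Vectors::mcols(rep_gr)$name <- bundle$repeats$class
  rtracklayer::export(rep_gr, paths[["repeats"]], format = "bed")
  invisible(paths)
}

#' Observed/expected CpG ratio of a sequence window
#'
#' o/e = (#CG / len) / (fC * fG), the standard CpG-island enrichment score.
#'
#' @param sequence ACGT string.
#' @return a single number (NA if the window has no C or no G).
#' @export
cpg_obs_exp <- function(sequence) {
  L <- nchar(sequence)
  n_cg <- length(gregexpr("CG", sequence, fixed = TRUE)[[1]])
  if (substr(sequence, 1, 1) == "" ||
      gregexpr("CG", sequence, fixed = TRUE)[[1]][1] == -1L) n_cg <- 0L
  fc <- lengths(regmatches(sequence, gregexpr("C", sequence))) / L
  fg <- lengths(regmatches(sequence, gregexpr("G", sequence))) / L
  if (fc == 0 || fg == 0) return(NA_real_)
  (n_cg / L) / (fc * fg)
}
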