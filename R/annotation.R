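GENE_FEATURE_PRECEDENCE <- c("tss", "tts", "five_prime_utr",
                             "three_prime_utr", "exon", "intron",
                             "promoter", "upstream_10kb",
                             "downstream_10kb")

# Accept data.frame(chrom, pos) sites or (chrom, start, end) regions and
# return a GRanges (1-based closed).
as_query_granges <- function(query) {
  if (is(query, "GRanges")) return(query)
  stopifnot(is.data.frame(query))
  if (all(c("start", "end") %in% names(query)))
    GenomicRanges::GRanges(query$chrom,
                           IRanges::IRanges(query$start, query$end))
  else if ("pos" %in% names(query))
    GenomicRanges::GRanges(query$chrom,
                           IRanges::IRanges(query$pos, query$pos))
  else stop("query needs chrom+pos or chrom+start+end")
}

#' Read gene models from a GTF file
#'
#' Imports exon and UTR features (attribute `gene_id` required) and
#' reconstructs per-gene spans, strands and terminal coordinates.
#'
#' @param path GTF file.
#' @return list of class `gene_models` with data.frames `genes` (gene_id,
#'   chrom, start, end, strand, tss, tts), `exons` and `utrs` (1-based
#'   closed).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% names(S4Vectors::mcols(gr)))
    stop("GTF lacks the required gene_id attribute")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(S4Vectors::mcols(gr)$type),
                   gene_id = S4Vectors::mcols(gr)$gene_id,
                   stringsAsFactors = FALSE)
  exons <- df[df$type == "exon", c("gene_id", "chrom", "start", "end",
                                   "strand")]
  utrs <- df[df$type %in% c("five_prime_utr", "three_prime_utr"),
             c("gene_id", "chrom", "start", "end", "strand", "type")]
  if (!nrow(exons)) stop("GTF contains no exon features")
  spans <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e)
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = min(e$start), end = max(e$end),
               strand = e$strand[1], stringsAsFactors = FALSE)))
  spans$tss <- ifelse(spans$strand == "+", spans$start, spans$end)
  spans$tts <- ifelse(spans$strand == "+", spans$end, spans$start)
  rownames(spans) <- rownames(exons) <- rownames(utrs) <- NULL
  out <- list(genes = spans, exons = exons, utrs = utrs)
  class(out) <- "gene_models"
  out
}

#' Gene models from a genome bundle
#'
#' @param bundle a `genome_bundle` from [generate_toy_genome()].
#' @return a `gene_models` object (same shape as [read_gene_models()]).
#' @export
bundle_gene_models <- function(bundle) {
  g <- bundle$genes
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tts <- ifelse(g$strand == "+", g$end, g$start)
  out <- list(genes = g, exons = bundle$exons, utrs = bundle$utrs)
  class(out) <- "gene_models"
  out
}

#' Derive gene-feature windows
#'
#' Builds the strand-aware annotation windows around each gene: TSS window
#' (100 bp either side of the transcription start), promoter (2000 to
#' 100 bp upstream of the TSS), TTS window (100 bp either side of the
#' transcription termination site), 10-kb upstream and downstream flanks,
#' exons, introns and UTRs.  Windows extending past a chromosome edge are
#' clipped when `chrom_lengths` is supplied.
#'
#' @param models a `gene_models`.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return a [GenomicRanges::GRanges] with metadata columns `type` and
#'   `gene_id`.
#' @export
derive_windows <- function(models, chrom_lengths = NULL) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  plus <- g$strand == "+"
  win <- function(type, start, end, gene_id, chrom)
    data.frame(chrom = chrom, start = pmin(start, end),
               end = pmax(start, end), type = type, gene_id = gene_id,
               stringsAsFactors = FALSE)
  rows <- list(
    win("tss", g$tss - 100L, g$tss + 100L, g$gene_id, g$chrom),
    win("tts", g$tts - 100L, g$tts + 100L, g$gene_id, g$chrom),
    win("promoter", ifelse(plus, g$tss - 2000L, g$tss + 101L),
        ifelse(plus, g$tss - 101L, g$tss + 2000L), g$gene_id, g$chrom),
    win("upstream_10kb", ifelse(plus, g$tss - 10000L, g$tss + 1L),
        ifelse(plus, g$tss - 1L, g$tss + 10000L), g$gene_id, g$chrom),
    win("downstream_10kb", ifelse(plus, g$tts + 1L, g$tts - 10000L),
        ifelse(plus, g$tts + 10000L, g$tts - 1L), g$gene_id, g$chrom),
    win("exon", models$exons$start, models$exons$end, models$exons$gene_id,
        models$exons$chrom))
  if (nrow(models$utrs))
    rows <- c(rows, list(win(models$utrs$type, models$utrs$start,
                             models$utrs$end, models$utrs$gene_id,
                             models$utrs$chrom)))
  # introns: gene span minus its exons
  introns <- lapply(split(models$exons, models$exons$gene_id), function(e) {
    span <- g[match(e$gene_id[1], g$gene_id), ]
    ir <- IRanges::setdiff(IRanges::IRanges(span$start, span$end),
                           IRanges::reduce(IRanges::IRanges(e$start,
                                                            e$end)))
    if (!length(ir)) return(NULL)
    win("intron", IRanges::start(ir), IRanges::end(ir), span$gene_id,
        span$chrom)
  })
  rows <- c(rows, introns[!vapply(introns, is.null, logical(1))])
  all <- do.call(rbind, rows)
  all$start <- pmax(all$start, 1L)
  if (!is.null(chrom_lengths))
    all$end <- pmin(all$end, chrom_lengths[all$chrom])
  all <- all[all$start <= all$end, ]
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start, all$end))
  S4Vectors::mcols(gr)$type <- all$type
  S4Vectors::mcols(gr)$gene_id <- all$gene_id
  gr
}

#' Assign a gene-feature label to each query
#'
#' Any-base overlap against the derived windows, resolved by a fixed
#' precedence (TSS > TTS > 5'UTR > 3'UTR > exon > intron > promoter >
#' 10-kb upstream > 10-kb downstream); queries hitting nothing are
#' intergenic.  With overlapping genes, the highest-precedence overlap
#' across all genes wins.
#'
#' @param query data.frame(chrom, pos) / (chrom, start, end) or GRanges.
#' @param windows from [derive_windows()].
#' @return character vector of labels.
#' @export
assign_gene_feature <- function(query, windows) {
  q <- as_query_granges(query)
  label <- rep("intergenic", length(q))
  types <- S4Vectors::mcols(windows)$type
  for (ft in rev(GENE_FEATURE_PRECEDENCE)) {
    hit <- IRanges::overlapsAny(q, windows[types == ft])
    label[hit] <- ft
  }
  label
}

#' Derive CpG-island context tracks (island / shore / shelf)
#'
#' Shores are the 2000-bp bands flanking an island; shelves the next
#' 2000-bp bands.  The three classes are made disjoint by precedence
#' (island over shore over shelf) and clipped to the chromosome.
#'
#' @param cgis data.frame(chrom, start, end) or GRanges of islands.
#' @param chrom_lengths optional named vector for end clipping.
#' @param band width in bp of the shore and shelf bands.
#' @return list of class `context_tracks` with disjoint GRanges `island`,
#'   `shore`, `shelf`.
#' @export
derive_context_tracks <- function(cgis, chrom_lengths = NULL, band = 2000L) {
  gr <- if (is(cgis, "GRanges")) cgis else
    GenomicRanges::GRanges(cgis$chrom,
                           IRanges::IRanges(cgis$start, cgis$end))
  island <- GenomicRanges::reduce(gr)
  grow <- function(x, by) {
    y <- GenomicRanges::resize(x, GenomicRanges::width(x) + 2 * by,
                               fix = "center")
    GenomicRanges::start(y) <- pmax(GenomicRanges::start(y), 1L)
    if (!is.null(chrom_lengths)) {
      lim <- chrom_lengths[as.character(GenomicRanges::seqnames(y))]
      GenomicRanges::end(y) <- pmin(GenomicRanges::end(y), lim)
    }
    GenomicRanges::reduce(y)
  }
  shore <- GenomicRanges::setdiff(grow(island, band), island)
  shelf <- GenomicRanges::setdiff(grow(island, 2L * band),
                                  GenomicRanges::union(island, shore))
  out <- list(island = island, shore = shore, shelf = shelf)
  class(out) <- "context_tracks"
  out
}

# fraction of each query's length covered by `subject`
overlap_fraction <- function(q, subject) {
  hits <- GenomicRanges::findOverlaps(q, subject)
  inter <- GenomicRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                     subject[S4Vectors::subjectHits(hits)])
  w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
  frac <- rep(0, length(q))
  frac[as.integer(names(w))] <- as.numeric(w)
  frac / GenomicRanges::width(q)
}

#' Assign CpG-density context to each query
#'
#' A region belongs to the island (shore, shelf) class when at least
#' `min_overlap` of its length overlaps that class; a single-base site
#' belongs to the class containing it.  Precedence: island > shore >
#' shelf; everything else is open sea.
#'
#' @param query data.frame or GRanges.
#' @param tracks a `context_tracks` from [derive_context_tracks()].
#' @param min_overlap required overlap fraction for regions.
#' @return character vector: "island", "shore", "shelf" or "open_sea".
#' @export
assign_cpg_context <- function(query, tracks, min_overlap = 0.75) {
  stopifnot(inherits(tracks, "context_tracks"))
  q <- as_query_granges(query)
  label <- rep("open_sea", length(q))
  for (cls in c("shelf", "shore", "island")) {
    frac <- overlap_fraction(q, tracks[[cls]])
    label[frac >= min_overlap] <- cls
  }
  label
}

#' Assign repeat classes to each query
#'
#' A query is associated with every repeat class it overlaps by at least
#' one base, whatever the extent of the overlap; an empty set means "not
#' associated with repeats".
#'
#' @param query data.frame or GRanges.
#' @param repeats data.frame(chrom, start, end, class) or GRanges with a
#'   `class`/`name` metadata column.
#' @return list of character vectors (possibly empty), one per query.
#' @export
assign_repeats <- function(query, repeats) {
  q <- as_query_granges(query)
  if (is.data.frame(repeats)) {
    rgr <- GenomicRanges::GRanges(repeats$chrom,
                                  IRanges::IRanges(repeats$start,
                                                   repeats$end))
    cls <- repeats$class
  } else {
    rgr <- repeats
    mc <- S4Vectors::mcols(repeats)
    cls <- if ("class" %in% names(mc)) mc$class else mc$name
  }
  hits <- GenomicRanges::findOverlaps(q, rgr)
  out <- rep(list(character(0)), length(q))
  if (length(hits)) {
    by_q <- split(cls[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    out[as.integer(names(by_q))] <- lapply(by_q,
                                           function(v) sort(unique(v)))
  }
  out
}

#' Associate positions with genes within a distance
#'
#' A query associates with every gene whose span, extended by
#' `max_distance` bp on both sides, contains it (many-to-many).
#'
#' @param query data.frame or GRanges of sites/regions.
#' @param models a `gene_models`.
#' @param max_distance association distance in bp (inclusive).
#' @return list with `map` (data.frame query_index, gene_id) and `genes`
#'   (unique associated gene ids, sorted).
#' @export
associate_genes <- function(query, models, max_distance = 10000L) {
  q <- as_query_granges(query)
  g <- models$genes
  span <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(g$start - max_distance, 1L),
                              g$end + max_distance))
  hits <- GenomicRanges::findOverlaps(q, span)
  map <- data.frame(query_index = S4Vectors::queryHits(hits),
                    gene_id = g$gene_id[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  list(map = map, genes = sort(unique(map$gene_id)))
}

#' Full genomic-context annotation
#'
#' Combines the gene-feature, CpG-context, repeat and gene-association
#' assignments into one table (one gene feature and one CpG context per
#' query, a possibly-empty repeat class set, and the genes within 10 kb).
#'
#' @param query data.frame(chrom, pos) or (chrom, start, end).
#' @param models a `gene_models`.
#' @param tracks a `context_tracks`.
#' @param repeats repeat track (data.frame or GRanges).
#' @param chrom_lengths optional, for window clipping.
#' @param max_gene_distance gene-association distance (bp).
#' @return data.frame: the query columns plus gene_feature, cpg_context,
#'   repeat_classes (comma-separated, "" = none) and associated_genes.
#' @export
annotate_positions <- function(query, models, tracks, repeats,
                               chrom_lengths = NULL,
                               max_gene_distance = 10000L) {
  windows <- derive_windows(models, chrom_lengths)
  rep_cls <- assign_repeats(query, repeats)
  assoc <- associate_genes(query, models, max_gene_distance)
  gene_col <- rep("", nrow(as.data.frame(query)))
  if (nrow(assoc$map)) {
    by_q <- split(assoc$map$gene_id, assoc$map$query_index)
    gene_col[as.integer(names(by_q))] <-
      vapply(by_q, function(v) paste(sort(unique(v)), collapse = ","),
             character(1))
  }
  out <- data.frame(as.data.frame(query),
                    gene_feature = assign_gene_feature(query, windows),
                    cpg_context = assign_cpg_context(query, tracks),
                    repeat_classes = vapply(rep_cls, paste, character(1),
                                            collapse = ","),
                    associated_genes = gene_col,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Category enrichment of a query set against the background
#'
#' For each annotation category (gene features, CpG contexts, repeat
#' classes plus "no_repeat"), compares the proportion among the queries to
#' the proportion among the background and flags a more than 25% relative
#' increase or decrease ("increase" if ratio > 1.25, "decrease" if
#' < 0.75, otherwise "equal"; categories absent from the background are
#' flagged "undefined").
#'
#' @param query_annot,background_annot outputs of [annotate_positions()];
#'   the background is typically all analysis-eligible CpGs.
#' @param ratio_threshold relative-change threshold (default 0.25).
#' @return data.frame: panel, category, query_prop, background_prop,
#'   ratio, flag.
#' @export
enrichment_vs_background <- function(query_annot, background_annot,
                                     ratio_threshold = 0.25) {
  panels <- list(
    gene_feature = function(a) a$gene_feature,
    cpg_context = function(a) a$cpg_context)
  rows <- list()
  for (panel in names(panels)) {
    qv <- panels[[panel]](query_annot)
    bv <- panels[[panel]](background_annot)
    cats <- sort(unique(c(qv, bv)))
    for (ct in cats)
      rows[[length(rows) + 1L]] <- data.frame(
        panel = panel, category = ct, query_prop = mean(qv == ct),
        background_prop = mean(bv == ct), stringsAsFactors = FALSE)
  }
  # repeats: overlap with each class (non-exclusive) + no-repeat fraction
  split_cls <- function(a) strsplit(a$repeat_classes, ",", fixed = TRUE)
  qc <- split_cls(query_annot); bc <- split_cls(background_annot)
  cats <- sort(unique(unlist(c(qc, bc))))
  cats <- cats[cats != ""]
  has <- function(lst, ct) vapply(lst, function(v) ct %in% v, logical(1))
  for (ct in cats)
    rows[[length(rows) + 1L]] <- data.frame(
      panel = "repeats", category = ct, query_prop = mean(has(qc, ct)),
      background_prop = mean(has(bc, ct)), stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    panel = "repeats", category = "no_repeat",
    query_prop = mean(query_annot$repeat_classes == ""),
    background_prop = mean(background_annot$repeat_classes == ""),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$ratio <- ifelse(out$background_prop > 0,
                      out$query_prop / out$background_prop, NA_real_)
  out$flag <- ifelse(is.na(out$ratio), "undefined",
                     ifelse(out$ratio > 1 + ratio_threshold, "increase",
                            ifelse(out$ratio < 1 - ratio_threshold,
                                   "decrease", "equal")))
  rownames(out) <- NULL
  out
}

#' Background gene list
#'
#' Genes with at least one background CpG within `max_distance` bp — the
#' universe for downstream gene-set enrichment tools.
#'
#' @param background_sites data.frame(chrom, pos) of analysis-eligible
#'   CpGs.
#' @param models a `gene_models`.
#' @param max_distance association distance (bp).
#' @return sorted character vector of gene ids.
#' @export
background_gene_list <- function(background_sites, models,
                                 max_distance = 10000L) {
  associate_genes(background_sites, models, max_distance)$genes
}
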