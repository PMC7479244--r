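simple_models <- function(genes, exons = NULL, utrs = NULL) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end,
                        strand = genes$strand)
  if (is.null(utrs))
    utrs <- data.frame(gene_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), type = character(0))
  structure(list(genes = genes, exons = exons, utrs = utrs),
            class = "gene_models")
}

test_that("windows follow the documented strand-aware conventions", {
  g <- data.frame(gene_id = c("P", "M"), chrom = "chr1",
                  start = c(10000L, 50000L), end = c(20000L, 60000L),
                  strand = c("+", "-"))
  w <- derive_windows(simple_models(g))
  df <- data.frame(start = GenomicRanges::start(w),
                   end = GenomicRanges::end(w),
                   type = w$type, gene_id = w$gene_id)
  tssP <- df[df$type == "tss" & df$gene_id == "P", ]
  expect_equal(c(tssP$start, tssP$end), c(9900L, 10100L))
  promP <- df[df$type == "promoter" & df$gene_id == "P", ]
  expect_equal(c(promP$start, promP$end), c(8000L, 9899L))
  upP <- df[df$type == "upstream_10kb" & df$gene_id == "P", ]
  expect_equal(c(upP$start, upP$end), c(1L, 9999L))  # clipped at chrom start
  # minus strand: promoter on the higher-coordinate side of its TSS
  promM <- df[df$type == "promoter" & df$gene_id == "M", ]
  expect_equal(c(promM$start, promM$end), c(60101L, 62000L))
  ttsM <- df[df$type == "tts" & df$gene_id == "M", ]
  expect_equal(c(ttsM$start, ttsM$end), c(49900L, 50100L))
})

test_that("gene-feature precedence and the 10-kb boundary hold", {
  g <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                  start = c(100000L, 130000L), end = c(120000L, 150000L),
                  strand = "+")
  # gene A's exon overlaps gene B's promoter region?  Build the inverse:
  # a site inside an exon of A and inside the promoter of B
  g2 <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                   start = c(100000L, 120500L), end = c(119500L, 140000L),
                   strand = "+")
  w <- derive_windows(simple_models(g2))
  # B's promoter = [118500, 120399]; site 119000 is inside exon A too
  expect_equal(assign_gene_feature(
    data.frame(chrom = "chr1", pos = 119000L), w), "exon")
  w1 <- derive_windows(simple_models(g[1, ]))
  expect_equal(assign_gene_feature(
    data.frame(chrom = "chr1", pos = 95000L), w1), "upstream_10kb")
  expect_equal(assign_gene_feature(
    data.frame(chrom = "chr1", pos = 85000L), w1), "intergenic")
  expect_equal(assign_gene_feature(
    data.frame(chrom = "chr1", pos = 90000L), w1), "upstream_10kb")
})

test_that("CpG-density context distances and 75% rule behave", {
  cgis <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  tracks <- derive_context_tracks(cgis)
  site_at <- function(p) data.frame(chrom = "chr1", pos = p)
  expect_equal(assign_cpg_context(site_at(10500L), tracks), "island")
  expect_equal(assign_cpg_context(site_at(11000L + 1500L), tracks),
               "shore")
  expect_equal(assign_cpg_context(site_at(11000L + 3500L), tracks),
               "shelf")
  expect_equal(assign_cpg_context(site_at(11000L + 8000L), tracks),
               "open_sea")
  # region rule: >= 75% of the region length inside the class
  reg80 <- data.frame(chrom = "chr1", start = 10921L, end = 11020L)
  expect_equal(assign_cpg_context(reg80, tracks), "island")  # 80/100
  # 70% island fails the rule; the remaining 30% is shore, also < 75%,
  # so the region falls through to open sea
  reg70 <- data.frame(chrom = "chr1", start = 10931L, end = 11030L)
  expect_equal(assign_cpg_context(reg70, tracks), "open_sea")
  lab <- oracle_context_vector(20000L, cgis)
  expect_lt(mean(lab[10931:11030] == "island"), 0.75)
  expect_lt(mean(lab[10931:11030] == "shore"), 0.75)
})

test_that("island, shore and shelf tracks are disjoint", {
  set.seed(10)
  cgis <- data.frame(chrom = "chr1",
                     start = sort(sample.int(200000, 20)) )
  cgis$end <- cgis$start + sample(200:3000, 20, replace = TRUE)
  tracks <- derive_context_tracks(cgis)
  expect_equal(length(GenomicRanges::intersect(tracks$island,
                                               tracks$shore)), 0)
  expect_equal(length(GenomicRanges::intersect(tracks$shore,
                                               tracks$shelf)), 0)
  expect_equal(length(GenomicRanges::intersect(tracks$island,
                                               tracks$shelf)), 0)
})

test_that("repeat association is any-overlap and class-valued", {
  reps <- data.frame(chrom = "chr1", start = c(1000L, 1200L),
                     end = c(1500L, 1250L),
                     class = c("LINE", "SINE"))
  q <- data.frame(chrom = "chr1", start = c(1500L, 1200L, 2000L),
                  end = c(1600L, 1260L, 2100L))
  got <- assign_repeats(q, reps)
  expect_equal(got[[1]], "LINE")            # 1-bp overlap counts
  expect_equal(got[[2]], c("LINE", "SINE"))
  expect_equal(got[[3]], character(0))
})

test_that("assignments match the per-base oracle on a toy genome", {
  sim <- tiny_sim()
  b <- sim$bundle
  L <- tiny_cfg()$chrom_length
  models <- bundle_gene_models(b)
  windows <- derive_windows(models, c(chr1 = L))
  wdf <- data.frame(start = GenomicRanges::start(windows),
                    end = GenomicRanges::end(windows),
                    type = windows$type)
  feat_oracle <- oracle_feature_vector(L, wdf)
  ctx_oracle <- oracle_context_vector(L, b$cgis)
  cpgs <- sim$truth[, c("chrom", "pos")]
  expect_equal(assign_gene_feature(cpgs, windows), feat_oracle[cpgs$pos])
  tracks <- derive_context_tracks(b$cgis, c(chr1 = L))
  expect_equal(assign_cpg_context(cpgs, tracks), ctx_oracle[cpgs$pos])
  # repeats: brute-force recount of the unassociated fraction
  rep_sets <- assign_repeats(cpgs, b$repeats)
  none <- vapply(rep_sets, function(v) length(v) == 0, logical(1))
  in_any <- rep(FALSE, L)
  for (k in seq_len(nrow(b$repeats)))
    in_any[b$repeats$start[k]:min(b$repeats$end[k], L)] <- TRUE
  expect_equal(none, !in_any[cpgs$pos])
})

test_that("every query receives exactly one feature and one context", {
  sim <- tiny_sim()
  b <- sim$bundle
  ann <- annotate_positions(sim$truth[1:500, c("chrom", "pos")],
                            bundle_gene_models(b),
                            derive_context_tracks(b$cgis),
                            b$repeats)
  expect_false(any(is.na(ann$gene_feature)))
  expect_false(any(is.na(ann$cpg_context)))
  expect_equal(nrow(ann), 500)
})

test_that("enrichment flags follow the 25% rule", {
  qa <- data.frame(gene_feature = c(rep("intron", 52), rep("exon", 48)),
                   cpg_context = "open_sea", repeat_classes = "")
  bg <- data.frame(gene_feature = c(rep("intron", 40), rep("exon", 60)),
                   cpg_context = "open_sea", repeat_classes = "")
  enr <- enrichment_vs_background(qa, bg)
  intron <- enr[enr$category == "intron", ]
  expect_equal(intron$ratio, 1.3)
  expect_equal(intron$flag, "increase")
  exon <- enr[enr$category == "exon", ]
  expect_equal(exon$flag, "equal")       # 0.8 ratio is within [0.75, 1.25]
  # query == background: every flag equal, ratio 1
  self <- enrichment_vs_background(bg, bg)
  expect_true(all(self$flag == "equal"))
  expect_true(all(self$ratio == 1))
})

test_that("planted intronic enrichment is recovered", {
  sim <- tiny_sim()
  b <- sim$bundle
  tracks <- derive_context_tracks(b$cgis)
  models <- bundle_gene_models(b)
  bg <- annotate_positions(sim$truth[, c("chrom", "pos")], models,
                           tracks, b$repeats)
  hits <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    w <- ifelse(bg$gene_feature == "intron", 2, 1)
    idx <- sample(nrow(bg), 300, prob = w)
    enr <- enrichment_vs_background(bg[idx, ], bg)
    intron <- enr[enr$panel == "gene_feature" &
                    enr$category == "intron", ]
    hits <- hits + (intron$flag == "increase")
  }
  expect_gte(hits, 9)
})

test_that("gene association respects the 10-kb boundary, many-to-many", {
  g <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                  start = c(50000L, 55000L), end = c(60000L, 70000L),
                  strand = "+")
  models <- simple_models(g)
  q <- data.frame(chrom = "chr1",
                  pos = c(60000L + 9999L, 60000L + 10000L,
                          60000L + 10001L, 57000L))
  got <- associate_genes(q, models)
  by_q <- split(got$map$gene_id, got$map$query_index)
  expect_equal(by_q[["1"]], c("A", "B"))
  expect_equal(by_q[["2"]], c("A", "B"))   # exactly 10 kb: associated
  expect_equal(by_q[["3"]], "B")           # 10,001 bp past gene A
  expect_equal(sort(by_q[["4"]]), c("A", "B"))  # inside both spans
  # brute-force distance scan oracle
  for (k in seq_len(nrow(q))) {
    assoc_k <- by_q[[as.character(k)]]
    if (is.null(assoc_k)) assoc_k <- character(0)
    for (gi in seq_len(nrow(g))) {
      d_in <- q$pos[k] >= g$start[gi] - 10000 &
        q$pos[k] <= g$end[gi] + 10000
      expect_equal(g$gene_id[gi] %in% assoc_k, d_in)
    }
  }
})
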