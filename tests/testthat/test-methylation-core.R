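write_cov <- function(lines) {
  f <- withr::local_tempfile(fileext = ".cov",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("coverage records are parsed and the percentage recomputed", {
  f <- write_cov("chr1\t100\t100\t75.0\t9\t3")
  rec <- read_coverage_file(f, "s1")
  expect_equal(rec$chrom, "chr1")
  expect_equal(rec$pos, 100L)
  expect_equal(rec$count_M, 9L)
  expect_equal(rec$count_U, 3L)
  expect_equal(methylation_percent(rec$count_M,
                                   rec$count_M + rec$count_U), 75)
})

test_that("malformed count fields are reported with their line number", {
  f <- write_cov(c("chr1\t100\t100\t75.0\t9\t3",
                   "chr1\t200\t200\t50.0\tx\t5"))
  expect_error(read_coverage_file(f), "line 2")
})

test_that("an empty coverage file warns and yields zero records", {
  f <- write_cov(character(0))
  expect_warning(rec <- read_coverage_file(f), "empty")
  expect_equal(nrow(rec), 0)
})

test_that("counts survive a write/read round trip", {
  sim <- tiny_sim()
  dir <- withr::local_tempdir()
  paths <- write_coverage_files(sim$counts, dir)
  sid <- sim$sample_sheet$sample_id[1]
  rec <- read_coverage_file(paths[[sid]], sid)
  keep <- !is.na(sim$counts$total[, sid])
  expect_equal(rec$pos, sim$counts$sites$pos[keep])
  expect_equal(rec$count_M, unname(sim$counts$meth[keep, sid]))
  expect_equal(rec$count_M + rec$count_U,
               unname(sim$counts$total[keep, sid]))
  # the emitted percentage column agrees with the formula
  raw <- read.table(paths[[sid]], sep = "\t")
  expect_equal(raw[[4]],
               round(methylation_percent(rec$count_M,
                                         rec$count_M + rec$count_U), 6))
})

test_that("dyad strand merging sums adjacent positions", {
  rec <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                    pos = c(100L, 101L, 500L, 101L),
                    count_M = c(5L, 4L, 2L, 7L),
                    count_U = c(0L, 2L, 8L, 1L))
  merged <- merge_strand_counts(rec, "merged")
  expect_equal(nrow(merged), 3)
  expect_equal(merged$count_M[merged$pos == 100], 9L)
  expect_equal(merged$count_U[merged$pos == 100], 2L)
  expect_equal(merged$count_M[merged$chrom == "chr2"], 7L)
  # forward_only leaves everything untouched
  expect_equal(merge_strand_counts(rec, "forward_only"), rec)
})

test_that("strand merging halves dyad-paired sites on split records", {
  sim <- tiny_sim()
  sid <- sim$sample_sheet$sample_id[1]
  keep <- which(!is.na(sim$counts$total[, sid]))[1:500]
  m <- sim$counts$meth[keep, sid]; tt <- sim$counts$total[keep, sid]
  # split every dyad-merged record into forward/reverse strand records
  set.seed(1)
  m_f <- rbinom(length(m), m, 0.5); t_f <- m_f + rbinom(length(m),
                                                        tt - m, 0.5)
  split_rec <- data.frame(
    chrom = rep(sim$counts$sites$chrom[keep], 2),
    pos = c(sim$counts$sites$pos[keep], sim$counts$sites$pos[keep] + 1L),
    count_M = c(m_f, m - m_f),
    count_U = c(t_f - m_f, (tt - m) - (t_f - m_f)))
  merged <- merge_strand_counts(split_rec, "merged")
  expect_equal(nrow(merged), 500)
  expect_equal(merged$count_M, unname(m))
  expect_equal(merged$count_M + merged$count_U, unname(tt))
})

test_that("the CpG10 filter is an inclusive >= 10 boundary and idempotent", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L))
  sheet <- manual_sheet(1, 1)
  tot <- matrix(c(10L, 9L, 3L, 25L, 10L, 2L), ncol = 2)
  meth <- matrix(c(5L, 4L, 1L, 20L, 3L, 1L), ncol = 2)
  cm <- CountMatrix(sites, sheet, meth, tot)
  f <- filter_cpg10(cm)
  expect_equal(nrow(f$sites), 2)              # site 3 missing everywhere
  expect_equal(unname(f$total[1, ]), c(10L, 25L))
  expect_true(is.na(f$total[2, 1]))           # total 9 dropped
  expect_equal(unname(f$total[2, 2]), 10L)    # total 10 kept
  expect_identical(filter_cpg10(f), f)        # idempotent
  # min_reads = 1 removes nothing that was covered
  expect_equal(dim(filter_cpg10(cm, 1L)), dim(cm))
  expect_error(filter_cpg10(cm, 0L), "min_reads")
})

test_that("methylation percentages follow the count formula and bounds", {
  expect_equal(methylation_percent(9, 12), 75)
  expect_equal(methylation_percent(0, 10), 0)
  expect_equal(methylation_percent(10, 10), 100)
  expect_true(is.na(methylation_percent(0, 0)))
  expect_error(methylation_percent(11, 10), "exceeds")
  # monotone in count_M at fixed total
  v <- methylation_percent(0:10, rep(10, 11))
  expect_true(all(diff(v) > 0))
})

test_that("class boundaries put 20 and 80 in the intermediate class", {
  cl <- classify_sites(c(19.999, 20, 80, 80.001))$class
  expect_equal(as.character(cl),
               c("hypo", "intermediate", "intermediate", "hyper"))
  fr <- classify_sites(rep(50, 10))$fractions
  expect_equal(unname(fr), c(0, 100, 0))
  expect_error(classify_sites(c(50, 101)), "\\[0, 100\\]")
  # partition: fractions always sum to 100
  set.seed(2)
  fr2 <- classify_sites(runif(1000, 0, 100))$fractions
  expect_equal(sum(fr2), 100, tolerance = 1e-9)
})

test_that("conversion rate is the converted spike-in percentage", {
  expect_equal(estimate_conversion_rate(994, 1000), 99.4)
  expect_equal(estimate_conversion_rate(1000, 1000), 100)
  expect_warning(out <- estimate_conversion_rate(0, 0), "undefined")
  expect_true(is.na(out))
  # simulated spike-ins recover the configured rate within 3 binomial sd
  sim <- tiny_sim()
  est <- estimate_conversion_rate(sum(sim$spikeins$converted),
                                  sum(sim$spikeins$total))
  n <- sum(sim$spikeins$total)
  sd3 <- 3 * 100 * sqrt(0.994 * 0.006 / n)
  expect_lt(abs(est - 99.4), sd3)
})

test_that("the QC summary derives every count-based statistic", {
  sites <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L))
  sheet <- manual_sheet(1, 0)
  tot <- matrix(c(12L, 9L, 10L), ncol = 1)
  meth <- matrix(c(6L, 9L, 10L), ncol = 1)
  cm <- CountMatrix(sites, sheet, meth, tot)
  qc <- qc_summary(cm)
  expect_equal(qc$n_covered, 3L)
  expect_equal(qc$pct_cpgs10, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(qc$mean_coverage, mean(c(12, 9, 10)))
  expect_equal(qc$mean_methylation_cpgs10, mean(c(50, 100)))
  # empty matrix does not crash
  empty <- CountMatrix(sites[0, ], sheet,
                       matrix(integer(0), 0, 1), matrix(integer(0), 0, 1))
  expect_equal(qc_summary(empty)$n_covered, 0L)
})

test_that("simulated cohort QC matches the generator's global structure", {
  sim <- tiny_sim()
  qc <- qc_summary(sim$counts, sim$spikeins)
  expect_lt(abs(mean(qc$mean_methylation_cpgs10) - 50), 2)
  expect_lt(abs(mean(qc$mean_coverage) - 25) / 25, 0.1)
})
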