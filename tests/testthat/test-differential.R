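const_counts <- function(n_sites, n_samples, meth, total) {
  list(m = matrix(as.integer(meth), n_sites, n_samples),
       t = matrix(as.integer(total), n_sites, n_samples))
}

test_that("identical proportions at high coverage give phi at the clip", {
  g1 <- const_counts(50, 8, 500, 1000)
  g2 <- const_counts(50, 8, 500, 1000)
  d <- estimate_dispersion_shrunk(g1$m, g1$t, g2$m, g2$t)
  expect_true(all(d$phi <= 1e-5))
})

test_that("shrinkage pulls a single outlying site toward the prior", {
  set.seed(4)
  n <- 200
  tot <- matrix(25L, n, 16)
  p <- runif(n, 0.3, 0.7)
  meth <- matrix(rbinom(n * 16, tot, rep(p, 16)), n, 16)
  # make site 1 wildly overdispersed
  meth[1, ] <- as.integer(rep(c(0, 25), 8))
  d <- estimate_dispersion_shrunk(meth[, 1:8], tot[, 1:8],
                                  meth[, 9:16], tot[, 9:16])
  raw1 <- d$phi_raw[1]
  expect_gt(raw1, d$prior_phi)
  expect_lt(d$phi[1], raw1)            # moved toward the prior
  expect_gt(d$phi[1], d$prior_phi)
  # a stronger prior moves it further
  d2 <- estimate_dispersion_shrunk(meth[, 1:8], tot[, 1:8],
                                   meth[, 9:16], tot[, 9:16],
                                   prior_df = 200)
  expect_lt(abs(d2$phi[1] - d2$prior_phi), abs(d$phi[1] - d$prior_phi))
})

test_that("dispersion estimation recovers a known phi", {
  set.seed(5)
  n <- 20000; J <- 9; phi_true <- 0.1
  p <- runif(n, 0.2, 0.8)
  draw <- function() {
    tot <- matrix(rpois(n * J, 25) + 1L, n, J)
    a <- p * (1 - phi_true) / phi_true
    b <- (1 - p) * (1 - phi_true) / phi_true
    q <- matrix(rbeta(n * J, a, b), n, J)
    list(m = matrix(rbinom(n * J, tot, q), n, J), t = tot)
  }
  g1 <- draw(); g2 <- draw()
  d <- estimate_dispersion_shrunk(g1$m, g1$t, g2$m, g2$t)
  expect_gt(median(d$phi), 0.05)
  expect_lt(median(d$phi), 0.2)
})

test_that("the Wald test is symmetric, and separates extreme groups", {
  g <- const_counts(3, 4, c(5L, 0L, 25L), 25)
  same <- wald_test(g$m, g$t, g$m, g$t, rep(0.01, 3))
  expect_equal(same$diff, rep(0, 3))
  expect_equal(same$wald, rep(0, 3))
  expect_equal(same$p, rep(1, 3))
  hi <- const_counts(1, 4, 25, 25)
  lo <- const_counts(1, 4, 0, 25)
  sep <- wald_test(hi$m, hi$t, lo$m, lo$t, 1e-6)
  expect_equal(sep$diff, 100)
  expect_lt(sep$p, 1e-6)
})

test_that("one-bin covariate weighting is exactly Benjamini-Hochberg", {
  adj <- ihw_adjust(c(0.01, 0.02, 0.04, 0.8), n_bins = 1)
  expect_equal(adj$p_adj, c(0.04, 0.04, 0.04 * 4 / 3, 0.8),
               tolerance = 1e-12)
  expect_equal(adj$weights, rep(1, 4))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(50)^sample(1:3, 1)
    cov <- rnorm(50)
    a1 <- ihw_adjust(p, cov, n_bins = 1)
    expect_equal(a1$p_adj, p.adjust(p, "BH"), tolerance = 1e-12)
    a10 <- ihw_adjust(p, cov, n_bins = 10, min_bin = 5)
    expect_equal(mean(a10$weights), 1, tolerance = 1e-9)
  }
})

test_that("a zero-weight bin forces its adjusted p to 1", {
  set.seed(7)
  p <- c(rep(0.001, 250), runif(250, 0.55, 1))
  cov <- rep(c(0, 1), each = 250)
  adj <- ihw_adjust(p, cov, n_bins = 2, weight_smooth = 0)
  expect_true(all(adj$weights[251:500] == 0))
  expect_true(all(adj$p_adj[251:500] == 1))
  expect_equal(mean(adj$weights), 1, tolerance = 1e-9)
})

test_that("covariates must be finite and bins positive", {
  expect_error(ihw_adjust(runif(10), c(1:9, NA)), "finite")
  expect_error(ihw_adjust(runif(10), 1:10, n_bins = 0), "n_bins")
  expect_error(ihw_adjust(c(0.5, 2), 1:2), "\\[0, 1\\]")
})

fake_tests <- function(p_adj, diff, n1 = 5L, n2 = 5L) {
  out <- data.frame(chrom = "chr1",
                    pos = seq(1000L, by = 1000L,
                              length.out = length(p_adj)),
                    n1 = n1, n2 = n2, mean1 = 50 + diff, mean2 = 50,
                    diff = diff, se = 1, wald = 1, p = p_adj / 2,
                    phi = 0.01, covariate = 50, weight = 1,
                    p_adj = p_adj)
  attr(out, "spec") <- comparison_spec("HM15", "MM15")
  out
}

test_that("DMC thresholds are strict on p and inclusive on difference", {
  tests <- fake_tests(p_adj = c(0.1, 0.099, 0.099, 0.001),
                      diff = c(15, 10, 9.99, 9.99))
  dmcs <- call_dmcs(tests)
  expect_equal(dmcs$pos, 2000L)   # only p_adj = 0.099 with diff = 10.0
  expect_equal(dmcs$direction, "hyper_in_group1")
  # below the per-group coverage minimum nothing is called
  low <- fake_tests(0.001, 20, n1 = 3L)
  expect_equal(nrow(call_dmcs(low)), 0)
})

test_that("lowering min_diff never removes a DMC", {
  set.seed(8)
  tests <- fake_tests(p_adj = runif(200, 0, 0.2),
                      diff = runif(200, -30, 30))
  strict <- call_dmcs(tests, comparison_spec("HM15", "MM15",
                                             min_diff = 10))
  loose <- call_dmcs(tests, comparison_spec("HM15", "MM15",
                                            min_diff = 8))
  expect_true(all(paste(strict$chrom, strict$pos) %in%
                    paste(loose$chrom, loose$pos)))
})

test_that("DMR chaining follows the gap and size rules", {
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos,
                                 diff = rep(12, length(pos)))
  one <- call_dmrs(mk(c(1000, 1050, 1140)))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end, one$n_dmcs), c(1000, 1140, 3))
  # gap of 101 breaks the chain
  expect_equal(nrow(call_dmrs(mk(c(1000, 1050, 1151)))), 0)
  # gap of exactly 100 joins
  expect_equal(nrow(call_dmrs(mk(c(1000, 1100, 1200)))), 1)
  # fewer than 3 members is never a DMR
  expect_equal(nrow(call_dmrs(mk(c(1000, 1050)))), 0)
  # direction is the member majority
  mixed <- data.frame(chrom = "chr1", pos = c(10, 60, 110),
                      diff = c(12, 15, -11))
  expect_equal(call_dmrs(mixed)$direction, "hyper_in_group1")
})

test_that("DMR calling agrees with the exhaustive window oracle", {
  set.seed(9)
  for (i in 1:100) {
    pos <- sort(sample.int(3000, sample(3:40, 1)))
    got <- call_dmrs(data.frame(chrom = "chr1", pos = pos))
    want <- oracle_dmrs(pos)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_dmcs, want$n)
    }
  }
})

test_that("set comparison reproduces printed set arithmetic", {
  mk <- function(pos) data.frame(chrom = "chr9", pos = pos,
                                 direction = "hyper_in_group1")
  a <- mk(1:491); b <- mk(417:580)          # overlap 417..491 = 75 sites
  cmp <- compare_dmc_sets(a, b)
  expect_equal(cmp$intersection, 75)
  expect_equal(cmp$union, 580)
  expect_equal(round(cmp$shared_pct, 1), 12.9)
  self <- compare_dmc_sets(a, a)
  expect_equal(self$shared_pct, 100)
  disj <- compare_dmc_sets(mk(1:10), mk(11:20))
  expect_equal(disj$shared_pct, 0)
  expect_equal(disj$union, 20)
})

test_that("volcano export mirrors the DMC calls", {
  tests <- fake_tests(p_adj = c(0.01, 0.2, 0.01),
                      diff = c(15, 15, 5))
  v <- volcano_table(tests)
  expect_equal(v$is_dmc, c(TRUE, FALSE, FALSE))
  expect_equal(v$fail_reason, c(NA, "p_adj", "diff"))
  expect_equal(volcano_table(fake_tests(0.02, 20))$neg_log10_p,
               -log10(0.01))
  # cross-module consistency on simulated data
  sim <- tiny_sim()
  tt <- dm_test(filter_cpg10(sim$counts),
                comparison_spec("HM15", "MM15"))
  vv <- volcano_table(tt)
  dmcs <- call_dmcs(tt)
  expect_setequal(paste(vv$chrom[vv$is_dmc], vv$pos[vv$is_dmc]),
                  paste(dmcs$chrom, dmcs$pos))
})

test_that("every emitted DMC satisfies all thresholds on a real run", {
  sim <- tiny_sim()
  spec <- comparison_spec("HM15", "MM15")
  tests <- dm_test(filter_cpg10(sim$counts), spec)
  dmcs <- call_dmcs(tests, spec)
  expect_gt(nrow(dmcs), 0)
  expect_true(all(dmcs$p_adj < 0.1))
  expect_true(all(abs(dmcs$diff) >= 10))
  expect_true(all(dmcs$n1 >= 4 & dmcs$n2 >= 4))
  expect_true(all(dmcs$direction == ifelse(dmcs$diff > 0,
                                           "hyper_in_group1",
                                           "hypo_in_group1")))
})
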