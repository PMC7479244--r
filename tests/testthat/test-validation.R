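long_reps <- function(...) {
  groups <- list(...)
  do.call(rbind, lapply(seq_along(groups), function(i)
    data.frame(region_id = "R1", cpg_index = i, sample_id = "s1",
               replicate = seq_along(groups[[i]]),
               percentage = groups[[i]])))
}

test_that("replicate consolidation follows the >5 point rule", {
  out <- consolidate_replicates(long_reps(c(42, 44), c(40, 50),
                                          c(40, 50, 41), c(70)))
  expect_equal(out$percentage[out$cpg_index == 1], 43)
  expect_equal(out$flag[out$cpg_index == 1], "ok")
  expect_equal(out$n_used[out$cpg_index == 1], 2L)
  # inconsistent duplicate with no repeat: missing, flagged
  expect_true(is.na(out$percentage[out$cpg_index == 2]))
  expect_equal(out$flag[out$cpg_index == 2], "inconsistent")
  # a repeat rescues the pair: largest consistent subset {40, 41}
  expect_equal(out$percentage[out$cpg_index == 3], 40.5)
  expect_equal(out$n_used[out$cpg_index == 3], 2L)
  # single replicate: excluded
  expect_true(is.na(out$percentage[out$cpg_index == 4]))
  expect_equal(out$flag[out$cpg_index == 4], "single_replicate")
  # boundary: exactly 5 points apart is consistent
  b <- consolidate_replicates(long_reps(c(40, 45)))
  expect_equal(b$percentage, 42.5)
})

test_that("noise-free duplicates are never flagged inconsistent", {
  sim <- tiny_sim()
  sites <- sim$truth[, c("chrom", "pos")]
  regions <- data.frame(region_id = "R", chrom = sites$chrom[1:20],
                        pos = sites$pos[1:20])
  pyro <- simulate_pyro(sim$sample_levels, sites, regions, noise_sd = 0,
                        seed = 5, inconsistent_rate = 0)
  out <- consolidate_replicates(pyro)
  expect_true(all(out$flag == "ok"))
  expect_true(all(out$percentage >= 0 & out$percentage <= 100))
})

test_that("Spearman concordance is rank-based and symmetric", {
  rrbs <- data.frame(region_id = "R1",
                     sample_id = sprintf("s%d", 1:8),
                     percentage = c(10, 20, 30, 40, 50, 60, 70, 80))
  pyro <- data.frame(region_id = "R1", cpg_index = 1,
                     sample_id = sprintf("s%d", 1:8),
                     replicate = 1,
                     percentage = c(10, 20, 30, 40, 50, 60, 70, 80))
  expect_equal(spearman_concordance(rrbs, pyro)$rho, 1)
  # monotone transform leaves rho at 1
  pyro2 <- pyro; pyro2$percentage <- pyro$percentage^2 / 100
  expect_equal(spearman_concordance(rrbs, pyro2)$rho, 1)
  # symmetry in arguments
  r1 <- spearman_concordance(rrbs, pyro2)$rho
  rrbs2 <- pyro2[, c("region_id", "sample_id", "percentage")]
  pyro3 <- cbind(rrbs[, c("region_id", "sample_id")], cpg_index = 1,
                 replicate = 1, percentage = rrbs$percentage)
  expect_equal(spearman_concordance(rrbs2, pyro3)$rho, r1)
  # constant vector: rho undefined, reported missing
  rrbs_const <- rrbs; rrbs_const$percentage <- 50
  expect_true(is.na(spearman_concordance(rrbs_const, pyro)$rho))
  # too few pairs aborts
  expect_error(spearman_concordance(rrbs[1:3, ], pyro), "paired")
})

test_that("noisy pyro assays stay strongly concordant with the truth", {
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    truth <- runif(23, 10, 90)
    rrbs <- data.frame(region_id = "R", sample_id = sprintf("s%d", 1:23),
                       percentage = truth)
    pyro <- data.frame(region_id = "R", cpg_index = 1,
                       sample_id = sprintf("s%d", 1:23), replicate = 1,
                       percentage = pmin(pmax(truth + rnorm(23, 0, 3),
                                              0), 100))
    hits <- hits + (spearman_concordance(rrbs, pyro)$rho >= 0.8)
  }
  expect_gte(hits, 9)
})

test_that("stratification protects the two-sample test from an age
          effect", {
  # age 16 adds +4 units; groups are balanced within each age stratum,
  # so the group effect is null
  set.seed(11)
  age <- rep(c(15, 16), each = 8)
  group <- rep(c("HM", "MM"), 8)
  v <- ifelse(age == 16, 4, 0) + rnorm(16)
  strat <- stratified_permutation_test(v, group, strata = age,
                                       n_perm = 2000, seed = 2)
  expect_gt(strat$p, 0.05)
  # the statistic's sign convention is first level minus second
  v2 <- ifelse(group == "HM", 10, 0)
  r2 <- stratified_permutation_test(v2, factor(group,
                                               levels = c("HM", "MM")),
                                    strata = age, n_perm = 500, seed = 3)
  expect_equal(r2$observed, 10)
  # two-sided doubling of the smaller add-one tail: near its 2/(n+1) floor
  expect_lte(r2$p, 0.02)
})

test_that("per-CpG pyro group tests flag the planted DMR signal", {
  sim <- tiny_sim()
  spec <- comparison_spec("HM15", "MM15")
  cm10 <- filter_cpg10(sim$counts)
  dmcs <- call_dmcs(dm_test(cm10, spec), spec)
  skip_if(nrow(dmcs) < 3, "no DMCs in tiny simulation")
  sites <- sim$truth[, c("chrom", "pos")]
  regions <- data.frame(region_id = "R1", chrom = dmcs$chrom[1:3],
                        pos = dmcs$pos[1:3])
  pyro <- consolidate_replicates(
    simulate_pyro(sim$sample_levels, sites, regions, noise_sd = 1,
                  seed = 6, inconsistent_rate = 0))
  # the simulated cohort has no HM16 samples, so the age-16 stratum is
  # MM-only and is dropped with a warning
  expect_warning(
    tests <- pyro_group_tests(pyro, sim$sample_sheet, n_perm = 2000,
                              seed = 7),
    "without both diet groups")
  expect_equal(nrow(tests), 3)
  expect_true(all(tests$p >= 1 / 2001 & tests$p <= 1))
})
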