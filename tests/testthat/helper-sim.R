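# Small, fast simulation configs shared across tests.  Expensive objects
# are generated once per test run and cached.

tiny_cfg <- function(...) {
  args <- list(seed = 7L, n_chroms = 1L, chrom_length = 300000L,
               n_genes = 15L, n_cgis = 20L, planted_age_dmcs = 0L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

tiny_sim <- function() cached("tiny_sim", simulate_rrbs(tiny_cfg()))

# a hand-rolled truth object for targeted count-simulation tests
manual_truth <- function(levels_hm, levels_mm = levels_hm) {
  n <- length(levels_hm)
  truth <- data.frame(chrom = "chr1", pos = seq(100L, by = 50L,
                                                length.out = n),
                      baseline = levels_hm, HM15 = levels_hm,
                      MM15 = levels_mm,
                      planted_dmc = FALSE, planted_direction = "none",
                      clamped = FALSE, stringsAsFactors = FALSE)
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

manual_sheet <- function(n_hm = 2, n_mm = 2) {
  data.frame(
    sample_id = c(sprintf("HM15_b%02d", seq_len(n_hm)),
                  sprintf("MM15_b%02d", n_hm + seq_len(n_mm))),
    bull_id = sprintf("b%02d", seq_len(n_hm + n_mm)),
    group = rep(c("HM", "MM"), c(n_hm, n_mm)),
    age = 15L,
    group_label = rep(c("HM15", "MM15"), c(n_hm, n_mm)),
    stringsAsFactors = FALSE)
}
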