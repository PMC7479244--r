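#' Configuration for the synthetic RRBS study
#'
#' Builds a validated configuration object for the synthetic-data module.
#' The defaults define the simulated study conditions: a cohort of bulls on
#' two pre-pubertal planes of nutrition (HM = high-then-moderate, MM =
#' moderate throughout), sampled at 15 and/or 16 months of age, with RRBS
#' count data whose global structure mirrors a mature sperm methylome:
#' roughly 50% mean methylation arising from a strongly bimodal per-CpG
#' distribution (about 47% of sites above 80% methylation, about 46% below
#' 20%, and 7% intermediate), mean coverage of 25 reads at a CpG, a
#' bisulfite conversion rate of 99.4%, and inter-individual (bull-level)
#' variability that dominates the small planted diet effect.
#'
#' @param seed integer seed; every downstream draw is reproducible from it.
#' @param n_chroms,chrom_length number and length (bp) of toy chromosomes.
#' @param gc_content genome-wide GC fraction.
#' @param cpg_depletion fraction of CpG dinucleotides outside CpG islands
#'   destroyed after the initial i.i.d. draw, emulating the genome-wide CpG
#'   depletion that makes islands stand out.
#' @param n_genes,n_cgis number of gene models / CpG islands to place.
#' @param cgi_length two-element range (bp) of island lengths.
#' @param repeat_fraction named fractions of the genome covered by each
#'   repeat class (LINE, SINE, LTR, satellite, simple).
#' @param frag_min,frag_max genomic size-selection window (bp) applied to
#'   MspI fragments (adapters excluded).
#' @param mean_coverage mean per-CpG read coverage.
#' @param coverage_dispersion negative-binomial size (shape) parameter of
#'   per-site coverage; smaller = more overdispersed.
#' @param baseline_mixture list with `props`, a named vector of mixture
#'   proportions (hyper, hypo, intermediate) summing to 1, and shape pairs
#'   `hyper_shape`, `hypo_shape`, `intermediate_shape` for the within-class
#'   beta draws (hyper levels live in (0.8, 1], hypo in [0, 0.2),
#'   intermediate in [0.2, 0.8]).
#' @param planted_dmc_fraction fraction of CpGs given a true diet effect.
#' @param planted_block_fraction fraction of the planted sites laid down as
#'   contiguous blocks of 3-5 neighbouring CpGs (within 100 bp steps,
#'   sharing one direction), emulating the regional coherence that lets a
#'   minority of differential CpGs form differentially methylated regions;
#'   the remainder are scattered singly.
#' @param effect_size planted group difference in percentage points.
#' @param hyper_bias fraction of planted effects oriented so that the HM
#'   group is the hypermethylated one.
#' @param biological_dispersion beta-binomial dispersion phi in (0,1) of
#'   methylated counts across replicate bulls.
#' @param sample_jitter_sd standard deviation, on the logit scale, of the
#'   bull-level random effect shared by samples from the same bull.
#' @param conversion_rate bisulfite conversion probability for an
#'   unmethylated cytosine.
#' @param n_samples_per_group named counts for the HM15 / MM15 / MM16
#'   groups; MM16 reuses the MM15 bulls first (paired design) and adds new
#'   bulls if larger.
#' @param spikein_cytosines number of unmethylated spike-in cytosines per
#'   sample used to estimate the conversion rate.
#' @param planted_age_dmcs number of CpGs at which MM16 differs from MM15
#'   (default 1, mirroring the near-absence of age effects).
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L,
                       chrom_length = 1200000L,
                       gc_content = 0.5,
                       cpg_depletion = 0.5,
                       n_genes = 60L,
                       n_cgis = 90L,
                       cgi_length = c(500L, 2000L),
                       repeat_fraction = c(LINE = 0.06, SINE = 0.04,
                                           LTR = 0.03, satellite = 0.01,
                                           simple = 0.02),
                       frag_min = 40L,
                       frag_max = 290L,
                       mean_coverage = 25,
                       coverage_dispersion = 2,
                       baseline_mixture = list(
                         props = c(hyper = 0.471, hypo = 0.458,
                                   intermediate = 0.071),
                         hyper_shape = c(5, 1),
                         hypo_shape = c(1, 5),
                         intermediate_shape = c(1, 1)),
                       planted_dmc_fraction = 0.01,
                       planted_block_fraction = 0.2,
                       effect_size = 15,
                       hyper_bias = 0.7,
                       biological_dispersion = 0.02,
                       sample_jitter_sd = 0.25,
                       conversion_rate = 0.994,
                       n_samples_per_group = c(HM15 = 9L, MM15 = 7L,
                                               MM16 = 9L),
                       spikein_cytosines = 20000L,
                       planted_age_dmcs = 1L) {
  if (n_chroms < 1 || chrom_length < 1000)
    stop("degenerate genome: need >= 1 chromosome of >= 1000 bp")
  if (n_genes < 0 || n_cgis < 0)
    stop("n_genes and n_cgis must be non-negative")
  if (frag_min >= frag_max) stop("frag_min must be < frag_max")
  if (effect_size <= 0) stop("effect_size must be > 0")
  stopifnot_fraction(gc_content, "gc_content")
  stopifnot_fraction(cpg_depletion, "cpg_depletion")
  stopifnot_fraction(repeat_fraction, "repeat_fraction")
  stopifnot_fraction(planted_dmc_fraction, "planted_dmc_fraction")
  stopifnot_fraction(planted_block_fraction, "planted_block_fraction")
  stopifnot_fraction(hyper_bias, "hyper_bias")
  stopifnot_fraction(conversion_rate, "conversion_rate")
  if (biological_dispersion <= 0 || biological_dispersion >= 1)
    stop("biological_dispersion must lie in (0, 1)")
  props <- baseline_mixture$props
  if (is.null(names(props)) ||
      !setequal(names(props), c("hyper", "hypo", "intermediate")))
    stop("baseline_mixture$props needs names hyper, hypo, intermediate")
  if (abs(sum(props) - 1) > 1e-8)
    stop("baseline_mixture proportions must sum to 1")
  if (is.null(names(n_samples_per_group)))
    stop("n_samples_per_group must be a named vector of group labels")
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              gc_content = gc_content, cpg_depletion = cpg_depletion,
              n_genes = as.integer(n_genes), n_cgis = as.integer(n_cgis),
              cgi_length = as.integer(cgi_length),
              repeat_fraction = repeat_fraction,
              frag_min = as.integer(frag_min),
              frag_max = as.integer(frag_max),
              mean_coverage = mean_coverage,
              coverage_dispersion = coverage_dispersion,
              baseline_mixture = baseline_mixture,
              planted_dmc_fraction = planted_dmc_fraction,
              planted_block_fraction = planted_block_fraction,
              effect_size = effect_size, hyper_bias = hyper_bias,
              biological_dispersion = biological_dispersion,
              sample_jitter_sd = sample_jitter_sd,
              conversion_rate = conversion_rate,
              n_samples_per_group = n_samples_per_group,
              spikein_cytosines = as.integer(spikein_cytosines),
              planted_age_dmcs = as.integer(planted_age_dmcs))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("RRBS simulation config\n")
  cat(sprintf("  genome: %d chrom(s) x %s bp, GC %.2f\n", x$n_chroms,
              format(x$chrom_length, big.mark = ","), x$gc_content))
  cat(sprintf("  cohort: %s\n", paste(sprintf("%s=%d",
              names(x$n_samples_per_group), x$n_samples_per_group),
              collapse = ", ")))
  cat(sprintf("  effect: %.0f pts at %.2g%% of CpGs (hyper bias %.2f)\n",
              x$effect_size, 100 * x$planted_dmc_fraction, x$hyper_bias))
  cat(sprintf("  coverage %.0fx, phi %.3g, conversion %.3f, seed %d\n",
              x$mean_coverage, x$biological_dispersion, x$conversion_rate,
              x$seed))
  invisible(x)
}

#' Sample sheet for a simulated cohort
#'
#' Expands the per-group sample counts of a [sim_config()] into a sample
#' sheet.  MM16 reuses the MM15 bulls first, so those bulls contribute
#' paired samples at 15 and 16 months; extra MM16 slots get new bulls.
#'
#' @param config a [sim_config()].
#' @return data.frame with sample_id, bull_id, group (HM/MM), age (months)
#'   and group_label (e.g. "HM15").
#' @export
make_sample_sheet <- function(config) {
  ns <- config$n_samples_per_group
  sheets <- list()
  next_bull <- 1L
  mm15_bulls <- integer(0)
  for (lab in names(ns)) {
    n <- ns[[lab]]
    if (n == 0L) next
    grp <- sub("[0-9]+$", "", lab)
    age <- as.integer(sub("^[A-Za-z]+", "", lab))
    if (lab == "MM16" && length(mm15_bulls)) {
      reuse <- head(mm15_bulls, n)
      fresh <- if (n > length(reuse))
        seq.int(next_bull, length.out = n - length(reuse)) else integer(0)
      bulls <- c(reuse, fresh)
      next_bull <- next_bull + length(fresh)
    } else {
      bulls <- seq.int(next_bull, length.out = n)
      next_bull <- next_bull + n
    }
    if (lab == "MM15") mm15_bulls <- bulls
    sheets[[lab]] <- data.frame(
      sample_id = sprintf("%s_b%02d", lab, bulls),
      bull_id = sprintf("b%02d", bulls),
      group = grp, age = age, group_label = lab,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, sheets)
  rownames(out) <- NULL
  if (anyDuplicated(out[, c("bull_id", "age")]))
    stop("internal error: duplicated (bull, age) in sample sheet")
  out
}
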