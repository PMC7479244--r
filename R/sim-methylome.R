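#' Simulate per-group true methylation levels
#'
#' Assigns every CpG in the retained fragments a baseline methylation level
#' drawn from a three-component mixture (hypermethylated, hypomethylated,
#' intermediate: the bimodal structure of a mature sperm methylome), then
#' plants group effects at a configured fraction of sites.  A planted
#' "hyper in HM" effect raises the HM level by `effect_size` points when
#' that fits in \[0,1\], and otherwise lowers the MM level instead, so the
#' true between-group difference is exactly +/- `effect_size` points.  The
#' two MM age groups share identical truth, except for
#' `config$planted_age_dmcs` optional single-site age effects.
#'
#' @param bundle a `genome_bundle`.
#' @param fragments per-chromosome retained fragments from [digest_bundle()].
#' @param config the [sim_config()].
#' @return data.frame of class `sim_truth`: chrom, pos, baseline level,
#'   per-group levels (one column per group label), `planted_dmc`,
#'   `planted_direction` (hyper_in_group1 / hypo_in_group1 / none, group 1
#'   being the HM-like group) and `clamped`.
#' @export
simulate_methylome <- function(bundle, fragments, config) {
  sites <- cpg_sites_in_fragments(bundle, fragments)
  if (!nrow(sites)) stop("no CpGs in retained fragments")
  with_seed(config$seed + 1L, {
    n <- nrow(sites)
    mix <- config$baseline_mixture
    comp <- sample(names(mix$props), n, replace = TRUE, prob = mix$props)
    level <- numeric(n)
    ih <- comp == "hyper"; io <- comp == "hypo"; im <- comp == "intermediate"
    level[ih] <- 0.8 + 0.2 * rbeta(sum(ih), mix$hyper_shape[1],
                                   mix$hyper_shape[2])
    level[io] <- 0.2 * rbeta(sum(io), mix$hypo_shape[1], mix$hypo_shape[2])
    level[im] <- 0.2 + 0.6 * rbeta(sum(im), mix$intermediate_shape[1],
                                   mix$intermediate_shape[2])

    labels <- names(config$n_samples_per_group)
    hm_labels <- grep("^HM", labels, value = TRUE)
    mm_labels <- grep("^MM", labels, value = TRUE)
    lv <- matrix(level, nrow = n, ncol = length(labels),
                 dimnames = list(NULL, labels))

    # choose planted sites: part regional blocks (3-5 neighbouring CpGs at
    # <= 100 bp steps, one shared direction), part scattered singles
    n_target <- round(config$planted_dmc_fraction * n)
    planted <- rep(FALSE, n)
    block_id <- rep(NA_integer_, n)
    n_block_sites <- round(config$planted_block_fraction * n_target)
    gap_ok <- c(diff(sites$pos) <= 100 &
                  sites$chrom[-n] == sites$chrom[-1], FALSE)
    b <- 0L; tries <- 0L
    while (sum(planted & !is.na(block_id)) < n_block_sites && n > 5L) {
      anchor <- sample.int(n - 5L, 1L)
      size <- sample(3:5, 1L)
      run <- anchor
      while (length(run) < size && gap_ok[run[length(run)]])
        run <- c(run, run[length(run)] + 1L)
      if (length(run) < 3L || any(planted[run])) {
        tries <- tries + 1L
        if (tries > 50000L) break          # CpGs too sparse for blocks
        next
      }
      planted[run] <- TRUE
      block_id[run] <- b <- b + 1L
    }
    singles <- sample(which(!planted), max(0L, n_target - sum(planted)))
    planted[singles] <- TRUE

    dir <- rep("none", n)
    clamped <- rep(FALSE, n)
    eff <- config$effect_size / 100
    idx <- which(planted)
    if (length(idx)) {
      hyper1 <- runif(length(idx)) < config$hyper_bias
      # sites of one block share the block anchor's direction
      for (bb in unique(stats::na.omit(block_id[idx]))) {
        members <- which(block_id[idx] == bb)
        hyper1[members] <- hyper1[members[1]]
      }
      dir[idx] <- ifelse(hyper1, "hyper_in_group1", "hypo_in_group1")
      for (j in seq_along(idx)) {
        i <- idx[j]; b <- level[i]
        if (hyper1[j]) {        # HM higher: raise HM, or lower MM instead
          if (b + eff <= 1) lv[i, hm_labels] <- b + eff
          else if (b - eff >= 0) lv[i, mm_labels] <- b - eff
          else { lv[i, hm_labels] <- 1; clamped[i] <- TRUE }
        } else {                # HM lower: lower HM, or raise MM instead
          if (b - eff >= 0) lv[i, hm_labels] <- b - eff
          else if (b + eff <= 1) lv[i, mm_labels] <- b + eff
          else { lv[i, hm_labels] <- 0; clamped[i] <- TRUE }
        }
      }
    }

    # optional age effect: a handful of sites where MM16 departs from MM15
    if (config$planted_age_dmcs > 0 && all(c("MM15", "MM16") %in% labels)) {
      free <- setdiff(which(!planted & level + eff <= 1),
                      integer(0))
      age_idx <- head(free, config$planted_age_dmcs)
      lv[age_idx, "MM16"] <- lv[age_idx, "MM15"] + eff
    }

    truth <- data.frame(sites, baseline = level, lv, planted_dmc = planted,
                        planted_direction = dir, clamped = clamped,
                        stringsAsFactors = FALSE)
    class(truth) <- c("sim_truth", "data.frame")
    truth
  })
}

# beta-binomial draw, vectorised; phi -> 0 collapses to binomial
rbetabinom <- function(n_trials, prob, phi) {
  stopifnot(length(n_trials) == length(prob))
  q <- prob
  if (phi > 1e-8) {
    a <- prob * (1 - phi) / phi
    b <- (1 - prob) * (1 - phi) / phi
    pos <- prob > 0 & prob < 1
    q[pos] <- rbeta(sum(pos), a[pos], b[pos])
  }
  rbinom(length(n_trials), n_trials, q)
}

#' Simulate per-sample bisulfite counts
#'
#' For each sample, per-site coverage is negative binomial; the sample-level
#' methylation level jitters the group truth through a bull-level random
#' effect on the logit scale (shared by samples from the same bull, which is
#' what makes paired 15/16-month samples resemble each other more than their
#' diet-mates); methylated counts are beta-binomial with the configured
#' biological dispersion; incomplete bisulfite conversion converts a small
#' fraction of truly unmethylated reads into apparent methylated ones; and
#' an unmethylated spike-in is read at the conversion rate.  Sites with zero
#' coverage in a sample are omitted, as in real coverage files.
#'
#' @param truth a `sim_truth` from [simulate_methylome()].
#' @param sample_sheet from [make_sample_sheet()].
#' @param config the [sim_config()].
#' @return list with `matrix` (a [CountMatrix]), `spikeins` (data.frame
#'   sample_id, converted, total) and `sample_levels` (sites x samples
#'   matrix of true sample-level methylation fractions).
#' @export
simulate_sample_counts <- function(truth, sample_sheet, config) {
  stopifnot(inherits(truth, "sim_truth"))
  labels <- unique(sample_sheet$group_label)
  if (!all(labels %in% colnames(truth)))
    stop("sample sheet groups missing from truth: ",
         paste(setdiff(labels, colnames(truth)), collapse = ", "))
  with_seed(config$seed + 2L, {
    n <- nrow(truth); m <- nrow(sample_sheet)
    bulls <- unique(sample_sheet$bull_id)
    bull_eff <- matrix(rnorm(n * length(bulls), 0, config$sample_jitter_sd),
                       nrow = n, dimnames = list(NULL, bulls))
    eps <- 1e-6
    levels <- matrix(NA_real_, n, m,
                     dimnames = list(NULL, sample_sheet$sample_id))
    meth <- tot <- matrix(NA_integer_, n, m,
                          dimnames = list(NULL, sample_sheet$sample_id))
    spike <- data.frame(sample_id = sample_sheet$sample_id,
                        converted = NA_integer_,
                        total = config$spikein_cytosines)
    for (j in seq_len(m)) {
      g <- sample_sheet$group_label[j]
      base <- pmin(pmax(truth[[g]], eps), 1 - eps)
      p <- plogis(qlogis(base) + bull_eff[, sample_sheet$bull_id[j]])
      levels[, j] <- p
      cov <- rnbinom(n, size = config$coverage_dispersion,
                     mu = config$mean_coverage)
      mm <- rbetabinom(cov, p, config$biological_dispersion)
      fail <- rbinom(n, cov - mm, 1 - config$conversion_rate)
      meth[, j] <- as.integer(mm + fail)
      tot[, j] <- as.integer(cov)
      spike$converted[j] <- rbinom(1, config$spikein_cytosines,
                                   config$conversion_rate)
    }
    meth[tot == 0L] <- NA_integer_
    tot[tot == 0L] <- NA_integer_
    cm <- CountMatrix(truth[, c("chrom", "pos")], sample_sheet, meth, tot)
    list(matrix = cm, spikeins = spike, sample_levels = levels)
  })
}

#' Write per-sample bisulfite coverage files
#'
#' One tab-separated file per sample in the standard 6-column coverage
#' dialect: chrom, 1-based start, 1-based end (= start), methylation
#' percentage, count methylated, count unmethylated.  Zero-coverage sites
#' are omitted.
#'
#' @param counts a [CountMatrix].
#' @param dir output directory.
#' @return invisibly, the named vector of file paths.
#' @export
write_coverage_files <- function(counts, dir) {
  stopifnot(inherits(counts, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (sid in counts$samples$sample_id) {
    keep <- !is.na(counts$total[, sid]) & counts$total[, sid] > 0
    m <- counts$meth[keep, sid]; tt <- counts$total[keep, sid]
    df <- data.frame(chrom = counts$sites$chrom[keep],
                     start = counts$sites$pos[keep],
                     end = counts$sites$pos[keep],
                     pct = round(100 * m / tt, 6),
                     count_m = m, count_u = tt - m)
    path <- file.path(dir, paste0(sid, ".cov"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths[sid] <- path
  }
  invisible(paths)
}

#' Simulate a bisulfite-pyrosequencing assay
#'
#' Measures the given CpGs in each sample in duplicate: each replicate is
#' the sample-level true percentage plus Gaussian noise, truncated to
#' \[0, 100\].  A configurable fraction of duplicates is planted to be
#' inconsistent (shifted apart by more than 5 points); inconsistent pairs
#' receive `n_extra` additional replicates, mimicking the repeat-on-failure
#' laboratory rule.
#'
#' @param sample_levels sites x samples matrix of true sample-level
#'   fractions (from [simulate_sample_counts()]).
#' @param sites data.frame(chrom, pos) aligned with `sample_levels` rows.
#' @param regions data.frame(region_id, chrom, pos): the CpGs to assay,
#'   which must be a subset of `sites`.
#' @param noise_sd replicate noise standard deviation (percentage points).
#' @param seed integer seed.
#' @param inconsistent_rate fraction of duplicates planted inconsistent.
#' @param n_extra additional replicates measured for inconsistent pairs.
#' @return long data.frame: region_id, cpg_index (5'->3' within region),
#'   chrom, pos, sample_id, replicate, percentage.
#' @export
simulate_pyro <- function(sample_levels, sites, regions, noise_sd = 2,
                          seed = 1L, inconsistent_rate = 0.03,
                          n_extra = 2L) {
  key <- paste(sites$chrom, sites$pos)
  rkey <- paste(regions$chrom, regions$pos)
  if (!all(rkey %in% key)) stop("assay regions must be a subset of sites")
  ridx <- match(rkey, key)
  with_seed(seed, {
    out <- list()
    for (k in seq_along(ridx)) {
      i <- ridx[k]
      region <- regions$region_id[k]
      for (sid in colnames(sample_levels)) {
        tr <- 100 * sample_levels[i, sid]
        reps <- pmin(pmax(tr + rnorm(2L, 0, noise_sd), 0), 100)
        if (runif(1) < inconsistent_rate)
          reps[2] <- pmin(pmax(reps[1] + sample(c(-1, 1), 1) *
                                 runif(1, 6, 15), 0), 100)
        if (abs(reps[1] - reps[2]) > 5 && n_extra > 0)
          reps <- c(reps, pmin(pmax(tr + rnorm(n_extra, 0, noise_sd), 0),
                               100))
        out[[length(out) + 1L]] <- data.frame(
          region_id = region, chrom = regions$chrom[k],
          pos = regions$pos[k], sample_id = sid,
          replicate = seq_along(reps), percentage = reps,
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    # cpg_index: 5'->3' order within each region
    res$cpg_index <- ave(res$pos, res$region_id,
                         FUN = function(p) match(p, sort(unique(p))))
    rownames(res) <- NULL
    res[, c("region_id", "cpg_index", "chrom", "pos", "sample_id",
            "replicate", "percentage")]
  })
}

#' One-call synthetic RRBS study
#'
#' Generates the toy genome, digests it, simulates truth and per-sample
#' counts, and (optionally) writes every artifact: genome tracks, coverage
#' files, sample sheet, spike-in table and truth table.
#'
#' @param config a [sim_config()].
#' @param outdir if non-NULL, write all files below this directory.
#' @return list with `bundle`, `fragments`, `truth`, `sample_sheet`,
#'   `counts` (CountMatrix), `spikeins`, `sample_levels`, and `paths` when
#'   files were written.
#' @export
simulate_rrbs <- function(config = sim_config(), outdir = NULL) {
  bundle <- generate_toy_genome(config)
  fragments <- digest_bundle(bundle)
  truth <- simulate_methylome(bundle, fragments, config)
  sheet <- make_sample_sheet(config)
  sim <- simulate_sample_counts(truth, sheet, config)
  res <- list(bundle = bundle, fragments = fragments, truth = truth,
              sample_sheet = sheet, counts = sim$matrix,
              spikeins = sim$spikeins, sample_levels = sim$sample_levels)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_genome_bundle(bundle, file.path(outdir, "genome"))
    cov <- write_coverage_files(sim$matrix, file.path(outdir, "coverage"))
    sheet_path <- file.path(outdir, "sample_sheet.csv")
    write.csv(sheet, sheet_path, row.names = FALSE)
    spike_path <- file.path(outdir, "spikeins.csv")
    write.csv(sim$spikeins, spike_path, row.names = FALSE)
    truth_path <- file.path(outdir, "truth.csv")
    write.csv(truth, truth_path, row.names = FALSE)
    res$paths <- list(genome = paths, coverage = cov,
                      sample_sheet = sheet_path, spikeins = spike_path,
                      truth = truth_path)
  }
  res
}
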