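#' Pipeline configuration
#'
#' Collects the inputs and thresholds of an end-to-end run.  Either a
#' simulation config (synthetic study) or a set of input paths (coverage
#' directory, sample sheet, GTF, CGI BED, repeat BED) must be given.
#'
#' @param simulation a [sim_config()], or NULL when analysing real files.
#' @param paths named list of input paths (coverage_dir, sample_sheet,
#'   gtf, cgi_bed, repeat_bed); ignored when `simulation` is given.
#' @param comparisons list of 2-element character vectors of group labels;
#'   the first label is the reference (HM-like) group.  A comparison whose
#'   two labels share the same diet group (e.g. MM15 vs MM16) is analysed
#'   on bulls present at both ages only (paired design).
#' @param min_reads CpG10 coverage threshold.
#' @param min_samples per-group completeness threshold.
#' @param alpha_adj,min_diff,ihw_alpha,ihw_bins DMC thresholds (see
#'   [comparison_spec()]).
#' @param dmr_min,dmr_gap DMR rule (see [call_dmrs()]).
#' @param n_perm Monte-Carlo permutations for QC group tests.
#' @param seed master seed.
#' @param outdir output directory, or NULL to skip writing artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(), paths = NULL,
                            comparisons = list(c("HM15", "MM15"),
                                               c("HM15", "MM16"),
                                               c("MM15", "MM16")),
                            min_reads = 10L, min_samples = 4L,
                            alpha_adj = 0.1, min_diff = 10,
                            ihw_alpha = 0.05, ihw_bins = 10L,
                            dmr_min = 3L, dmr_gap = 100L,
                            n_perm = 100000L, seed = NULL,
                            outdir = NULL) {
  if (is.null(simulation) && is.null(paths))
    stop("either a simulation config or input paths are required")
  cfg <- list(simulation = simulation, paths = paths,
              comparisons = comparisons, min_reads = as.integer(min_reads),
              min_samples = as.integer(min_samples), alpha_adj = alpha_adj,
              min_diff = min_diff, ihw_alpha = ihw_alpha,
              ihw_bins = as.integer(ihw_bins), dmr_min = as.integer(dmr_min),
              dmr_gap = as.integer(dmr_gap), n_perm = as.integer(n_perm),
              seed = seed %||% (if (!is.null(simulation)) simulation$seed
                                else 1L),
              outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — simulate (or read inputs), QC, cluster,
#' differential analysis per comparison, annotation, validation — and
#' writes the module artifacts plus a JSON run manifest echoing every
#' threshold and the record counts at each stage.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  emit <- !is.null(outdir)
  if (emit) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rrbsmeth")),
    seed = config$seed,
    thresholds = config[c("min_reads", "min_samples", "alpha_adj",
                          "min_diff", "ihw_alpha", "ihw_bins", "dmr_min",
                          "dmr_gap", "n_perm")],
    linkage = "average", correlation = "pearson",
    qc_test_statistic = "between-group variance of group means",
    counts = list())

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (emit)
        jsonlite::write_json(
          list(stage = stage, error = conditionMessage(e)),
          file.path(outdir, "error.json"), auto_unbox = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- stage: input (simulate or read) ----
  input <- run_stage("input", {
    if (!is.null(config$simulation)) {
      sim_dir <- if (emit) file.path(outdir, "simulated") else NULL
      sim <- simulate_rrbs(config$simulation, outdir = sim_dir)
      if (emit) {
        # the analysis consumes the emitted files through its own readers
        cm <- build_count_matrix(sim$paths$coverage,
                                 read_sample_sheet(sim$paths$sample_sheet))
        spike <- read.csv(sim$paths$spikeins)
        models <- read_gene_models(sim$paths$genome[["gtf"]])
        cgis <- rtracklayer::import(sim$paths$genome[["cgi"]])
        reps <- rtracklayer::import(sim$paths$genome[["repeats"]])
      } else {
        cm <- sim$counts
        spike <- sim$spikeins
        models <- bundle_gene_models(sim$bundle)
        cgis <- GenomicRanges::GRanges(
          sim$bundle$cgis$chrom,
          IRanges::IRanges(sim$bundle$cgis$start, sim$bundle$cgis$end))
        reps <- sim$bundle$repeats
      }
      chrom_len <- setNames(rep(config$simulation$chrom_length,
                                config$simulation$n_chroms),
                            names(sim$bundle$sequences))
      list(cm = cm, spike = spike, models = models, cgis = cgis,
           repeats = reps, chrom_lengths = chrom_len, sim = sim)
    } else {
      sheet <- read_sample_sheet(config$paths$sample_sheet)
      cov_files <- setNames(
        file.path(config$paths$coverage_dir,
                  paste0(sheet$sample_id, ".cov")), sheet$sample_id)
      spike <- if (!is.null(config$paths$spikeins))
        read.csv(config$paths$spikeins) else NULL
      list(cm = build_count_matrix(cov_files, sheet), spike = spike,
           models = read_gene_models(config$paths$gtf),
           cgis = rtracklayer::import(config$paths$cgi_bed),
           repeats = rtracklayer::import(config$paths$repeat_bed),
           chrom_lengths = NULL, sim = NULL)
    }
  })
  sim <- input$sim
  cm_raw <- input$cm
  manifest$counts$cpgs_read <- nrow(cm_raw$sites)
  stage_log("input", "%d CpGs x %d samples", nrow(cm_raw$sites),
            nrow(cm_raw$samples))

  # ---- stage: QC ----
  qc <- run_stage("qc", {
    cm10 <- filter_cpg10(cm_raw, config$min_reads)
    summary <- qc_summary(cm_raw, input$spike, config$min_reads)
    labs <- cm_raw$samples$group_label
    perm <- list()
    if (length(unique(labs)) >= 2) {
      perm$mean_coverage <- ksample_permutation_test(
        summary$mean_coverage, labs, n_perm = config$n_perm,
        seed = config$seed + 101L)
      perm$mean_methylation <- ksample_permutation_test(
        summary$mean_methylation_cpgs10, labs, n_perm = config$n_perm,
        seed = config$seed + 102L)
    }
    list(cm10 = cm10, summary = summary, permutation = perm)
  })
  manifest$counts$cpgs10 <- nrow(qc$cm10$sites)
  stage_log("qc", "%d CpGs10 retained", nrow(qc$cm10$sites))
  if (emit)
    write.csv(qc$summary, file.path(outdir, "qc_summary.csv"),
              row.names = FALSE)

  # ---- stage: clustering ----
  clust <- run_stage("cluster", {
    cluster_samples(qc$cm10, min_per_group = config$min_samples)
  })
  stage_log("cluster", "%d sites after completeness filter",
            nrow(clust$matrix$sites))
  manifest$counts$cpgs_clustering <- nrow(clust$matrix$sites)
  if (emit) {
    export_newick(clust$tree, file.path(outdir, "clustering.nwk"))
    write.csv(as.data.frame(clust$distances),
              file.path(outdir, "distance_matrix.csv"))
    write.csv(data.frame(sample_id = names(clust$clusters),
                         cluster = clust$clusters),
              file.path(outdir, "cluster_assignments.csv"),
              row.names = FALSE)
  }

  # ---- stage: differential ----
  diffs <- list()
  for (cmp in config$comparisons) {
    name <- paste0(cmp[1], "_vs_", cmp[2])
    diffs[[name]] <- run_stage(paste0("diff:", name), {
      cm_use <- qc$cm10
      sheet <- cm_use$samples
      paired <- substr(cmp[1], 1, 2) == substr(cmp[2], 1, 2)
      if (paired) {
        # same diet at two ages: restrict to bulls sampled at both
        b1 <- sheet$bull_id[sheet$group_label == cmp[1]]
        b2 <- sheet$bull_id[sheet$group_label == cmp[2]]
        both <- intersect(b1, b2)
        keep <- sheet$bull_id %in% both |
          !(sheet$group_label %in% cmp)
        cm_use <- subset_matrix(cm_use, samples = which(keep))
      }
      spec <- comparison_spec(cmp[1], cmp[2],
                              min_samples_per_group = config$min_samples,
                              alpha_adj = config$alpha_adj,
                              min_diff = config$min_diff,
                              ihw_alpha = config$ihw_alpha,
                              ihw_bins = config$ihw_bins)
      tests <- dm_test(cm_use, spec)
      dmcs <- call_dmcs(tests, spec)
      dmrs <- call_dmrs(dmcs, config$dmr_min, config$dmr_gap)
      volcano <- volcano_table(tests, spec)
      list(spec = spec, tests = tests, dmcs = dmcs, dmrs = dmrs,
           volcano = volcano, paired = paired)
    })
    manifest$counts[[name]] <- list(tested = nrow(diffs[[name]]$tests),
                                    dmcs = nrow(diffs[[name]]$dmcs),
                                    dmrs = nrow(diffs[[name]]$dmrs))
    stage_log("diff", "%s: %d tested, %d DMCs, %d DMRs", name,
              nrow(diffs[[name]]$tests), nrow(diffs[[name]]$dmcs),
              nrow(diffs[[name]]$dmrs))
    if (emit) {
      write.csv(diffs[[name]]$dmcs,
                file.path(outdir, paste0("dmcs_", name, ".csv")),
                row.names = FALSE)
      write.csv(diffs[[name]]$volcano,
                file.path(outdir, paste0("volcano_", name, ".csv")),
                row.names = FALSE)
      dmr <- diffs[[name]]$dmrs
      write.csv(dmr, file.path(outdir, paste0("dmrs_", name, ".csv")),
                row.names = FALSE)
      # BED is 0-based half-open
      if (nrow(dmr))
        write.table(data.frame(dmr$chrom, dmr$start - 1L, dmr$end,
                               sprintf("DMR_%03d", seq_len(nrow(dmr))),
                               dmr$n_dmcs,
                               ifelse(dmr$direction == "hyper_in_group1",
                                      "+", "-")),
                    file.path(outdir, paste0("dmrs_", name, ".bed")),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
  }

  # ---- stage: set comparison (first two comparisons) ----
  set_cmp <- NULL
  if (length(diffs) >= 2) {
    nm <- names(diffs)[1:2]
    set_cmp <- compare_dmc_sets(diffs[[nm[1]]]$dmcs, diffs[[nm[2]]]$dmcs,
                                nm[1], nm[2])
    if (emit)
      jsonlite::write_json(unclass(set_cmp),
                           file.path(outdir, "dmc_set_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
  }

  # ---- stage: annotation ----
  annot <- run_stage("annotate", {
    tracks <- derive_context_tracks(input$cgis, input$chrom_lengths)
    background <- qc$cm10$sites
    bg_annot <- annotate_positions(background, input$models, tracks,
                                   input$repeats, input$chrom_lengths)
    per_cmp <- list()
    for (name in names(diffs)) {
      dmcs <- diffs[[name]]$dmcs
      if (!nrow(dmcs)) next
      q_annot <- annotate_positions(dmcs[, c("chrom", "pos")],
                                    input$models, tracks, input$repeats,
                                    input$chrom_lengths)
      enr <- enrichment_vs_background(q_annot, bg_annot)
      genes <- associate_genes(dmcs[, c("chrom", "pos")], input$models)
      per_cmp[[name]] <- list(annotation = q_annot, enrichment = enr,
                              genes = genes$genes)
      if (emit) {
        write.csv(cbind(dmcs, q_annot[, c("gene_feature", "cpg_context",
                                          "repeat_classes",
                                          "associated_genes")]),
                  file.path(outdir, paste0("dmcs_annotated_", name,
                                           ".csv")), row.names = FALSE)
        write.csv(enr, file.path(outdir, paste0("enrichment_", name,
                                                ".csv")),
                  row.names = FALSE)
      }
    }
    bg_genes <- background_gene_list(background, input$models)
    if (emit)
      writeLines(bg_genes, file.path(outdir, "background_genes.txt"))
    list(tracks = tracks, background = bg_annot, per_comparison = per_cmp,
         background_genes = bg_genes)
  })

  # ---- stage: validation (simulated pyro assay of top DMRs) ----
  validation <- NULL
  if (!is.null(sim)) validation <- run_stage("validate", {
    first <- diffs[[1]]
    dmrs <- first$dmrs
    if (!nrow(dmrs)) return(NULL)
    top <- head(dmrs[order(-dmrs$n_dmcs), ], 4)
    regions <- do.call(rbind, lapply(seq_len(nrow(top)), function(k)
      data.frame(region_id = sprintf("%s:%d-%d", top$chrom[k],
                                     top$start[k], top$end[k]),
                 chrom = top$chrom[k],
                 pos = as.integer(strsplit(top$member_pos[k], ",")[[1]]),
                 stringsAsFactors = FALSE)))
    pyro_raw <- simulate_pyro(sim$sample_levels,
                              sim$truth[, c("chrom", "pos")], regions,
                              seed = config$seed + 7L)
    pyro <- consolidate_replicates(pyro_raw)
    rrbs_means <- dmr_sample_means(qc$cm10, top)
    concord <- spearman_concordance(rrbs_means, pyro)
    tests <- pyro_group_tests(pyro, sim$sample_sheet,
                              n_perm = min(config$n_perm, 20000L),
                              seed = config$seed + 8L)
    if (emit) {
      write.csv(concord, file.path(outdir, "pyro_concordance.csv"),
                row.names = FALSE)
      write.csv(tests, file.path(outdir, "pyro_group_tests.csv"),
                row.names = FALSE)
    }
    list(raw = pyro_raw, consolidated = pyro, concordance = concord,
         tests = tests)
  })

  if (emit)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = config, input = input, sim = sim, qc = qc,
                 clustering = clust, differential = diffs,
                 set_comparison = set_cmp, annotation = annot,
                 validation = validation, manifest = manifest))
}
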