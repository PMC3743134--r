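# End-to-end orchestration: simulate or load inputs, run every analysis
# stage in dependency order, write TSV outputs and a run manifest.

#' Build and validate a pipeline configuration
#'
#' Collects the simulation plan (or input paths), every analysis threshold,
#' replicate design and output directory. All thresholds surface the
#' pipeline defaults: twofold enrichment, 99th-percentile signal filter,
#' 500 bp TBP distance, TU-enrichment pausing cutoff 1, top-20% reference
#' fraction for dual genes, maternal/active RPKM cutoffs 1 and 5, nc10
#' maternal filter 16, duplicate-stack cutoff 10, 10,000 resampling draws
#' and alpha 0.05.
#'
#' @param plan A [simulation_plan()] (used unless `inputs` is given).
#' @param inputs Optional named list of input file paths (annotation,
#'   pre_ip, pre_wce, mbt_ip, mbt_wce, expression, promoters, tbp_peaks,
#'   reference_ranking); all must exist.
#' @param outdir Output directory.
#' @param n_pre_replicates,n_mbt_replicates Replicates per stage.
#' @param thresholds Named list overriding individual defaults.
#' @param seed Integer seed for the analysis-side randomness (resampling).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(plan = simulation_plan(), inputs = NULL,
                            outdir = tempfile("pausekit_run_"),
                            n_pre_replicates = 4, n_mbt_replicates = 3,
                            thresholds = list(), seed = 1L) {
  defaults <- list(twofold = 2, percentile = 0.99, tbp_distance = 500,
                   tu_paused_cutoff = 1, dual_top_fraction = 0.20,
                   rpkm_maternal = 1, rpkm_active = 5, maternal_filter = 16,
                   dedup_max = 10, zelda_samples = 10000, alpha = 0.05)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  cfg <- structure(list(plan = plan, inputs = inputs, outdir = outdir,
                        n_pre_replicates = as.integer(n_pre_replicates),
                        n_mbt_replicates = as.integer(n_mbt_replicates),
                        thresholds = defaults, seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  positive <- c("twofold", "tbp_distance", "tu_paused_cutoff",
                "dual_top_fraction", "rpkm_maternal", "rpkm_active",
                "maternal_filter", "dedup_max", "zelda_samples", "alpha")
  for (nm in positive)
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0)
      stop("threshold '", nm, "' must be positive")
  if (th$percentile <= 0 || th$percentile >= 1)
    stop("threshold 'percentile' must be in (0, 1)")
  if (cfg$n_pre_replicates < 1 || cfg$n_mbt_replicates < 1)
    stop("need at least one replicate per stage")
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs, use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  } else {
    validate_plan(cfg$plan)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `plan` keys
#' mirror [simulation_plan()] arguments (scalar parameters only).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  plan_args <- y$plan
  plan <- if (is.null(plan_args)) simulation_plan()
  else do.call(simulation_plan, plan_args)
  pipeline_config(plan = plan, inputs = y$inputs,
                  outdir = y$outdir %||% tempfile("pausekit_run_"),
                  n_pre_replicates = y$n_pre_replicates %||% 4,
                  n_mbt_replicates = y$n_mbt_replicates %||% 3,
                  thresholds = y$thresholds %||% list(),
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_inputs <- function(cfg) {
  if (is.null(cfg$inputs)) {
    study <- simulate_study(cfg$plan, cfg$n_pre_replicates,
                            cfg$n_mbt_replicates)
    return(study)
  }
  ins <- cfg$inputs
  transcripts <- read_annotation_bed(ins$annotation)
  chrom_sizes <- tapply(transcripts$end, transcripts$chrom, max) + 1000L
  fl <- cfg$plan$fragment_length
  pair <- function(ip_paths, wce_paths) lapply(seq_along(ip_paths),
    function(r) list(ip = read_bed_reads(ip_paths[[r]], fl),
                     wce = read_bed_reads(wce_paths[[r]], fl)))
  promoters <- Biostrings::readDNAStringSet(ins$promoters)
  names(promoters) <- sub(" .*", "", names(promoters))
  list(plan = cfg$plan, transcripts = transcripts,
       truth = list(chrom_sizes = chrom_sizes),
       pre_replicates = pair(ins$pre_ip, ins$pre_wce),
       mbt_replicates = pair(ins$mbt_ip, ins$mbt_wce),
       expression = read_tsv(ins$expression),
       promoters = list(sequences = promoters, offset = -2000L,
                        plants = NULL),
       conservation = if (!is.null(ins$conservation))
         read_wig(ins$conservation) else NULL,
       patterns = if (!is.null(ins$patterns)) read_tsv(ins$patterns) else NULL,
       reference_ranking = read_tsv(ins$reference_ranking),
       tbp_peaks = read_peaks(ins$tbp_peaks))
}

#' Run the full pausing-analysis pipeline
#'
#' Stages, in dependency order: input generation/loading; duplicate
#' filtering, read extension and coverage; per-replicate enrichment records
#' for both stages; pre-MBT and MBT gene identification and classification;
#' promoter element scanning, per-group enrichments, Zelda resampling test
#' and co-occurrence; TSS group-average profile; gene-structure,
#' conservation and earliest-expression statistics. All tabular outputs are
#' written as TSV under the configured output directory together with a JSON
#' run manifest (parameters, seeds, record counts). Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisible list with all stage results and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_config(config)
  th <- config$thresholds
  say <- function(...) if (!quiet) message("[pausekit] ", ...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  say("stage 1/6: inputs")
  study <- .load_inputs(config)
  chrom_sizes <- study$truth$chrom_sizes
  transcripts <- study$transcripts

  say("stage 2/6: coverage and enrichment (",
      length(study$pre_replicates), " pre-MBT + ",
      length(study$mbt_replicates), " MBT replicates)")
  pre_records <- enrichment_records(study$pre_replicates, transcripts,
                                    chrom_sizes, max_duplicates = th$dedup_max)
  mbt_records <- enrichment_records(study$mbt_replicates, transcripts,
                                    chrom_sizes, max_duplicates = th$dedup_max)
  # keep one MBT replicate's tracks for the profile stage
  r1 <- study$mbt_replicates[[1]]
  ip1 <- compute_coverage(extend_reads(
    remove_duplicate_stacks(r1$ip, th$dedup_max)$reads,
    chrom_sizes = chrom_sizes), chrom_sizes)

  say("stage 3/6: gene classification")
  cls <- classify_genes(pre_records, mbt_records, transcripts,
                        study$tbp_peaks, study$expression,
                        study$reference_ranking,
                        min_fold = th$twofold, percentile = th$percentile,
                        max_tss_distance = th$tbp_distance,
                        tu_cutoff = th$tu_paused_cutoff,
                        dual_top_fraction = th$dual_top_fraction,
                        maternal_min = th$rpkm_maternal,
                        active_min = th$rpkm_active)
  classes <- cls$classes

  say("stage 4/6: promoter elements")
  hits <- scan_promoters(study$promoters$sequences,
                         seq_offset = study$promoters$offset)
  hit_gene <- transcripts$gene_id[match(hits$transcript_id,
                                        transcripts$transcript_id)]
  rep_tx <- classes$transcript_id[!is.na(classes$transcript_id)]
  motif_enr <- list()
  zelda <- list()
  for (g in intersect(bound_groups(), unique(classes$group))) {
    ids <- classes$transcript_id[classes$group == g &
                                   !is.na(classes$transcript_id)]
    if (length(ids) < 2) next
    motif_enr[[g]] <- cbind(group = g,
                            element_enrichment(ids, hits,
                                               motifs = setdiff(
                                                 motif_catalog()$name, "Zelda"),
                                               alpha = th$alpha))
    counts <- stats::setNames(hits$Zelda_count, hits$transcript_id)
    zl <- zelda_sampling_test(ids, counts, n_samples = th$zelda_samples,
                              seed = derive_seed(config$seed, "zelda", g))
    zelda[[g]] <- data.frame(group = g, enrichment = zl$enrichment,
                             p_value = zl$p_value,
                             n_samples = zl$n_samples)
  }
  motif_enr <- if (length(motif_enr)) do.call(rbind, motif_enr) else NULL
  zelda <- if (length(zelda)) do.call(rbind, zelda) else NULL
  cooc <- if (length(rep_tx) >= 2)
    motif_cooccurrence(hits, transcripts = rep_tx, alpha = th$alpha) else NULL

  say("stage 5/6: profiles")
  disp <- transcripts[match(rep_tx, transcripts$transcript_id), ]
  disp$group <- classes$group[match(disp$gene_id, classes$gene_id)]
  profile <- if (nrow(disp)) group_average_profile(ip1, disp) else NULL

  say("stage 6/6: statistics")
  struct <- structure_summary(classes, transcripts)
  consv <- if (!is.null(study$conservation))
    conservation_summary(study$conservation, transcripts, classes) else NULL
  patt <- if (!is.null(study$patterns) &&
              any(classes$group == "MBT poised")) {
    first_expression_enrichment(study$patterns,
                                classes$gene_id[classes$group == "MBT poised"],
                                alpha = th$alpha)
  } else NULL

  say("writing outputs to ", config$outdir)
  out <- function(name) file.path(config$outdir, name)
  params <- c(config$thresholds, seed = config$seed)
  write_tsv(rbind(cbind(stage = "pre-MBT", pre_records),
                  cbind(stage = "MBT", mbt_records)),
            out("enrichments.tsv"), params = params)
  write_tsv(classes, out("classes.tsv"), params = params)
  if (!is.null(motif_enr)) write_tsv(motif_enr, out("motif_enrichment.tsv"),
                                     params = params)
  if (!is.null(zelda)) write_tsv(zelda, out("zelda_enrichment.tsv"),
                                 params = params)
  if (!is.null(cooc)) {
    cm <- as.data.frame(cooc$enrichment)
    cm <- cbind(motif = rownames(cm), cm)
    write_tsv(cm, out("motif_cooccurrence.tsv"), params = params)
  }
  if (!is.null(profile)) write_tsv(profile, out("group_profiles.tsv"),
                                   params = params)
  write_tsv(struct$table, out("structure_summary.tsv"), params = params)
  if (!is.null(struct$tests)) write_tsv(struct$tests,
                                        out("structure_tests.tsv"),
                                        params = params)
  if (!is.null(consv)) write_tsv(consv$scores, out("conservation.tsv"),
                                 params = params)
  if (!is.null(patt)) write_tsv(patt$enrichment,
                                out("first_expression_enrichment.tsv"),
                                params = params)

  manifest <- list(
    package = "pausekit",
    version = as.character(utils::packageVersion("pausekit")),
    seed = config$seed,
    plan_seed = if (is.null(config$inputs)) config$plan$seed else NULL,
    thresholds = config$thresholds,
    n_pre_replicates = length(study$pre_replicates),
    n_mbt_replicates = length(study$mbt_replicates),
    counts = cls$log,
    outputs = list.files(config$outdir, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(study = study, pre_records = pre_records,
                 mbt_records = mbt_records, classification = cls,
                 hits = hits, motif_enrichment = motif_enr, zelda = zelda,
                 cooccurrence = cooc, profile = profile,
                 structure = struct, conservation = consv,
                 first_expression = patt, outdir = config$outdir,
                 manifest = manifest))
}
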