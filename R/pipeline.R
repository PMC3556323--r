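#' @importFrom utils packageVersion modifyList
NULL

## ---------------------------------------------------------------------------
## End-to-end orchestration: simulate -> call peaks per condition ->
## knockout-null subtraction -> classify responses -> integrate -> annotate
## -> scan motifs -> summary JSON. All randomness flows from one seed.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param seed master seed for the bundled simulation.
#' @param out_dir output directory.
#' @param sim a [sim_config()]; its `seed` is overridden by `seed`.
#' @param peaks a [peak_params()].
#' @param thresholds a [response_thresholds()].
#' @param motif a [motif_params()].
#' @param window_bp TSS occupancy window for direct targets (bp).
#' @param write_tags also write the (large) per-condition tag BED files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "cistrotype_out",
                            sim = NULL, peaks = peak_params(),
                            thresholds = response_thresholds(),
                            motif = motif_params(), window_bp = 10000,
                            write_tags = FALSE) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  else { sim$seed <- seed }
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 peaks = peaks, thresholds = thresholds, motif = motif,
                 window_bp = window_bp, write_tags = isTRUE(write_tags)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `out_dir`, `window_bp`, `write_tags`,
#' plus nested `sim`, `peaks`, `thresholds`, `motif` blocks whose entries
#' override the corresponding constructor defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  sim_args <- y$sim
  if (!is.null(y$seed)) sim_args$seed <- y$seed
  pipeline_config(
    seed = if (is.null(y$seed)) 1L else y$seed,
    out_dir = if (is.null(y$out_dir)) "cistrotype_out" else y$out_dir,
    sim = build(sim_config, sim_args),
    peaks = build(peak_params, y$peaks),
    thresholds = build(response_thresholds, y$thresholds),
    motif = build(motif_params, y$motif),
    window_bp = if (is.null(y$window_bp)) 10000 else y$window_bp,
    write_tags = isTRUE(y$write_tags))
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  invisible(NULL)
}

#' Run the full pipeline on a simulated study
#'
#' Executes every stage on data drawn from the configured generator and
#' writes all stage outputs plus `summary.json` under `out_dir`. The
#' summary contains per-type gene counts, the direct-target set sizes
#' (|A|, |B|, |A intersect B|, |A union B|), per-category and per-chromosome
#' enrichment, per-motif co-occurrence, and ground-truth recovery metrics
#' (planted-site recall, response-type accuracy, artifact removal).
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress and effective parameters.
#' @return list of class `cistrotype_run` with all stage results and the
#'   `summary` list.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(verbose, "config: seed=", config$seed,
               " z>", config$peaks$z_threshold,
               " fc>=", config$thresholds$fc_min,
               " fdr<=", config$thresholds$fdr_max,
               " window=", config$window_bp, "bp")

  ## stage: simulate -------------------------------------------------------
  pipeline_log(verbose, "simulate: genome/annotation/mappability")
  sim <- simulate_genome(config$sim)
  chrom_lengths <- sim$manifest$chrom_lengths
  tags <- list()
  for (cond in SIM_CONDITIONS) {
    pipeline_log(verbose, "simulate: tags ", cond)
    tags[[cond]] <- simulate_tags(sim, cond)
  }
  expr <- simulate_expression(sim)
  write_simulation(sim, file.path(config$out_dir, "inputs"),
                   conditions = if (config$write_tags) SIM_CONDITIONS else character(0),
                   expression = expr)

  ## stage: peak calling per condition ------------------------------------
  chip_conditions <- grep("^chip_", SIM_CONDITIONS, value = TRUE)
  peaks <- list()
  for (cond in chip_conditions) {
    input_cond <- if (grepl("_null_", cond)) "input_null" else "input_wt"
    inp <- normalize_input(tags[[input_cond]], tags[[cond]]$total_tags)
    pipeline_log(verbose, "callpeaks: ", cond, " (input ", input_cond, ")")
    peaks[[cond]] <- call_hotspots(tags[[cond]], inp, sim$mappability,
                                   chrom_lengths, config$peaks)
    write_peaks(peaks[[cond]], file.path(config$out_dir, paste0("peaks_", cond, ".bed")))
  }

  ## stage: knockout-null subtraction --------------------------------------
  null_set <- sort_genomic(suppressWarnings(
    c(granges_strip(peaks$chip_null_veh), granges_strip(peaks$chip_null_lig))))
  filtered <- list(
    without_ligand = subtract_null_peaks(peaks$chip_wt_veh, null_set),
    with_ligand = subtract_null_peaks(peaks$chip_wt_lig, null_set))
  pipeline_log(verbose, "null-subtract: ",
               length(peaks$chip_wt_veh) - length(filtered$without_ligand), "+",
               length(peaks$chip_wt_lig) - length(filtered$with_ligand),
               " peaks removed")
  for (nm in names(filtered))
    write_peaks(filtered[[nm]], file.path(config$out_dir, paste0("peaks_", nm, "_filtered.bed")))

  ## stage: response classification ----------------------------------------
  pipeline_log(verbose, "classify: ", nrow(expr$matrix), " genes")
  classification <- classify_all(expr$matrix, expr$design, config$thresholds)
  resp <- classification$assignments
  data.table::fwrite(resp, file.path(config$out_dir, "responses.tsv"), sep = "\t")

  ## stage: integration ----------------------------------------------------
  assignments <- lapply(filtered, assign_peaks_to_tss, genes = sim$genes)
  targets <- direct_target_sets(assignments$without_ligand,
                                assignments$with_ligand,
                                resp, config$window_bp)
  pipeline_log(verbose, "integrate: |A|=", targets$summary$n_without,
               " |B|=", targets$summary$n_with,
               " |A.B|=", targets$summary$n_intersect,
               " |AuB|=", targets$summary$n_union)
  data.table::fwrite(targets$genes, file.path(config$out_dir, "direct_targets.tsv"),
                     sep = "\t")
  for (nm in names(assignments))
    data.table::fwrite(assignments[[nm]],
                       file.path(config$out_dir, paste0("assignments_", nm, ".tsv")),
                       sep = "\t")
  profiles <- lapply(names(assignments), function(nm)
    tss_distance_profile(targets, assignments[[nm]], resp, config$window_bp))
  names(profiles) <- names(assignments)

  ## stage: annotation ------------------------------------------------------
  partition <- genome_feature_partition(sim$genes, chrom_lengths)
  baselines <- genome_category_fractions(partition, chrom_lengths)
  annotation <- list()
  for (nm in names(filtered)) {
    cats <- annotate_peaks(filtered[[nm]], partition)
    annotation[[nm]] <- list(
      features = category_enrichment(cats, baselines$category),
      chromosomes = chromosome_enrichment(filtered[[nm]], chrom_lengths))
    data.table::fwrite(annotation[[nm]]$features,
                       file.path(config$out_dir, paste0("enrichment_features_", nm, ".tsv")),
                       sep = "\t")
    data.table::fwrite(annotation[[nm]]$chromosomes,
                       file.path(config$out_dir, paste0("enrichment_chromosomes_", nm, ".tsv")),
                       sep = "\t")
  }

  ## stage: motifs ----------------------------------------------------------
  pipeline_log(verbose, "scan-motifs: building PWM library")
  ppre_sites <- readLines(system.file("extdata", "ppre_sites_synthetic.txt",
                                      package = "cistrotype"))
  ppre_sites <- ppre_sites[!startsWith(ppre_sites, "#") & nzchar(ppre_sites)]
  pwms <- list(
    PPRE = build_pfm(ppre_sites, name = "PPRE"),
    PPRE_half = build_pfm(substr(ppre_sites, 8, 13), name = "PPRE_half"),
    decoy = build_pfm(rep(config$sim$decoy_consensus, 4), name = "decoy"))
  write_transfac(pwms, file.path(config$out_dir, "motifs.transfac"))

  region_seq <- function(pk) {
    if (length(pk) == 0) return(character(0))
    region_sequences(sim$genome,
                     expand_region(pk, chrom_lengths, config$motif$region_bp))
  }
  groups <- list(without_ligand = region_seq(filtered$without_ligand),
                 with_ligand = region_seq(filtered$with_ligand))
  null_seqs <- region_seq(peaks$chip_null_veh)
  cooc <- region_cooccurrence(groups, pwms, null_seqs, config$motif,
                              wt_group = "without_ligand")
  data.table::fwrite(cooc, file.path(config$out_dir, "motif_cooccurrence.tsv"),
                     sep = "\t")
  tree <- motif_tree(pwms)
  writeLines(tree$newick, file.path(config$out_dir, "motif_tree.nwk"))
  consensus <- consensus_iupac(pwms$PPRE, config$motif)

  ## ground-truth recovery --------------------------------------------------
  truth <- pipeline_truth_metrics(sim, peaks, filtered, resp)
  pipeline_log(verbose, "truth: site recall veh=", round(truth$recall_without, 3),
               " lig=", round(truth$recall_with, 3),
               " type accuracy=", round(truth$type_accuracy, 3))

  ## summary ----------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    package_version = as.character(packageVersion("cistrotype")),
    parameters = list(z_threshold = config$peaks$z_threshold,
                      window_bp = config$window_bp,
                      fc_min = config$thresholds$fc_min,
                      fdr_max = config$thresholds$fdr_max,
                      region_bp = config$motif$region_bp),
    n_peaks = lapply(peaks, length),
    n_peaks_filtered = lapply(filtered, length),
    response_counts = as.list(classification$counts),
    response_summary = summarize_response_counts(classification$counts),
    switch_ratio = as.list(classification$switch_ratio),
    direct_targets = targets$summary,
    occupancy_by_type = as.data.frame(targets$by_type),
    consensus = consensus,
    motif_cooccurrence = cooc,
    truth_recovery = truth)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  structure(list(config = config, sim = sim, tags = tags, peaks = peaks,
                 filtered = filtered, expression = expr,
                 classification = classification,
                 assignments = assignments, targets = targets,
                 profiles = profiles, annotation = annotation,
                 pwms = pwms, cooccurrence = cooc, tree = tree,
                 summary = summary),
            class = "cistrotype_run")
}

# Planted-truth recovery: site recall per condition, artifact removal, and
# response-type accuracy.
pipeline_truth_metrics <- function(sim, peaks, filtered, resp) {
  man <- sim$manifest
  to_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(GRanges())
    GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  }
  recall <- function(sites_df, called) {
    sites <- to_gr(sites_df)
    if (length(sites) == 0) return(NA_real_)
    mean(IRanges::overlapsAny(sites, granges_strip(called)))
  }
  art <- to_gr(man$artifact_sites)
  artifact_surviving <- function(pk) {
    if (length(pk) == 0) return(0L)
    sum(IRanges::overlapsAny(granges_strip(pk), art, minoverlap = 2L))
  }
  truth_types <- man$response_types
  called_types <- resp$type[match(names(truth_types), resp$gene_id)]
  planted <- truth_types != "none"
  ps <- man$planted_sites
  list(
    recall_without = recall(ps[ps$class %in% c("veh_only", "both"), ],
                            peaks$chip_wt_veh),
    recall_with = recall(ps[ps$class %in% c("lig_only", "both"), ],
                         peaks$chip_wt_lig),
    artifact_peaks_before = artifact_surviving(peaks$chip_wt_veh) +
      artifact_surviving(peaks$chip_wt_lig),
    artifact_peaks_after = artifact_surviving(filtered$without_ligand) +
      artifact_surviving(filtered$with_ligand),
    type_accuracy = mean(called_types[planted] == truth_types[planted]),
    n_planted_de = sum(planted))
}

#' @export
print.cistrotype_run <- function(x, ...) {
  s <- x$summary
  cat("cistrotype run (seed ", s$seed, ")\n", sep = "")
  cat("  peaks: ", paste(names(s$n_peaks), unlist(s$n_peaks), collapse = ", "), "\n")
  cat("  direct targets: |A|=", s$direct_targets$n_without,
      " |B|=", s$direct_targets$n_with,
      " union=", s$direct_targets$n_union, "\n", sep = "")
  cat("  consensus: ", s$consensus, "\n", sep = "")
  invisible(x)
}
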