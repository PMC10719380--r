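#' Pipeline configuration
#'
#' Collects every tunable of the simulate-to-report pipeline with its
#' default, so a run is fully described by one object. The configuration
#' round-trips through YAML ([read_config()] / [write_config()]) and its
#' hash is embedded in the header of every output file the pipeline writes.
#'
#' @param seed Master seed; all stage RNG streams derive from it.
#' @param n_per_category Simulated events per category.
#' @param grid_size PSI quadrature grid size.
#' @param bf_threshold Bayes-factor calling threshold.
#' @param min_info Minimum pooled depth per condition for testability.
#' @param ks_magnitude `"absolute"` or `"signed"` delta-PSI for the K-S
#'   comparison.
#' @param n_replicates Replicates per condition in the simulator.
#' @param coverage Coverage model list (`model`, `mean`, `dispersion`).
#' @param frac_differential Named differential fractions (treatment,
#'   disease).
#' @param frac_switch Planted switch fraction among jointly differential
#'   events.
#' @param frac_disease_given_treatment Overlap linkage between contrasts.
#' @param effect_dist `list(min, max)` bounds of planted |delta-PSI|.
#' @param out_dir Output directory (`NULL`: nothing is written).
#' @return A list of class `splice_config`.
#' @export
splice_config <- function(seed = 1L,
                          n_per_category = 300L,
                          grid_size = 1001L,
                          bf_threshold = 20,
                          min_info = 10,
                          ks_magnitude = "absolute",
                          n_replicates = 3L,
                          coverage = list(model = "nb", mean = 100,
                                          dispersion = 0.3),
                          frac_differential = c(treatment = 0.03,
                                                disease = 0.0443),
                          frac_switch = 0.63,
                          frac_disease_given_treatment = 0.17,
                          effect_dist = list(min = 0.25, max = 0.45),
                          out_dir = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    n_per_category = as.integer(n_per_category),
    grid_size = as.integer(grid_size),
    bf_threshold = bf_threshold,
    min_info = min_info,
    ks_magnitude = ks_magnitude,
    n_replicates = as.integer(n_replicates),
    coverage = coverage,
    frac_differential = as.list(frac_differential),
    frac_switch = frac_switch,
    frac_disease_given_treatment = frac_disease_given_treatment,
    effect_dist = effect_dist,
    out_dir = out_dir
  )
  structure(cfg, class = "splice_config")
}

#' @rdname splice_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname splice_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- splice_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname splice_config
#' @param cfg A `splice_config`.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  # hash the analysis parameters only: where outputs land is not part of
  # the scientific configuration
  cfg$out_dir <- NULL
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.splice_config <- function(x, ...) {
  cat("<splice_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Run the full simulate-to-report pipeline
#'
#' Executes every stage on synthetic data with known ground truth: catalog
#' and truth simulation, replicate-level count simulation for the four
#' conditions, differential calling for the treatment (apigenin vs DMSO)
#' and disease (TNBC vs NBT, tumor minus normal) contrasts, per-category
#' composition statistics, RBP-substrate hypergeometric enrichment and K-S
#' delta-PSI comparison, and the switch analysis intersecting the two
#' contrasts. When `cfg$out_dir` is set, every stage writes its TSV output
#' plus a JSON run manifest (package version, resolved configuration, its
#' hash, and md5 checksums of all outputs) and a plain-text report; outputs
#' are byte-identical across runs at the same configuration and seed.
#'
#' @param cfg A [splice_config()].
#' @param quiet Suppress per-stage funnel messages.
#' @return A named list with all stage outputs: `catalog`, `truth`,
#'   `counts`, `treatment`, `disease`, `composition_treatment`,
#'   `composition_disease`, `enrichment`, `ks`, `shared`, `switch_calls`,
#'   `switch_summary`, `switch_enrichment`.
#' @export
run_splice_pipeline <- function(cfg = splice_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(cfg)

  catalog <- simulate_event_catalog(cfg$n_per_category, seed = cfg$seed)
  say("catalog: %d events (%d per category)", nrow(catalog),
      cfg$n_per_category)
  truth <- simulate_truth(
    catalog,
    frac_differential = unlist(cfg$frac_differential),
    effect_dist = cfg$effect_dist,
    frac_switch = cfg$frac_switch,
    frac_disease_given_treatment = cfg$frac_disease_given_treatment,
    seed = cfg$seed
  )
  counts <- simulate_counts(truth, catalog, coverage = cfg$coverage,
                            n_replicates = cfg$n_replicates, seed = cfg$seed)
  say("counts: %d rows (%d replicates x 4 conditions)", nrow(counts),
      cfg$n_replicates)

  treatment <- call_contrast(
    counts, catalog, conditions = c("DMSO", "apigenin"),
    bf_threshold = cfg$bf_threshold, min_info = cfg$min_info,
    grid_size = cfg$grid_size, contrast_label = "apigenin vs DMSO"
  )
  say("treatment contrast: %d tested -> %d significant",
      attr(treatment, "n_tested"), attr(treatment, "n_significant"))
  disease <- call_contrast(
    counts, catalog, conditions = c("NBT", "TNBC"),
    bf_threshold = cfg$bf_threshold, min_info = cfg$min_info,
    grid_size = cfg$grid_size, contrast_label = "TNBC vs NBT"
  )
  say("disease contrast: %d tested -> %d significant",
      attr(disease, "n_tested"), attr(disease, "n_significant"))

  comp_t <- composition_summary(treatment,
                                ratio_orientation = "excluded_over_included")
  comp_d <- composition_summary(disease,
                                ratio_orientation = "included_over_excluded")

  gene_sets <- truth_gene_sets(truth)
  universe <- contrast_gene_universe(treatment)
  enr <- hypergeometric_enrichment(contrast_differential_genes(treatment),
                                   gene_sets, universe)
  ks <- ks_delta_psi(treatment, gene_sets,
                     magnitude_mode = cfg$ks_magnitude)

  shared <- intersect_contrasts(treatment, disease)
  switch_calls <- classify_switch(shared)
  sw_sum <- switch_summary(treatment, shared, switch_calls)
  say("switch: %d shared, %d switched toward non-tumor (%.1f%%)",
      sw_sum$n_shared, sw_sum$n_switched,
      sw_sum$pct_switched_of_shared)
  sw_enr <- switched_category_enrichment(switch_calls, disease)

  res <- list(
    config = cfg, config_hash = hash,
    catalog = catalog, truth = truth, counts = counts,
    treatment = treatment, disease = disease,
    composition_treatment = comp_t, composition_disease = comp_d,
    enrichment = enr, ks = ks,
    shared = shared, switch_calls = switch_calls,
    switch_summary = sw_sum, switch_enrichment = sw_enr
  )
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(res, cfg, hash)
  invisible(res)
}

.write_pipeline_outputs <- function(res, cfg, hash) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_event_catalog(res$catalog, p("catalog.tsv"), hash)
  write_sim_truth(res$truth, p("truth.tsv"), hash)
  write_event_counts(res$counts, p("counts.tsv"), hash)
  write_contrast(res$treatment, p("contrast_treatment.tsv"), hash)
  write_contrast(res$disease, p("contrast_disease.tsv"), hash)
  .write_stage_tsv(res$composition_treatment, p("composition_treatment.tsv"),
                   "composition", hash)
  .write_stage_tsv(res$composition_disease, p("composition_disease.tsv"),
                   "composition", hash)
  .write_stage_tsv(res$enrichment, p("enrichment.tsv"), "enrichment", hash)
  .write_stage_tsv(res$ks, p("ks_delta_psi.tsv"), "ks", hash)
  sw <- res$switch_calls
  .write_stage_tsv(sw, p("switch_calls.tsv"), "switch", hash)
  .write_stage_tsv(res$switch_summary, p("switch_summary.tsv"), "switch",
                   hash)
  .write_stage_tsv(res$switch_enrichment, p("switch_enrichment.tsv"),
                   "switch", hash)
  cfg_out <- cfg
  cfg_out$out_dir <- NULL  # run-local, not part of the analysis parameters
  write_config(cfg_out, p("config.yaml"))
  writeLines(pipeline_report(res), p("report.txt"))
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    tool = "spliceswitch",
    version = as.character(utils::packageVersion("spliceswitch")),
    seed = cfg$seed,
    config_hash = hash,
    config = unclass(cfg),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(cfg$out_dir, files))), files
    ))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(res)
}

#' Human-readable run report
#'
#' Aggregates the stage outputs of [run_splice_pipeline()] into a short
#' plain-text summary: the event funnel of each contrast, composition
#' highlights, enrichment results and the switch percentages.
#'
#' @param res Result list from [run_splice_pipeline()].
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(res) {
  gt <- glance(res$treatment)
  gd <- glance(res$disease)
  ss <- res$switch_summary
  enr_lines <- sprintf(
    "  %-8s k=%d/%d  p=%.3g", res$enrichment$set_name, res$enrichment$k,
    res$enrichment$K, res$enrichment$p_value
  )
  ks_lines <- sprintf(
    "  %-8s D=%.3f  p=%.3g", res$ks$set_name, res$ks$d_statistic,
    res$ks$p_value
  )
  ov <- attr(res$shared, "overlap_enrichment")
  c(
    "spliceswitch pipeline report",
    sprintf("config_hash: %s", res$config_hash),
    "",
    sprintf("[%s] %d events, %d tested, %d significant (%d included / %d excluded)",
            gt$contrast, gt$n_events, gt$n_tested, gt$n_significant,
            gt$n_included, gt$n_excluded),
    sprintf("[%s] %d events, %d tested, %d significant (%d included / %d excluded)",
            gd$contrast, gd$n_events, gd$n_tested, gd$n_significant,
            gd$n_included, gd$n_excluded),
    "",
    "substrate enrichment (hypergeometric, treatment contrast):",
    enr_lines,
    "delta-PSI K-S comparison (substrates vs non-substrates):",
    ks_lines,
    "",
    sprintf("shared events: %d of %d treatment-significant (%.1f%%), overlap p = %.3g",
            ss$n_shared, ss$n_treatment_significant,
            ss$pct_shared_of_treatment, ov$p_value),
    sprintf("switched toward non-tumor profile: %d of %d shared (%.1f%%)",
            ss$n_switched, ss$n_shared, ss$pct_switched_of_shared)
  )
}
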