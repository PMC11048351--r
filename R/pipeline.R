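# End-to-end orchestration: simulate (or load) -> classify -> enrich in both
# directions -> build features -> cross-validate, with a deterministic set of
# result files, a structured run log and a MANIFEST.

#' Pipeline configuration
#'
#' Either builds a configuration from arguments or reads one from a YAML
#' file. The configuration holds an input block (a `simulation` parameter
#' list, or `paths` to abundance TSVs / FASTA / motif files), the thresholds
#' of every stage, seeds and the model list.
#'
#' @param path Optional YAML file; entries override the defaults below.
#' @param simulation Named list of [simulation_config()] arguments, or
#'   `NULL` when `paths` is given.
#' @param paths Named list with `cell`, `sev` (abundance TSVs), `fasta`,
#'   `pwm_dir`, `metadata`; or `NULL` to simulate.
#' @param dabg_alpha DABG detection threshold.
#' @param q FDR level for localization calls.
#' @param e_threshold Motif E-value significance threshold.
#' @param holdout_frac Holdout fraction for enrichment.
#' @param k Cross-validation folds.
#' @param models Classifiers to evaluate, subset of `c("rf", "nb")`.
#' @param seed Master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, simulation = list(), paths = NULL,
                            dabg_alpha = 0.05, q = 0.05, e_threshold = 0.05,
                            holdout_frac = 0.10, k = 10,
                            models = c("rf", "nb"), seed = 1) {
  cfg <- list(simulation = simulation, paths = paths,
              dabg_alpha = dabg_alpha, q = q, e_threshold = e_threshold,
              holdout_frac = holdout_frac, k = k, models = models,
              seed = seed)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  }
  for (nm in c("dabg_alpha", "q", "e_threshold", "holdout_frac"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1)
      stop(nm, " must lie in (0, 1]")
  if (!is.null(cfg$paths)) {
    need <- c("cell", "sev", "fasta", "pwm_dir", "metadata")
    missing <- setdiff(need, names(cfg$paths))
    if (length(missing) > 0)
      stop("paths block is missing: ", paste(missing, collapse = ", "))
    gone <- !vapply(cfg$paths[need], file.exists, logical(1))
    if (any(gone))
      stop("input path does not exist: ",
           paste(unlist(cfg$paths[need][gone]), collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full localization pipeline
#'
#' Stages: load or simulate the inputs; classify miRNAs by compartment;
#' run motif enrichment in both directions (sEV-enriched vs cell-enriched
#' backgrounds and the reverse); build the thresholded motif-strength
#' feature matrix; cross-validate the classifiers. All result tables, a run
#' log (versions, seed, parameters, per-stage counts; no timestamps, so
#' reruns are byte-identical) and a MANIFEST with per-file MD5 checksums are
#' written under `out_dir`. A failing stage aborts with a stage-named error;
#' files written so far are retained and the MANIFEST records the incomplete
#' state.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`localization`, `enrich_sev`, `enrich_cell`, `features`, `cv`,
#'   `seq_stats`, plus `truth` when simulating).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("mirsort run log",
                 sprintf("mirsort version: %s",
                         as.character(utils::packageVersion("mirsort"))),
                 sprintf("R version: %s.%s", R.version$major, R.version$minor),
                 sprintf("seed: %d", config$seed),
                 sprintf("thresholds: dabg_alpha=%g q=%g e_threshold=%g holdout_frac=%g",
                         config$dabg_alpha, config$q, config$e_threshold,
                         config$holdout_frac),
                 sprintf("models: %s  k=%d", paste(config$models,
                                                   collapse = ","), config$k))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  written <- character(0)
  finish <- function(status, stage = NA_character_) {
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    man <- c(sprintf("status: %s", status),
             if (!is.na(stage)) sprintf("failed_stage: %s", stage),
             sprintf("%s  %s", tools::md5sum(file.path(out_dir, written)),
                     written))
    writeLines(man, file.path(out_dir, "MANIFEST"))
  }
  stage <- "load_inputs"
  res <- list()
  tryCatch({
    if (is.null(config$paths)) {
      sim_args <- config$simulation
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      sim <- do.call(simulation_config, sim_args)
      ds <- simulate_dataset(sim)
      res$truth <- ds$truth
      note("stage load_inputs: simulated %d miRNAs, %d motifs",
           length(ds$cell$mirna_ids), length(ds$motifs))
    } else {
      ds <- list(cell = read_abundance_table(config$paths$cell, "CELL"),
                 sev = read_abundance_table(config$paths$sev, "SEV"),
                 seqs = read_fasta(config$paths$fasta),
                 motifs = read_cisbp_motifs(config$paths$pwm_dir,
                                            config$paths$metadata))
      note("stage load_inputs: read %d miRNAs, %d motifs",
           length(ds$cell$mirna_ids), length(ds$motifs))
    }

    stage <- "classify"
    loc <- classify_localization(ds$cell, ds$sev, q = config$q,
                                 alpha = config$dabg_alpha)
    res$localization <- loc
    write_localization_table(loc, file.path(out_dir, "localization.tsv"))
    written <- c(written, "localization.tsv")
    counts <- table(factor(loc$call, LOCALIZATION_CALLS))
    note("stage classify: %s",
         paste(names(counts), counts, sep = "=", collapse = " "))

    stage <- "sequence_stats"
    seq_stats <- compare_class_sequence_stats(loc, ds$seqs)
    res$seq_stats <- seq_stats
    utils::write.table(seq_stats$class_stats,
                       file.path(out_dir, "sequence_class_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(seq_stats$tests,
                       file.path(out_dir, "sequence_class_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, "sequence_class_stats.tsv",
                 "sequence_class_tests.tsv")

    stage <- "enrich"
    pick <- function(cl) {
      ids <- loc$mirna_id[loc$call == cl]
      sequence_set(unclass(ds$seqs)[ids])
    }
    sev_seqs <- pick("SEV_ENRICHED")
    cell_seqs <- pick("CELL_ENRICHED")
    res$enrich_sev <- sea_enrich(sev_seqs, cell_seqs, ds$motifs,
                                 holdout_frac = config$holdout_frac,
                                 seed = config$seed,
                                 e_threshold = config$e_threshold)
    res$enrich_cell <- sea_enrich(cell_seqs, sev_seqs, ds$motifs,
                                  holdout_frac = config$holdout_frac,
                                  seed = config$seed + 1,
                                  e_threshold = config$e_threshold)
    write_enrichment_table(res$enrich_sev,
                           file.path(out_dir, "enrichment_sev_vs_cell.tsv"))
    write_enrichment_table(res$enrich_cell,
                           file.path(out_dir, "enrichment_cell_vs_sev.tsv"))
    written <- c(written, "enrichment_sev_vs_cell.tsv",
                 "enrichment_cell_vs_sev.tsv")
    note("stage enrich: pos=%d bg=%d significant sev=%d cell=%d",
         length(sev_seqs), length(cell_seqs),
         sum(res$enrich_sev$significant), sum(res$enrich_cell$significant))

    stage <- "features"
    scans <- scan_motifs(ds$seqs, ds$motifs,
                         background = base_frequencies(ds$seqs))
    features <- build_features(scans, list(res$enrich_sev, res$enrich_cell),
                               loc)
    res$features <- features
    feat_df <- data.frame(mirna_id = features$mirna_ids,
                          label = as.character(features$y), features$x,
                          check.names = FALSE)
    utils::write.table(feat_df, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, "features.tsv")
    note("stage features: %d miRNAs x %d motifs", nrow(features$x),
         ncol(features$x))

    stage <- "cross_validate"
    cv <- cross_validate(features, k = config$k, seed = config$seed,
                         models = config$models)
    res$cv <- cv
    write_cv_report(cv, file.path(out_dir, "cv_metrics.tsv"),
                    file.path(out_dir, "roc_points.tsv"))
    written <- c(written, "cv_metrics.tsv", "roc_points.tsv")
    for (m in names(cv$models))
      note("stage cross_validate: %s AUC=%.6f", m, cv$models[[m]]$auc)

    finish("complete")
    invisible(res)
  }, error = function(e) {
    finish("incomplete", stage)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
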