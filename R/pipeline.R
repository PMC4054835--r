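# Orchestration: a config-driven end-to-end run (simulate -> reproducibility
# metrics -> MI differential expression -> fluctuation analysis -> sequence
# QC -> sample structure) writing intermediate TSVs and a single JSON report.
# One master seed; every stage and sample derives its own stream, so toggling
# a stage never perturbs the others and reruns are bit-identical.

#' Pipeline configuration
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run, a subset of
#'   `c("repro", "mide", "fluct", "seqqc", "structure")` (simulation always
#'   runs; it feeds everything else).
#' @param n_genes,n_de Synthetic gene counts (see [synth_config()]).
#' @param n_cells_per_type Single cells per cell type.
#' @param n_pooled Pooled-equivalent samples (technical error only).
#' @param n_reads,read_length,adaptor_rate Read-simulation settings.
#' @param min_expr,fold_threshold Reproducibility rule parameters.
#' @param q_de DE significance threshold on Benjamini-Hochberg q.
#' @param q_fluct Reproducible-fluctuation threshold (adjusted p above it).
#' @param config Extra overrides merged into [synth_config()].
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("scbench_run_"),
                            stages = c("repro", "mide", "fluct", "seqqc",
                                       "structure"),
                            n_genes = 1000L, n_de = 100L,
                            n_cells_per_type = 12L, n_pooled = 8L,
                            n_reads = 2000L, read_length = 50L,
                            adaptor_rate = 0.05,
                            min_expr = 1, fold_threshold = 2,
                            q_de = 0.05, q_fluct = 0.6,
                            config = list()) {
  known <- c("repro", "mide", "fluct", "seqqc", "structure")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage: ", bad[1L])
  if (length(seed) != 1L || is.na(seed)) stop("exactly one master seed required")
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML or JSON
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, paste0("FAILED_", name)))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic experiment
#' generated from the config, writes intermediate files under
#' `config$out_dir`, and returns (and writes as `report.json`) a
#' machine-readable report. A rerun with the same config and seed reproduces
#' the report byte for byte. A failing stage aborts with a stage-named error
#' and leaves a `FAILED_<stage>` marker next to the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to standard error.
#' @return The report, a nested list of class `PipelineReport`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[scbench] ", ...)
  seed <- config$seed
  hashed <- config[setdiff(sort(names(config)), "out_dir")]  # location-free
  report <- list(provenance = list(
    config_hash = hash_label(paste(deparse(hashed), collapse = "")),
    seed = as.integer(seed),
    package_version = "0.1.0"))

  # --- simulation (always runs; feeds every stage) -------------------------
  say("simulate")
  truth <- run_stage("simulate", config$out_dir, {
    cfg <- utils::modifyList(
      synth_config(n_genes = config$n_genes, n_de = config$n_de,
                   adaptor_rate = config$adaptor_rate),
      config$config)
    make_truth(cfg, seed = derive_seed(seed, "stage_simulate"))
  })
  design <- rbind(
    design_grid(c("ES", "PrE"), "G1", "single_cell",
                config$n_cells_per_type, batch = "batch1"),
    design_grid("ES", "G1", "single_cell", config$n_cells_per_type,
                batch = "batch2"),
    design_grid("ES", "G1", "pooled_equivalent", config$n_pooled,
                batch = "pooled"),
    design_grid("ES", "G1", "bulk_reference", 2L, batch = "techrep"))
  sim <- simulate_experiment(truth, design,
                             seed = derive_seed(seed, "stage_simulate"))
  mat <- sim$matrix; ann <- sim$annotation
  write_matrix(mat, file.path(config$out_dir, "expression.tsv"))
  write_annotation(ann, file.path(config$out_dir, "annotation.tsv"))
  write_truth(truth, file.path(config$out_dir, "truth.tsv"))
  is_spike <- startsWith(gene_ids(mat), "spike_")
  endo <- mat$values[!is_spike, , drop = FALSE]
  gt <- truth$gene_table
  report$simulate <- list(n_genes = nrow(gt), n_de = sum(gt$de_flag),
                          n_samples = ncol(mat$values))

  sel <- function(class, batch = NULL, type = NULL) {
    keep <- ann$sample_class == class
    if (!is.null(batch)) keep <- keep & ann$batch == batch
    if (!is.null(type)) keep <- keep & ann$cell_type == type
    ann$sample_id[keep]
  }

  if ("repro" %in% config$stages) {
    say("repro")
    report$repro <- run_stage("repro", config$out_dir, {
      reps <- sel("bulk_reference", "techrep")
      rr <- count_reproducible(endo[, reps[1]], endo[, reps[2]],
                               min_expr = config$min_expr,
                               fold_threshold = config$fold_threshold)
      counts <- round(endo[, reps[1]] * 50)
      total <- sum(counts)
      depths <- unique(pmax(1, round(total * c(0.01, 0.1, 0.5, 1))))
      curve <- downsample_detection(
        counts, depths,
        gene_lengths = gt$transcript_length,
        min_fpkm = config$min_expr,
        seed = derive_seed(seed, "stage_repro"))
      utils::write.table(curve, file.path(config$out_dir, "downsample.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(pcc = rr$pcc, n_detected = rr$n_detected,
           n_reproducible = rr$n_reproducible,
           fraction_reproducible = rr$fraction_reproducible,
           downsample = curve)
    })
  }

  if ("mide" %in% config$stages) {
    say("mide")
    report$mide <- run_stage("mide", config$out_dir, {
      singles <- sel("single_cell", "batch1")
      sub <- expression_matrix(endo[, singles, drop = FALSE], unit = mat$unit)
      de <- de_scan(sub, ann, c("ES", "PrE"))
      utils::write.table(de, file.path(config$out_dir, "de_scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      strong <- abs(gt$log2_fold_change) >= 2 | !gt$de_flag
      auc <- auroc(de$mi_bits[strong], gt$de_flag[strong])
      list(n_tested = sum(de$tested),
           n_significant = sum(de$q_value < config$q_de, na.rm = TRUE),
           auroc_mi_strong_fc = auc)
    })
  }

  if ("fluct" %in% config$stages) {
    say("fluct")
    report$fluct <- run_stage("fluct", config$out_dir, {
      a <- endo[, sel("single_cell", "batch1", "ES"), drop = FALSE]
      b <- endo[, sel("single_cell", "batch2", "ES"), drop = FALSE]
      fr <- fluctuation_reproducibility(a, b, q_threshold = config$q_fluct)
      utils::write.table(fr$records, file.path(config$out_dir, "fluct.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pooled <- endo[, sel("pooled_equivalent"), drop = FALSE]
      fe <- fluctuation_vs_error(a, pooled)
      list(pcc_of_sds = fr$pcc_of_sds,
           n_reproducible = sum(fr$records$reproducible_flag),
           n_fluct_above_error = fe$n_significant)
    })
  }

  if ("seqqc" %in% config$stages) {
    say("seqqc")
    report$seqqc <- run_stage("seqqc", config$out_dir, {
      reads <- simulate_reads(config$n_reads, config$read_length,
                              adaptor_rate = truth$adaptor_rate,
                              seed = derive_seed(seed, "stage_seqqc"))
      write_fastq(reads, file.path(config$out_dir, "reads.fastq"))
      scan <- adaptor_scan(reads)
      meta <- mat$gene_meta[!is_spike, , drop = FALSE]
      prof <- gc_length_profile(
        meta, detection_flags(expression_matrix(endo, unit = mat$unit),
                              min_expr = config$min_expr))
      # groups can be empty (e.g. every gene detected): report NA, not NULL
      gc_of <- function(group) if (is.null(group)) NA_real_ else group$mean_gc
      list(adaptor_fraction = scan$fraction_hits,
           adaptor_rate_planted = truth$adaptor_rate,
           mean_gc_detected = gc_of(prof$detected),
           mean_gc_undetected = gc_of(prof$undetected))
    })
  }

  if ("structure" %in% config$stages) {
    say("structure")
    report$structure <- run_stage("structure", config$out_dir, {
      singles <- sel("single_cell", "batch1")
      sub <- expression_matrix(endo[, singles, drop = FALSE], unit = mat$unit)
      pca <- pca_embed(sub, n_components = 2L)
      utils::write.table(
        data.frame(sample_id = rownames(pca$scores), pca$scores),
        file.path(config$out_dir, "pca_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      wc <- ward_cluster(sub)
      writeLines(wc$newick, file.path(config$out_dir, "ward.nwk"))
      types <- ann$cell_type[match(singles, ann$sample_id)]
      pc1_auc <- auroc(pca$scores[, 1], types[match(rownames(pca$scores),
                                                    singles)] == "PrE")
      pc1_auc <- max(pc1_auc, 1 - pc1_auc)  # orientation-free separation
      memb <- wc$cut2[singles]
      agree <- mean((memb == memb[1]) == (types == types[1]))
      ora <- ora_hypergeom(top_loading_genes(pca, 1L, m = config$n_de),
                           list(planted_de = gt$id[gt$de_flag]),
                           universe = gt$id)
      list(pc1_type_auroc = pc1_auc,
           ward_2cut_accuracy = max(agree, 1 - agree),
           variance_explained = pca$variance_explained,
           ora_planted_de_p = ora$p_hyper[1])
    })
  }

  class(report) <- c("PipelineReport", "list")
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
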