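# End-to-end workflow: simulate (or load), collapse, normalize, test,
# compare across cell types, prepare visualization tables, and report
# parameter recovery against the simulation truth.

#' Recovery of the simulated DE truth by the pipeline's calls
#'
#' Compares the DEG calls of both cell types against the generator's
#' ground truth: a gene is truly differentially expressed in a cell type
#' when its true log2 fold change there is nonzero. Sensitivity is the
#' fraction of truly-DE genes called; the empirical FDR is the fraction
#' of called genes that are truly null in that cell type.
#'
#' @param degs_astro,degs_micro [call_degs()] tables.
#' @param truth [generate_truth()] table.
#' @return data.frame with rows `astrocyte`, `microglia`, `pooled` and
#'   columns `n_true`, `n_called`, `tp`, `fp`, `sensitivity`,
#'   `empirical_fdr`.
#' @export
recovery_report <- function(degs_astro, degs_micro, truth) {
  one <- function(degs, true_fc) {
    idx <- match(degs$gene_id, truth$gene_id)
    if (anyNA(idx)) stop("DE table contains genes absent from the truth table")
    is_true <- true_fc[idx] != 0
    called <- degs$is_deg
    c(n_true = sum(is_true), n_called = sum(called),
      tp = sum(called & is_true), fp = sum(called & !is_true))
  }
  a <- one(degs_astro, truth$true_log2fc_astro)
  m <- one(degs_micro, truth$true_log2fc_micro)
  p <- a + m
  stats <- rbind(astrocyte = a, microglia = m, pooled = p)
  out <- as.data.frame(stats)
  out$sensitivity <- ifelse(out$n_true > 0, out$tp / out$n_true, NA_real_)
  out$empirical_fdr <- ifelse(out$n_called > 0, out$fp / out$n_called, 0)
  out
}

# Flat key: value dump of the run configuration; deterministic text.
.write_manifest <- function(path, config, collapse, norm, criteria,
                            fourway_p_cutoff, fourway_log2fc_threshold, io) {
  kv <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("glialarray"))),
    sprintf("io: %s", io),
    sprintf("seed: %d", config$seed),
    sprintf("n_genes: %d", config$n_genes),
    sprintf("n_onchip_replicates: %d", config$n_onchip_replicates),
    sprintf("n_bio_replicates: %d", config$n_bio_replicates),
    sprintf("baseline_mean: %g", config$baseline_mean),
    sprintf("baseline_sd: %g", config$baseline_sd),
    sprintf("class_proportions: %s",
            paste(sprintf("%s=%g", names(config$class_proportions),
                          config$class_proportions), collapse = ",")),
    sprintf("effect_size_range: %g,%g", config$effect_size_range[1],
            config$effect_size_range[2]),
    sprintf("gene_sd_shape: df=%g,scale=%g", config$gene_sd_shape[["df"]],
            config$gene_sd_shape[["scale"]]),
    sprintf("array_scale_sd: %g", config$array_scale_sd),
    sprintf("spot_sd: %g", config$spot_sd),
    sprintf("frac_manual_flag: %g", config$frac_manual_flag),
    sprintf("frac_fe_outlier: %g", config$frac_fe_outlier),
    sprintf("frac_high_pixel_cv: %g", config$frac_high_pixel_cv),
    sprintf("n_negative_controls: %d", config$n_negative_controls),
    sprintf("collapse_iqr_multiplier: %g", collapse$iqr_multiplier),
    sprintf("collapse_pixel_cv_max: %g", collapse$pixel_cv_max),
    sprintf("collapse_min_surviving: %d", collapse$min_surviving_replicates),
    sprintf("collapse_iqr_strategy: %s", collapse$iqr_strategy),
    sprintf("norm_reference_percentile: %g", norm$reference_percentile),
    sprintf("norm_reference_value: %g", norm$reference_value),
    sprintf("norm_surrogate_floor: %g", norm$surrogate_floor),
    sprintf("deg_fc_threshold: %g", criteria$fc_threshold),
    sprintf("deg_alpha: %g", criteria$alpha),
    sprintf("deg_strict_fc: %s", criteria$strict_fc),
    sprintf("fourway_p_cutoff: %g", fourway_p_cutoff),
    sprintf("fourway_log2fc_threshold: %g", fourway_log2fc_threshold)
  )
  writeLines(kv, path)
  invisible(path)
}

#' Run the full simulated-experiment pipeline
#'
#' Generates a synthetic experiment with known truth and runs every
#' analysis stage: feature emission and collapsing (or the direct matrix
#' route), normalization (quantile, global linear scaling, surrogate
#' floor, log2), per-cell-type moderated-t DE calling, the four-way
#' cross-cell-type comparison, volcano tables, and recovery of the
#' simulated truth. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param out_dir If non-`NULL`, result tables and a run manifest are
#'   written there as TSV/text.
#' @param io `"files"` (default) emits Feature-Extraction files into a
#'   directory and re-reads them through the parsing and collapsing
#'   stages; `"matrix"` skips the file round trip and uses the directly
#'   simulated collapsed matrix (no spot noise or contamination).
#' @param collapse A [collapse_params()] object.
#' @param norm A [norm_params()] object.
#' @param criteria A [deg_criteria()] object.
#' @param fourway_p_cutoff Corrected-p cutoff for the FC = 1 adjustment.
#' @param fourway_log2fc_threshold Direction threshold of the 3x3 grid.
#' @param heatmap_genes Optional gene panel for the heat-map table.
#' @return List of class `pipeline_result`: `config`, `truth`,
#'   `raw_matrix`, `normalized` ([normalize_pipeline()] output),
#'   `de_astro`, `de_micro`, `fourway` ([fourway_analysis()] output),
#'   `volcano_astro`, `volcano_micro`, `heatmap` (or `NULL`), `recovery`,
#'   `paths` (written files, when `out_dir` is given).
#' @export
run_full_pipeline <- function(config = sim_config(),
                              out_dir = NULL,
                              io = c("files", "matrix"),
                              collapse = collapse_params(),
                              norm = norm_params(),
                              criteria = deg_criteria(),
                              fourway_p_cutoff = 0.05,
                              fourway_log2fc_threshold = 1,
                              heatmap_genes = NULL) {
  io <- match.arg(io)
  stopifnot(inherits(config, "sim_config"))

  truth <- generate_truth(config)
  if (io == "files") {
    data_dir <- if (is.null(out_dir)) {
      d <- tempfile("glialarray_sim_")
      dir.create(d)
      d
    } else file.path(out_dir, "arrays")
    emit_feature_extraction_files(truth, config, data_dir)
    raw <- build_intensity_matrix(data_dir, collapse)
  } else {
    raw <- simulate_collapsed_matrix(truth, config)
  }

  normalized <- normalize_pipeline(raw, norm)
  log2m <- normalized$log2_matrix

  de_astro <- de_analysis(log2m, "astrocyte", criteria)
  de_micro <- de_analysis(log2m, "microglia", criteria)

  fourway <- fourway_analysis(de_astro, de_micro,
                              p_cutoff = fourway_p_cutoff,
                              log2fc_threshold = fourway_log2fc_threshold)

  volcano_astro <- volcano_table(de_astro)
  volcano_micro <- volcano_table(de_micro)

  heatmap <- if (!is.null(heatmap_genes))
    heatmap_table(attr(de_astro, "rep_log2fc"),
                  attr(de_micro, "rep_log2fc"),
                  heatmap_params(heatmap_genes))
  else NULL

  recovery <- recovery_report(de_astro, de_micro, truth)

  paths <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtab <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      p
    }
    paths <- c(
      normalized_matrix = write_intensity_matrix(
        log2m, file.path(out_dir, "normalized_log2.tsv")),
      report = wtab(normalized$report, "normalization_report.tsv"),
      de_astro = wtab(de_astro, "de_astrocyte.tsv"),
      de_micro = wtab(de_micro, "de_microglia.tsv"),
      fourway_scatter = wtab(fourway$summary$scatter, "fourway_scatter.tsv"),
      fourway_counts = wtab(
        data.frame(class = names(fourway$summary$aggregates),
                   count = as.integer(fourway$summary$aggregates),
                   percent = fourway$summary$percentages),
        "fourway_counts.tsv"),
      volcano_astro = wtab(volcano_astro, "volcano_astrocyte.tsv"),
      volcano_micro = wtab(volcano_micro, "volcano_microglia.tsv"),
      recovery = wtab(cbind(group = rownames(recovery), recovery),
                      "recovery_report.tsv"),
      manifest = .write_manifest(
        file.path(out_dir, "manifest.txt"), config, collapse, norm,
        criteria, fourway_p_cutoff, fourway_log2fc_threshold, io)
    )
    if (!is.null(heatmap))
      paths <- c(paths, heatmap = wtab(heatmap, "heatmap_table.tsv"))
  }

  structure(list(config = config,
                 truth = truth,
                 raw_matrix = raw,
                 normalized = normalized,
                 de_astro = de_astro,
                 de_micro = de_micro,
                 fourway = fourway,
                 volcano_astro = volcano_astro,
                 volcano_micro = volcano_micro,
                 heatmap = heatmap,
                 recovery = recovery,
                 paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("glialarray pipeline result\n")
  cat(sprintf("  %d genes, seed %d\n", x$config$n_genes, x$config$seed))
  cat(sprintf("  DEGs: %d astrocyte, %d microglia; union %d\n",
              sum(x$de_astro$is_deg), sum(x$de_micro$is_deg),
              x$fourway$summary$n_union))
  cat(sprintf("  recovery (pooled): sensitivity %.3f, empirical FDR %.3f\n",
              x$recovery["pooled", "sensitivity"],
              x$recovery["pooled", "empirical_fdr"]))
  invisible(x)
}
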