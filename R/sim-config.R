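#' Gene classes recognised by the simulator
#'
#' The generator assigns every gene to one of eight classes describing its
#' true response to treatment in the two cell types: unaffected (`null`),
#' regulated in the same direction in both cell types (`common_up`,
#' `common_down`), regulated in exactly one cell type (`astro_up`,
#' `micro_up`, `astro_down`, `micro_down`), or regulated in opposite
#' directions (`discordant`).
#'
#' @export
GENE_CLASSES <- c("null", "common_up", "common_down",
                  "astro_up", "micro_up", "astro_down", "micro_down",
                  "discordant")

#' Simulation configuration
#'
#' Builds the configuration object consumed by [generate_truth()],
#' [simulate_true_intensities()] and [emit_feature_extraction_files()].
#' The defaults encode the study design the pipeline targets: two cell
#' types (astrocyte, microglia) x two treatments (medium, Th1) x four
#' biological replicates, every probe printed four times per array, 10%
#' of genes truly differentially expressed with |log2 fold change| drawn
#' from \[1.5, 3\], and per-gene noise SDs around 0.3 on the log2 scale.
#'
#' @param n_genes Number of non-control genes (one probe per gene).
#' @param n_onchip_replicates Times each probe is printed on one array.
#' @param n_bio_replicates Biological replicates per cell type x treatment.
#' @param baseline_mean,baseline_sd Mean and SD (log2 intensity units) of
#'   per-gene baseline expression.
#' @param class_proportions Named fractions over [GENE_CLASSES]; must be
#'   non-negative and sum to 1 (classes omitted from the vector get 0).
#' @param effect_size_range Lower/upper bound of |true log2 fold change|
#'   for non-null genes; lower bound must be >= 0.
#' @param gene_sd_shape Named vector `c(df = , scale = )` of the scaled
#'   inverse-chi-square distribution from which per-gene noise variances
#'   (log2 scale) are drawn; the resulting spread of variances is what the
#'   empirical-Bayes moderation step estimates.
#' @param array_scale_sd SD (log2 scale) of the per-array multiplicative
#'   scale distortion that normalization must remove.
#' @param spot_sd SD (log2 scale) of independent multiplicative spot noise
#'   added to each on-chip replicate feature.
#' @param frac_manual_flag,frac_fe_outlier,frac_high_pixel_cv Fractions of
#'   non-control features carrying a manual flag, a feature-extraction
#'   outlier flag (these also get a 10x intensity spike so the flag is
#'   consequential), and a pixel-intensity CV above 0.5.
#' @param n_negative_controls Number of negative-control probes per array;
#'   their intensities sit below the surrogate floor after typical scaling.
#' @param seed Integer seed; all downstream simulation draws derive from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 42)
#' cfg$n_bio_replicates
#' @export
sim_config <- function(n_genes = 5000L,
                       n_onchip_replicates = 4L,
                       n_bio_replicates = 4L,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       class_proportions = c(null = 0.90,
                                             common_up = 0.02,
                                             common_down = 0.01,
                                             astro_up = 0.015,
                                             micro_up = 0.015,
                                             astro_down = 0.01,
                                             micro_down = 0.01,
                                             discordant = 0.02),
                       effect_size_range = c(1.5, 3),
                       gene_sd_shape = c(df = 8, scale = 0.09),
                       array_scale_sd = 0.2,
                       spot_sd = 0.15,
                       frac_manual_flag = 0.01,
                       frac_fe_outlier = 0.01,
                       frac_high_pixel_cv = 0.02,
                       n_negative_controls = 100L,
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("configuration error: 'n_genes' must be a positive count")
  if (n_onchip_replicates < 1 || n_bio_replicates < 1)
    stop("configuration error: replicate counts must be positive")
  if (baseline_sd < 0)
    stop("configuration error: 'baseline_sd' must be >= 0")

  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% GENE_CLASSES))
    stop("configuration error: class_proportions names must be among: ",
         paste(GENE_CLASSES, collapse = ", "))
  props <- stats::setNames(numeric(length(GENE_CLASSES)), GENE_CLASSES)
  props[names(class_proportions)] <- class_proportions
  if (any(props < 0))
    stop("configuration error: class proportions must be >= 0")
  if (abs(sum(props) - 1) > 1e-9)
    stop("configuration error: class proportions must sum to 1 (got ",
         format(sum(props)), ")")

  if (length(effect_size_range) != 2L || effect_size_range[1] < 0 ||
      effect_size_range[2] < effect_size_range[1])
    stop("configuration error: effect_size_range must be 0 <= lower <= upper")
  if (!all(c("df", "scale") %in% names(gene_sd_shape)) ||
      gene_sd_shape[["df"]] <= 0 || gene_sd_shape[["scale"]] <= 0)
    stop("configuration error: gene_sd_shape needs positive 'df' and 'scale'")
  fracs <- c(frac_manual_flag, frac_fe_outlier, frac_high_pixel_cv)
  if (any(fracs < 0 | fracs > 1))
    stop("configuration error: contamination fractions must lie in [0, 1]")
  if (array_scale_sd < 0 || spot_sd < 0)
    stop("configuration error: noise SDs must be >= 0")
  if (n_negative_controls < 0)
    stop("configuration error: 'n_negative_controls' must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("configuration error: 'seed' must be an integer")

  structure(list(
    n_genes = as.integer(n_genes),
    n_onchip_replicates = as.integer(n_onchip_replicates),
    n_bio_replicates = as.integer(n_bio_replicates),
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    class_proportions = props,
    effect_size_range = as.numeric(effect_size_range),
    gene_sd_shape = gene_sd_shape,
    array_scale_sd = array_scale_sd,
    spot_sd = spot_sd,
    frac_manual_flag = frac_manual_flag,
    frac_fe_outlier = frac_fe_outlier,
    frac_high_pixel_cv = frac_high_pixel_cv,
    n_negative_controls = as.integer(n_negative_controls),
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d genes x %d on-chip replicates, %d bio replicates per group\n",
              x$n_genes, x$n_onchip_replicates, x$n_bio_replicates))
  nz <- x$class_proportions[x$class_proportions > 0]
  cat("  classes:", paste(sprintf("%s=%.3g", names(nz), nz), collapse = ", "), "\n")
  cat(sprintf("  |log2FC| in [%.3g, %.3g]; seed %d\n",
              x$effect_size_range[1], x$effect_size_range[2], x$seed))
  invisible(x)
}
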