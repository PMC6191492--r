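# Synthetic one-color microarray experiment with known DE truth.
# All randomness derives from config$seed; distinct sub-steps use fixed
# small offsets so each stage is individually reproducible.

.seed_truth <- 0L
.seed_arrays <- 1L
.seed_samples <- 2L
.seed_spots <- 3L

#' Generate the ground-truth gene table
#'
#' Assigns every gene a class, true per-cell-type log2 fold changes and a
#' per-gene noise SD. Class counts follow `class_proportions` exactly after
#' largest-remainder rounding, so bookkeeping tests can assert them.
#' Non-null effect magnitudes are drawn uniformly from
#' `effect_size_range`, independently per cell type where the class
#' involves both; discordant genes get opposite signs with random
#' orientation. Gene noise variances are scaled inverse-chi-square:
#' `sd^2 = df * scale / rchisq(df)`.
#'
#' @param config A [sim_config()] object.
#' @return A data.frame with columns `gene_id`, `gene_class`,
#'   `true_log2fc_astro`, `true_log2fc_micro`, `gene_sd`.
#' @examples
#' truth <- generate_truth(sim_config(n_genes = 50, seed = 7))
#' table(truth$gene_class)
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  counts <- .round_proportions(config$class_proportions, n)

  set.seed(config$seed + .seed_truth)
  cls <- rep(names(counts), counts)
  gene_id <- sprintf("G%05d", seq_len(n))

  lo <- config$effect_size_range[1]
  hi <- config$effect_size_range[2]
  mag <- function(k) stats::runif(k, lo, hi)

  fc_a <- numeric(n)
  fc_m <- numeric(n)
  for (cl in names(counts)) {
    idx <- which(cls == cl)
    k <- length(idx)
    if (k == 0L || cl == "null") next
    switch(cl,
      common_up   = { fc_a[idx] <-  mag(k); fc_m[idx] <-  mag(k) },
      common_down = { fc_a[idx] <- -mag(k); fc_m[idx] <- -mag(k) },
      astro_up    = { fc_a[idx] <-  mag(k) },
      astro_down  = { fc_a[idx] <- -mag(k) },
      micro_up    = { fc_m[idx] <-  mag(k) },
      micro_down  = { fc_m[idx] <- -mag(k) },
      discordant  = {
        s <- sample(c(-1, 1), k, replace = TRUE)
        fc_a[idx] <-  s * mag(k)
        fc_m[idx] <- -s * mag(k)
      })
  }

  df <- config$gene_sd_shape[["df"]]
  sc <- config$gene_sd_shape[["scale"]]
  gene_sd <- sqrt(df * sc / stats::rchisq(n, df))

  data.frame(gene_id = gene_id,
             gene_class = cls,
             true_log2fc_astro = fc_a,
             true_log2fc_micro = fc_m,
             gene_sd = gene_sd,
             stringsAsFactors = FALSE)
}

# Largest-remainder apportionment: counts sum to n exactly, deterministic.
.round_proportions <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Sample metadata for the simulated study design
#'
#' @param config A [sim_config()] object.
#' @return data.frame with `sample_id`, `cell_type`, `treatment`,
#'   `replicate`, one row per array, in canonical order (cell type, then
#'   treatment, then replicate).
#' @export
sim_sample_metadata <- function(config) {
  g <- expand.grid(replicate = seq_len(config$n_bio_replicates),
                   treatment = c("medium", "Th1"),
                   cell_type = c("astrocyte", "microglia"),
                   stringsAsFactors = FALSE)
  g <- g[, c("cell_type", "treatment", "replicate")]
  g$sample_id <- sprintf("%s_%s_r%d", g$cell_type, g$treatment, g$replicate)
  g[, c("sample_id", "cell_type", "treatment", "replicate")]
}

#' Noise-free expected intensities per array
#'
#' Computes, for every gene and array, the expected log2 intensity
#' `baseline_g + true_log2fc * 1[treatment = Th1] + array_log2_scale`,
#' where the array term is the per-array multiplicative distortion the
#' normalization stage must undo. Linear intensities are `2^x` and hence
#' strictly positive.
#'
#' @param truth Output of [generate_truth()].
#' @param config The same [sim_config()] object.
#' @return List of class `true_intensities`: `expected_log2` (gene x
#'   array matrix), `samples` (metadata), `baseline`, `array_log2_scale`,
#'   `config`.
#' @export
simulate_true_intensities <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) != config$n_genes)
    stop("truth table does not cover all configured genes")
  samples <- sim_sample_metadata(config)

  set.seed(config$seed + .seed_arrays)
  baseline <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  array_scale <- stats::rnorm(nrow(samples), 0, config$array_scale_sd)

  fc <- cbind(astrocyte = truth$true_log2fc_astro,
              microglia = truth$true_log2fc_micro)
  e <- matrix(baseline, nrow = config$n_genes, ncol = nrow(samples))
  th1 <- samples$treatment == "Th1"
  e[, th1] <- e[, th1] + fc[, samples$cell_type[th1]]
  e <- sweep(e, 2, array_scale, "+")
  dimnames(e) <- list(truth$gene_id, samples$sample_id)

  structure(list(expected_log2 = e,
                 samples = samples,
                 baseline = baseline,
                 array_log2_scale = array_scale,
                 config = config),
            class = "true_intensities")
}

# Realized per-array (biological-replicate level) log2 intensities:
# expected + N(0, gene_sd) per entry. Shared by the file emitter and the
# direct matrix route so both see the same biological draw.
.realize_sample_log2 <- function(ti) {
  cfg <- ti$config
  set.seed(cfg$seed + .seed_samples)
  e <- ti$expected_log2
  noise <- matrix(stats::rnorm(length(e)), nrow(e), ncol(e)) * ti$gene_sd_vec
  e + noise
}

#' Simulate the collapsed probe-by-array intensity matrix directly
#'
#' Bypasses file emission and on-chip replicate collapsing: returns the
#' linear-scale intensity matrix a perfect collapse would recover
#' (expected intensity plus per-array gene-level noise, no spot noise, no
#' contamination). Useful for fast parameter-recovery studies of the
#' normalization and testing stages.
#'
#' @param truth Output of [generate_truth()].
#' @param config The matching [sim_config()].
#' @return An [intensity_matrix()] of linear intensities.
#' @export
simulate_collapsed_matrix <- function(truth, config) {
  ti <- simulate_true_intensities(truth, config)
  ti$gene_sd_vec <- truth$gene_sd
  values <- 2^.realize_sample_log2(ti)
  intensity_matrix(values, ti$samples)
}

#' Write Feature-Extraction-style files for a simulated experiment
#'
#' Emits one tab-delimited file per array in the dialect read by
#' [read_feature_extraction()]: each gene probe appears
#' `n_onchip_replicates` times with independent multiplicative spot noise;
#' a configured fraction of features carries a manual flag, a software
#' outlier flag (with a 10x intensity spike, so the flag marks a truly
#' corrupted value), or a pixel CV above 0.5; negative-control probes are
#' included with intensities low enough to fall under the surrogate floor
#' after typical scaling. Also writes `metadata.tsv` (file to sample
#' mapping) and `truth.tsv`.
#'
#' @param truth Output of [generate_truth()].
#' @param config The matching [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a manifest list: `out_dir`, `metadata`, and `files`,
#'   a per-file data.frame of row and contamination counts (the emission
#'   log round-trip tests check against).
#' @export
emit_feature_extraction_files <- function(truth, config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create output directory '", out_dir, "'")
  }
  if (file.access(out_dir, 2) != 0)
    stop("I/O error: output directory '", out_dir, "' is not writable")

  ti <- simulate_true_intensities(truth, config)
  ti$gene_sd_vec <- truth$gene_sd
  sample_log2 <- .realize_sample_log2(ti)
  samples <- ti$samples

  n_g <- config$n_genes
  n_rep <- config$n_onchip_replicates
  n_ctrl <- config$n_negative_controls
  n_spots <- n_g * n_rep

  set.seed(config$seed + .seed_spots)
  log_rows <- vector("list", nrow(samples))
  files <- character(nrow(samples))

  for (j in seq_len(nrow(samples))) {
    spot_log2 <- rep(sample_log2[, j], each = n_rep) +
      stats::rnorm(n_spots, 0, config$spot_sd)
    gps <- 2^spot_log2

    manual <- stats::runif(n_spots) < config$frac_manual_flag
    outlier <- stats::runif(n_spots) < config$frac_fe_outlier
    gps[outlier] <- gps[outlier] * 10
    high_cv <- stats::runif(n_spots) < config$frac_high_pixel_cv
    pixel_cv <- ifelse(high_cv,
                       stats::runif(n_spots, 0.55, 1.0),
                       stats::runif(n_spots, 0.02, 0.30))

    spot <- data.frame(
      ProbeName = rep(truth$gene_id, each = n_rep),
      GeneName = rep(truth$gene_id, each = n_rep),
      EntrezID = rep(seq_len(n_g), each = n_rep),
      gProcessedSignal = gps,
      ControlType = 0L,
      IsManualFlag = as.integer(manual),
      gIsFeatNonUnifOL = as.integer(outlier),
      PixelCV = round(pixel_cv, 4),
      stringsAsFactors = FALSE
    )
    if (n_ctrl > 0) {
      # negative controls: low log-normal intensities (~2^1.5 linear units)
      ctrl <- data.frame(
        ProbeName = sprintf("NegCtrl%04d", seq_len(n_ctrl)),
        GeneName = "NegativeControl",
        EntrezID = NA_integer_,
        gProcessedSignal = 2^stats::rnorm(n_ctrl, 1.5, 0.5),
        ControlType = 1L,
        IsManualFlag = 0L,
        gIsFeatNonUnifOL = 0L,
        PixelCV = round(stats::runif(n_ctrl, 0.02, 0.30), 4),
        stringsAsFactors = FALSE
      )
      spot <- rbind(spot, ctrl)
    }
    spot <- spot[sample.int(nrow(spot)), , drop = FALSE]

    fn <- paste0(samples$sample_id[j], ".txt")
    utils::write.table(spot, file.path(out_dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    files[j] <- fn
    log_rows[[j]] <- data.frame(
      file_name = fn, sample_id = samples$sample_id[j],
      n_rows = nrow(spot), n_control = n_ctrl,
      n_manual_flag = sum(manual), n_fe_outlier = sum(outlier),
      n_high_pixel_cv = sum(high_cv), stringsAsFactors = FALSE
    )
  }

  metadata <- cbind(file_name = files, samples, stringsAsFactors = FALSE)
  utils::write.table(metadata, file.path(out_dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(out_dir = out_dir,
                 metadata = metadata,
                 files = do.call(rbind, log_rows)))
}
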