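# Numeric tables behind the volcano plots and heat maps.

#' Volcano-plot classification table
#'
#' Classifies every transcript in the universe by significance and fold
#' change: `green` when both `p < p_cutoff` and the fold-change criterion
#' hold, `red` when only the p criterion holds, `orange` when only the
#' fold-change criterion holds, `grey` otherwise. The fold-change
#' criterion defaults to `|log2FC| > 2` (strict, as used for plot
#' coloring); set `fc_class_threshold = 1, fc_strict = FALSE` for a
#' classification matching the DEG gate (`|FC| >= 2`). Zero p-values are
#' mapped to a display ceiling on the -log10 axis.
#'
#' @param de_results [call_degs()] or [moderated_t_test()] output covering
#'   the full transcript universe.
#' @param p_cutoff Significance threshold (default 0.01, on the corrected
#'   p-value by default).
#' @param fc_class_threshold Classification threshold in log2 units
#'   (default 2).
#' @param fc_strict Use strict `>` for the fold-change criterion
#'   (default `TRUE`, matching the plot legend wording).
#' @param p_column Which p-value feeds the y-axis and the classification:
#'   `"p_adj"` (default) or `"p_raw"`.
#' @param p_ceiling Display value of `-log10(p)` for `p = 0`
#'   (default 320, just above the smallest representable double).
#' @return data.frame: `gene_id`, `log2fc`, `neg_log10_p`, `color_class`.
#' @export
volcano_table <- function(de_results, p_cutoff = 0.01,
                          fc_class_threshold = 2, fc_strict = TRUE,
                          p_column = c("p_adj", "p_raw"),
                          p_ceiling = 320) {
  p_column <- match.arg(p_column)
  if (is.null(de_results[[p_column]]))
    stop("de_results lacks column '", p_column, "'")
  p <- de_results[[p_column]]
  lfc <- de_results$log2fc
  neg <- -log10(p)
  neg[p == 0] <- p_ceiling
  sig_p <- p < p_cutoff
  sig_fc <- if (fc_strict) abs(lfc) > fc_class_threshold
            else abs(lfc) >= fc_class_threshold
  cls <- ifelse(sig_p & sig_fc, "green",
                ifelse(sig_p, "red",
                       ifelse(sig_fc, "orange", "grey")))
  data.frame(gene_id = de_results$gene_id,
             log2fc = lfc,
             neg_log10_p = neg,
             color_class = cls,
             stringsAsFactors = FALSE)
}

#' Heat-map parameters
#'
#' @param gene_list Gene identifiers of the panel to display, in display
#'   order (e.g. a cytokine/growth-factor panel).
#' @param cap Upper cap for mean log2 fold changes (default 6): values
#'   above it are replaced by the cap for better color scaling.
#' @param mode `"literal"` (default) caps only values above `cap`,
#'   exactly as stated; `"symmetric"` also caps values below `-cap`.
#' @param center Color-scale center (log2FC units, default 0).
#' @return Object of class `heatmap_params`.
#' @export
heatmap_params <- function(gene_list, cap = 6,
                           mode = c("literal", "symmetric"), center = 0) {
  if (cap <= 0) stop("'cap' must be > 0")
  if (length(gene_list) == 0L) stop("empty gene list")
  structure(list(gene_list = as.character(gene_list), cap = cap,
                 mode = match.arg(mode), center = center),
            class = "heatmap_params")
}

#' Heat-map table of capped mean fold changes
#'
#' For every gene of the panel and each cell type, averages the
#' replicate-paired log2 fold-change columns (the four per-replicate
#' columns produced by [compute_fold_changes()]) and applies the cap.
#' Genes of the panel absent from the universe trigger a warning and get
#' a missing row.
#'
#' @param rep_fc_astro,rep_fc_micro Gene x replicate log2 fold-change
#'   matrices with gene rownames (e.g. `attr(de, "rep_log2fc")`).
#' @param params A [heatmap_params()] object.
#' @return data.frame `gene_id`, `mean_log2fc_astro`, `mean_log2fc_micro`
#'   (capped), ordered as `params$gene_list`.
#' @export
heatmap_table <- function(rep_fc_astro, rep_fc_micro, params) {
  stopifnot(inherits(params, "heatmap_params"))
  cap_fun <- function(v) {
    v[!is.na(v) & v > params$cap] <- params$cap
    if (params$mode == "symmetric")
      v[!is.na(v) & v < -params$cap] <- -params$cap
    v
  }
  mean_for <- function(m) {
    idx <- match(params$gene_list, rownames(m))
    out <- rep(NA_real_, length(idx))
    out[!is.na(idx)] <- rowMeans(m[idx[!is.na(idx)], , drop = FALSE])
    out
  }
  ma <- mean_for(rep_fc_astro)
  mm <- mean_for(rep_fc_micro)
  absent <- params$gene_list[!(params$gene_list %in% rownames(rep_fc_astro)) &
                             !(params$gene_list %in% rownames(rep_fc_micro))]
  if (length(absent))
    warning("gene(s) absent from the universe: ",
            paste(absent, collapse = ", "))
  data.frame(gene_id = params$gene_list,
             mean_log2fc_astro = cap_fun(ma),
             mean_log2fc_micro = cap_fun(mm),
             stringsAsFactors = FALSE)
}
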