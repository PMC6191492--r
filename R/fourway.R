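# Cross-cell-type comparison of DEG sets: union building, the FC = 1
# adjustment for non-significant genes, the 3x3 directional partition,
# and a generic regulator-activation z-score.

.directions <- c("up", "unchanged", "down")

#' Union of the two cell types' DEG sets
#'
#' Collects every gene called differentially expressed in at least one
#' cell type and attaches both cell types' fold changes and adjusted
#' p-values.
#'
#' @param degs_astro,degs_micro [call_degs()] tables over the same gene
#'   universe for astrocytes and microglia.
#' @return data.frame: `gene_id`, `log2fc_astro`, `p_adj_astro`,
#'   `deg_astro`, `log2fc_micro`, `p_adj_micro`, `deg_micro`.
#' @export
build_union_set <- function(degs_astro, degs_micro) {
  if (!length(intersect(degs_astro$gene_id, degs_micro$gene_id)))
    stop("disjoint gene universes: the two DE tables share no genes")
  ids <- union(degs_astro$gene_id[degs_astro$is_deg],
               degs_micro$gene_id[degs_micro$is_deg])
  ia <- match(ids, degs_astro$gene_id)
  im <- match(ids, degs_micro$gene_id)
  data.frame(gene_id = ids,
             log2fc_astro = degs_astro$log2fc[ia],
             p_adj_astro = degs_astro$p_adj[ia],
             deg_astro = !is.na(ia) & degs_astro$is_deg[ia],
             log2fc_micro = degs_micro$log2fc[im],
             p_adj_micro = degs_micro$p_adj[im],
             deg_micro = !is.na(im) & degs_micro$is_deg[im],
             stringsAsFactors = FALSE)
}

#' Set non-significant fold changes to FC = 1
#'
#' For each cell type, genes whose corrected p-value exceeds `p_cutoff`
#' (or whose statistics are missing) get their fold change adjusted to
#' FC = 1, i.e. log2 fold change 0; significant fold changes pass through
#' unchanged. The operation is idempotent.
#'
#' @param union_set Output of [build_union_set()].
#' @param p_cutoff Corrected-p cutoff for keeping a fold change
#'   (default 0.05; deliberately distinct from the DEG-calling alpha).
#' @return The input with columns `adj_log2fc_astro`, `adj_log2fc_micro`
#'   and `both_adjusted` (flagging the degenerate case where both cell
#'   types were zeroed).
#' @export
adjust_nonsignificant_fc <- function(union_set, p_cutoff = 0.05) {
  zero_a <- is.na(union_set$p_adj_astro) | union_set$p_adj_astro > p_cutoff
  zero_m <- is.na(union_set$p_adj_micro) | union_set$p_adj_micro > p_cutoff
  out <- union_set
  out$adj_log2fc_astro <- ifelse(zero_a, 0, union_set$log2fc_astro)
  out$adj_log2fc_micro <- ifelse(zero_m, 0, union_set$log2fc_micro)
  out$both_adjusted <- zero_a & zero_m
  out
}

#' Classify genes on the 3x3 four-way grid
#'
#' Per cell type, a gene is `up` if its adjusted log2 fold change is at
#' least `log2fc_threshold`, `down` if at most `-log2fc_threshold`, else
#' `unchanged`; the `cell9_label` is the pair of directions.
#'
#' @param records Output of [adjust_nonsignificant_fc()].
#' @param log2fc_threshold Direction threshold in log2 units (default 1,
#'   i.e. 2-fold).
#' @return The input with `direction_astro`, `direction_micro`,
#'   `cell9_label` (e.g. `"up|down"`).
#' @export
classify_fourway <- function(records, log2fc_threshold = 1) {
  dir_of <- function(x) ifelse(x >= log2fc_threshold, "up",
                               ifelse(x <= -log2fc_threshold, "down",
                                      "unchanged"))
  out <- records
  out$direction_astro <- dir_of(records$adj_log2fc_astro)
  out$direction_micro <- dir_of(records$adj_log2fc_micro)
  out$cell9_label <- paste(out$direction_astro, out$direction_micro,
                           sep = "|")
  out
}

#' Summarize the four-way classification
#'
#' Produces the 3x3 count table (astrocyte direction x microglia
#' direction; a true partition of the union set), the derived aggregate
#' classes and their percentages of the union size, and a scatter-ready
#' table. Aggregates follow the verbal definitions: `astro_specific_up`
#' counts genes up in astrocytes that are unchanged or down in microglia,
#' etc.; discordant genes (up in one, down in the other) are therefore
#' counted in both relevant cell-type-specific aggregates and also
#' reported separately.
#'
#' @param records Output of [classify_fourway()].
#' @return List: `cell9` (3x3 matrix), `aggregates` (named counts),
#'   `percentages` (of union size), `n_union`, `scatter` (data.frame
#'   `gene_id`, `adj_log2fc_astro`, `adj_log2fc_micro`, `cell9_label`).
#' @export
summarize_fourway_counts <- function(records) {
  fa <- factor(records$direction_astro, levels = .directions)
  fm <- factor(records$direction_micro, levels = .directions)
  cell9 <- table(astro = fa, micro = fm)
  m <- as.matrix(unclass(cell9))

  aggregates <- c(
    common_up = m["up", "up"],
    common_down = m["down", "down"],
    astro_specific_up = m["up", "unchanged"] + m["up", "down"],
    astro_specific_down = m["down", "unchanged"] + m["down", "up"],
    micro_specific_up = m["unchanged", "up"] + m["down", "up"],
    micro_specific_down = m["unchanged", "down"] + m["up", "down"],
    discordant = m["up", "down"] + m["down", "up"],
    unchanged_both = m["unchanged", "unchanged"]
  )
  n <- nrow(records)
  list(cell9 = m,
       aggregates = aggregates,
       percentages = 100 * aggregates / n,
       n_union = n,
       scatter = records[, c("gene_id", "adj_log2fc_astro",
                             "adj_log2fc_micro", "cell9_label")])
}

#' Regulator activation z-score over a signed regulon
#'
#' Generic activation score for an upstream regulator given a signed
#' regulator-to-target network: targets whose observed differential
#' expression direction matches the edge sign count as consistent,
#' opposite directions as inconsistent, unchanged targets as neither;
#' `z = (n_consistent - n_inconsistent) / sqrt(n_consistent +
#' n_inconsistent)`. A regulator is predicted `activated` if `z > 2`,
#' `inhibited` if `z < -2` (the rule is strict), otherwise
#' `not_significant`. Regulators with no scored targets get `z = NA` and
#' are flagged.
#'
#' @param regulon data.frame `regulator_id`, `target_gene`, `sign`
#'   (+1 = the regulator induces the target, -1 = represses).
#' @param observed Named vector of observed per-gene directions over the
#'   gene universe: `"up"`/`"down"`/`"unchanged"` or numeric +1/-1/0.
#' @param z_cutoff Significance cutoff (default 2).
#' @return data.frame per regulator: `regulator_id`, `n_consistent`,
#'   `n_inconsistent`, `z`, `predicted_state`, `no_scored_targets`.
#' @export
regulator_activation_zscore <- function(regulon, observed, z_cutoff = 2) {
  if (is.null(regulon) || nrow(regulon) == 0L)
    stop("contract error: empty regulon")
  if (!all(c("regulator_id", "target_gene", "sign") %in% names(regulon)))
    stop("regulon needs columns regulator_id, target_gene, sign")
  if (!all(regulon$sign %in% c(-1, 1)))
    stop("regulon signs must be +1 or -1")

  obs <- if (is.character(observed))
    c(up = 1, unchanged = 0, down = -1)[observed]
  else as.numeric(observed)
  names(obs) <- names(observed)
  if (anyNA(obs)) stop("observed directions must be up/down/unchanged or +1/0/-1")

  res <- lapply(split(regulon, regulon$regulator_id), function(rg) {
    o <- obs[rg$target_gene]
    o[is.na(o)] <- 0                      # targets absent from the universe
    scored <- o != 0
    nc <- sum(rg$sign[scored] * o[scored] > 0)
    ni <- sum(rg$sign[scored] * o[scored] < 0)
    z <- if (nc + ni > 0) (nc - ni) / sqrt(nc + ni) else NA_real_
    state <- if (is.na(z)) "not_significant"
             else if (z > z_cutoff) "activated"
             else if (z < -z_cutoff) "inhibited"
             else "not_significant"
    data.frame(regulator_id = rg$regulator_id[1],
               n_consistent = nc, n_inconsistent = ni, z = z,
               predicted_state = state,
               no_scored_targets = nc + ni == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full four-way comparison in one call
#'
#' @param degs_astro,degs_micro [call_degs()] tables.
#' @param p_cutoff Corrected-p cutoff for the FC = 1 adjustment.
#' @param log2fc_threshold Direction threshold (log2 units).
#' @return List: `records` (classified union table) and `summary`
#'   ([summarize_fourway_counts()] output).
#' @export
fourway_analysis <- function(degs_astro, degs_micro,
                             p_cutoff = 0.05, log2fc_threshold = 1) {
  u <- build_union_set(degs_astro, degs_micro)
  u <- adjust_nonsignificant_fc(u, p_cutoff)
  u <- classify_fourway(u, log2fc_threshold)
  list(records = u, summary = summarize_fourway_counts(u))
}
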