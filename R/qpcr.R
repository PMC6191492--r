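# Delta-delta-Ct relative quantification with dual reference genes.

.qpcr_required <- c("sample_id", "cell_type", "condition", "timepoint_h",
                    "target_gene", "ct_target", "ct_hprt1", "ct_gapdh")

#' Validate a qPCR measurement table
#'
#' Checks the input layout (one row per sample x target, Ct of the target
#' plus the two reference genes Hprt1 and Gapdh) and that all Ct values
#' are finite and positive; a missing reference Ct is reported with the
#' offending sample and target gene.
#'
#' @param df data.frame with columns `sample_id`, `cell_type`,
#'   `condition` (`"medium"`/`"Th1"`), `timepoint_h`, `target_gene`,
#'   `ct_target`, `ct_hprt1`, `ct_gapdh`.
#' @return The validated data.frame (invisibly usable as-is).
#' @export
validate_qpcr <- function(df) {
  missing_cols <- setdiff(.qpcr_required, names(df))
  if (length(missing_cols))
    stop("qPCR table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("ct_target", "ct_hprt1", "ct_gapdh")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad))
      stop("missing or invalid ", col, " for sample '",
           df$sample_id[bad[1]], "' (target ", df$target_gene[bad[1]], ")")
  }
  df
}

# Per-sample delta Ct: target Ct minus the arithmetic mean of the two
# reference-gene Cts (geometric-mean normalization on the expression scale).
.delta_ct <- function(df) df$ct_target - (df$ct_hprt1 + df$ct_gapdh) / 2

#' Delta-delta-Ct between a treated and a control arm
#'
#' Computes per-sample `dCt = Ct_target - mean(Ct_refs)`, averages per
#' arm, takes `ddCt = dCt_treated - dCt_control` and the fold change
#' `2^(-ddCt)` (amplification efficiency fixed at 2). Per-replicate fold
#' changes (each treated replicate against the control-arm mean,
#' exponentiated first) are returned for mean +/- SD reporting, alongside
#' the fold change derived from the mean ddCt.
#'
#' @param treated,control Measurement subsets (validated layout of
#'   [validate_qpcr()]) for one target gene, cell type and timepoint.
#' @param threshold Fold-change threshold for the regulation call.
#' @return One-row data.frame: `target_gene`, `cell_type`, `timepoint_h`,
#'   `delta_ct_treated`, `delta_ct_control`, `delta_delta_ct`,
#'   `fold_change` (from mean ddCt), `fold_change_mean`,
#'   `fold_change_sd` (over per-replicate fold changes),
#'   `regulation_call`; attribute `per_replicate_fc`.
#' @export
delta_delta_ct <- function(treated, control, threshold = 2) {
  treated <- validate_qpcr(treated)
  control <- validate_qpcr(control)
  key <- function(df) {
    k <- unique(df[, c("target_gene", "cell_type", "timepoint_h")])
    rownames(k) <- NULL
    k
  }
  kt <- key(treated); kc <- key(control)
  if (nrow(kt) != 1L || nrow(kc) != 1L || !identical(kt, kc))
    stop("treated and control arms must cover exactly one matching ",
         "target gene, cell type and timepoint")

  dct_t <- .delta_ct(treated)
  dct_c <- .delta_ct(control)
  ddct <- mean(dct_t) - mean(dct_c)
  fc <- 2^(-ddct)
  per_rep_fc <- 2^(-(dct_t - mean(dct_c)))

  out <- data.frame(target_gene = kt$target_gene,
                    cell_type = kt$cell_type,
                    timepoint_h = kt$timepoint_h,
                    delta_ct_treated = mean(dct_t),
                    delta_ct_control = mean(dct_c),
                    delta_delta_ct = ddct,
                    fold_change = fc,
                    fold_change_mean = mean(per_rep_fc),
                    fold_change_sd = if (length(per_rep_fc) > 1)
                      stats::sd(per_rep_fc) else NA_real_,
                    regulation_call = classify_regulation(fc, threshold),
                    stringsAsFactors = FALSE)
  attr(out, "per_replicate_fc") <- per_rep_fc
  out
}

#' Classify a fold change at the 2-fold lines
#'
#' `up` if the fold change strictly exceeds `threshold`, `down` if it is
#' strictly below `1/threshold`, `none` otherwise (a fold change of
#' exactly 2 is not called, the rule being strictly "more than 2-fold").
#'
#' @param fold_change Positive linear fold change(s).
#' @param threshold Fold-change threshold (default 2).
#' @return Character vector of `"up"`, `"down"`, `"none"`.
#' @export
classify_regulation <- function(fold_change, threshold = 2) {
  if (any(!is.finite(fold_change) | fold_change <= 0))
    stop("fold changes must be positive and finite")
  ifelse(fold_change > threshold, "up",
         ifelse(fold_change < 1 / threshold, "down", "none"))
}

#' Delta-delta-Ct analysis of a full qPCR table
#'
#' Splits the table by cell type, target gene and timepoint, contrasts
#' the Th1-treated arm against the medium arm in each stratum and stacks
#' the [delta_delta_ct()] results.
#'
#' @param df Measurement table ([validate_qpcr()] layout).
#' @param threshold Fold-change threshold for regulation calls.
#' @param treated,control Condition labels of the two arms.
#' @return data.frame of stacked [delta_delta_ct()] rows.
#' @export
qpcr_analysis <- function(df, threshold = 2,
                          treated = "Th1", control = "medium") {
  df <- validate_qpcr(df)
  strata <- split(df, list(df$cell_type, df$target_gene, df$timepoint_h),
                  drop = TRUE)
  rows <- lapply(strata, function(s) {
    tr <- s[s$condition == treated, , drop = FALSE]
    ct <- s[s$condition == control, , drop = FALSE]
    if (nrow(tr) == 0L || nrow(ct) == 0L)
      stop("stratum ", s$target_gene[1], "/", s$cell_type[1], "/",
           s$timepoint_h[1], "h lacks a ", if (nrow(tr) == 0L) treated
           else control, " arm")
    delta_delta_ct(tr, ct, threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_type, out$target_gene, out$timepoint_h), ,
      drop = FALSE]
}
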