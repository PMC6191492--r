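# Differential expression: treatment vs medium within one cell type.
# Empirical-Bayes moderated t with the variance prior fitted by the
# closed-form moment method on log sample variances.

#' Define the within-cell-type treatment contrast
#'
#' @param samples Sample metadata (`sample_id`, `cell_type`, `treatment`,
#'   `replicate`).
#' @param cell_type Cell type to contrast within.
#' @param treated,control Treatment labels of the two arms.
#' @return Object of class `de_contrast`: `cell_type`, `treated_ids`,
#'   `control_ids`, and replicate indices of both arms.
#' @export
make_contrast <- function(samples, cell_type,
                          treated = "Th1", control = "medium") {
  sel <- samples$cell_type == cell_type
  if (!any(sel)) stop("no samples of cell type '", cell_type, "'")
  t_rows <- samples[sel & samples$treatment == treated, , drop = FALSE]
  c_rows <- samples[sel & samples$treatment == control, , drop = FALSE]
  if (nrow(t_rows) == 0L || nrow(c_rows) == 0L)
    stop("both contrast arms must be non-empty for cell type '",
         cell_type, "'")
  if (length(intersect(t_rows$sample_id, c_rows$sample_id)))
    stop("contrast arms overlap")
  structure(list(cell_type = cell_type,
                 treated_ids = t_rows$sample_id,
                 control_ids = c_rows$sample_id,
                 treated_reps = t_rows$replicate,
                 control_reps = c_rows$replicate),
            class = "de_contrast")
}

#' Per-gene log2 fold changes for a contrast
#'
#' `log2fc = mean(treated) - mean(control)` on the log2 scale. When
#' `per_replicate = TRUE` also returns replicate-paired per-replicate
#' fold-change columns (`treated_i - control_i`, matched by replicate
#' index), the inputs of the heat-map stage.
#'
#' @param mat A log2-scale [intensity_matrix()].
#' @param contrast A [make_contrast()] object.
#' @param per_replicate Return paired per-replicate columns?
#' @return List: `log2fc`, `mean_treated`, `mean_control`, and (if
#'   requested) `rep_log2fc`, a gene x replicate matrix.
#' @export
compute_fold_changes <- function(mat, contrast, per_replicate = TRUE) {
  v <- mat$values
  mt <- v[, contrast$treated_ids, drop = FALSE]
  mc <- v[, contrast$control_ids, drop = FALSE]
  out <- list(log2fc = rowMeans(mt) - rowMeans(mc),
              mean_treated = rowMeans(mt),
              mean_control = rowMeans(mc))
  if (per_replicate) {
    if (!setequal(contrast$treated_reps, contrast$control_reps) ||
        length(contrast$treated_reps) != length(contrast$control_reps))
      stop("replicate-paired fold changes need matching replicate indices ",
           "in both arms")
    ot <- order(contrast$treated_reps)
    oc <- order(contrast$control_reps)
    rep_fc <- mt[, ot, drop = FALSE] - mc[, oc, drop = FALSE]
    colnames(rep_fc) <- paste0("rep", sort(contrast$treated_reps))
    out$rep_log2fc <- rep_fc
  }
  out
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration; used when
#' fitting the variance-prior degrees of freedom.
#'
#' @param x Positive value.
#' @return `y` with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) stop("trigamma_inverse needs finite x > 0")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (!is.finite(y)) stop("trigamma inversion diverged")
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Fit the scaled inverse-chi-square variance prior by moments
#'
#' Given per-gene sample variances `s2` on `df` residual degrees of
#' freedom, estimates the prior degrees of freedom `d0` and prior
#' variance `s0_2` of the hierarchical model
#' `s2_g | sigma2_g ~ sigma2_g * chi2_df / df`,
#' `1 / sigma2_g ~ chi2_d0 / (d0 * s0_2)`, using the closed-form moment
#' method on `log(s2)`: the excess of the empirical variance of
#' `e_g = log(s2_g) - digamma(df/2) + log(df/2)` over `trigamma(df/2)`
#' equals `trigamma(d0/2)`, inverted numerically; the mean of `e_g`
#' identifies `s0_2`. A non-positive excess yields `d0 = Inf`
#' (fully pooled variance); fewer than two usable genes yield `d0 = 0`
#' (no moderation, ordinary t).
#'
#' @param s2 Per-gene sample variances.
#' @param df Residual degrees of freedom (scalar; same design for all
#'   genes).
#' @return List `d0`, `s0_2`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  n <- length(z)
  if (n == 0L) return(list(d0 = 0, s0_2 = NA_real_))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  if (n < 2L) return(list(d0 = 0, s0_2 = exp(emean)))
  evar <- sum((e - emean)^2) / (n - 1)
  excess <- evar - trigamma(df / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated t-test for one contrast
#'
#' Pools the two arms' per-gene variances
#' (`s2 = ((n1-1) v1 + (n2-1) v2) / (n1 + n2 - 2)`), fits the variance
#' prior with [fit_variance_prior()], shrinks each gene's variance to the
#' posterior `s2_post = (d0 * s0_2 + dg * s2) / (d0 + dg)`, and forms
#' `t_mod = log2fc / sqrt(s2_post * (1/n1 + 1/n2))` with two-sided p from
#' a t distribution on `d0 + dg` degrees of freedom. When `d0` is
#' estimated infinite the total degrees of freedom are capped at the sum
#' of residual degrees of freedom across genes. Genes with zero posterior
#' variance and zero fold change get `p = 1` by convention and are
#' flagged in the `degenerate` column.
#'
#' @param mat A log2-scale [intensity_matrix()].
#' @param contrast A [make_contrast()] object (>= 2 samples per arm).
#' @return data.frame with `gene_id`, `mean_treated`, `mean_control`,
#'   `log2fc`, `s2`, `t_mod`, `df_total`, `p_raw`, `degenerate`;
#'   attributes `prior` (`d0`, `s0_2`), `rep_log2fc` (replicate-paired
#'   fold-change matrix) and `contrast`.
#' @export
moderated_t_test <- function(mat, contrast) {
  v <- mat$values
  n1 <- length(contrast$treated_ids)
  n2 <- length(contrast$control_ids)
  if (n1 < 2L || n2 < 2L)
    stop("moderated t-test needs >= 2 samples per arm")
  mt <- v[, contrast$treated_ids, drop = FALSE]
  mc <- v[, contrast$control_ids, drop = FALSE]
  if (anyNA(mt) || anyNA(mc))
    stop("contract error: matrix contains missing values; normalize first")

  rv <- function(m) rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * rv(mt) + (n2 - 1) * rv(mc)) / dg

  prior <- fit_variance_prior(s2, dg)
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s0_2, length(s2))
             else if (d0 == 0) s2
             else (d0 * prior$s0_2 + dg * s2) / (d0 + dg)

  df_total <- if (is.infinite(d0)) dg * length(s2) else d0 + dg

  fc <- compute_fold_changes(mat, contrast, per_replicate = TRUE)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- fc$log2fc / se
  degenerate <- !is.finite(se) | se == 0
  t_mod[degenerate & fc$log2fc == 0] <- 0
  t_mod[degenerate & fc$log2fc != 0] <-
    sign(fc$log2fc[degenerate & fc$log2fc != 0]) * Inf
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_raw[degenerate & fc$log2fc == 0] <- 1

  res <- data.frame(gene_id = rownames(v),
                    mean_treated = fc$mean_treated,
                    mean_control = fc$mean_control,
                    log2fc = fc$log2fc,
                    s2 = s2,
                    t_mod = t_mod,
                    df_total = df_total,
                    p_raw = p_raw,
                    degenerate = degenerate,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "prior") <- prior
  attr(res, "rep_log2fc") <- fc$rep_log2fc
  attr(res, "contrast") <- contrast
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")` after contract checks); input order is
#' preserved.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("contract error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' DEG-calling criteria
#'
#' @param fc_threshold Linear fold-change cutoff (default 2).
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param strict_fc If `TRUE`, require |FC| strictly greater than
#'   `fc_threshold` ("more than 2-fold"); default is the inclusive
#'   `|FC| >= fc_threshold` reading.
#' @return Object of class `deg_criteria`.
#' @export
deg_criteria <- function(fc_threshold = 2, alpha = 0.01, strict_fc = FALSE) {
  if (fc_threshold < 1) stop("'fc_threshold' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 strict_fc = isTRUE(strict_fc)),
            class = "deg_criteria")
}

#' Call differentially expressed genes
#'
#' Adds BH-adjusted p-values (unless already present), the DEG call
#' (`p_adj < alpha` and the fold-change gate) and direction to a
#' [moderated_t_test()] result.
#'
#' @param results [moderated_t_test()] output.
#' @param criteria A [deg_criteria()] object.
#' @return The augmented data.frame with columns `p_adj`, `fc_linear`
#'   (`2^log2fc`), `is_deg`, `direction` (`"up"`, `"down"`, `"none"`);
#'   attributes of `results` are preserved.
#' @export
call_degs <- function(results, criteria = deg_criteria()) {
  out <- results
  if (is.null(out$p_adj)) out$p_adj <- bh_adjust(out$p_raw)
  lfc_cut <- log2(criteria$fc_threshold)
  pass_fc <- if (criteria$strict_fc) abs(out$log2fc) > lfc_cut
             else abs(out$log2fc) >= lfc_cut
  out$fc_linear <- 2^out$log2fc
  out$is_deg <- out$p_adj < criteria$alpha & pass_fc
  out$direction <- ifelse(!out$is_deg, "none",
                          ifelse(out$log2fc > 0, "up", "down"))
  for (a in c("prior", "rep_log2fc", "contrast"))
    attr(out, a) <- attr(results, a)
  attr(out, "criteria") <- criteria
  out
}

#' Split a DEG table into up- and down-regulated genes
#'
#' @param results Output of [call_degs()].
#' @return List `up`, `down` of data.frame subsets.
#' @export
deg_split <- function(results) {
  list(up = results[results$is_deg & results$log2fc > 0, , drop = FALSE],
       down = results[results$is_deg & results$log2fc < 0, , drop = FALSE])
}

#' One-call differential expression analysis for a cell type
#'
#' Contrast construction, fold changes, moderated t, BH adjustment and
#' DEG calling in one step.
#'
#' @param mat Normalized log2-scale [intensity_matrix()].
#' @param cell_type Cell type to analyse.
#' @param criteria A [deg_criteria()] object.
#' @param treated,control Treatment labels.
#' @return A [call_degs()] table.
#' @export
de_analysis <- function(mat, cell_type, criteria = deg_criteria(),
                        treated = "Th1", control = "medium") {
  contrast <- make_contrast(mat$samples, cell_type, treated, control)
  call_degs(moderated_t_test(mat, contrast), criteria)
}
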