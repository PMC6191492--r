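# Between-array normalization: quantile normalization, global linear
# scaling to a reference 75th percentile, surrogate flooring, log2.

#' Normalization parameters
#'
#' @param reference_percentile Quantile level used for global linear
#'   scaling (default 0.75, i.e. the 75th percentile).
#' @param reference_value Reference intensity the chosen percentile of
#'   every array is scaled to (default 1500, applied series-wide).
#' @param surrogate_floor Lower intensity threshold; values below it (and
#'   missing entries) are substituted by this surrogate value (default 15
#'   finally normalized gPS units).
#' @return An object of class `norm_params`.
#' @export
norm_params <- function(reference_percentile = 0.75,
                        reference_value = 1500,
                        surrogate_floor = 15) {
  if (reference_percentile <= 0 || reference_percentile >= 1)
    stop("'reference_percentile' must lie in (0, 1)")
  if (!(reference_value > surrogate_floor && surrogate_floor > 0))
    stop("need reference_value > surrogate_floor > 0")
  structure(list(reference_percentile = reference_percentile,
                 reference_value = reference_value,
                 surrogate_floor = surrogate_floor),
            class = "norm_params")
}

#' Quantile normalization across arrays
#'
#' Forces every array's distribution of non-missing intensities onto the
#' common reference distribution (the cross-array mean of order
#' statistics). Tied values receive the mean of the order-statistic means
#' over their rank span, so within-array order is preserved up to ties.
#' Missing entries are excluded from rank computation and remain missing
#' (they are substituted by the surrogate floor later in the pipeline).
#' Columns with unequal numbers of non-missing values are matched through
#' linear interpolation of the sorted values on the common quantile grid.
#'
#' @param mat An [intensity_matrix()].
#' @return The quantile-normalized [intensity_matrix()].
#' @export
quantile_normalize <- function(mat) {
  v <- mat$values
  if (ncol(v) < 2L) stop("quantile normalization needs >= 2 samples")
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0L))
    stop("column(s) entirely missing: ",
         paste(colnames(v)[n_obs == 0L], collapse = ", "))

  nr <- nrow(v)
  probs <- if (nr > 1L) (seq_len(nr) - 1) / (nr - 1) else 0.5

  # reference curve: mean of per-array order statistics on a common grid
  ref_cols <- vapply(seq_len(ncol(v)), function(j) {
    xs <- sort(v[, j])            # drops NA
    nk <- length(xs)
    if (nk == nr) xs
    else if (nk == 1L) rep(xs, nr)
    else stats::approx((seq_len(nk) - 1) / (nk - 1), xs,
                       xout = probs, rule = 2)$y
  }, numeric(nr))
  ref <- rowMeans(ref_cols)

  out <- v
  for (j in seq_len(ncol(v))) {
    idx <- which(!is.na(v[, j]))
    x <- v[idx, j]
    nk <- length(x)
    o <- order(x)
    val <- if (nk == nr) ref
    else if (nk == 1L) mean(ref)
    else stats::approx(probs, ref, xout = (seq_len(nk) - 1) / (nk - 1),
                       rule = 2)$y
    assigned <- numeric(nk)
    assigned[o] <- val
    assigned <- stats::ave(assigned, match(x, x), FUN = mean)  # tie spans
    out[idx, j] <- assigned
  }
  intensity_matrix(out, mat$samples)
}

#' Global linear scaling to a reference percentile
#'
#' Multiplies every array by its own scaling factor
#' `reference_value / percentile(array)`, so that each array's chosen
#' percentile (default: 75th) equals `reference_value` (default: 1500)
#' afterwards. Percentiles use the linear-interpolation (type-7) quantile
#' and ignore missing entries.
#'
#' @param mat An [intensity_matrix()] (typically quantile-normalized).
#' @param params A [norm_params()] object.
#' @return List with `matrix` (the scaled [intensity_matrix()]) and
#'   `report` (data.frame `sample_id`, `pre_p75`, `factor`, `n_floored`;
#'   the floored count is filled in by [apply_surrogate_floor()]).
#' @export
global_linear_scale <- function(mat, params = norm_params()) {
  v <- mat$values
  p75 <- apply(v, 2, stats::quantile, probs = params$reference_percentile,
               na.rm = TRUE, names = FALSE, type = 7)
  if (any(!is.finite(p75) | p75 <= 0))
    stop("non-positive ", params$reference_percentile * 100,
         "th percentile in sample(s): ",
         paste(colnames(v)[!is.finite(p75) | p75 <= 0], collapse = ", "))
  fac <- params$reference_value / p75
  scaled <- sweep(v, 2, fac, "*")
  report <- data.frame(sample_id = colnames(v),
                       pre_p75 = p75,
                       factor = fac,
                       n_floored = NA_integer_,
                       stringsAsFactors = FALSE)
  list(matrix = intensity_matrix(scaled, mat$samples), report = report)
}

#' Substitute the surrogate floor
#'
#' Every value strictly below `surrogate_floor`, and every missing entry,
#' becomes exactly the floor; values at or above the floor are unchanged.
#'
#' @param mat A scaled [intensity_matrix()].
#' @param params A [norm_params()] object.
#' @return List with `matrix` (floored [intensity_matrix()], no missing
#'   entries left) and `n_floored` (named per-sample count of substituted
#'   entries).
#' @export
apply_surrogate_floor <- function(mat, params = norm_params()) {
  v <- mat$values
  hit <- is.na(v) | v < params$surrogate_floor
  v[hit] <- params$surrogate_floor
  list(matrix = intensity_matrix(v, mat$samples),
       n_floored = colSums(hit))
}

#' Elementwise log2 transform
#'
#' @param mat An [intensity_matrix()] of strictly positive values.
#' @return The [intensity_matrix()] in log2 units.
#' @export
log2_transform <- function(mat) {
  v <- mat$values
  if (any(is.na(v)) || any(v <= 0))
    stop("contract error: log2 transform requires strictly positive, ",
         "non-missing values (apply the surrogate floor first)")
  intensity_matrix(log2(v), mat$samples)
}

#' Full between-array normalization pipeline
#'
#' Runs, in order: quantile normalization, global linear scaling to the
#' reference percentile, surrogate flooring (on the finally normalized
#' linear scale), log2 transform.
#'
#' @param mat An [intensity_matrix()] of collapsed linear gPS values.
#' @param params A [norm_params()] object.
#' @return List of class `normalized_experiment`: `log2_matrix`
#'   (log2-scale [intensity_matrix()]), `linear_matrix` (the floored
#'   linear-scale matrix), `scaled_matrix` (the scaled matrix before
#'   flooring, missing entries still masked; its per-array reference
#'   percentile equals `reference_value` exactly), `report` (per-array
#'   pre-scaling percentile, scaling factor and floored-entry count) and
#'   `params`.
#' @export
normalize_pipeline <- function(mat, params = norm_params()) {
  q <- quantile_normalize(mat)
  s <- global_linear_scale(q, params)
  f <- apply_surrogate_floor(s$matrix, params)
  l <- log2_transform(f$matrix)
  report <- s$report
  report$n_floored <- as.integer(f$n_floored[report$sample_id])
  structure(list(log2_matrix = l,
                 linear_matrix = f$matrix,
                 scaled_matrix = s$matrix,
                 report = report,
                 params = params),
            class = "normalized_experiment")
}

#' @export
print.normalized_experiment <- function(x, ...) {
  cat(sprintf(
    "normalized_experiment: %d probes x %d samples; %sth percentile scaled to %g, floor %g\n",
    nrow(x$log2_matrix$values), ncol(x$log2_matrix$values),
    x$params$reference_percentile * 100, x$params$reference_value,
    x$params$surrogate_floor))
  invisible(x)
}
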