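# Reading Feature-Extraction-style files and collapsing on-chip replicate
# features to one value per probe per array.

.fe_required_cols <- c("ProbeName", "GeneName", "gProcessedSignal",
                       "ControlType", "IsManualFlag", "gIsFeatNonUnifOL",
                       "PixelCV")

#' Read a Feature-Extraction-style tab-delimited file
#'
#' Parses the one-color Feature Extraction dialect: tab-separated, header
#' row, with columns `ProbeName`, `GeneName`, `EntrezID` (optional),
#' `gProcessedSignal` (the background-corrected green-channel intensity,
#' gPS), `ControlType` (0 = non-control), `IsManualFlag` (0/1),
#' `gIsFeatNonUnifOL` (0/1 software outlier), `PixelCV` (pixel-intensity
#' coefficient of variation). Numeric parsing is locale-independent
#' (C locale, `.` decimal separator; scientific notation accepted).
#'
#' @param path Path to the file.
#' @return A data.frame of feature records: `probe_id`, `gene_symbol`,
#'   `entrez_id`, `gps`, `is_control`, `manual_flag`, `fe_outlier`,
#'   `pixel_cv`, one row per data row, control rows retained but marked.
#' @export
read_feature_extraction <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.fe_required_cols, names(raw))
  if (length(missing_cols))
    stop("format error in '", path, "': missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  num_col <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !(is.na(raw[[col]]) | raw[[col]] == ""))
    if (length(bad))
      stop("format error in '", path, "': non-numeric ", col,
           " at line ", bad[1] + 1L, " (value '", raw[[col]][bad[1]], "')")
    x
  }
  gps <- num_col("gProcessedSignal")
  pixel_cv <- num_col("PixelCV")
  if (any(gps < 0, na.rm = TRUE))
    stop("format error in '", path, "': negative gProcessedSignal at line ",
         which(gps < 0)[1] + 1L)
  if (any(pixel_cv < 0, na.rm = TRUE))
    stop("format error in '", path, "': negative PixelCV at line ",
         which(pixel_cv < 0)[1] + 1L)

  data.frame(
    probe_id = raw$ProbeName,
    gene_symbol = raw$GeneName,
    entrez_id = if ("EntrezID" %in% names(raw)) raw$EntrezID else NA_character_,
    gps = gps,
    is_control = num_col("ControlType") != 0,
    manual_flag = num_col("IsManualFlag") != 0,
    fe_outlier = num_col("gIsFeatNonUnifOL") != 0,
    pixel_cv = pixel_cv,
    stringsAsFactors = FALSE
  )
}

#' Parameters for on-chip replicate collapsing
#'
#' @param iqr_multiplier Width multiplier of the interquartile-range rule:
#'   surviving features must lie within an interval of total width
#'   `iqr_multiplier * IQR` of the replicate population (see
#'   `iqr_strategy`). Set to `Inf` to disable the rule.
#' @param pixel_cv_max Features whose pixel-intensity CV strictly exceeds
#'   this value are excluded.
#' @param min_surviving_replicates Minimum number of surviving features
#'   required to report a collapsed value; otherwise the probe is missing
#'   on that array.
#' @param iqr_strategy How the IQR interval is anchored:
#'   `"median-centered"` (default) uses
#'   `median +/- iqr_multiplier * IQR / 2` (total width 1.42 x IQR at the
#'   default multiplier); `"quartile-fenced"` uses Tukey-style fences
#'   `[Q1 - m * IQR, Q3 + m * IQR]`.
#' @return An object of class `collapse_params`.
#' @export
collapse_params <- function(iqr_multiplier = 1.42,
                            pixel_cv_max = 0.5,
                            min_surviving_replicates = 1L,
                            iqr_strategy = c("median-centered", "quartile-fenced")) {
  if (!is.numeric(iqr_multiplier) || iqr_multiplier <= 0)
    stop("'iqr_multiplier' must be > 0")
  if (!is.numeric(pixel_cv_max) || pixel_cv_max <= 0)
    stop("'pixel_cv_max' must be > 0")
  if (min_surviving_replicates < 1)
    stop("'min_surviving_replicates' must be >= 1")
  structure(list(iqr_multiplier = iqr_multiplier,
                 pixel_cv_max = pixel_cv_max,
                 min_surviving_replicates = as.integer(min_surviving_replicates),
                 iqr_strategy = match.arg(iqr_strategy)),
            class = "collapse_params")
}

.iqr_bounds <- function(x, params) {
  # sample IQR cannot flag outliers with < 3 points; rule is skipped there
  if (length(x) < 3L || !is.finite(params$iqr_multiplier))
    return(c(-Inf, Inf))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (params$iqr_strategy == "median-centered")
    c(q[2] - params$iqr_multiplier * iqr / 2,
      q[2] + params$iqr_multiplier * iqr / 2)
  else
    c(q[1] - params$iqr_multiplier * iqr,
      q[3] + params$iqr_multiplier * iqr)
}

#' Collapse the on-chip replicates of a single probe on one array
#'
#' Applies the four exclusion rules in order -- (i) manual flag,
#' (ii) software outlier flag, (iv) pixel CV above `pixel_cv_max` on
#' individual features, then (iii) the interquartile-range interval rule
#' on the surviving gPS values -- and returns the geometric mean of the
#' survivors. Flag-based rules run first so corrupted spots cannot
#' distort the IQR. Returns `NA` when fewer than
#' `min_surviving_replicates` features survive.
#'
#' @param records Feature records (as from [read_feature_extraction()])
#'   of one probe on one array.
#' @param params A [collapse_params()] object.
#' @return The collapsed gPS value (or `NA_real_`), with attribute
#'   `exclusions`: per input feature, `"none"`, `"manual_flag"`,
#'   `"fe_outlier"`, `"pixel_cv"` or `"iqr"` (the first rule that fired).
#' @examples
#' r <- data.frame(probe_id = "p", gps = c(100, 100, 100, 100),
#'                 manual_flag = FALSE, fe_outlier = FALSE, pixel_cv = 0.1)
#' collapse_onchip_replicates(r)
#' @export
collapse_onchip_replicates <- function(records, params = collapse_params()) {
  if (is.null(records) || nrow(records) == 0L)
    stop("contract error: no features supplied")
  if (length(unique(records$probe_id)) != 1L)
    stop("contract error: features of more than one probe supplied")

  reason <- rep("none", nrow(records))
  reason[records$pixel_cv > params$pixel_cv_max] <- "pixel_cv"
  reason[records$fe_outlier] <- "fe_outlier"
  reason[records$manual_flag] <- "manual_flag"

  surv <- which(reason == "none")
  if (length(surv)) {
    b <- .iqr_bounds(records$gps[surv], params)
    out <- records$gps[surv] < b[1] | records$gps[surv] > b[2]
    reason[surv[out]] <- "iqr"
    surv <- surv[!out]
  }

  value <- if (length(surv) >= params$min_surviving_replicates)
    exp(mean(log(records$gps[surv])))
  else NA_real_
  attr(value, "exclusions") <- reason
  value
}

#' Collapse all probes of one array (vectorized)
#'
#' Equivalent to calling [collapse_onchip_replicates()] per probe, but
#' vectorized over the whole array. Control features are dropped.
#'
#' @param records All feature records of one array.
#' @param params A [collapse_params()] object.
#' @return Named numeric vector: collapsed gPS per non-control probe
#'   (`NA` where too few features survived), in first-appearance order.
#' @export
collapse_array <- function(records, params = collapse_params()) {
  r <- records[!records$is_control, , drop = FALSE]
  if (nrow(r) == 0L) stop("contract error: no non-control features")
  f <- factor(r$probe_id, levels = unique(r$probe_id))

  keep <- !(r$manual_flag | r$fe_outlier | r$pixel_cv > params$pixel_cv_max)
  ks <- which(keep)
  g <- f[ks]
  x <- r$gps[ks]

  if (length(ks) && is.finite(params$iqr_multiplier)) {
    nsurv <- tabulate(g, nbins = nlevels(f))
    qs <- function(p) {
      q <- tapply(x, g, stats::quantile, probs = p, names = FALSE, type = 7)
      as.numeric(q)[as.integer(g)]
    }
    q1 <- qs(0.25); med <- qs(0.5); q3 <- qs(0.75)
    iqr <- q3 - q1
    if (params$iqr_strategy == "median-centered") {
      lo <- med - params$iqr_multiplier * iqr / 2
      hi <- med + params$iqr_multiplier * iqr / 2
    } else {
      lo <- q1 - params$iqr_multiplier * iqr
      hi <- q3 + params$iqr_multiplier * iqr
    }
    few <- nsurv[as.integer(g)] < 3L   # IQR rule needs >= 3 survivors
    inside <- few | (x >= lo & x <= hi)
    g <- g[inside]
    x <- x[inside]
  }

  n_ok <- tabulate(g, nbins = nlevels(f))
  gm <- rep(NA_real_, nlevels(f))
  if (length(x)) {
    sums <- tapply(log(x), g, sum)
    has <- !is.na(sums)
    gm[which(has)] <- exp(as.numeric(sums[has]) / n_ok[which(has)])
  }
  gm[n_ok < params$min_surviving_replicates] <- NA_real_
  stats::setNames(gm, levels(f))
}

#' Probe-by-sample intensity matrix with sample metadata
#'
#' The pipeline's central container: a numeric probe x sample matrix
#' (missing entries `NA`) plus a per-sample metadata table with
#' `sample_id`, `cell_type`, `treatment`, `replicate`.
#'
#' @param values Numeric matrix, probes as rows (rownames), samples as
#'   columns (colnames matching `samples$sample_id`).
#' @param samples Sample metadata data.frame.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.data.frame(samples))
  req <- c("sample_id", "cell_type", "treatment", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample metadata must contain: ", paste(req, collapse = ", "))
  if (anyNA(samples[req]))
    stop("sample metadata is incomplete (NA entries)")
  if (ncol(values) != nrow(samples))
    stop("matrix has ", ncol(values), " columns but metadata has ",
         nrow(samples), " rows")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), samples$sample_id))
    stop("matrix column names do not match metadata sample_id order")
  if (is.null(rownames(values)))
    stop("matrix must have probe rownames")
  structure(list(values = values, samples = samples),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d probes x %d samples (%d missing entries)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.matrix.intensity_matrix <- function(x, ...) x$values

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Assemble per-array collapsed values into an intensity matrix
#'
#' @param per_array Named list (sample_id -> named numeric vector of
#'   collapsed probe values, as from [collapse_array()]).
#' @param metadata Sample metadata data.frame (`sample_id`, `cell_type`,
#'   `treatment`, `replicate`); its row order fixes the column order.
#' @return An [intensity_matrix()]. Probes collapsed to missing on some
#'   array appear as `NA` in that column but are retained as rows.
#' @export
assemble_matrix <- function(per_array, metadata) {
  req <- metadata$sample_id
  missing_arr <- setdiff(req, names(per_array))
  if (length(missing_arr))
    stop("no collapsed values supplied for sample(s): ",
         paste(missing_arr, collapse = ", "))
  probes <- names(per_array[[req[1]]])
  for (sid in req[-1]) {
    p2 <- names(per_array[[sid]])
    if (!setequal(probes, p2)) {
      diff <- c(setdiff(probes, p2), setdiff(p2, probes))
      stop("structural error: probe sets differ across arrays; ",
           "symmetric difference: ", paste(diff, collapse = ", "))
    }
  }
  values <- vapply(req, function(sid) per_array[[sid]][probes],
                   numeric(length(probes)))
  rownames(values) <- probes
  intensity_matrix(values, metadata)
}

#' Read, collapse and assemble a directory of Feature-Extraction files
#'
#' Convenience wrapper: reads `metadata.tsv` in `dir` (columns
#' `file_name`, `sample_id`, `cell_type`, `treatment`, `replicate`),
#' parses every listed file, collapses on-chip replicates per array and
#' assembles the probe x sample [intensity_matrix()].
#'
#' @param dir Directory containing the files and `metadata.tsv`.
#' @param params A [collapse_params()] object.
#' @return An [intensity_matrix()] of collapsed linear gPS values.
#' @export
build_intensity_matrix <- function(dir, params = collapse_params()) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path))
    stop("metadata file not found: '", meta_path, "'")
  metadata <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  per_array <- lapply(seq_len(nrow(metadata)), function(i) {
    recs <- read_feature_extraction(file.path(dir, metadata$file_name[i]))
    collapse_array(recs, params)
  })
  names(per_array) <- metadata$sample_id
  assemble_matrix(per_array, metadata[, c("sample_id", "cell_type",
                                          "treatment", "replicate")])
}

#' Write an intensity matrix as TSV
#'
#' Probes as rows, first column `probe_id`, masked cells written as `NA`.
#'
#' @param mat An [intensity_matrix()].
#' @param path Output path.
#' @export
write_intensity_matrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
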