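# Shared fixtures and independent oracles for the test suite.

# Feature-record rows for collapsing tests (vector arguments recycle).
feat <- function(gps, probe = "P1", manual = FALSE, outlier = FALSE,
                 cv = 0.1, control = FALSE) {
  data.frame(probe_id = probe, gene_symbol = probe,
             entrez_id = NA_character_, gps = gps, is_control = control,
             manual_flag = manual, fe_outlier = outlier, pixel_cv = cv,
             stringsAsFactors = FALSE)
}

gm <- function(x) exp(mean(log(x)))

im_from <- function(values, n_rep = ncol(values) / 4) {
  # wrap a bare matrix in an intensity_matrix with a plausible design
  cfg <- sim_config(n_genes = nrow(values), seed = 1,
                    n_bio_replicates = max(1, ncol(values) %/% 4))
  samples <- sim_sample_metadata(cfg)[seq_len(ncol(values)), , drop = FALSE]
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%05d", seq_len(nrow(values)))
  colnames(values) <- samples$sample_id
  intensity_matrix(values, samples)
}

# --- independent oracles (brute force, no shared code with R/) ----------

# Quantile normalization: sort, average order statistics, assign by rank,
# average assigned values over tied inputs. Complete matrices only.
oracle_quantile <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- numeric(nrow(m))
    v[order(m[, j])] <- ref
    for (val in unique(m[, j])) {
      idx <- m[, j] == val
      v[idx] <- mean(v[idx])
    }
    out[, j] <- v
  }
  out
}

# Benjamini-Hochberg step-up, written as the textbook loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  a <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) a[i] <- min(a[i], a[i + 1])
  a <- pmin(a, 1)
  out <- numeric(m)
  out[o] <- a
  out
}

# Moderated t: step-by-step recomputation of the moment-method shrinkage,
# with the trigamma inversion done by uniroot instead of Newton.
oracle_moderated_t <- function(values, treated, control) {
  mt <- values[, treated, drop = FALSE]
  mc <- values[, control, drop = FALSE]
  n1 <- ncol(mt); n2 <- ncol(mc)
  dg <- n1 + n2 - 2
  s2 <- sapply(seq_len(nrow(values)), function(g)
    ((n1 - 1) * var(mt[g, ]) + (n2 - 1) * var(mc[g, ])) / dg)
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  excess <- var(e) - trigamma(dg / 2)
  if (excess > 0) {
    half_d0 <- uniroot(function(y) trigamma(y) - excess,
                       c(1e-8, 1e8), tol = 1e-13)$root
    d0 <- 2 * half_d0
    s0_2 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
    s2_post <- (d0 * s0_2 + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  } else {
    s2_post <- rep(exp(mean(e)), length(s2))
    df_total <- dg * length(s2)
  }
  fc <- rowMeans(mt) - rowMeans(mc)
  t_mod <- fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  list(t_mod = t_mod, df_total = df_total,
       p_raw = 2 * pt(-abs(t_mod), df_total))
}
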