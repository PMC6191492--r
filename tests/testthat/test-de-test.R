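# Fold changes, variance-prior fitting, moderated t, BH, DEG calls.

sim_log2_matrix <- function(n_genes, sd = 0.3, seed = 1, effect = NULL) {
  set.seed(seed)
  cfg <- sim_config(n_genes = n_genes, seed = seed)
  samples <- sim_sample_metadata(cfg)
  v <- matrix(rnorm(n_genes * nrow(samples), 8, sd),
              nrow = n_genes, ncol = nrow(samples),
              dimnames = list(sprintf("G%05d", seq_len(n_genes)),
                              samples$sample_id))
  if (!is.null(effect)) {
    th1 <- samples$treatment == "Th1"
    v[, th1 & samples$cell_type == "astrocyte"] <-
      v[, th1 & samples$cell_type == "astrocyte"] + effect
  }
  intensity_matrix(v, samples)
}

test_that("fold changes are mean differences with replicate-paired columns", {
  cfg <- sim_config(n_genes = 2, seed = 1)
  samples <- sim_sample_metadata(cfg)
  v <- matrix(8, 2, 16, dimnames = list(c("A", "B"), samples$sample_id))
  th1_a <- samples$treatment == "Th1" & samples$cell_type == "astrocyte"
  v[1, th1_a] <- 10
  m <- intensity_matrix(v, samples)
  ct <- make_contrast(samples, "astrocyte")
  fc <- compute_fold_changes(m, ct)
  expect_equal(unname(fc$log2fc), c(2, 0))      # linear FC 4 and identity
  expect_equal(dim(fc$rep_log2fc), c(2L, 4L))
  expect_equal(unname(fc$rep_log2fc[1, ]), rep(2, 4))

  # brute-force recomputation on random data
  m2 <- sim_log2_matrix(30, seed = 6)
  fc2 <- compute_fold_changes(m2, ct)
  manual <- rowMeans(m2$values[, ct$treated_ids]) -
    rowMeans(m2$values[, ct$control_ids])
  expect_equal(fc2$log2fc, manual)
})

test_that("contrast construction validates the design", {
  samples <- sim_sample_metadata(sim_config(n_genes = 1, seed = 1))
  ct <- make_contrast(samples, "microglia")
  expect_length(ct$treated_ids, 4)
  expect_length(intersect(ct$treated_ids, ct$control_ids), 0)
  expect_error(make_contrast(samples, "neuron"), "no samples")
})

test_that("variance prior: homoscedastic data pools fully, single gene falls back", {
  # equal variances -> log-variance spread below sampling noise -> d0 = Inf
  s2 <- rep(0.09, 200)
  pr <- fit_variance_prior(s2, df = 6)
  expect_true(is.infinite(pr$d0))
  # single gene: no prior, ordinary t
  pr1 <- fit_variance_prior(0.2, df = 6)
  expect_equal(pr1$d0, 0)
})

test_that("homoscedastic limit: every gene shares the pooled denominator", {
  set.seed(31)
  m <- sim_log2_matrix(300, sd = 0.3, seed = 31)
  # overwrite with exactly equal per-gene variances is unnatural; instead
  # force the limit through the prior: constant sample variances
  samples <- m$samples
  base <- rnorm(300, 8, 1)
  v <- matrix(base, 300, 16, dimnames = dimnames(m$values))
  dev <- c(-1.5, -0.5, 0.5, 1.5) * 0.1          # same spread in every gene
  shift <- rnorm(300, 0, 0.5)                   # gene-specific true effects
  for (g in 1:300) {
    v[g, samples$treatment == "Th1"] <- base[g] + shift[g] + dev
    v[g, samples$treatment == "medium"] <- base[g] + dev
  }
  mt <- moderated_t_test(intensity_matrix(v, samples),
                         make_contrast(samples, "astrocyte"))
  pr <- attr(mt, "prior")
  expect_true(is.infinite(pr$d0))
  # t is proportional to log2fc with one common standard error
  se <- mt$log2fc / mt$t_mod
  se <- se[is.finite(se)]
  expect_lt(diff(range(se)), 1e-12)
})

test_that("single-gene moderated t equals the ordinary pooled two-sample t", {
  set.seed(41)
  samples <- sim_sample_metadata(sim_config(n_genes = 1, seed = 1))
  v <- matrix(rnorm(16, 8, 0.5), 1, 16,
              dimnames = list("G1", samples$sample_id))
  m <- intensity_matrix(v, samples)
  ct <- make_contrast(samples, "astrocyte")
  res <- moderated_t_test(m, ct)
  tt <- t.test(v[1, ct$treated_ids], v[1, ct$control_ids], var.equal = TRUE)
  expect_equal(res$t_mod, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df_total, unname(tt$parameter))
})

test_that("moderated t matches the independent brute-force oracle", {
  set.seed(51)
  m <- sim_log2_matrix(50, sd = 0.4, seed = 51, effect = 1)
  ct <- make_contrast(m$samples, "astrocyte")
  res <- moderated_t_test(m, ct)
  orc <- oracle_moderated_t(m$values, ct$treated_ids, ct$control_ids)
  expect_equal(res$t_mod, unname(orc$t_mod), tolerance = 1e-10)
  expect_equal(res$df_total, rep(orc$df_total, 50), tolerance = 1e-9)
  expect_equal(res$p_raw, unname(orc$p_raw), tolerance = 1e-10)
})

test_that("moderated t agrees with limma's empirical-Bayes machinery", {
  skip_if_not_installed("limma")
  set.seed(61)
  m <- sim_log2_matrix(400, sd = 0.5, seed = 61, effect = 0.8)
  ct <- make_contrast(m$samples, "astrocyte")
  res <- moderated_t_test(m, ct)

  design <- cbind(1, as.integer(m$samples$treatment == "Th1"))
  sub <- m$values[, c(ct$control_ids, ct$treated_ids)]
  design <- cbind(Intercept = 1, Th1 = rep(c(0, 1), each = 4))
  fit <- limma::eBayes(limma::lmFit(sub, design))
  expect_equal(attr(res, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "prior")$s0_2, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, "Th1"]), tolerance = 1e-6)
  expect_equal(res$p_raw, unname(fit$p.value[, "Th1"]), tolerance = 1e-6)
})

test_that("swapping group labels negates the statistic and preserves p", {
  m <- sim_log2_matrix(60, seed = 71, effect = 0.5)
  a <- moderated_t_test(m, make_contrast(m$samples, "astrocyte"))
  b <- moderated_t_test(m, make_contrast(m$samples, "astrocyte",
                                         treated = "medium", control = "Th1"))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$t_mod, -b$t_mod)
  expect_equal(a$p_raw, b$p_raw)
})

test_that("all-null data controls the raw type-I rate", {
  m <- sim_log2_matrix(2000, sd = 0.3, seed = 81)
  res <- moderated_t_test(m, make_contrast(m$samples, "microglia"))
  frac <- mean(res$p_raw < 0.01)
  se <- sqrt(0.01 * 0.99 / 2000)
  expect_lt(frac, 0.01 + 3 * se)
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "contract")
  set.seed(91)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))    # monotone in raw p
  }
})

test_that("DEG calls apply both gates with the inclusive 2-fold default", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(log2(3), log2(1.9), 1, -1.2),
                    p_raw = c(1e-4, 1e-4, 1e-4, 0.5))
  res$p_adj <- c(0.005, 0.005, 0.001, 0.8)
  called <- call_degs(res)
  expect_equal(called$is_deg, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(called$direction, c("up", "none", "up", "none"))
  # strict mode excludes FC exactly 2
  strict <- call_degs(res, deg_criteria(strict_fc = TRUE))
  expect_false(strict$is_deg[3])
  # split
  res$p_adj[4] <- 0.001
  sp <- deg_split(call_degs(res))
  expect_equal(sp$up$gene_id, c("a", "c"))
  expect_equal(sp$down$gene_id, "d")
})

test_that("invariant: adjusted p never below raw p and calls respect it", {
  m <- sim_log2_matrix(150, seed = 101, effect = 1.5)
  de <- de_analysis(m, "astrocyte")
  expect_true(all(de$p_adj >= de$p_raw - 1e-15))
  expect_true(all(de$p_adj <= 1 & de$p_adj >= 0))
  expect_equal(de$is_deg,
               de$p_adj < 0.01 & abs(de$log2fc) >= 1)
})
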