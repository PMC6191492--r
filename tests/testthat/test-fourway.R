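# Union building, the FC = 1 adjustment, the 3x3 partition, z-scores.

mini_de <- function(ids, lfc, p_adj, deg = NULL) {
  if (is.null(deg)) deg <- p_adj < 0.01 & abs(lfc) >= 1
  data.frame(gene_id = ids, log2fc = lfc, p_adj = p_adj, is_deg = deg,
             stringsAsFactors = FALSE)
}

test_that("the union set is the set union of the two DEG lists", {
  ids <- c("A", "B", "C", "D")
  da <- mini_de(ids, c(2, 2, 0, 0), c(0.001, 0.001, 0.5, 0.5))
  dm <- mini_de(ids, c(0, 2, 2, 0), c(0.5, 0.001, 0.001, 0.5))
  u <- build_union_set(da, dm)
  expect_setequal(u$gene_id, c("A", "B", "C"))

  # empty second set: union equals the first
  dm0 <- mini_de(ids, rep(0, 4), rep(0.9, 4))
  expect_setequal(build_union_set(da, dm0)$gene_id, c("A", "B"))

  # inclusion-exclusion on a simulated run
  set.seed(7)
  n <- 300
  ids2 <- sprintf("g%03d", 1:n)
  da2 <- mini_de(ids2, rnorm(n, 0, 1.5), runif(n)^3)
  dm2 <- mini_de(ids2, rnorm(n, 0, 1.5), runif(n)^3)
  u2 <- build_union_set(da2, dm2)
  expect_equal(nrow(u2),
               sum(da2$is_deg) + sum(dm2$is_deg) -
                 sum(da2$is_deg & dm2$is_deg))

  expect_error(build_union_set(da, mini_de(c("X", "Y"), c(2, 2), c(0.001, 0.001))),
               "disjoint")
})

test_that("non-significant fold changes are adjusted to FC = 1, idempotently", {
  u <- data.frame(gene_id = c("A", "B", "C"),
                  log2fc_astro = c(3, 2, 1.5), p_adj_astro = c(0.001, 0.02, 0.2),
                  log2fc_micro = c(1, -2, NA), p_adj_micro = c(0.2, 0.04, NA))
  adj <- adjust_nonsignificant_fc(u)
  expect_equal(adj$adj_log2fc_astro, c(3, 2, 0))   # p 0.2 > 0.05 zeroed
  expect_equal(adj$adj_log2fc_micro, c(0, -2, 0))  # missing stats zeroed
  expect_false(adj$both_adjusted[1])
  expect_true(adj$both_adjusted[3])
  # boundary: p = 0.05 is kept (rule is "> 0.05")
  u2 <- u; u2$p_adj_astro <- c(0.05, 0.05, 0.05)
  expect_equal(adjust_nonsignificant_fc(u2)$adj_log2fc_astro, u$log2fc_astro)
  # idempotence
  adj2 <- adjust_nonsignificant_fc(adj)
  expect_equal(adj2$adj_log2fc_astro, adj$adj_log2fc_astro)
  expect_equal(adj2$adj_log2fc_micro, adj$adj_log2fc_micro)
})

test_that("the 9-cell map is the full enumeration of direction pairs", {
  g <- expand.grid(a = c(3, 0.5, -3), m = c(2, 0, -2))
  rec <- data.frame(gene_id = sprintf("g%d", 1:9),
                    adj_log2fc_astro = g$a, adj_log2fc_micro = g$m)
  cl <- classify_fourway(rec)
  expect_equal(cl$direction_astro,
               rep(c("up", "unchanged", "down"), 3))
  expect_equal(cl$direction_micro,
               rep(c("up", "unchanged", "down"), each = 3))
  expect_equal(cl$cell9_label[1], "up|up")
  expect_equal(cl$cell9_label[4], "up|unchanged")   # astro-specific up
  expect_equal(cl$cell9_label[7], "up|down")        # discordant

  # sub-threshold pair is unchanged on both axes
  both_small <- classify_fourway(data.frame(gene_id = "x",
                                            adj_log2fc_astro = 0.5,
                                            adj_log2fc_micro = 0.5))
  expect_equal(both_small$cell9_label, "unchanged|unchanged")
  # threshold boundary is inclusive
  at_thr <- classify_fourway(data.frame(gene_id = "y",
                                        adj_log2fc_astro = 1,
                                        adj_log2fc_micro = -1))
  expect_equal(at_thr$cell9_label, "up|down")
})

test_that("four-way counts form a partition and aggregates follow the definitions", {
  set.seed(15)
  n <- 400
  rec <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    adj_log2fc_astro = rnorm(n, 0, 1.5),
                    adj_log2fc_micro = rnorm(n, 0, 1.5))
  cl <- classify_fourway(rec)
  s <- summarize_fourway_counts(cl)
  expect_equal(sum(s$cell9), n)
  expect_equal(s$n_union, n)
  expect_equal(sum(s$percentages[c("common_up", "common_down",
                                   "astro_specific_up", "astro_specific_down",
                                   "micro_specific_up", "micro_specific_down",
                                   "unchanged_both")]) -
                 s$percentages[["discordant"]],
               100)                       # discordant genes counted twice
  m <- s$cell9
  expect_equal(s$aggregates[["astro_specific_up"]],
               m["up", "unchanged"] + m["up", "down"])
  expect_equal(s$aggregates[["micro_specific_down"]],
               m["unchanged", "down"] + m["up", "down"])
  expect_equal(s$aggregates[["discordant"]],
               m["up", "down"] + m["down", "up"])
  expect_equal(nrow(s$scatter), n)

  # a one-class input concentrates the table in one cell
  rec1 <- data.frame(gene_id = c("a", "b"),
                     adj_log2fc_astro = c(2, 3), adj_log2fc_micro = c(2, 3))
  s1 <- summarize_fourway_counts(classify_fourway(rec1))
  expect_equal(sum(s1$cell9 > 0), 1)
  expect_equal(s1$cell9["up", "up"], 2)
})

test_that("regulator z-scores follow the signed-consistency formula", {
  reg <- data.frame(regulator_id = "R1",
                    target_gene = sprintf("t%d", 1:9),
                    sign = rep(1, 9), stringsAsFactors = FALSE)
  obs <- setNames(rep("up", 9), sprintf("t%d", 1:9))
  z <- regulator_activation_zscore(reg, obs)
  expect_equal(z$z, 3)                          # 9/sqrt(9)
  expect_equal(z$predicted_state, "activated")

  # equal consistent and inconsistent targets cancel
  obs2 <- setNames(rep(c("up", "down"), c(4, 4)), sprintf("t%d", 1:8))
  z2 <- regulator_activation_zscore(reg[1:8, ], obs2)
  expect_equal(z2$z, 0)
  expect_equal(z2$predicted_state, "not_significant")

  # z exactly 2 is NOT significant (strict rule)
  obs3 <- setNames(c(rep("up", 4), rep("unchanged", 5)), sprintf("t%d", 1:9))
  z3 <- regulator_activation_zscore(reg, obs3)
  expect_equal(z3$z, 2)
  expect_equal(z3$predicted_state, "not_significant")
  expect_equal(z3$n_consistent, 4)
  expect_equal(z3$n_inconsistent, 0)

  # repression edges: down targets of a repressor are consistent
  reg_neg <- transform(reg, sign = -1)
  z4 <- regulator_activation_zscore(reg_neg, setNames(rep("down", 9),
                                                      sprintf("t%d", 1:9)))
  expect_equal(z4$z, 3)
  expect_equal(z4$predicted_state, "activated")

  # no scored targets: flagged, not significant
  z5 <- regulator_activation_zscore(reg, setNames(rep("unchanged", 9),
                                                  sprintf("t%d", 1:9)))
  expect_true(is.na(z5$z))
  expect_true(z5$no_scored_targets)
  expect_equal(z5$predicted_state, "not_significant")

  expect_error(regulator_activation_zscore(reg[0, ], obs), "empty")
  expect_error(regulator_activation_zscore(transform(reg, sign = 2), obs),
               "sign")
})

test_that("flipping all observed directions negates the z-score", {
  set.seed(29)
  reg <- data.frame(regulator_id = rep(c("R1", "R2"), each = 20),
                    target_gene = sprintf("t%d", 1:40),
                    sign = sample(c(-1, 1), 40, replace = TRUE),
                    stringsAsFactors = FALSE)
  obs <- setNames(sample(c("up", "down", "unchanged"), 40, replace = TRUE),
                  sprintf("t%d", 1:40))
  flip <- c(up = "down", down = "up", unchanged = "unchanged")[obs]
  names(flip) <- names(obs)
  z1 <- regulator_activation_zscore(reg, obs)
  z2 <- regulator_activation_zscore(reg, flip)
  expect_equal(z1$z, -z2$z)
})
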