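test_that("bonferroni_threshold divides exactly and reproduces 0.008", {
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(bonferroni_threshold(0.05, 6, digits = 3), 0.008)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "m must")
  expect_error(bonferroni_threshold(1.2, 6), "family_alpha")
})

test_that("block ANOVA decomposes additively and degenerates correctly", {
  donors <- sprintf("d%d", 1:4)
  conds <- nk_conditions()
  # exactly additive data: block + treatment, zero residual
  vals <- array(0, dim = c(2, 4, 4),
                dimnames = list(c("g1", "g2"), donors, conds))
  block_eff <- c(0, 1, 2, 3); trt_eff <- c(0, 2, 4, 8)
  for (d in 1:4) for (k in 1:4) {
    vals[, d, k] <- 2^(5 + block_eff[d] + trt_eff[k])
  }
  st <- study_from_array(vals)
  fit <- fit_block_anova(st)
  expect_equal(fit$ss_error, c(g1 = 0, g2 = 0), tolerance = 1e-18)
  expect_equal(fit$mse, c(g1 = 0, g2 = 0))
  expect_equal(fit$df_error, 9L)

  # constant input: every SS component zero
  vals[] <- 64
  fit0 <- fit_block_anova(study_from_array(vals))
  expect_equal(unname(fit0$ss_block + fit0$ss_treatment + fit0$ss_error),
               c(0, 0))

  # incomplete design errors name the missing cell
  d <- st$design[-1, ]
  m <- st$intensities[, -1]
  expect_error(fit_block_anova(expression_study(m, d)), "d1:medium")
})

test_that("fit and contrasts match an explicit least-squares oracle", {
  set.seed(42)
  donors <- sprintf("d%d", 1:8); conds <- nk_conditions()
  vals <- array(2^rnorm(5 * 8 * 4, 8, 1), dim = c(5, 8, 4),
                dimnames = list(sprintf("g%d", 1:5), donors, conds))
  st <- study_from_array(vals)
  fit <- fit_block_anova(st)
  pairs <- list(c("IgG", "medium"), c("IgG_IL12", "IL12"),
                c("IL12", "medium"))
  for (g in 1:5) {
    y <- log2(st$intensities[g, ])
    ofit <- oracle_block_fit(y, st$design$donor, st$design$condition)
    expect_equal(unname(fit$mse[g]),
                 sum(resid(ofit)^2) / ofit$df.residual, tolerance = 1e-10)
    for (pr in pairs) {
      oc <- oracle_contrast(ofit, pr[1], pr[2])
      ct <- contrast_test(fit, pr)
      expect_equal(ct$estimate[g], oc$estimate, tolerance = 1e-10)
      expect_equal(ct$t[g], oc$t, tolerance = 1e-10)
      expect_equal(ct$p[g], oc$p, tolerance = 1e-10)
    }
  }
})

test_that("contrast_test honours the degenerate MSE conventions", {
  donors <- sprintf("d%d", 1:4); conds <- nk_conditions()
  set.seed(8)
  vals <- array(2^rnorm(1 * 4 * 4, 8, 0.5), dim = c(1, 4, 4),
                dimnames = list("g1", donors, conds))
  # force identical IgG and medium columns: estimate exactly 0, p = 1 ... no:
  # p = 1 requires t = 0, which identical cell means deliver exactly
  vals[, , "IgG"] <- vals[, , "medium"]
  st <- study_from_array(vals)
  fit <- fit_block_anova(st)
  ct <- contrast_test(fit, c("IgG", "medium"))
  expect_gt(fit$mse[1], 0)
  expect_equal(ct$estimate, 0)
  expect_equal(ct$p, 1)

  # noiseless planted difference: MSE = 0 convention gives p = 0
  for (d in 1:4) for (k in 1:4) vals[, d, k] <- 2^(5 + (k == 2) * 1)
  fit2 <- fit_block_anova(study_from_array(vals))
  ct2 <- contrast_test(fit2, c("IgG", "medium"))
  expect_equal(ct2$p, 0)
  expect_true(is.infinite(ct2$t))
  ct3 <- contrast_test(fit2, c("IL12", "medium"))
  expect_equal(ct3$p, 1)

  expect_error(contrast_test(fit2, c("IgG", "nothere")), "unknown condition")
})

test_that("fold-change statistics are per-block medians on the linear scale", {
  donors <- sprintf("d%d", 1:8); conds <- nk_conditions()
  set.seed(13)
  base <- matrix(2^rnorm(8, 8, 0.5), nrow = 1)
  vals <- array(NA_real_, dim = c(1, 8, 4),
                dimnames = list("g1", donors, conds))
  vals[, , "medium"] <- base
  vals[, , "IgG"] <- 3 * base        # constant ratio 3
  vals[, , "IL12"] <- base           # identity
  vals[, , "IgG_IL12"] <- base * 2^rnorm(8, 1, 0.7)
  st <- study_from_array(vals)
  expect_equal(fold_change_stats(st, c("IgG", "medium"))$median_fc, 3,
               tolerance = 1e-12)
  id <- fold_change_stats(st, c("IL12", "medium"))
  expect_equal(id$median_fc, 1)
  expect_equal(id$median_abs_diff, 0)
  # sort-based order-statistic oracle for the even-count median
  fc <- vals[, , "IgG_IL12"] / vals[, , "medium"]
  dd <- abs(vals[, , "IgG_IL12"] - vals[, , "medium"])
  med <- function(x) mean(sort(x)[4:5])
  got <- fold_change_stats(st, c("IgG_IL12", "medium"))
  expect_equal(got$median_fc, med(fc), tolerance = 1e-12)
  expect_equal(got$median_abs_diff, med(dd), tolerance = 1e-12)
  expect_error(fold_change_stats(st, c("IgG", "gone")), "unknown condition")
})

test_that("the triple filter requires all three conditions simultaneously", {
  donors <- sprintf("d%d", 1:8); conds <- nk_conditions()
  set.seed(17)
  vals <- array(2^rnorm(3 * 8 * 4, 8, 0.05), dim = c(3, 8, 4),
                dimnames = list(c("low_base", "big", "null"), donors, conds))
  # 3-fold ratio but baseline 10 vs 30: diff = 20 < 150 fails the diff filter
  vals["low_base", , "medium"] <- 10
  vals["low_base", , "IgG_IL12"] <- 30
  # clear change passing everything
  vals["big", , "medium"] <- 400
  vals["big", , "IgG_IL12"] <- 400 * 3 * 2^rnorm(8, 0, 0.05)
  st <- study_from_array(vals)
  ct <- call_differential_genes(st)
  row <- function(g) ct[ct$gene == g & ct$contrast == "IgG_IL12_vs_medium", ]
  lb <- row("low_base")
  expect_true(lb$pass_p && lb$pass_fc && !lb$pass_diff)
  expect_false(lb$significant)
  expect_equal(lb$direction, "none")
  bg <- row("big")
  expect_true(bg$significant)
  expect_equal(bg$direction, "up")
  # significant rows always satisfy all three flags
  expect_true(all(ct$significant == (ct$pass_p & ct$pass_fc & ct$pass_diff)))
  # 6 contrasts per gene, 3 primary
  expect_equal(nrow(ct), 3 * 6)
  expect_equal(sum(ct$primary), 3 * 3)
})

test_that("contrasts are antisymmetric and scale-equivariant", {
  set.seed(23)
  sim <- simulate_expression(simulation_config(n_genes = 30, seed = 23))
  st <- collapse_replicates(sim$study)
  fit <- fit_block_anova(st)
  f <- contrast_test(fit, c("IgG", "medium"))
  r <- contrast_test(fit, c("medium", "IgG"))
  expect_equal(f$estimate, -r$estimate)
  expect_equal(f$t, -r$t)
  expect_equal(f$p, r$p)
  ffc <- fold_change_stats(st, c("IgG", "medium"))
  rfc <- fold_change_stats(st, c("medium", "IgG"))
  expect_equal(ffc$median_abs_diff, rfc$median_abs_diff)
  # exact reciprocity of the median fold change needs an odd block count
  # (an even count averages the two central order statistics)
  st7 <- expression_study(
    st$intensities[, st$design$donor != "donor_8"],
    st$design[st$design$donor != "donor_8", ])
  f7 <- fold_change_stats(st7, c("IgG", "medium"))
  r7 <- fold_change_stats(st7, c("medium", "IgG"))
  expect_equal(f7$median_fc, 1 / r7$median_fc, tolerance = 1e-12)

  # multiply all intensities by c > 0
  st2 <- expression_study(st$intensities * 3.7, st$design, floor = -Inf)
  fit2 <- fit_block_anova(st2)
  f2 <- contrast_test(fit2, c("IgG", "medium"))
  expect_equal(f2$t, f$t, tolerance = 1e-9)
  expect_equal(f2$p, f$p, tolerance = 1e-9)
  fc2 <- fold_change_stats(st2, c("IgG", "medium"))
  expect_equal(fc2$median_fc, ffc$median_fc, tolerance = 1e-12)
  expect_equal(fc2$median_abs_diff, 3.7 * ffc$median_abs_diff,
               tolerance = 1e-12)
})

test_that("planted and null genes are called correctly at small scale", {
  classes <- data.frame(class = "combo_unique_up", n = 25, e_medium = 0,
                        e_IgG = 0, e_IL12 = 0, e_IgG_IL12 = log2(3))
  cfg <- simulation_config(n_genes = 100, effect_classes = classes,
                           baseline_log2_sd = 0.5, seed = 77)
  sim <- simulate_expression(cfg)
  ct <- call_differential_genes(sim$study)
  planted <- sim$truth$gene[sim$truth$class == "combo_unique_up"]
  hits <- significant_genes(ct, "IgG_IL12_vs_medium", "up")
  expect_gte(length(intersect(hits, planted)), 24)
  # planted genes stay silent in the IgG and IL12 primary comparisons
  expect_length(intersect(significant_genes(ct, "IgG_vs_medium"), planted), 0)
  expect_length(intersect(significant_genes(ct, "IL12_vs_medium"), planted), 0)
})
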