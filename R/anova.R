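#' Per-contrast Bonferroni threshold
#'
#' With six pairwise contrasts among the four stimulation conditions and a
#' family-wise level of 0.05, the exact per-contrast cutoff is 0.05/6; the
#' pipeline's default cutoff is that value rounded to three decimals (0.008)
#' for reproducibility of published gene lists.
#'
#' @param family_alpha family-wise error level in (0, 1) (default 0.05).
#' @param m number of contrasts (default 6).
#' @param digits if non-NULL, round the quotient to this many decimals.
#' @return The per-contrast threshold.
#' @export
bonferroni_threshold <- function(family_alpha = 0.05, m = 6L, digits = NULL) {
  if (!is.numeric(family_alpha) || family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || m < 1) stop("m must be a count >= 1", call. = FALSE)
  out <- family_alpha / m
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Differential-expression thresholds
#'
#' The triple filter: per-contrast p-value below the Bonferroni cutoff,
#' median per-subject fold change beyond `fc_threshold` (or below its
#' reciprocal for down-regulation), and median absolute intensity difference
#' above `diff_threshold`.
#'
#' @param alpha_per_contrast p cutoff (default 0.008, i.e. 0.05/6 rounded to
#'   3 decimals).
#' @param fc_threshold fold-change cutoff (default 2).
#' @param diff_threshold intensity-difference cutoff in linear intensity
#'   units (default 150).
#' @param m_contrasts number of contrasts for the Bonferroni family
#'   (default 6).
#' @param family_alpha family-wise level (default 0.05).
#' @return list of class `de_thresholds`.
#' @export
de_thresholds <- function(alpha_per_contrast = 0.008, fc_threshold = 2,
                          diff_threshold = 150, m_contrasts = 6L,
                          family_alpha = 0.05) {
  if (any(c(alpha_per_contrast, fc_threshold, diff_threshold) <= 0)) {
    stop("all thresholds must be > 0", call. = FALSE)
  }
  if (alpha_per_contrast > family_alpha) {
    stop("alpha_per_contrast must not exceed family_alpha", call. = FALSE)
  }
  structure(list(alpha_per_contrast = alpha_per_contrast,
                 fc_threshold = fc_threshold,
                 diff_threshold = diff_threshold,
                 m_contrasts = as.integer(m_contrasts),
                 family_alpha = family_alpha),
            class = "de_thresholds")
}

#' Fit the per-gene randomized complete block ANOVA
#'
#' Fits, for every gene simultaneously, the additive block-treatment model
#' (donors as blocks, stimulation conditions as treatments, no interaction)
#' on log2 intensities: SS_total = SS_block + SS_treatment + SS_error with
#' df_error = (b-1)(k-1). The balanced complete design makes the
#' least-squares solution the closed-form decomposition over cell, block and
#' grand means.
#'
#' @param study a replicate-collapsed `expression_study` (exactly one sample
#'   per donor x condition).
#' @param log2_transform fit on log2 intensities (default TRUE; the
#'   fold-change and difference filters always use the linear scale
#'   regardless).
#' @return object of class `block_anova_fit`: list with `genes`,
#'   `conditions`, `donors`, `cell_means` (gene x condition), `block_means`
#'   (gene x donor), `grand_mean`, `ss_block`, `ss_treatment`, `ss_error`,
#'   `mse`, `df_error`, `b`, `k`.
#' @export
fit_block_anova <- function(study, log2_transform = TRUE) {
  d <- study$design
  check_complete_design(study)
  cell <- paste(d$donor, d$condition)
  if (anyDuplicated(cell)) {
    dup <- unique(cell[duplicated(cell)])
    stop("design has replicated cell(s) (collapse replicates first): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  conds <- intersect(nk_conditions(), unique(d$condition))
  donors <- unique(d$donor)
  b <- length(donors); k <- length(conds)
  if (b < 2L || k < 2L) stop("need at least 2 blocks and 2 treatments",
                             call. = FALSE)
  y <- study$intensities
  if (log2_transform) y <- log2(y)

  cond_ind <- outer(d$condition, conds, "==") * 1
  donor_ind <- outer(d$donor, donors, "==") * 1
  cell_means <- (y %*% cond_ind) / b
  block_means <- (y %*% donor_ind) / k
  colnames(cell_means) <- conds
  colnames(block_means) <- donors
  grand <- rowMeans(y)

  # fitted value for sample in (donor d, condition c):
  # block_mean_d + cell_mean_c - grand
  fitted <- block_means[, match(d$donor, donors), drop = FALSE] +
    cell_means[, match(d$condition, conds), drop = FALSE] - grand
  resid <- y - fitted
  ss_error <- rowSums(resid^2)
  ss_block <- k * rowSums((block_means - grand)^2)
  ss_treatment <- b * rowSums((cell_means - grand)^2)
  df_error <- (b - 1L) * (k - 1L)
  structure(list(genes = rownames(y), conditions = conds, donors = donors,
                 cell_means = cell_means, block_means = block_means,
                 grand_mean = grand, ss_block = ss_block,
                 ss_treatment = ss_treatment, ss_error = ss_error,
                 mse = ss_error / df_error, df_error = df_error,
                 b = b, k = k, log2_transform = log2_transform),
            class = "block_anova_fit")
}

#' Cell-mean comparison contrast
#'
#' Tests the difference between two treatment cell means with the model's
#' pooled error variance: estimate = ybar_j - ybar_j', SE = sqrt(2 MSE / b),
#' t = estimate/SE, two-sided p from Student's t on (b-1)(k-1) df. When
#' MSE = 0 (noiseless fixtures) the degenerate convention p = 0 for a
#' non-zero estimate, p = 1 otherwise, is used.
#'
#' @param fit a `block_anova_fit`.
#' @param pair character vector `c(treatment, reference)` naming two
#'   conditions in the fit.
#' @return data.frame with columns `gene`, `estimate`, `t`, `p`.
#' @export
contrast_test <- function(fit, pair) {
  stopifnot(inherits(fit, "block_anova_fit"), length(pair) == 2L)
  bad <- setdiff(pair, fit$conditions)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  est <- fit$cell_means[, pair[1L]] - fit$cell_means[, pair[2L]]
  se <- sqrt(2 * fit$mse / fit$b)
  t <- est / se
  p <- 2 * stats::pt(-abs(t), df = fit$df_error)
  zero_mse <- fit$mse == 0
  if (any(zero_mse)) {
    t[zero_mse] <- ifelse(est[zero_mse] == 0, 0, sign(est[zero_mse]) * Inf)
    p[zero_mse] <- ifelse(est[zero_mse] == 0, 1, 0)
  }
  data.frame(gene = fit$genes, estimate = unname(est), t = unname(t),
             p = unname(p), stringsAsFactors = FALSE)
}

#' Per-subject fold-change and intensity-difference summaries
#'
#' For each gene and block (donor), forms the linear-scale intensity ratio
#' treatment/reference and the absolute intensity difference, then takes the
#' median over blocks of each (even block counts average the two central
#' order statistics).
#'
#' @param study a replicate-collapsed `expression_study`.
#' @param pair `c(treatment, reference)` condition pair.
#' @return data.frame with columns `gene`, `median_fc`, `median_abs_diff`.
#' @export
fold_change_stats <- function(study, pair) {
  stopifnot(length(pair) == 2L)
  d <- study$design
  bad <- setdiff(pair, unique(d$condition))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  donors <- unique(d$donor)
  idx_t <- match(paste(donors, pair[1L]), paste(d$donor, d$condition))
  idx_r <- match(paste(donors, pair[2L]), paste(d$donor, d$condition))
  if (anyNA(idx_t) || anyNA(idx_r)) {
    miss <- donors[is.na(idx_t) | is.na(idx_r)]
    stop("missing (donor, condition) cell(s) for donors: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  yt <- study$intensities[, idx_t, drop = FALSE]
  yr <- study$intensities[, idx_r, drop = FALSE]
  data.frame(gene = rownames(study$intensities),
             median_fc = row_medians(yt / yr),
             median_abs_diff = row_medians(abs(yt - yr)),
             stringsAsFactors = FALSE)
}

# the 6 unordered condition pairs, oriented (treatment, reference) with the
# reference earlier in the canonical condition order
contrast_pairs <- function(conditions = nk_conditions()) {
  cmb <- utils::combn(conditions, 2L)
  data.frame(treatment = cmb[2L, ], reference = cmb[1L, ],
             contrast = paste0(cmb[2L, ], "_vs_", cmb[1L, ]),
             primary = cmb[1L, ] == "medium",
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes with the triple filter
#'
#' Runs the block ANOVA, tests all six pairwise cell-mean contrasts, computes
#' the per-subject median fold change and median absolute difference on the
#' linear scale, and applies the triple filter: a gene is significant for a
#' contrast iff p < `alpha_per_contrast` AND (median_fc > `fc_threshold` OR
#' median_fc < 1/`fc_threshold`) AND median_abs_diff > `diff_threshold` (all
#' strict). Direction is `up` when median_fc > `fc_threshold`, `down` when
#' median_fc < 1/`fc_threshold`, else `none`. The three vs-medium contrasts
#' are flagged `primary`.
#'
#' @param study an `expression_study`; replicates are collapsed by mean if
#'   present.
#' @param thresholds a [de_thresholds()].
#' @param log2_transform passed to [fit_block_anova()].
#' @return data.frame of class `contrast_table`, one row per gene x contrast,
#'   with columns `gene`, `contrast`, `treatment`, `reference`, `primary`,
#'   `estimate`, `t`, `p`, `median_fc`, `median_abs_diff`, `pass_p`,
#'   `pass_fc`, `pass_diff`, `significant`, `direction`.
#' @export
call_differential_genes <- function(study, thresholds = de_thresholds(),
                                    log2_transform = TRUE) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  if (any(duplicated(paste(study$design$donor, study$design$condition)))) {
    study <- collapse_replicates(study)
  }
  fit <- fit_block_anova(study, log2_transform = log2_transform)
  pairs <- contrast_pairs(fit$conditions)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- c(pairs$treatment[i], pairs$reference[i])
    ct <- contrast_test(fit, pr)
    fc <- fold_change_stats(study, pr)
    stopifnot(identical(ct$gene, fc$gene))
    df <- cbind(ct[, "gene", drop = FALSE],
                contrast = pairs$contrast[i], treatment = pairs$treatment[i],
                reference = pairs$reference[i], primary = pairs$primary[i],
                ct[, c("estimate", "t", "p")],
                fc[, c("median_fc", "median_abs_diff")])
    df$pass_p <- df$p < thresholds$alpha_per_contrast
    df$pass_fc <- df$median_fc > thresholds$fc_threshold |
      df$median_fc < 1 / thresholds$fc_threshold
    df$pass_diff <- df$median_abs_diff > thresholds$diff_threshold
    df$significant <- df$pass_p & df$pass_fc & df$pass_diff
    df$direction <- ifelse(!df$significant, "none",
                           ifelse(df$median_fc > thresholds$fc_threshold,
                                  "up", "down"))
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "thresholds") <- thresholds
  class(res) <- c("contrast_table", "data.frame")
  res
}

#' Significant genes for one comparison and direction
#'
#' @param table a `contrast_table`.
#' @param contrast contrast label, e.g. `"IgG_IL12_vs_medium"`.
#' @param direction `"up"`, `"down"`, or `"any"`.
#' @return Character vector of gene ids.
#' @export
significant_genes <- function(table, contrast,
                              direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  rows <- table$contrast == contrast & table$significant
  if (direction != "any") rows <- rows & table$direction == direction
  sort(unique(table$gene[rows]))
}
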