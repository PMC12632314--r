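# Statistics harness: Shapiro-Wilk-gated paired/unpaired tests with the
# matching effect size (Hedge's g or rank-biserial), BH-FDR across families,
# and a Levene-gated classic/Welch ANOVA with Tukey HSD post-hocs. All
# underlying tests delegate to stats/car; the harness contributes the gating
# and the bookkeeping.

hedges_g_paired <- function(d) {
  df <- length(d) - 1
  j <- 1 - 3 / (4 * df - 1)
  j * mean(d) / sd(d)
}

hedges_g_unpaired <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  df <- na + nb - 2
  j <- 1 - 3 / (4 * df - 1)
  j * (mean(a) - mean(b)) / sp
}

#' Normality-gated two-sample comparison
#'
#' Paired design: a Shapiro-Wilk test on the paired differences gates the
#' choice between a paired t-test (with Hedge's g on the differences,
#' small-sample correction `J = 1 - 3/(4 df - 1)`) and a Wilcoxon
#' signed-rank test (with matched-pairs rank-biserial correlation).
#' Unpaired design: Shapiro-Wilk on each group gates a Welch t-test
#' (Hedge's g, pooled sd) versus a Mann-Whitney U test (rank-biserial
#' `1 - 2U/(n1 n2)`). The gate passes when every Shapiro p-value exceeds
#' 0.05. Two-tailed throughout.
#'
#' @param a,b numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return List of class `paired_result`: `test_name`, `statistic`,
#'   `p_value`, `effect_size`, `effect_method`, `n`, `shapiro_p`.
#' @export
paired_compare <- function(a, b, paired = TRUE) {
  if (paired && length(a) != length(b))
    stop("paired design requires equal lengths")
  if (min(length(a), length(b)) < 3) stop("need n >= 3 per sample")
  if (paired) {
    d <- a - b
    sw <- if (sd(d) == 0) list(p.value = 1) else shapiro.test(d)
    if (sw$p.value > 0.05) {
      if (sd(d) == 0) {
        res <- list(statistic = 0, p.value = 1)
        test <- "paired_ttest"; eff <- 0; em <- "hedges_g"
      } else {
        ht <- t.test(a, b, paired = TRUE)
        res <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
        test <- "paired_ttest"; eff <- hedges_g_paired(d); em <- "hedges_g"
      }
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
      nz <- sum(d != 0)
      s_tot <- nz * (nz + 1) / 2
      w_plus <- unname(ht$statistic)
      eff <- if (s_tot > 0) (2 * w_plus - s_tot) / s_tot else 0
      res <- list(statistic = w_plus, p.value = ht$p.value)
      test <- "wilcoxon_signed_rank"; em <- "rank_biserial"
    }
    n <- length(a); swp <- sw$p.value
  } else {
    sw_a <- shapiro.test(a); sw_b <- shapiro.test(b)
    swp <- min(sw_a$p.value, sw_b$p.value)
    if (swp > 0.05) {
      ht <- t.test(a, b)
      res <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      test <- "unpaired_ttest"; eff <- hedges_g_unpaired(a, b); em <- "hedges_g"
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      u <- unname(ht$statistic)
      eff <- 1 - 2 * u / (length(a) * length(b))
      res <- list(statistic = u, p.value = ht$p.value)
      test <- "mann_whitney_u"; em <- "rank_biserial"
    }
    n <- c(length(a), length(b))
  }
  structure(list(test_name = test, statistic = res$statistic,
                 p_value = res$p.value, effect_size = eff,
                 effect_method = em, n = n, shapiro_p = swp),
            class = "paired_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH across a family of p-values (e.g. per channel or frequency
#' bin), with the standard monotonicity enforcement.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Variance-gated multi-group comparison
#'
#' Levene's test gates a classic one-way ANOVA (homoscedastic) versus
#' Welch's ANOVA; a significant omnibus is followed by Tukey HSD pairwise
#' contrasts. Partial eta-squared is reported from the classic decomposition.
#'
#' @param values numeric outcome.
#' @param groups factor (>= 3 levels, each n >= 3).
#' @return List of class `multigroup_result`: `omnibus` (test, statistic,
#'   p_value, effect `partial_eta_sq`, levene_p), `posthoc` (Tukey table as a
#'   data frame, `NULL` when the omnibus is not significant).
#' @export
multigroup_compare <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 3) stop("need at least 3 groups")
  if (any(table(groups) < 3)) stop("each group needs n >= 3")
  lev <- car::leveneTest(values ~ groups)
  lev_p <- lev[["Pr(>F)"]][1]
  fit <- aov(values ~ groups)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  eta <- ss[1] / sum(ss)
  if (lev_p > 0.05) {
    sm <- summary(fit)[[1]]
    stat <- sm[["F value"]][1]; p <- sm[["Pr(>F)"]][1]
    test <- "oneway_anova"
  } else {
    wt <- oneway.test(values ~ groups, var.equal = FALSE)
    stat <- unname(wt$statistic); p <- wt$p.value
    test <- "welch_anova"
  }
  posthoc <- NULL
  if (p < 0.05) {
    tk <- TukeyHSD(fit)$groups
    posthoc <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL)
  }
  structure(list(omnibus = list(test = test, statistic = stat, p_value = p,
                                partial_eta_sq = eta, levene_p = lev_p),
                 posthoc = posthoc),
            class = "multigroup_result")
}
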