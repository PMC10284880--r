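#' Repeated-measures factorial ANOVA on cohort synchrony
#'
#' The population-level factorial model: a repeated-measures ANOVA with two
#' within-subject factors, effector (vocal tract vs. hands) and stimulus
#' (speech vs. tones), and synchrony group as the between-subjects factor;
#' optionally gender as a second between-subjects factor and years of
#' musical training as a covariate. Uses type-III sums of squares (the
#' between design is unbalanced: group sizes differ) with sum-to-zero
#' contrasts, via the multivariate-model route of `car::Anova`; the
#' univariate (sphericity-assuming) table is reported - with two levels per
#' within factor sphericity holds trivially.
#'
#' @param records cohort records: a `sync_cohort`, or a data frame with the
#'   four `plv_*` columns plus grouping columns.
#' @param group name of the between-subjects group column.
#' @param gender optional name of a second between-subjects factor column.
#' @param covariate optional name of a numeric covariate column (e.g.
#'   years of musical training).
#' @return an object of class `sync_anova`: data frame `effects` with
#'   columns effect, F, df1, df2, p, and the fitted `lm` as attribute.
#' @export
rm_anova <- function(records, group = "true_group", gender = NULL,
                     covariate = NULL) {
  rec <- if (inherits(records, "sync_cohort")) records$records else records
  keys <- paste0("plv_", condition_grid()$key)
  missing_cols <- setdiff(c(keys, group, gender, covariate), names(rec))
  if (length(missing_cols))
    stop_invalid("records are missing columns: ",
                 paste(missing_cols, collapse = ", "))
  if (any(!stats::complete.cases(rec[keys])))
    stop_invalid("participant ",
                 paste(which(!stats::complete.cases(rec[keys])), collapse = ","),
                 " has missing synchrony cells")
  Y <- as.matrix(rec[keys])
  g <- factor(rec[[group]])
  if (any(table(g) < 2)) stop_invalid("each group needs >= 2 participants")
  idata <- data.frame(
    effector = factor(c("vocal_tract", "hands", "vocal_tract", "hands")),
    stimulus = factor(c("speech", "speech", "tones", "tones")))
  dat <- data.frame(g = g)
  rhs <- "g"
  contr <- list(g = "contr.sum")
  if (!is.null(gender)) {
    dat$gender <- factor(rec[[gender]])
    rhs <- "g * gender"
    contr$gender <- "contr.sum"
  }
  if (!is.null(covariate)) {
    dat$covar <- as.numeric(rec[[covariate]])
    rhs <- paste(rhs, "+ covar")
  }
  mod <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = dat,
                   contrasts = contr)
  aov_res <- car::Anova(mod, idata = idata, idesign = ~ effector * stimulus,
                        type = 3)
  # sphericity corrections are vacuous with two-level within factors; car
  # warns when the error SSP is singular enough that it skips them
  tab <- suppressWarnings(
    summary(aov_res, multivariate = FALSE))$univariate.tests
  rename_term <- function(nm) {
    toks <- strsplit(nm, ":", fixed = TRUE)[[1]]
    toks[toks == "g"] <- "Group"
    toks[toks == "covar"] <- covariate %||% "covar"
    paste(toks, collapse = ":")
  }
  out <- data.frame(
    effect = vapply(rownames(tab), rename_term, character(1)),
    ss = tab[, "Sum Sq"],
    F = tab[, "F value"],
    df1 = tab[, "num Df"],
    df2 = tab[, "den Df"],
    p = tab[, "Pr(>F)"],
    row.names = NULL)
  out <- out[out$effect != "(Intercept)", ]
  structure(list(effects = out, model = mod),
            class = "sync_anova")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sync_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (type III):\n")
  eff <- x$effects
  eff$F <- round(eff$F, 3)
  eff$p <- signif(eff$p, 3)
  print(eff[c("effect", "F", "df1", "df2", "p")], row.names = FALSE)
  invisible(x)
}

#' Paired post-hoc contrast with Bonferroni correction
#'
#' Two-tailed paired Student's t-test between two repeated measurements of
#' the same participants, with the p-value scaled by the number of
#' comparisons in the post-hoc family (capped at 1).
#'
#' @param x,y paired observations (equal length, same participants).
#' @param n_comparisons size of the comparison family.
#' @return data frame row: contrast `t`, `df`, `p_raw`, `p_bonferroni`,
#'   `mean_diff`.
#' @export
posthoc_paired <- function(x, y, n_comparisons = 1) {
  if (length(x) != length(y) || length(x) < 2)
    stop_invalid("paired contrast needs >= 2 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    return(data.frame(t = tt, df = length(d) - 1, p_raw = p,
                      p_bonferroni = min(1, p * n_comparisons),
                      mean_diff = mean(d)))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p_raw = ht$p.value,
             p_bonferroni = min(1, ht$p.value * n_comparisons),
             mean_diff = mean(d))
}

#' Nonparametric circular comparison of two lag samples
#'
#' Permutation test for a common mean direction: the statistic is the
#' circular distance between the two samples' mean directions; group labels
#' are permuted (seeded) to build the null.
#'
#' @param lags_a,lags_b phase-lag samples in degrees (each n >= 5).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `statistic` (degrees), `p`, `mean_a`, `mean_b`.
#' @export
circular_group_compare <- function(lags_a, lags_b, n_perm = 10000, seed = 1) {
  if (length(lags_a) < 5 || length(lags_b) < 5)
    stop_invalid("each sample needs >= 5 angles")
  pooled <- c(lags_a, lags_b)
  if (max(circ_dist_deg(pooled, pooled[1])) < 1e-12)
    stop_invalid("degenerate data: all angles identical")
  n_a <- length(lags_a)
  stat <- circ_dist_deg(circ_mean_deg(lags_a), circ_mean_deg(lags_b))
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n_a)
      circ_dist_deg(circ_mean_deg(pooled[idx]), circ_mean_deg(pooled[-idx]))
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= stat)) / (1 + n_perm)
  list(statistic = stat, p = p,
       mean_a = circ_mean_deg(lags_a), mean_b = circ_mean_deg(lags_b))
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric two-sided test of association (e.g. synchrony group
#' vs. gender). The odds ratio is the sample cross-product ratio, with a
#' 0.5 continuity correction applied to the odds ratio only when the table
#' contains a zero cell.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` and `p`.
#' @examples
#' fisher_exact_2x2(matrix(c(12, 9, 15, 15), 2, byrow = TRUE))$p # ~0.777
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab)) || !all(is.finite(tab)))
    stop_invalid("table must be a 2x2 matrix of non-negative integers")
  p <- stats::fisher.test(tab)$p.value
  if (any(tab == 0)) tab <- tab + 0.5
  list(odds_ratio = unname(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])),
       p = p)
}

#' Independent-samples Student's t-test
#'
#' Pooled-variance two-sample two-tailed t-test (e.g. years of musical
#' training between synchrony groups). Identical samples with zero pooled
#' variance return t = 0, p = 1.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
independent_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("each sample needs >= 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                mean_a = mean(a), mean_b = mean(b)))
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_a = mean(a), mean_b = mean(b))
}
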