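test_that("BIC selects two clusters for separated blobs, one for a blob", {
  set.seed(2)
  blob2 <- rbind(matrix(stats::rnorm(100, 0, 0.5), 25, 4),
                 matrix(stats::rnorm(100, 4, 0.5), 25, 4))
  cl2 <- select_clusters_bic(blob2, k_max = 5)
  expect_equal(cl2$n_clusters, 2L)
  truth <- rep(c(2L, 1L), each = 25) # second blob has the larger mean
  expect_gte(mean(cl2$labels == truth), 0.95)
  expect_true(cl2$r_squared >= 0 && cl2$r_squared <= 1)
  expect_equal(cl2$n_clusters,
               as.integer(names(which.min(cl2$bic_by_k))))

  blob1 <- matrix(stats::rnorm(200), 50, 4)
  expect_equal(select_clusters_bic(blob1, k_max = 5)$n_clusters, 1L)
})

test_that("BIC selection is consistent across replicated 4-sigma mixtures", {
  set.seed(33)
  hits <- vapply(1:60, function(i) {
    X <- rbind(matrix(stats::rnorm(60, 0, 1), 15, 4),
               matrix(stats::rnorm(60, 4, 1), 15, 4))
    select_clusters_bic(X, k_max = 4)$n_clusters == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate zero-variance data fall back to a single cluster", {
  X <- matrix(0.5, 20, 4)
  expect_warning(cl <- select_clusters_bic(X, k_max = 3), "degenerate")
  expect_equal(cl$n_clusters, 1L)
  expect_error(select_clusters_bic(matrix(NA_real_, 20, 4)), "finite")
})

test_that("random-forest proximity mode recovers the two-group structure", {
  skip_if_not_installed("randomForest")
  skip_if_not_installed("cluster")
  set.seed(4)
  X <- rbind(matrix(stats::rnorm(80, 0, 0.4), 20, 4),
             matrix(stats::rnorm(80, 3, 0.4), 20, 4))
  cl <- select_clusters_bic(X, k_max = 4, method = "rf", seed = 9)
  expect_equal(cl$n_clusters, 2L)
  truth <- rep(c(2L, 1L), each = 20)
  expect_gte(mean(cl$labels == truth), 0.9)
})

test_that("rm ANOVA isolates a constructed crossover interaction", {
  n <- 20
  g <- rep(c("high", "low"), each = n / 2)
  # pure Group x Stimulus crossover, no other effect, no noise
  eff_gs <- ifelse(g == "high", 0.2, -0.2)
  d <- data.frame(true_group = g,
                  plv_speech_vt = 0.5 + eff_gs,
                  plv_speech_hands = 0.5 + eff_gs,
                  plv_tones_vt = 0.5 - eff_gs,
                  plv_tones_hands = 0.5 - eff_gs)
  # infinitesimal noise keeps error strata non-singular
  set.seed(8)
  for (k in 2:5) d[[k]] <- d[[k]] + stats::rnorm(n, sd = 1e-6)
  a <- rm_anova(d)
  eff <- a$effects
  gs <- eff[eff$effect == "Group:stimulus", ]
  expect_gt(gs$F, 1e6)
  expect_lt(gs$p, 1e-12)
  others <- eff[!eff$effect %in% c("Group:stimulus"), ]
  expect_true(all(others$F < 100))
  expect_equal(gs$df1, 1)
  expect_equal(gs$df2, n - 2)
})

test_that("rm ANOVA agrees with the aov error-strata decomposition", {
  # independent oracle: classic univariate aov with Error(id/(eff*stim))
  set.seed(15)
  n <- 16
  g <- rep(c("high", "low"), each = n / 2)
  Y <- matrix(stats::rnorm(n * 4, mean = 0.5, sd = 0.1), n, 4)
  d <- data.frame(true_group = g, plv_speech_vt = Y[, 1],
                  plv_speech_hands = Y[, 2], plv_tones_vt = Y[, 3],
                  plv_tones_hands = Y[, 4])
  a <- rm_anova(d)$effects

  long <- data.frame(
    y = as.vector(Y),
    id = factor(rep(seq_len(n), 4)),
    g = factor(rep(g, 4)),
    eff = factor(rep(c("vt", "hands", "vt", "hands"), each = n)),
    stim = factor(rep(c("speech", "speech", "tones", "tones"), each = n)))
  oracle <- stats::aov(y ~ g * eff * stim + Error(id / (eff * stim)),
                       data = long)
  so <- summary(oracle)
  pick <- function(stratum, term) {
    tab <- so[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, ]
  }
  expect_equal(a$F[a$effect == "Group"], pick("Error: id", "g")[["F value"]],
               tolerance = 1e-8)
  expect_equal(a$F[a$effect == "effector"],
               pick("Error: id:eff", "eff")[["F value"]], tolerance = 1e-8)
  expect_equal(a$F[a$effect == "Group:stimulus"],
               pick("Error: id:stim", "g:stim")[["F value"]],
               tolerance = 1e-8)
  expect_equal(a$F[a$effect == "Group:effector:stimulus"],
               pick("Error: id:eff:stim", "g:eff:stim")[["F value"]],
               tolerance = 1e-8)
  # sums of squares within each stratum are additive
  tab <- so[["Error: id:eff"]][[1]]
  expect_equal(sum(tab[, "Sum Sq"]),
               sum(pick("Error: id:eff", "eff")[["Sum Sq"]],
                   pick("Error: id:eff", "g:eff")[["Sum Sq"]],
                   pick("Error: id:eff", "Residuals")[["Sum Sq"]]),
               tolerance = 1e-10)
})

test_that("rm ANOVA supports gender factor and training covariate", {
  rec <- fx_cohort()$records
  a <- rm_anova(rec, gender = "gender", covariate = "musical_training")
  eff <- a$effects
  expect_true("Group:gender" %in% eff$effect)
  expect_true("musical_training" %in% eff$effect)
  expect_true(all(eff$p >= 0 & eff$p <= 1))
  expect_true(all(eff$F >= 0))
  # missing cells produce an informative error
  bad <- rec
  bad$plv_tones_vt[3] <- NA
  expect_error(rm_anova(bad), "3")
})

test_that("paired post-hoc handles ties, certainty and Bonferroni capping", {
  x <- c(0.5, 0.6, 0.7, 0.8)
  r <- posthoc_paired(x, x, n_comparisons = 4)
  expect_equal(r$t, 0)
  expect_equal(r$p_bonferroni, 1)
  r2 <- posthoc_paired(x + 0.1, x, n_comparisons = 2)
  expect_true(is.infinite(r2$t) && r2$t > 0)
  expect_equal(r2$p_bonferroni, 0)
  set.seed(3)
  r3 <- posthoc_paired(stats::rnorm(10), stats::rnorm(10), n_comparisons = 3)
  expect_gte(r3$p_bonferroni, r3$p_raw)
  expect_error(posthoc_paired(1, 2), ">= 2")
})

test_that("paired shift of 0.15 at sigma 0.1, n = 21 is detected reliably", {
  set.seed(12)
  hits <- vapply(1:1000, function(i) {
    base <- stats::rnorm(21, 0.4, 0.1)
    posthoc_paired(base + 0.15, base + stats::rnorm(21, 0, 0.1))$p_raw < 0.05
  }, logical(1))
  # noncentral-t oracle: ncp = 0.15 / (0.1 / sqrt(21)) = 6.87, power ~ 1
  expect_gte(mean(hits), 0.99)
})

test_that("circular comparison separates distinct directions, not identical ones", {
  set.seed(21)
  a <- rvonmises(20, 0, 8) * 180 / pi
  b <- rvonmises(20, pi / 2, 8) * 180 / pi
  r <- circular_group_compare(a, b, n_perm = 10000, seed = 5)
  expect_lt(r$p, 0.001)
  self <- circular_group_compare(a, a, n_perm = 2000, seed = 5)
  expect_equal(self$p, 1)
  expect_error(circular_group_compare(rep(10, 6), rep(10, 6)), "degenerate")
})

test_that("circular comparison is calibrated under the null", {
  set.seed(31)
  ps <- vapply(1:120, function(i) {
    a <- rvonmises(15, 1, 3) * 180 / pi
    b <- rvonmises(15, 1, 3) * 180 / pi
    circular_group_compare(a, b, n_perm = 400, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("Fisher's exact test matches exhaustive hypergeometric enumeration", {
  # independent oracle: enumerate all tables with the observed margins
  enum_fisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1])
    prob <- function(a) choose(r1, a) * choose(r2, c1 - a) /
      choose(r1 + r2, c1)
    as_ <- max(0, c1 - r2):min(r1, c1)
    probs <- vapply(as_, prob, numeric(1))
    p_obs <- prob(tab[1, 1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(14)
  for (i in 1:20) {
    tab <- matrix(stats::rpois(4, 6), 2)
    if (sum(tab) == 0 || sum(tab) > 30) next
    expect_equal(fisher_exact_2x2(tab)$p, enum_fisher(tab), tolerance = 1e-9)
  }
  # diagonal certainty: p = 2 / C(20, 10)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p,
               2 / choose(20, 10), tolerance = 1e-12)
  # perfect independence
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  # continuity-corrected odds ratio for zero cells
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$odds_ratio,
               10.5^2 / 0.25)
})

test_that("group-gender association from the reported counts is non-significant", {
  # lows: 12 F of 21; highs: 15 F of 30
  r <- fisher_exact_2x2(matrix(c(12, 9, 15, 15), 2, byrow = TRUE))
  expect_lt(abs(r$p - 0.77), 0.01)
})

test_that("independent t matches the hand-computed pooled formula", {
  a <- c(3, 5, 7, 9)
  b <- c(2, 4, 6)
  r <- independent_t(a, b)
  # formula oracle
  sp2 <- (3 * stats::var(a) + 2 * stats::var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 5)
  expect_equal(r$p, 2 * stats::pt(-abs(t_hand), 5), tolerance = 1e-12)
  eq <- independent_t(c(1, 1), c(1, 1))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(independent_t(1, c(1, 2)), ">= 2")
})

test_that("training-years comparison detects the simulated group difference", {
  rec <- fx_cohort()$records
  r <- independent_t(rec$musical_training[rec$true_group == "high"],
                     rec$musical_training[rec$true_group == "low"])
  expect_gt(r$t, 0) # highs above lows
})

test_that("circular mean utility behaves on wrapped samples", {
  expect_equal(circ_mean_deg(c(350, 10)), 0, tolerance = 1e-9)
  expect_equal(circ_mean_deg(c(170, -170)), 180, tolerance = 1e-9)
  expect_error(circ_mean_deg(numeric(0)), "non-empty")
})
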