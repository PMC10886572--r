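make_cohort <- function(seed = 1, n = 300, gamma = 1, slope = 1,
                        fn_rate = 0.3, n_sig = 8) {
  cfg <- sim_config(seed = seed, n_patients = as.integer(n),
                    hazard_coefficient = gamma, stage_logit_slope = slope,
                    stage_fn_rate = fn_rate)
  simulate_clinical_cohort(cfg, paste0("sig", seq_len(n_sig)))
}

test_that("signature scores are per-miRNA z-scores and affine invariant", {
  co <- make_cohort(seed = 2, n = 100, n_sig = 1)
  sc <- signature_score(co$clinical, "sig1")
  x <- log2(co$clinical$sig1 + 1)
  expect_equal(sc$score, as.numeric(scale(x)), tolerance = 1e-12)

  # rescaling one miRNA's expression column leaves scores almost unchanged
  co2 <- make_cohort(seed = 2, n = 100, n_sig = 3)
  sc_a <- signature_score(co2$clinical, paste0("sig", 1:3))
  mod <- as.data.frame(co2$clinical)
  mod$sig2 <- mod$sig2 * 50
  sc_b <- signature_score(clinical_table(mod), paste0("sig", 1:3))
  expect_equal(cor(sc_a$score, sc_b$score), 1, tolerance = 1e-3)

  const <- mod; const$sig1 <- 7
  expect_warning(sc_c <- signature_score(clinical_table(const),
                                         paste0("sig", 1:3)),
                 "zero-variance")
  expect_identical(attr(sc_c, "signature_used"), c("sig2", "sig3"))
  allc <- mod; allc$sig1 <- 1; allc$sig2 <- 2; allc$sig3 <- 3
  expect_warning(
    expect_error(signature_score(clinical_table(allc), paste0("sig", 1:3)),
                 "zero variance"))
  expect_error(signature_score(co$clinical, "absent"), "no signature")
})

test_that("signature score recovers the latent severity", {
  co <- make_cohort(seed = 3, n = 300)
  sc <- signature_score(co$clinical, paste0("sig", 1:8))
  expect_gt(cor(sc$score, co$truth$score_true), 0.7)
})

test_that("group comparisons: t-test, ANOVA/Tukey, and degenerate groups", {
  co <- make_cohort(seed = 4, n = 200, slope = 2)
  sc <- signature_score(co$clinical, paste0("sig", 1:8))
  same <- compare_groups(sc, rep(c("a", "b"), 100))
  expect_gt(same$p_value, 0.05)

  pn <- ifelse(co$clinical$pN == "N0", "pN0", "pN+")
  two <- compare_groups(sc, pn)
  expect_identical(two$design, "two_group")
  expect_lt(two$p_value, 0.01)
  expect_gt(two$group_means[["pN+"]] - two$group_means[["pN0"]], 0)

  multi <- compare_groups(sc, co$clinical$pT, design = "multi_group")
  expect_identical(multi$design, "multi_group")
  expect_true(is.matrix(multi$pairwise))
  expect_gt(multi$p_value, 0.001)  # pT is independent of the score

  expect_error(compare_groups(sc, c("solo", rep("x", 199))), "solo")
  na_lab <- pn; na_lab[1:10] <- NA
  expect_equal(compare_groups(sc, na_lab)$n_dropped, 10)
})

test_that("ANOVA type-I rate is calibrated on equal-mean groups", {
  set.seed(5)
  rej <- mean(vapply(1:200, function(i) {
    sc <- data.frame(patient_id = 1:60, score = rnorm(60))
    compare_groups(sc, rep(c("a", "b", "c"), 20),
                   design = "multi_group")$p_value < 0.05
  }, TRUE))
  expect_gt(rej, 0.015)
  expect_lt(rej, 0.085)
})

test_that("occult contrast runs its three comparisons and skips cleanly", {
  co <- make_cohort(seed = 6, n = 400, slope = 1, fn_rate = 0.3)
  sc <- signature_score(co$clinical, paste0("sig", 1:8))
  occ <- occult_contrast(sc, co$clinical)
  expect_named(occ, c("cN0_vs_cNpos", "occult_within_cN0", "pN0_vs_pNpos"))
  expect_identical(occ$occult_within_cN0$status, "ok")
  expect_gt(occ$occult_within_cN0$group_means[["pN+"]],
            occ$occult_within_cN0$group_means[["pN0"]])

  co0 <- make_cohort(seed = 6, n = 80, fn_rate = 1e-9)
  sc0 <- signature_score(co0$clinical, paste0("sig", 1:8))
  occ0 <- occult_contrast(sc0, co0$clinical)
  expect_identical(occ0$occult_within_cN0$status, "skipped")
})

test_that("KM with no censoring equals the empirical survivor function", {
  fit <- km_logrank(time = 1:4, event = rep(1, 4), group = rep("a", 4))
  expect_equal(fit$fits$a$survival, c(0.75, 0.5, 0.25, 0))
  expect_true(is.na(fit$statistic))
})

test_that("log-rank: identical groups give 0; hand tabulation and the
           survival package agree on random instances", {
  t0 <- rep(c(1, 2, 3), 2)
  g <- rep(c("A", "B"), 3)
  fit <- km_logrank(t0, rep(1, 6), g)
  expect_equal(fit$statistic, 0, tolerance = 1e-12)

  worked <- km_logrank(1:6, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(worked$statistic,
               logrank_hand(1:6, rep(1, 6), rep(c("A", "B"), each = 3)),
               tolerance = 1e-12)

  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    time <- sample(1:5, n, replace = TRUE)       # forces ties
    event <- rbinom(n, 1, 0.7)
    group <- c("A", "B", sample(c("A", "B"), n - 2, replace = TRUE))
    if (sum(event) == 0) event[1] <- 1
    mine <- km_logrank(time, event, group)$statistic
    expect_equal(mine, logrank_hand(time, event, group), tolerance = 1e-10)
    if (requireNamespace("survival", quietly = TRUE) && !is.na(mine)) {
      ref <- survival::survdiff(survival::Surv(time, event) ~ group)
      expect_equal(mine, unname(ref$chisq), tolerance = 1e-8)
    }
  }
})

test_that("log-rank is invariant to monotone time relabeling", {
  set.seed(8)
  time <- sample(1:20, 12, replace = TRUE)
  event <- rbinom(12, 1, 0.8); event[1] <- 1
  group <- rep(c("A", "B"), 6)
  a <- km_logrank(time, event, group)$statistic
  b <- km_logrank(exp(time / 3), event, group)$statistic
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("lowest-p cutpoint beats the median split and flags selection
           bias via the permutation-adjusted p", {
  co <- make_cohort(seed = 9, n = 300, gamma = 1)
  sc <- signature_score(co$clinical, paste0("sig", 1:8))
  cut <- optimal_cutpoint_survival(sc, co$clinical$time, co$clinical$event,
                                   n_perm = 99, seed = 1)
  med_grp <- ifelse(sc$score > median(sc$score), "high", "low")
  med_p <- km_logrank(co$clinical$time, co$clinical$event, med_grp)$p_value
  expect_lte(cut$p_value, med_p)
  expect_lt(cut$p_value, 0.05)
  expect_true(cut$high_worse)
  expect_lt(cut$p_perm_adjusted, 0.05)
  expect_true(all(cut$scan$n_high[cut$scan$admissible] >= 30))

  expect_error(optimal_cutpoint_survival(rep(1, 50), runif(50, 1, 10),
                                         rep(1, 50)),
               "no admissible")
})
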