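test_that("size factors: symmetry, scaling law, and hand calculation", {
  x <- tiny_counts(c(10, 20, 30, 40, 50,
                     10, 20, 30, 40, 50,
                     10, 20, 30, 40, 50,
                     10, 20, 30, 40, 50))
  expect_equal(unname(compute_size_factors(x)), rep(1, 4))

  set.seed(1)
  base <- matrix(rpois(20, 100) + 1, 5, 4)
  doubled <- base; doubled[, 2] <- base[, 1] * 2; doubled[, 1] <- base[, 1]
  x2 <- tiny_counts(doubled)
  sf <- compute_size_factors(x2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  vals <- matrix(c(2, 4, 8,
                   3, 6, 12,
                   10, 10, 40,
                   5, 20, 20,
                   7, 14, 28), 5, 3, byrow = TRUE)
  x3 <- tiny_counts(vals, n_mirna = 5, conds = c("cell", "cell", "sev"))
  gm <- apply(vals, 1, function(r) exp(mean(log(r))))
  manual <- apply(sweep(vals, 1, gm, "/"), 2, median)
  expect_equal(unname(compute_size_factors(x3)), manual)
})

test_that("size factors invariant to miRNA order; all-zero overlap errors", {
  cfg <- sim_config(seed = 2, n_mirnas = 50L)
  x <- simulate_count_experiment(cfg)$counts
  sf1 <- compute_size_factors(x)
  perm <- sample(nrow(x$counts))
  x2 <- count_matrix(x$counts[perm, ], x$samples)
  expect_equal(compute_size_factors(x2), sf1)

  z <- tiny_counts(c(0, 1, 1, 1, 1,  1, 0, 1, 1, 1,
                     1, 1, 0, 1, 1,  1, 1, 1, 0, 0))
  zz <- count_matrix(z$counts[1:4, ], z$samples)
  expect_error(compute_size_factors(zz), "filter")
})

test_that("dispersion estimates: Poisson floor, NB consistency, constants", {
  cfg <- sim_config(seed = 3, n_mirnas = 300L, dispersion = 0,
                    replicates = 3L, secretion_shift_log2 = 0, effect_sd = 0)
  x <- simulate_count_experiment(cfg)$counts
  a <- estimate_dispersions(x)
  expect_lt(median(a), 0.02)

  cfg2 <- sim_config(seed = 3, n_mirnas = 300L, dispersion = 0.1,
                     replicates = 100L, n_lines = 1L,
                     secretion_shift_log2 = 0, effect_sd = 0,
                     size_factor_range = c(1, 1))
  x2 <- simulate_count_experiment(cfg2)$counts
  a2 <- estimate_dispersions(x2)
  expect_gt(median(a2), 0.08)
  expect_lt(median(a2), 0.12)

  const <- tiny_counts(rep(7, 20))
  expect_equal(unname(estimate_dispersions(const)), rep(1e-8, 5))
  single <- tiny_counts(conds = c("cell", "sev", "sev", "sev"))
  expect_error(estimate_dispersions(single), "2 replicates")
})

test_that("an 8-fold mean shift is estimated as log2FC near 3", {
  # most miRNAs unchanged so the size factors anchor on the null bulk
  set.seed(4)
  base <- rpois(40, 4000)
  shifted <- 1:8
  sev1 <- base; sev2 <- base + rpois(40, 10)
  sev1[shifted] <- 8 * base[shifted]
  sev2[shifted] <- 8 * base[shifted] + rpois(8, 10)
  vals <- cbind(base, base + rpois(40, 10), sev1, sev2)
  x <- tiny_counts(vals, n_mirna = 40)
  d <- differential_test(x)
  expect_equal(mean(d$log2fc[shifted]), 3, tolerance = 0.1)
  expect_lt(abs(mean(d$log2fc[-shifted])), 0.1)
  expect_true(all(d$p_adjusted >= d$p_value))
})

test_that("all-zero miRNAs are excluded and reported", {
  vals <- matrix(rpois(20, 50), 5, 4)
  vals[3, ] <- 0
  x <- tiny_counts(vals)
  d <- differential_test(x)
  expect_identical(attr(d, "excluded"), "mir3")
  expect_false("mir3" %in% d$mirna_id)
})

test_that("null p-values are uniform under the t reference", {
  set.seed(5)
  ps <- unlist(lapply(1:30, function(i) {
    cfg <- sim_config(seed = 100 + i, n_mirnas = 80L,
                      secretion_shift_log2 = 0, effect_sd = 0)
    differential_test(simulate_count_experiment(cfg)$counts)$p_value
  }))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(adjust_pvalues_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues_bh(0.2), 0.2)
  expect_equal(adjust_pvalues_bh(rep(1, 5)), rep(1, 5))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_pvalues_bh(p), bh_brute(p))
  }
  expect_error(adjust_pvalues_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("compartment classification applies the screen and strict rules", {
  d <- data.frame(mirna_id = paste0("m", 1:5),
                  base_mean = 10, se_log2fc = 1, stat = 0,
                  log2fc = c(0.5, 3, -1.5, 3, -0.4),
                  p_value = c(0.001, 0.001, 0.001, 0.2, 0.01),
                  p_adjusted = c(0.01, 0.01, 0.01, 0.2, 0.04),
                  compartment = "neutral")
  screen <- classify_compartments(d, "screen")
  expect_identical(screen$compartment,
                   c("secretory", "secretory", "retained", "neutral",
                     "retained"))
  strict <- classify_compartments(d, "strict")
  expect_identical(strict$compartment,
                   c("neutral", "secretory", "retained", "neutral",
                     "neutral"))
  expect_error(classify_compartments(d, "loose"))
})

test_that("clustering recovers separable blocks and handles edge cases", {
  set.seed(7)
  up <- matrix(rpois(40, 200), 10, 4) * rep(c(1, 1, 8, 8), each = 10)
  dn <- matrix(rpois(40, 200), 10, 4) * rep(c(8, 8, 1, 1), each = 10)
  x <- tiny_counts(rbind(up, dn), n_mirna = 20)
  cl <- cluster_expression(x, k = 2)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_false(cl$cluster[1] == cl$cluster[11])

  singles <- cluster_expression(x, k = 20)
  expect_equal(length(unique(singles$cluster)), 20)
  expect_error(cluster_expression(x, k = 21), "exceeds")

  dup <- x$counts; dup[2, ] <- dup[1, ]
  cl2 <- cluster_expression(count_matrix(dup, x$samples), k = 4)
  expect_identical(cl2$cluster[["mir1"]], cl2$cluster[["mir2"]])
})
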