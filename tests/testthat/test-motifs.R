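test_that("motif enumeration is complete, lexicographic and duplicate-free", {
  m4 <- enumerate_motifs(4, 4)
  expect_length(m4, 256)
  expect_identical(m4[1:3], c("AAAA", "AAAC", "AAAG"))
  expect_false(anyDuplicated(m4) > 0)
  expect_length(enumerate_motifs(4, 7), 21760)
  expect_identical(enumerate_motifs(5, 5)[1], "AAAAA")
  expect_error(enumerate_motifs(0, 4))
  expect_error(enumerate_motifs(5, 4), "k_min")
})

test_that("motif set membership equals a naive double-loop scan", {
  sets <- build_motif_sets("GCGC", c(m1 = "AAGCGCGCAA", m2 = "AAAAAAAAAA",
                                     m3 = "GCGCAAAAAA", m4 = "AGCGCA",
                                     m5 = "AAGCGC", m6 = "GCGCGC",
                                     m7 = "AAGCGU"), min_size = 1)
  expect_identical(sets$GCGC, c("m1", "m3", "m4", "m5", "m6"))

  set.seed(1)
  sq <- generate_sequences_with_motif(sim_config(seed = 20,
                                                 n_mirnas = 200L))$sequences
  motifs <- enumerate_motifs(4, 5)
  sets2 <- build_motif_sets(motifs, sq, min_size = 6)
  naive <- lapply(motifs, function(m)
    names(sq)[vapply(sq, function(s) grepl(m, s, fixed = TRUE), TRUE)])
  names(naive) <- motifs
  naive <- naive[lengths(naive) >= 6]
  expect_setequal(names(sets2), names(naive))
  for (m in names(sets2)) expect_setequal(sets2[[m]], naive[[m]])
})

test_that("the min-size filter drops exactly the sets with <6 members", {
  seqs <- setNames(c(paste0(strrep("A", 14), "GCGC"),
                     rep(strrep("A", 18), 9)), paste0("m", 1:10))
  seqs[2:6] <- paste0(strrep("C", 14), "GCGC")  # 6 carriers total
  sets6 <- build_motif_sets("GCGC", seqs, min_size = 6)
  expect_length(sets6$GCGC, 6)
  seqs[6] <- strrep("A", 18)                     # now only 5 carriers
  expect_length(build_motif_sets("GCGC", seqs, min_size = 6), 0)
})

test_that("enrichment score matches the hand-walk oracle exactly", {
  r <- data.frame(mirna_id = c("g1", "g2", "g3"), metric = c(2, 1, -1))
  es <- enrichment_score(r, "g1")
  expect_identical(es$es, 1)
  expect_identical(es$leading_edge, "g1")

  set.seed(2)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    ids <- paste0("g", 1:N)
    metric <- round(sort(rnorm(N), decreasing = TRUE), 3)
    members <- sample(ids, sample(1:(N - 1), 1))
    w <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(data.frame(mirna_id = ids, metric = metric),
                           members, weight = w)
    expect_identical(es$es, naive_es(ids, metric, members, w))
    expect_true(es$es >= -1 && es$es <= 1)
    expect_true(all(es$leading_edge %in% members))
  }
})

test_that("weight 0 recovers the unweighted KS statistic and reversal
           negates the score", {
  set.seed(3)
  N <- 40
  ids <- paste0("g", 1:N)
  metric <- sort(rnorm(N), decreasing = TRUE)
  members <- sample(ids, 12)
  es <- enrichment_score(data.frame(mirna_id = ids, metric = metric),
                         members, weight = 0)
  # independent unweighted formulation: D+/D- of the hit ECDF vs miss ECDF
  hit <- ids %in% members
  cdf_hit <- cumsum(hit) / sum(hit)
  cdf_miss <- cumsum(!hit) / sum(!hit)
  dev <- cdf_hit - cdf_miss
  expect_equal(abs(es$es), max(abs(dev)))

  rev_es <- enrichment_score(
    data.frame(mirna_id = rev(ids), metric = rev(metric)), members,
    weight = 0)
  expect_equal(rev_es$es, -es$es, tolerance = 1e-12)
})

test_that("permutation NES is deterministic and the plus-one p floor holds", {
  set.seed(4)
  N <- 100
  r <- data.frame(mirna_id = paste0("g", 1:N),
                  metric = sort(rnorm(N, sd = 2), decreasing = TRUE))
  members <- r$mirna_id[1:12]   # top-ranked block: maximal enrichment
  a <- permutation_nes(r, members, n_perm = 500, seed = 7)
  b <- permutation_nes(r, members, n_perm = 500, seed = 7)
  expect_identical(a$nes, b$nes)
  expect_identical(a$p_perm, b$p_perm)
  expect_equal(a$p_perm, 1 / (1 + a$n_same_sign))
  expect_gt(a$nes, 1)
})

test_that("null member sets give calibrated permutation p and NES near 1", {
  set.seed(5)
  N <- 150
  r <- data.frame(mirna_id = paste0("g", 1:N),
                  metric = sort(rnorm(N), decreasing = TRUE))
  res <- vapply(1:60, function(i) {
    members <- sample(r$mirna_id, 15)
    out <- permutation_nes(r, members, n_perm = 200, seed = i)
    c(out$p_perm, out$nes)
  }, c(0, 0))
  expect_gt(mean(res[1, ] > 0.2), 0.6)
  expect_equal(mean(abs(res[2, ])), 1, tolerance = 0.25)
})

test_that("enrichment scores agree with fgsea on shared instances", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  N <- 80
  ids <- paste0("g", 1:N)
  stats <- sort(rnorm(N, sd = 1.5), decreasing = TRUE)
  names(stats) <- ids
  r <- data.frame(mirna_id = ids, metric = stats)
  for (i in 1:10) {
    members <- sample(ids, 10)
    mine <- enrichment_score(r, members)$es
    ref <- suppressWarnings(
      fgsea::calcGseaStat(stats, selectedStats = which(ids %in% members)))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("motif screen recovers a planted sorting motif with positive NES
           and a planted retention motif with negative NES", {
  run_screen <- function(shift, seed) {
    cfg <- sim_config(seed = seed, n_mirnas = 300L,
                      secretion_shift_log2 = shift)
    sq <- generate_sequences_with_motif(cfg)
    sim <- simulate_count_experiment(cfg, sq$carriers)
    d <- differential_test(sim$counts)
    motif_screen(d, sq$sequences, k_min = 4, k_max = 4, n_perm = 200,
                 seed = seed)
  }
  up <- run_screen(2, 30)
  expect_identical(up$motif[1], "GCGC")
  expect_identical(up$direction[1], "sev_sorting")
  expect_lt(up$p_perm[1], 0.02)
  expect_gt(up$nes[1], 1.5)

  dn <- run_screen(-2, 31)
  gc <- dn[dn$motif == "GCGC", ]
  expect_lt(gc$nes, 0)
  expect_identical(gc$direction, "cell_retention")
  expect_equal(which(dn$motif == "GCGC"), nrow(dn))
})

test_that("degenerate member sets are rejected", {
  r <- data.frame(mirna_id = paste0("g", 1:5), metric = 5:1)
  expect_error(enrichment_score(r, "absent"), "no member")
  expect_error(enrichment_score(r, r$mirna_id), "whole ranked list")
})
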