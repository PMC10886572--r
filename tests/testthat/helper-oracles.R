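# Independent oracles used across the suite. These deliberately use the
# most naive formulation available so they share no code with the package.

# literal left-to-right walk of the weighted running sum
naive_es <- function(ids, metric, members, weight = 1) {
  hit <- ids %in% members
  w <- abs(metric)^weight
  denom_hit <- sum(w[hit])
  denom_miss <- length(ids) - sum(hit)
  run <- 0
  best <- 0
  for (i in seq_along(ids)) {
    run <- run + if (hit[i]) w[i] / denom_hit else -1 / denom_miss
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# step-up definition of Benjamini-Hochberg, straight from the procedure
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# upper-tail hypergeometric probability by explicit binomial-coefficient
# summation
hyper_brute <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# per-event-time O/E/V tabulation of the two-group log-rank statistic
logrank_hand <- function(time, event, group) {
  glev <- sort(unique(group))
  stopifnot(length(glev) == 2)
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == glev[2])
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == glev[2])
    e1 <- d_tot * n1 / n_tot
    oe <- oe + d1 - e1
    if (n_tot > 1)
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  if (v <= 0) return(NA_real_)
  oe^2 / v
}

# small hand-built count experiment: 2 conditions x 2 replicates
tiny_counts <- function(values = NULL, n_mirna = 5, conds = c("cell", "cell", "sev", "sev")) {
  m <- length(conds)
  if (is.null(values)) {
    set.seed(42)
    values <- matrix(rpois(n_mirna * m, 50), n_mirna, m)
  }
  values <- matrix(as.integer(values), nrow = n_mirna)
  rownames(values) <- paste0("mir", seq_len(n_mirna))
  colnames(values) <- paste0("s", seq_len(m))
  count_matrix(values, data.frame(sample_id = colnames(values),
                                  condition = conds,
                                  cell_line = "L1",
                                  stringsAsFactors = FALSE))
}
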