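#' Enumerate all k-mer motifs over the RNA alphabet
#'
#' All 4^k strings over A/C/G/U for each k in `k_min..k_max`, in
#' lexicographic order.
#'
#' @param k_min,k_max inclusive motif length range.
#' @return Character vector of motifs.
#' @export
enumerate_motifs <- function(k_min = 4L, k_max = 7L) {
  k_min <- check_count(k_min, "k_min")
  k_max <- check_count(k_max, "k_max")
  if (k_min > k_max) stop_input("k_min must be <= k_max")
  unlist(lapply(k_min:k_max, function(k) {
    grid <- expand.grid(rep(list(rna_alphabet), k),
                        stringsAsFactors = FALSE)
    do.call(paste0, grid[, k:1, drop = FALSE])
  }), use.names = FALSE)
}

#' Build motif membership gene sets over mature sequences
#'
#' A miRNA is a member of a motif's set iff the motif occurs as a
#' contiguous substring of its mature sequence (overlapping occurrences
#' count membership once). Sets with fewer than `min_size` members are
#' dropped. Membership is computed by enumerating every substring of the
#' relevant lengths per sequence, so only motifs that actually occur are
#' materialized before the requested list is applied.
#'
#' @param motifs character vector of motifs over A/C/G/U.
#' @param sequences named character vector of RNA sequences.
#' @param min_size minimum member count for a set to survive.
#' @return Named list of member-id vectors (a motif gene-set collection),
#'   with the filter threshold in the `"min_size"` attribute.
#' @export
build_motif_sets <- function(motifs, sequences, min_size = 6L) {
  if (any(!grepl("^[ACGU]+$", motifs)))
    stop_input("motifs must be strings over A/C/G/U")
  sequences <- validate_sequences(sequences)
  ks <- sort(unique(nchar(motifs)))
  ids <- names(sequences)
  occ_motif <- character(0); occ_id <- character(0)
  for (k in ks) {
    for (i in seq_along(sequences)) {
      L <- nchar(sequences[i])
      if (L < k) next
      subs <- unique(substring(sequences[i], 1:(L - k + 1), k:L))
      occ_motif <- c(occ_motif, subs)
      occ_id <- c(occ_id, rep(ids[i], length(subs)))
    }
  }
  sets <- split(occ_id, occ_motif)
  sets <- sets[names(sets) %in% motifs]
  sets <- sets[lengths(sets) >= min_size]
  sets <- sets[order(names(sets))]
  attr(sets, "min_size") <- min_size
  sets
}

#' Build the log2FC-ranked miRNA list
#'
#' Orders the differential table by log2 fold change, descending; ties
#' are broken lexicographically by miRNA id so the ranking is total and
#' deterministic.
#'
#' @param diff a `mir_diff` table (or any data.frame with `mirna_id` and
#'   `log2fc`).
#' @return data.frame with columns `mirna_id` and `metric`, in rank order.
#' @export
ranked_list <- function(diff) {
  if (anyDuplicated(diff$mirna_id)) stop_input("duplicate ids in ranking")
  ord <- order(-diff$log2fc, diff$mirna_id)
  data.frame(mirna_id = diff$mirna_id[ord], metric = diff$log2fc[ord],
             stringsAsFactors = FALSE)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list top to bottom: a member ("hit") at position i
#' adds |metric_i|^weight / sum of hit weights, a non-member subtracts
#' 1/(N - N_hits). The enrichment score is the running sum's signed
#' maximum deviation from zero (first extremum on ties), and the leading
#' edge is the members at or before the extremum (at or after it for a
#' negative score).
#'
#' @param ranked a [ranked_list()] data.frame.
#' @param members character vector of member ids; ids absent from the
#'   ranking are ignored (their count is reported in the result).
#' @param weight exponent on |metric| (0 recovers the unweighted
#'   Kolmogorov-Smirnov statistic).
#' @return List with `es`, `running` (the full profile), `hit_positions`,
#'   `leading_edge` and `n_outside`.
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  ids <- ranked$mirna_id
  hit <- ids %in% members
  n_outside <- length(setdiff(members, ids))
  nh <- sum(hit); N <- length(ids)
  if (nh == 0) stop_input("no member appears in the ranked list")
  if (nh == N) stop_input("set covers the whole ranked list")
  w <- abs(ranked$metric)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - nh))
  run <- cpp_cumsum_d(inc)
  peak <- which.max(abs(run))
  es <- run[peak]
  le <- if (es >= 0) ids[hit & seq_len(N) <= peak]
        else ids[hit & seq_len(N) >= peak]
  list(es = es, running = run, hit_positions = which(hit),
       leading_edge = le, n_outside = n_outside)
}

#' Permutation normalization of an enrichment score
#'
#' Draws `n_perm` random member sets of identical size from the ranked
#' ids (gene permutation, the standard pre-ranked null), computes their
#' enrichment scores, and normalizes: NES = ES divided by the mean |null
#' ES| among nulls of the same sign; p = (1 + #same-sign nulls at least
#' as extreme) / (1 + #same-sign nulls). With fewer than 10 same-sign
#' nulls the p-value is an upper bound and the result is flagged.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (the draw is deterministic given it).
#' @return List with `es`, `nes`, `p_perm`, `n_same_sign`, `flagged` and
#'   the observed-score details.
#' @export
permutation_nes <- function(ranked, members, n_perm = 1000L, seed = 1L,
                            weight = 1) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  obs <- enrichment_score(ranked, members, weight)
  set.seed(seed)
  w <- abs(ranked$metric)^weight
  null_es <- cpp_null_es(w, length(obs$hit_positions), n_perm)[, 1]
  same <- null_es[sign(null_es) == sign(obs$es)]
  n_same <- length(same)
  flagged <- n_same < 10
  nes <- if (n_same > 0) obs$es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + n_same)
  c(obs, list(nes = nes, p_perm = p, n_same_sign = n_same,
              flagged = flagged))
}

#' Screen every k-mer motif for association with sEV sorting or retention
#'
#' Enumerates all motifs of length `k_min..k_max`, builds membership sets
#' over the mature sequences, and scores each surviving set against the
#' log2FC-ranked miRNA list: positive scores indicate sEV-sorting motifs,
#' negative scores cell-retention motifs. Null enrichment scores are
#' shared across motifs of equal member count (the null depends only on
#' set size), so the permutation budget is spent once per size.
#' FDR is reported both within each motif length (`fdr_per_k`) and across
#' all lengths jointly (`fdr_joint`).
#'
#' @param diff a `mir_diff` differential table.
#' @param sequences named character vector of mature sequences.
#' @param k_min,k_max motif length range.
#' @param min_size minimum members per surviving set.
#' @param n_perm permutations for the null.
#' @param weight running-sum weight exponent.
#' @param seed integer seed.
#' @return data.frame of class `mir_motifs`, sorted by NES descending,
#'   with columns `motif`, `k`, `size`, `es`, `nes`, `p_perm`,
#'   `fdr_per_k`, `fdr_joint`, `direction`, `leading_size`, `flagged`;
#'   leading-edge membership is kept in the `"leading_edge"` attribute
#'   and the surviving sets in the `"sets"` attribute.
#' @export
motif_screen <- function(diff, sequences, k_min = 4L, k_max = 7L,
                         min_size = 6L, n_perm = 1000L, weight = 1,
                         seed = 1L) {
  ranked <- ranked_list(diff)
  shared <- intersect(ranked$mirna_id, names(sequences))
  if (length(shared) < min_size)
    stop_input("differential table and sequences share too few ids")
  motifs <- enumerate_motifs(k_min, k_max)
  sets <- build_motif_sets(motifs, sequences[shared], min_size)
  if (length(sets) == 0) stop_input("no motif set survives the size filter")
  N <- nrow(ranked)
  w <- abs(ranked$metric)^weight
  hit_list <- lapply(sets, function(m) which(ranked$mirna_id %in% m))
  sizes <- lengths(hit_list)
  keep <- sizes >= min_size & sizes < N
  sets <- sets[keep]; hit_list <- hit_list[keep]; sizes <- sizes[keep]
  if (length(sets) == 0) stop_input("no motif set survives the size filter")

  miss_base <- -1 / (N - sizes)
  obs <- vapply(seq_along(sets), function(i) {
    inc <- rep(miss_base[i], N)
    pos <- hit_list[[i]]
    inc[pos] <- w[pos] / sum(w[pos])
    run <- cpp_cumsum_d(inc)
    run[which.max(abs(run))]
  }, 0)

  set.seed(seed)
  usize <- sort(unique(sizes))
  null_mat <- cpp_null_es(w, usize, n_perm)
  col <- match(sizes, usize)
  nes <- p <- numeric(length(sets))
  n_same <- integer(length(sets))
  for (i in seq_along(sets)) {
    nulls <- null_mat[, col[i]]
    same <- nulls[sign(nulls) == sign(obs[i])]
    n_same[i] <- length(same)
    nes[i] <- if (n_same[i] > 0) obs[i] / mean(abs(same)) else NA_real_
    p[i] <- (1 + sum(abs(same) >= abs(obs[i]))) / (1 + n_same[i])
  }
  kk <- nchar(names(sets))
  out <- data.frame(motif = names(sets), k = kk, size = sizes,
                    es = obs, nes = nes, p_perm = p,
                    fdr_per_k = NA_real_,
                    fdr_joint = adjust_pvalues_bh(p),
                    direction = ifelse(nes >= 0, "sev_sorting",
                                       "cell_retention"),
                    leading_size = NA_integer_,
                    flagged = n_same < 10,
                    stringsAsFactors = FALSE)
  for (k in unique(kk))
    out$fdr_per_k[kk == k] <- adjust_pvalues_bh(p[kk == k])
  le <- lapply(seq_along(sets), function(i) {
    inc <- rep(miss_base[i], N)
    pos <- hit_list[[i]]
    inc[pos] <- w[pos] / sum(w[pos])
    run <- cpp_cumsum_d(inc)
    peak <- which.max(abs(run))
    if (run[peak] >= 0) ranked$mirna_id[pos[pos <= peak]]
    else ranked$mirna_id[pos[pos >= peak]]
  })
  names(le) <- names(sets)
  out$leading_size <- lengths(le)
  ord <- order(-out$nes, out$motif)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "leading_edge") <- le
  attr(out, "sets") <- sets
  class(out) <- c("mir_motifs", "data.frame")
  out
}
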