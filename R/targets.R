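#' Pool the target mRNAs of secretory miRNAs
#'
#' Collects each secretory miRNA's target genes from an miRNA-mRNA
#' interaction table and forms the pooled (unique) target set. The gene
#' universe is every gene targeted by at least one detected miRNA
#' (`universe_policy = "interaction"`), optionally widened by the marker
#' gene space (`"union"`); restricting the universe to assay-reachable
#' genes avoids inflating significance with genes no detected miRNA
#' could ever select.
#'
#' @param secretory character vector of secretory miRNA ids.
#' @param interactions miRNA-mRNA [interaction_table()].
#' @param universe_mirnas all detected miRNA ids.
#' @param markers optional named list of marker sets (used by the
#'   `"union"` policy).
#' @param universe_policy `"interaction"` or `"union"`.
#' @return List with `targets` (per-miRNA sets), `pool` and `universe`.
#' @export
collect_target_pool <- function(secretory, interactions, universe_mirnas,
                                markers = NULL,
                                universe_policy = c("interaction", "union")) {
  universe_policy <- match.arg(universe_policy)
  edges <- interactions[interactions$source %in% universe_mirnas, ,
                        drop = FALSE]
  universe <- unique(edges$target)
  if (universe_policy == "union" && !is.null(markers))
    universe <- unique(c(universe, unlist(markers, use.names = FALSE)))
  sec_edges <- edges[edges$source %in% secretory, , drop = FALSE]
  targets <- split(sec_edges$target, sec_edges$source)
  no_edge <- setdiff(secretory, names(targets))
  if (length(targets) == 0)
    stop_input("no secretory miRNA has any target in the interaction table")
  pool <- intersect(unique(sec_edges$target), universe)
  list(targets = lapply(targets, unique), pool = pool, universe = universe,
       no_edge = no_edge)
}

#' Hypergeometric over-representation of gene sets in a target pool
#'
#' For each tested set, computes the exact upper-tail probability
#' P\[X >= k\] for X ~ Hypergeometric(N, K, n) where N is the universe
#' size, K the set size within the universe, n the pool size and k the
#' observed overlap; one-sided, since the question is which sets the
#' pool over-represents. BH adjustment across the tested sets.
#'
#' @param pool output of [collect_target_pool()] (or a list with `pool`
#'   and `universe`).
#' @param sets named list of gene-id vectors (marker table or GMT
#'   collection).
#' @return data.frame sorted by p with columns `set`, `overlap_k`,
#'   `set_size_K`, `pool_size_n`, `universe_size_N`, `p`, `p_adjusted`,
#'   `neg_log10_p`; overlap members are kept in the `"overlap_genes"`
#'   attribute.
#' @export
hypergeometric_overrepresentation <- function(pool, sets) {
  universe <- pool$universe
  px <- pool$pool
  if (length(universe) == 0) stop_input("empty universe")
  if (length(px) == 0) stop_input("empty target pool")
  if (!all(px %in% universe)) stop_input("pool must lie in the universe")
  N <- length(universe); n <- length(px)
  rows <- lapply(names(sets), function(nm) {
    inset <- intersect(sets[[nm]], universe)
    K <- length(inset)
    ov <- intersect(inset, px)
    k <- length(ov)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    list(row = data.frame(set = nm, overlap_k = k, set_size_K = K,
                          pool_size_n = n, universe_size_N = N, p = p,
                          stringsAsFactors = FALSE),
         ov = ov)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  out$p_adjusted <- adjust_pvalues_bh(out$p)
  out$neg_log10_p <- -log10(out$p)
  ov <- lapply(rows, `[[`, "ov")
  names(ov) <- out$set
  ord <- order(out$p, out$set)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "overlap_genes") <- ov
  out
}

#' Screen candidate target cell types of the sEV secretory miRNAs
#'
#' Pools the secretory miRNAs' target mRNAs, tests every cell type's
#' marker set for over-representation, and for each significant type
#' exports the bipartite secretory-miRNA -> marker-gene subnetwork as an
#' edge list. The globally most significant type is reported as the
#' headline candidate target cell.
#'
#' @param diff a classified `mir_diff` table (see
#'   [classify_compartments()]); rows with `compartment == "secretory"`
#'   define the signature.
#' @param interactions miRNA-mRNA [interaction_table()].
#' @param markers named list of marker gene sets.
#' @param alpha adjusted-p threshold for subnetwork export.
#' @param universe_policy see [collect_target_pool()].
#' @return List with `enrichment` (the test table), `subnetworks` (named
#'   list of edge data.frames), `headline` and `pool`.
#' @export
cell_type_screen <- function(diff, interactions, markers, alpha = 0.05,
                             universe_policy = "interaction") {
  secretory <- diff$mirna_id[diff$compartment == "secretory"]
  if (length(secretory) == 0)
    stop_input("no secretory miRNAs; run classify_compartments first")
  pool <- collect_target_pool(secretory, interactions, diff$mirna_id,
                              markers, universe_policy)
  enr <- hypergeometric_overrepresentation(pool, markers)
  sig <- enr$set[enr$p_adjusted < alpha]
  nets <- lapply(sig, function(ct) {
    keep <- interactions$source %in% secretory &
      interactions$target %in% intersect(markers[[ct]], pool$pool)
    edges <- interactions[keep, , drop = FALSE]
    edges$cell_type <- ct
    rownames(edges) <- NULL
    edges
  })
  names(nets) <- sig
  list(enrichment = enr, subnetworks = nets,
       headline = enr$set[1], pool = pool)
}
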