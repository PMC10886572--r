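#' Build per-RBP 2x2 contingency tables
#'
#' For each RNA-binding protein with at least one interaction inside the
#' detected miRNA universe, tabulates bound/unbound counts among
#' compartment-enriched miRNAs (a, b) and among the background (c, d),
#' where background = universe minus the enriched set, so the two groups
#' are disjoint. Edges to miRNAs outside the universe are ignored (their
#' count is reported in the `"n_ignored"` attribute).
#'
#' @param interactions miRNA-RBP [interaction_table()] (source = miRNA,
#'   target = RBP).
#' @param enriched character vector of compartment-enriched miRNA ids.
#' @param universe character vector of all detected miRNA ids.
#' @return data.frame with columns `rbp`, `a`, `b`, `c`, `d`.
#' @export
build_contingencies <- function(interactions, enriched, universe) {
  if (!all(enriched %in% universe))
    stop_input("enriched ids must be a subset of the universe")
  inside <- interactions$source %in% universe
  n_ignored <- sum(!inside)
  edges <- interactions[inside, , drop = FALSE]
  background <- setdiff(universe, enriched)
  bound <- split(unique(edges)[["source"]], unique(edges)[["target"]])
  rows <- lapply(names(bound), function(r) {
    a <- sum(bound[[r]] %in% enriched)
    cc <- length(bound[[r]]) - a
    data.frame(rbp = r, a = a, b = length(enriched) - a,
               c = cc, d = length(background) - cc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(rbp = character(), a = integer(), b = integer(),
               c = integer(), d = integer())
  attr(out, "n_ignored") <- n_ignored
  out
}

#' Chi-squared screen of RBPs for biased binding to enriched miRNAs
#'
#' Pearson chi-squared (no continuity correction) on each 2x2 table via
#' the closed form (ad - bc)^2 n / (r1 r2 c1 c2). Tables with any
#' expected cell below `expected_min` are flagged; with
#' `small = "exact"` they are instead tested by a two-sided exact
#' (Fisher) test. Tables with a zero column margin (no miRNA bound, or
#' every miRNA bound) are untestable and excluded from ranking. Results
#' are BH-adjusted and ranked by observed/expected ratio among RBPs with
#' adjusted p below `alpha`; ties are broken by p, then id.
#'
#' @param contingencies output of [build_contingencies()].
#' @param alpha adjusted-p threshold for the ranking.
#' @param small `"flag"` (default) or `"exact"`.
#' @param expected_min flag threshold on expected cell counts.
#' @param top_k size of the headline report.
#' @return List with `table` (all results) and `top` (the top-`top_k`
#'   over-represented RBPs by ratio).
#' @export
rbp_screen <- function(contingencies, alpha = 0.05,
                       small = c("flag", "exact"), expected_min = 5,
                       top_k = 10L) {
  small <- match.arg(small)
  ct <- contingencies
  if (nrow(ct) == 0) stop_input("no contingency tables to test")
  n <- ct$a + ct$b + ct$c + ct$d
  if (any(n < 1)) stop_input("empty contingency table")
  r1 <- ct$a + ct$b; r2 <- ct$c + ct$d
  c1 <- ct$a + ct$c; c2 <- ct$b + ct$d
  untestable <- c1 == 0 | c2 == 0 | r1 == 0 | r2 == 0
  chi2 <- ifelse(untestable, NA_real_,
                 n * (ct$a * ct$d - ct$b * ct$c)^2 /
                   (as.numeric(r1) * r2 * c1 * c2))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  expected_lo <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  flag_small <- !untestable & expected_lo < expected_min
  if (small == "exact" && any(flag_small)) {
    for (i in which(flag_small)) {
      p[i] <- fisher.test(matrix(c(ct$a[i], ct$b[i], ct$c[i], ct$d[i]),
                                 2, byrow = TRUE))$p.value
    }
  }
  ratio <- (ct$a / r1) / (c1 / n)
  out <- data.frame(rbp = ct$rbp, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
                    chi2 = chi2, p = p, p_adjusted = NA_real_,
                    obs_exp_ratio = ratio,
                    direction = ifelse(ratio >= 1, "over", "under"),
                    small_expected = flag_small,
                    untestable = untestable,
                    stringsAsFactors = FALSE)
  testable <- !untestable
  out$p_adjusted[testable] <- adjust_pvalues_bh(p[testable])
  ranked <- out[testable & out$p_adjusted < alpha & out$direction == "over", ]
  ranked <- ranked[order(-ranked$obs_exp_ratio, ranked$p, ranked$rbp), ]
  list(table = out, top = head(ranked, top_k))
}
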