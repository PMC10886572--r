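#' Score patients on an miRNA signature
#'
#' Each signature miRNA's expression is log2(x + 1)-transformed and
#' z-scored across patients; a patient's score is the mean over the
#' signature miRNAs available for them. Z-scoring makes the score
#' invariant to per-miRNA affine rescaling and stops abundant miRNAs
#' from dominating the mean. Zero-variance miRNA columns carry no
#' ordering information and are excluded with a warning.
#'
#' @param clinical a [clinical_table()].
#' @param signature character vector of signature miRNA ids.
#' @param min_coverage patients quantified on a smaller fraction of the
#'   signature are flagged.
#' @param signature_id label stored with the result (`"secretory"` /
#'   `"retention"` in the standard pipeline).
#' @return data.frame with `patient_id`, `score`, `coverage`, `flagged`;
#'   the usable signature is kept in the `"signature_used"` attribute.
#' @export
signature_score <- function(clinical, signature, min_coverage = 0.5,
                            signature_id = "secretory") {
  expr_cols <- attr(clinical, "expression_cols")
  present <- intersect(signature, expr_cols)
  if (length(present) == 0)
    stop_input("no signature miRNA found among expression columns")
  X <- log2(as.matrix(as.data.frame(clinical)[, present, drop = FALSE]) + 1)
  sds <- apply(X, 2, sd, na.rm = TRUE)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning("excluding zero-variance signature miRNA(s): ",
            paste(present[drop], collapse = ", "))
    present <- present[!drop]
    if (length(present) == 0)
      stop_input("all signature miRNAs have zero variance")
    X <- X[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  Z <- scale(X)
  score <- rowMeans(Z, na.rm = TRUE)
  coverage <- rowMeans(!is.na(Z))
  out <- data.frame(patient_id = clinical$patient_id, score = score,
                    coverage = coverage,
                    flagged = coverage < min_coverage,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "signature_used") <- present
  attr(out, "signature_id") <- signature_id
  out
}

#' Compare signature scores between patient groups
#'
#' Two groups: Welch (unequal-variance) unpaired t-test. More than two
#' groups: one-way ANOVA with post hoc Tukey HSD pairwise comparisons
#' (the nodal- and T-stage contrasts). Patients with a missing group
#' label are dropped and counted.
#'
#' @param scores a [signature_score()] data.frame.
#' @param grouping vector of group labels, parallel to `scores` (NA =
#'   missing).
#' @param design `"auto"` (by number of groups), `"two_group"` or
#'   `"multi_group"`.
#' @return List with `design`, `statistic`, `p_value`, `group_means`,
#'   `n_dropped` and, for the multi-group design, `pairwise` (Tukey HSD
#'   table).
#' @export
compare_groups <- function(scores, grouping,
                           design = c("auto", "two_group", "multi_group")) {
  design <- match.arg(design)
  grouping <- as.character(grouping)
  keep <- !is.na(grouping)
  n_dropped <- sum(!keep)
  s <- scores$score[keep]; g <- grouping[keep]
  tab <- table(g)
  if (length(tab) < 2) stop_input("need >= 2 non-empty groups")
  if (any(tab < 2))
    stop_input("group '", names(tab)[tab < 2][1], "' has < 2 patients")
  if (design == "auto")
    design <- if (length(tab) == 2) "two_group" else "multi_group"
  means <- tapply(s, g, mean)
  if (design == "two_group") {
    if (length(tab) != 2) stop_input("two_group design needs 2 groups")
    tt <- t.test(s ~ g)
    list(design = design, statistic = unname(tt$statistic),
         p_value = tt$p.value, group_means = means,
         group_n = as.vector(tab), n_dropped = n_dropped)
  } else {
    fit <- aov(s ~ factor(g))
    an <- summary(fit)[[1]]
    tuk <- TukeyHSD(fit)[[1]]
    list(design = design, statistic = an[["F value"]][1],
         p_value = an[["Pr(>F)"]][1], group_means = means,
         group_n = as.vector(tab), n_dropped = n_dropped,
         pairwise = tuk)
  }
}

#' Nodal-stage and occult-metastasis score contrasts
#'
#' Three two-group comparisons of the signature score: (i) clinically
#' node-negative (cN0) vs clinically node-positive; (ii) within cN0,
#' pathologically node-negative vs node-positive -- the occult-metastasis
#' contrast; (iii) pathologically node-negative vs node-positive overall.
#' A comparison whose subgroup is empty (or too small to test) is
#' reported with status `"skipped"` rather than an error.
#'
#' @param scores a [signature_score()] data.frame.
#' @param clinical the matching [clinical_table()] (must carry `cN` and
#'   `pN`).
#' @return Named list of three comparisons, each with `status` and, when
#'   run, the [compare_groups()] result.
#' @export
occult_contrast <- function(scores, clinical) {
  if (!all(c("cN", "pN") %in% names(clinical)))
    stop_input("clinical table must carry cN and pN stages")
  stopifnot(identical(scores$patient_id, clinical$patient_id))
  cn_pos <- ifelse(is.na(clinical$cN), NA,
                   ifelse(clinical$cN == "N0", "cN0", "cN1-3"))
  pn_pos <- ifelse(is.na(clinical$pN), NA,
                   ifelse(clinical$pN == "N0", "pN0", "pN+"))
  run <- function(lab, sel = rep(TRUE, nrow(scores))) {
    lab[!sel] <- NA
    tab <- table(lab)
    if (length(tab) < 2 || any(tab < 2))
      return(list(status = "skipped",
                  reason = "a subgroup is empty or has < 2 patients"))
    c(list(status = "ok"), compare_groups(scores, lab, "two_group"))
  }
  list(
    cN0_vs_cNpos = run(cn_pos),
    occult_within_cN0 = run(pn_pos, sel = !is.na(cn_pos) & cn_pos == "cN0"),
    pN0_vs_pNpos = run(pn_pos)
  )
}

km_curve <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time[event == 1])
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             survival = surv)
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' Product-limit survivor curves per group (deaths precede censorings at
#' tied times) and, for two groups, the log-rank statistic
#' (sum(O - E))^2 / sum(V) with the hypergeometric variance at each
#' distinct event time, referred to chi-square with 1 df. A single group
#' yields the curve only.
#'
#' @param time positive survival times.
#' @param event 0/1 event indicators (>= 1 event required).
#' @param group group labels (1 or 2 distinct values).
#' @return List of class `mir_survfit` with `fits` (per-group KM
#'   data.frames), `statistic`, `p_value` and `group_n`.
#' @export
km_logrank <- function(time, event, group) {
  if (any(!is.finite(time) | time <= 0)) stop_input("times must be > 0")
  if (!all(event %in% c(0, 1))) stop_input("event must be 0/1")
  if (sum(event) == 0) stop_input("no events observed")
  group <- as.character(group)
  glev <- sort(unique(group))
  if (length(glev) > 2) stop_input("log-rank comparison supports 2 groups")
  fits <- lapply(glev, function(g) km_curve(time[group == g],
                                            event[group == g]))
  names(fits) <- glev
  stat <- p <- NA_real_
  if (length(glev) == 2) {
    ord <- order(time)
    stat <- cpp_logrank(time[ord], as.integer(event[ord]),
                        as.integer(group[ord] == glev[2]))
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(fits = fits, statistic = stat, p_value = p,
                 group_n = table(group)),
            class = "mir_survfit")
}

#' Lowest-p cutpoint survival analysis with a selection-bias guardrail
#'
#' Scans every distinct score value between the 10% and 90% score
#' quantiles as a candidate high/low cutpoint, keeps cuts leaving each
#' arm at least max(10, 10% of n) patients, and returns the cut with the
#' smallest log-rank p. The minimal p is selection-biased by
#' construction, so the full (cutpoint, p) scan is always attached and,
#' when `n_perm > 0`, a permutation-adjusted p (min-p distribution under
#' score permutation) is reported alongside the uncorrected one.
#'
#' @param scores numeric score vector (or a [signature_score()]
#'   data.frame).
#' @param time,event survival outcome, parallel to `scores`.
#' @param n_perm permutations for the adjusted p (0 = skip).
#' @param min_arm_frac,min_arm_n arm-size floor: each arm must hold at
#'   least `max(min_arm_n, ceiling(min_arm_frac * n))` patients.
#' @param quantile_band score-quantile band searched for cuts.
#' @param seed seed for the permutation draw.
#' @return List with `cutpoint`, `statistic`, `p_value`,
#'   `p_perm_adjusted` (NA when `n_perm = 0`), `scan` (data.frame of all
#'   candidate cuts), `fit` (the [km_logrank()] at the chosen cut) and
#'   `high_worse` (logical: does the high-score arm have lower survival).
#' @export
optimal_cutpoint_survival <- function(scores, time, event, n_perm = 0L,
                                      min_arm_frac = 0.1, min_arm_n = 10L,
                                      quantile_band = c(0.1, 0.9),
                                      seed = 1L) {
  s <- if (is.data.frame(scores)) scores$score else scores
  n <- length(s)
  if (n < 20) stop_input("need n >= 20 for a cutpoint scan")
  if (any(!is.finite(time) | time <= 0)) stop_input("times must be > 0")
  if (sum(event) == 0) stop_input("no events observed")
  qs <- quantile(s, quantile_band)
  cuts <- sort(unique(s[s >= qs[1] & s <= qs[2]]))
  floor_n <- max(min_arm_n, ceiling(min_arm_frac * n))
  n_high <- vapply(cuts, function(cc) sum(s > cc), 0L)
  admissible <- n_high >= floor_n & (n - n_high) >= floor_n
  if (!any(admissible)) stop_input("no admissible cutpoint (scores too ",
                                   "concentrated or n too small)")
  ord <- order(time)
  t_s <- time[ord]; e_s <- as.integer(event[ord]); s_s <- s[ord]
  stat <- cpp_cut_scan(t_s, e_s, s_s, cuts)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  scan <- data.frame(cutpoint = cuts, n_high = n_high, n_low = n - n_high,
                     admissible = admissible, statistic = stat, p = p)
  cand <- which(admissible & is.finite(p))
  if (length(cand) == 0) stop_input("no testable admissible cutpoint")
  best <- cand[which.min(p[cand])]
  obs_min_p <- p[best]
  p_adj <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      sp <- sample(s_s)
      pb <- pchisq(cpp_cut_scan(t_s, e_s, sp, cuts), 1, lower.tail = FALSE)
      mb <- suppressWarnings(min(pb[admissible], na.rm = TRUE))
      if (is.finite(mb) && mb <= obs_min_p) hits <- hits + 1L
    }
    p_adj <- (1 + hits) / (1 + n_perm)
  }
  grp <- ifelse(s > cuts[best], "high", "low")
  fit <- km_logrank(time, event, grp)
  high_worse <- mean_km_surv(fit$fits[["high"]], max(time)) <
    mean_km_surv(fit$fits[["low"]], max(time))
  list(cutpoint = cuts[best], statistic = stat[best], p_value = obs_min_p,
       p_perm_adjusted = p_adj, n_perm = n_perm, scan = scan, fit = fit,
       high_worse = high_worse)
}

# area under the KM step function up to horizon (restricted mean survival)
mean_km_surv <- function(fit, horizon) {
  tt <- c(0, fit$time[fit$time <= horizon], horizon)
  ss <- c(1, fit$survival[fit$time <= horizon])
  sum(diff(tt) * ss) / horizon
}
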