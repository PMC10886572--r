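#' Simulation configuration for the synthetic secretome experiment
#'
#' Bundles every parameter of the synthetic-data generators: the planted
#' sorting motif and its carrier fraction, the negative-binomial count
#' model for the 2-line x 2-compartment x replicate design, the biased
#' RBP binding model, the marker-set overlap model and the clinical
#' cohort model. All downstream ground-truth recovery tests are driven by
#' these values.
#'
#' @param seed integer seed; every generator is deterministic given it.
#' @param n_mirnas number of simulated miRNAs.
#' @param length_range integer pair, mature-sequence length range (nt).
#' @param motif planted sorting motif, a string over A/C/G/U.
#' @param carrier_fraction fraction of miRNAs carrying the motif.
#' @param secretion_shift_log2 mean log2 fold change (sEV vs cell) added
#'   to carriers; per-carrier effects are jittered around it.
#' @param effect_sd sd of the per-miRNA jitter around the mean effect
#'   (carriers) and around zero (all other miRNAs); 0 gives an exact
#'   null for non-carriers.
#' @param baseline_mean_log meanlog/sdlog of the log-normal baseline
#'   expression means.
#' @param dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2); 0 gives the Poisson limit.
#' @param replicates biological replicates per condition per cell line.
#' @param n_lines number of cell lines.
#' @param size_factor_range library size factors drawn log-uniformly here.
#' @param n_rbps,enriched_rbp_count RBP universe size and number with
#'   binding biased toward secretory miRNAs.
#' @param p_bind_secretory,p_bind_background binding probability of an
#'   enriched RBP to a secretory miRNA, and the background probability
#'   used everywhere else.
#' @param n_genes size of the target-gene universe.
#' @param targets_per_mirna number of mRNA targets drawn per miRNA.
#' @param n_cell_types number of simulated cell types (1 true + decoys).
#' @param markers_per_type marker genes per cell type.
#' @param target_overlap_fraction fraction of the true cell type's markers
#'   drawn from the secretory target pool; `NULL` makes the true type a
#'   decoy (chance-level overlap, the null configuration).
#' @param n_patients cohort size.
#' @param hazard_coefficient gamma, log-hazard per unit latent score.
#' @param baseline_hazard exponential baseline hazard (events/day).
#' @param censor_max uniform censoring window upper bound (days).
#' @param stage_logit_slope slope of the latent score in the logit of
#'   nodal positivity.
#' @param stage_fn_rate probability a pathologically node-positive patient
#'   is clinically staged N0 (creates occult-metastasis cases).
#' @param expr_noise_sd sd of per-miRNA noise around the latent score in
#'   the cohort expression columns.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_mirnas = 500L,
                       length_range = c(18L, 25L),
                       motif = "GCGC",
                       carrier_fraction = 0.2,
                       secretion_shift_log2 = 2.0,
                       effect_sd = 0.25,
                       baseline_mean_log = c(log(100), 1.0),
                       dispersion = 0.1,
                       replicates = 3L,
                       n_lines = 2L,
                       size_factor_range = c(0.5, 2),
                       n_rbps = 50L,
                       enriched_rbp_count = 5L,
                       p_bind_secretory = 0.5,
                       p_bind_background = 0.1,
                       n_genes = 5000L,
                       targets_per_mirna = 8L,
                       n_cell_types = 9L,
                       markers_per_type = 50L,
                       target_overlap_fraction = 0.6,
                       n_patients = 300L,
                       hazard_coefficient = 1.0,
                       baseline_hazard = 1 / 1000,
                       censor_max = 3000,
                       stage_logit_slope = 1.0,
                       stage_fn_rate = 0.3,
                       expr_noise_sd = 0.5) {
  seed <- check_count(seed, "seed", min = 0L)
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  replicates <- check_count(replicates, "replicates")
  motif <- toupper(motif)
  if (!grepl("^[ACGU]+$", motif))
    stop_input("motif must be a string over A/C/G/U")
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < nchar(motif))
    stop_input("length_range must be an increasing pair >= motif length")
  check_prob(carrier_fraction, "carrier_fraction")
  if (!is.numeric(dispersion) || dispersion < 0)
    stop_input("dispersion must be >= 0")
  if (any(size_factor_range <= 0) || size_factor_range[1] > size_factor_range[2])
    stop_input("size_factor_range must be a positive increasing pair")
  check_prob(p_bind_secretory, "p_bind_secretory")
  check_prob(p_bind_background, "p_bind_background")
  if (!is.null(target_overlap_fraction) &&
      !(target_overlap_fraction > 0 && target_overlap_fraction <= 1))
    stop_input("target_overlap_fraction must be in (0, 1]")
  check_prob(stage_fn_rate, "stage_fn_rate", open = FALSE)
  if (baseline_hazard <= 0) stop_input("baseline_hazard must be > 0")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

random_rna <- function(n, len_min, len_max) {
  lens <- sample(len_min:len_max, n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(rna_alphabet, L, replace = TRUE), collapse = ""), "")
}

#' Generate mature miRNA sequences with a planted sorting motif
#'
#' Exactly `round(carrier_fraction * n_mirnas)` sequences contain the
#' motif as a contiguous substring (inserted at a uniformly chosen
#' position); the remaining sequences are rejection-sampled so they do
#' not contain it. All other bases are iid uniform over A/C/G/U.
#'
#' @param cfg a [sim_config()].
#' @param max_retry rejection-sampling cap per non-carrier sequence.
#' @return List with `sequences` (named character vector) and `carriers`
#'   (ids of motif-carrying miRNAs).
#' @export
generate_sequences_with_motif <- function(cfg, max_retry = 1000L) {
  set.seed(cfg$seed + 11L)
  n <- cfg$n_mirnas
  ids <- sprintf("sim-miR-%04d", seq_len(n))
  n_carrier <- round(cfg$carrier_fraction * n)
  carrier_idx <- sort(sample.int(n, n_carrier))
  motif <- cfg$motif
  k <- nchar(motif)
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (i %in% carrier_idx) {
      s <- random_rna(1, cfg$length_range[1], cfg$length_range[2])
      pos <- sample.int(nchar(s) - k + 1L, 1L)
      substr(s, pos, pos + k - 1L) <- motif
      seqs[i] <- s
    } else {
      for (try in seq_len(max_retry)) {
        s <- random_rna(1, cfg$length_range[1], cfg$length_range[2])
        if (!grepl(motif, s, fixed = TRUE)) break
        if (try == max_retry)
          stop_input("could not sample a motif-free sequence after ",
                     max_retry, " tries; use a longer motif")
      }
      seqs[i] <- s
    }
  }
  names(seqs) <- ids
  list(sequences = seqs, carriers = ids[carrier_idx])
}

#' Simulate the sEV-vs-cell miRNA count experiment
#'
#' Counts follow NB(mean = s_j * lambda_g * 2^(beta_g * 1\[sEV\]),
#' dispersion alpha) over a `n_lines` x \{cell, sEV\} x `replicates`
#' design. Carriers of the planted motif get
#' beta ~ Normal(shift, effect_sd); all other miRNAs get
#' beta ~ Normal(0, effect_sd).
#'
#' @param cfg a [sim_config()].
#' @param carriers character vector of carrier miRNA ids (subset of the
#'   simulated ids).
#' @param mirna_ids optional explicit miRNA ids; defaults to the ids the
#'   sequence generator produces for `cfg`.
#' @return List with `counts` (a [count_matrix()]) and `truth`
#'   (data.frame of realized per-miRNA log2 fold changes).
#' @export
simulate_count_experiment <- function(cfg, carriers = character(),
                                      mirna_ids = NULL) {
  set.seed(cfg$seed + 23L)
  n <- cfg$n_mirnas
  ids <- mirna_ids %||% sprintf("sim-miR-%04d", seq_len(n))
  if (!all(carriers %in% ids)) stop_input("carriers must be simulated ids")
  lines <- paste0("L", seq_len(cfg$n_lines))
  design <- expand.grid(rep = seq_len(cfg$replicates),
                        condition = c("cell", "sev"),
                        cell_line = lines,
                        stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%s_%d", design$cell_line, design$condition,
                        design$rep),
    condition = design$condition,
    cell_line = design$cell_line,
    stringsAsFactors = FALSE)
  m <- nrow(samples)
  lambda <- rlnorm(n, cfg$baseline_mean_log[1], cfg$baseline_mean_log[2])
  is_carrier <- ids %in% carriers
  beta <- rnorm(n, ifelse(is_carrier, cfg$secretion_shift_log2, 0),
                cfg$effect_sd)
  sf <- exp(runif(m, log(cfg$size_factor_range[1]),
                  log(cfg$size_factor_range[2])))
  is_sev <- samples$condition == "sev"
  mu <- outer(lambda, sf) * 2^(beta %o% as.numeric(is_sev))
  counts <- matrix(0L, n, m, dimnames = list(ids, samples$sample_id))
  if (cfg$dispersion > 0) {
    counts[] <- rnbinom(n * m, mu = mu, size = 1 / cfg$dispersion)
  } else {
    counts[] <- stats::rpois(n * m, lambda = mu)
  }
  truth <- data.frame(mirna_id = ids, carrier = is_carrier,
                      log2fc_true = beta, baseline_mean = lambda,
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, samples), truth = truth,
       size_factors_true = setNames(sf, samples$sample_id))
}

#' Simulate miRNA-RBP and miRNA-mRNA interaction tables and marker sets
#'
#' Enriched RBPs bind secretory miRNAs with `p_bind_secretory` and other
#' miRNAs with `p_bind_background`; non-enriched RBPs bind everything at
#' background rate. Each miRNA targets a random gene pool; the true cell
#' type's markers overlap the pooled secretory targets at
#' `target_overlap_fraction`, decoy cell types' markers are drawn from
#' universe genes outside that pool.
#'
#' @param cfg a [sim_config()].
#' @param secretory character vector of secretory miRNA ids.
#' @param mirna_ids all simulated miRNA ids (the detected universe).
#' @return List with `rbp` and `mrna` interaction tables, `markers`
#'   (named list), `enriched_rbps` and `true_cell_type`.
#' @export
simulate_interaction_tables <- function(cfg, secretory, mirna_ids) {
  set.seed(cfg$seed + 37L)
  if (!all(secretory %in% mirna_ids))
    stop_input("secretory ids must be simulated ids")
  rbps <- sprintf("RBP%02d", seq_len(cfg$n_rbps))
  enriched <- rbps[seq_len(cfg$enriched_rbp_count)]
  is_sec <- mirna_ids %in% secretory
  src <- character(0); tgt <- character(0)
  for (r in rbps) {
    p <- ifelse(r %in% enriched & is_sec, cfg$p_bind_secretory,
                cfg$p_bind_background)
    hit <- runif(length(mirna_ids)) < p
    src <- c(src, mirna_ids[hit])
    tgt <- c(tgt, rep(r, sum(hit)))
  }
  rbp_tab <- interaction_table(src, tgt, "mirna-rbp")

  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  target_list <- lapply(mirna_ids, function(m)
    sample(genes, cfg$targets_per_mirna))
  names(target_list) <- mirna_ids
  mrna_tab <- interaction_table(
    rep(mirna_ids, lengths(target_list)),
    unlist(target_list, use.names = FALSE), "mirna-mrna")

  universe <- unique(unlist(target_list, use.names = FALSE))
  pool <- unique(unlist(target_list[secretory], use.names = FALSE))
  off_pool <- setdiff(universe, pool)
  types <- c("true_type", sprintf("decoy_type%02d",
                                  seq_len(cfg$n_cell_types - 1L)))
  markers <- vector("list", length(types))
  names(markers) <- types
  for (ct in types) {
    if (ct == "true_type" && !is.null(cfg$target_overlap_fraction)) {
      n_in <- round(cfg$target_overlap_fraction * cfg$markers_per_type)
      markers[[ct]] <- c(sample(pool, min(n_in, length(pool))),
                         sample(off_pool, cfg$markers_per_type - n_in))
    } else {
      markers[[ct]] <- sample(off_pool, cfg$markers_per_type)
    }
  }
  list(rbp = rbp_tab, mrna = mrna_tab, markers = markers,
       enriched_rbps = enriched, true_cell_type = "true_type")
}

#' Simulate a clinical cohort whose stage and hazard track a signature
#'
#' Each patient carries a latent score z ~ Normal(0,1). Signature miRNA
#' log2-expressions are z plus independent noise (stored on a positive
#' linear scale around 2^6 reads). Survival time is exponential with
#' hazard `baseline_hazard * exp(gamma z)` under independent uniform
#' censoring; nodal positivity follows a logit in z, and clinical N stage
#' is the pathological stage masked to N0 at the false-negative rate
#' (producing occult-metastasis cases). pT is independent of z, matching
#' the absent T-stage association this design emulates.
#'
#' @param cfg a [sim_config()].
#' @param signature character vector of signature miRNA ids (used as
#'   expression column names).
#' @return List with `clinical` (a [clinical_table()]) and `truth`
#'   (data.frame with the latent scores).
#' @export
simulate_clinical_cohort <- function(cfg, signature) {
  set.seed(cfg$seed + 53L)
  if (length(signature) == 0) stop_input("signature must be non-empty")
  n <- cfg$n_patients
  z <- rnorm(n)
  expr <- vapply(signature, function(s)
    2^(6 + z + rnorm(n, 0, cfg$expr_noise_sd)), numeric(n))
  t_event <- rexp(n, rate = cfg$baseline_hazard *
                    exp(cfg$hazard_coefficient * z))
  t_cens <- runif(n, 0, cfg$censor_max)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  # cumulative-logit nodal stage: thresholds at 0 / 1.5 / 3 on the logit
  eta <- cfg$stage_logit_slope * z
  u <- runif(n)
  pN <- ifelse(u < stats::plogis(eta - 3), "N3",
          ifelse(u < stats::plogis(eta - 1.5), "N2",
            ifelse(u < stats::plogis(eta), "N1", "N0")))
  cN <- pN
  occ <- pN != "N0" & runif(n) < cfg$stage_fn_rate
  cN[occ] <- "N0"
  pT <- sample(paste0("T", 1:4), n, replace = TRUE,
               prob = c(0.25, 0.35, 0.25, 0.15))
  tab <- data.frame(patient_id = sprintf("PT%04d", seq_len(n)),
                    time = pmax(time, 1e-6), event = event,
                    pT = pT, pN = pN, cN = cN,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(expr, check.names = FALSE))
  list(clinical = clinical_table(tab),
       truth = data.frame(patient_id = tab$patient_id, score_true = z,
                          occult = occ, stringsAsFactors = FALSE))
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Generates sequences, counts, interaction tables, markers and a
#' clinical cohort for one configuration and writes them in the external
#' formats the readers consume (FASTA, TSV, GMT, JSON ground truth).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the generated in-memory objects.
#' @export
simulate_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sq <- generate_sequences_with_motif(cfg)
  ex <- simulate_count_experiment(cfg, sq$carriers)
  it <- simulate_interaction_tables(cfg, sq$carriers, names(sq$sequences))
  ch <- simulate_clinical_cohort(cfg, sq$carriers)
  write_sequences_fasta(sq$sequences, p("sequences.fasta"))
  write_count_matrix(ex$counts, p("counts.tsv"), p("samples.tsv"))
  write_interaction_table(it$rbp, p("mirna_rbp.tsv"))
  write_interaction_table(it$mrna, p("mirna_mrna.tsv"))
  write_marker_table(it$markers, p("markers.tsv"))
  write_clinical_table(ch$clinical, p("clinical.tsv"))
  truth <- list(carriers = sq$carriers,
                log2fc_true = setNames(ex$truth$log2fc_true,
                                       ex$truth$mirna_id),
                enriched_rbps = it$enriched_rbps,
                true_cell_type = it$true_cell_type,
                score_true = setNames(ch$truth$score_true,
                                      ch$truth$patient_id))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(sequences = sq, experiment = ex, interactions = it,
                 cohort = ch))
}
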