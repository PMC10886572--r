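#' Default pipeline configuration
#'
#' @param out_dir run directory (all stage outputs and the manifest go
#'   here).
#' @param seed integer seed used by every stochastic stage.
#' @param ... overrides for any default field (stage toggles under
#'   `stages`, input paths under `inputs`, thresholds at the top level).
#' @return A config list understood by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, seed, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = check_count(seed, "seed", min = 0L),
    stages = list(simulate = TRUE, diff = TRUE, motifs = TRUE,
                  rbp = TRUE, celltypes = TRUE, clinical = TRUE),
    inputs = list(counts = NULL, samples = NULL, fasta = NULL,
                  rbp = NULL, mrna = NULL, markers = NULL,
                  clinical = NULL),
    p_adj_cutoff = 0.05,
    profile = "screen",
    k_min = 4L, k_max = 7L, min_set_size = 6L,
    n_perm = 1000L,
    weight = 1,
    n_clusters = 4L,
    min_arm_n = 10L, min_arm_frac = 0.1,
    cutpoint_n_perm = 0L,
    sim = list()
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

validate_run_config <- function(cfg) {
  check_count(cfg$seed, "seed", min = 0L)
  check_prob(cfg$p_adj_cutoff, "p_adj_cutoff")
  if (!cfg$profile %in% c("screen", "strict"))
    stop_input("profile must be 'screen' or 'strict'")
  check_count(cfg$k_min, "k_min"); check_count(cfg$k_max, "k_max")
  if (cfg$k_min > cfg$k_max) stop_input("k_min must be <= k_max")
  check_count(cfg$min_set_size, "min_set_size")
  check_count(cfg$n_perm, "n_perm", min = 100L)
  invisible(cfg)
}

default_input <- function(cfg, key, file) {
  cfg$inputs[[key]] %||% file.path(cfg$out_dir, file)
}

#' Run the end-to-end secretome analysis pipeline
#'
#' Orchestrates simulate -> differential abundance -> motif screen ->
#' RBP screen -> target-cell-type screen -> clinical signature analysis
#' from one configuration. Stages communicate through files (TSV, GMT,
#' FASTA) under `out_dir`, so any stage is independently re-runnable;
#' enabled stages run in dependency order, a failing stage halts its
#' dependents, and a machine-readable manifest (stage statuses, output
#' paths, parameter echo, output checksums) is written to
#' `manifest.json`. The whole run is deterministic given the seed.
#'
#' @param config a [pipeline_config()] list, or the path of a YAML file
#'   holding one.
#' @return The manifest, invisibly (also written to disk).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_input("reading YAML configs needs the yaml package")
    config <- do.call(pipeline_config,
                      yaml::read_yaml(config))
  }
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  on_stage <- function(x) isTRUE(cfg$stages[[x]])

  # pre-flight: every enabled stage must have its inputs available
  need <- character(0)
  if (!on_stage("simulate")) {
    if (on_stage("diff"))
      need <- c(need, default_input(cfg, "counts", "counts.tsv"),
                default_input(cfg, "samples", "samples.tsv"))
    if (on_stage("motifs"))
      need <- c(need, default_input(cfg, "fasta", "sequences.fasta"))
    if (on_stage("rbp"))
      need <- c(need, default_input(cfg, "rbp", "mirna_rbp.tsv"))
    if (on_stage("celltypes"))
      need <- c(need, default_input(cfg, "mrna", "mirna_mrna.tsv"),
                default_input(cfg, "markers", "markers.tsv"))
    if (on_stage("clinical"))
      need <- c(need, default_input(cfg, "clinical", "clinical.tsv"))
    miss <- need[!file.exists(need)]
    if (length(miss) > 0)
      stop_input("missing input file(s): ", paste(miss, collapse = ", "))
  }

  manifest <- list(seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg),
                                            c("stages", "inputs", "sim"))],
                   stages = list())
  outputs <- character(0)
  halted <- FALSE
  run_stage <- function(name, deps_ok, fn) {
    if (!on_stage(name)) {
      manifest$stages[[name]] <<- list(status = "disabled")
      return(NULL)
    }
    if (halted || !deps_ok) {
      manifest$stages[[name]] <<- list(status = "halted")
      return(NULL)
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      halted <<- TRUE
      return(NULL)
    }
    manifest$stages[[name]] <<- c(list(status = "ok"), res$log)
    outputs <<- c(outputs, res$files)
    res$value
  }
  p <- function(f) file.path(cfg$out_dir, f)

  run_stage("simulate", TRUE, function() {
    sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    simulate_bundle(sim, cfg$out_dir)
    files <- file.path(cfg$out_dir,
                       c("sequences.fasta", "counts.tsv", "samples.tsv",
                         "mirna_rbp.tsv", "mirna_mrna.tsv", "markers.tsv",
                         "clinical.tsv", "truth.json"))
    list(value = TRUE, files = files,
         log = list(n_mirnas = sim$n_mirnas))
  })

  diff <- run_stage("diff", TRUE, function() {
    x <- read_count_matrix(default_input(cfg, "counts", "counts.tsv"),
                           default_input(cfg, "samples", "samples.tsv"))
    d <- differential_test(x)
    d <- classify_compartments(d, cfg$profile, cfg$p_adj_cutoff)
    cl <- cluster_expression(x, cfg$n_clusters)
    write.table(as.data.frame(d), p("differential.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(mirna_id = names(cl$cluster),
                           cluster = cl$cluster),
                p("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(value = d, files = p(c("differential.tsv", "clusters.tsv")),
         log = list(n_detected = nrow(d),
                    n_all_zero = length(attr(d, "excluded")),
                    n_secretory = sum(d$compartment == "secretory"),
                    n_retained = sum(d$compartment == "retained")))
  })

  run_stage("motifs", !is.null(diff), function() {
    seqs <- read_sequences_fasta(default_input(cfg, "fasta",
                                               "sequences.fasta"))
    res <- motif_screen(diff, seqs, cfg$k_min, cfg$k_max,
                        cfg$min_set_size, cfg$n_perm, cfg$weight,
                        seed = cfg$seed)
    write.table(as.data.frame(res), p("motif_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_gmt(attr(res, "sets"), p("motif_sets.gmt"),
              description = "kmer motif members")
    list(value = res, files = p(c("motif_results.tsv", "motif_sets.gmt")),
         log = list(n_sets = nrow(res)))
  })

  run_stage("rbp", !is.null(diff), function() {
    it <- read_interaction_table(default_input(cfg, "rbp",
                                               "mirna_rbp.tsv"),
                                 "mirna-rbp")
    files <- character(0); log <- list()
    for (comp in c("secretory", "retained")) {
      enr <- diff$mirna_id[diff$compartment == comp]
      if (length(enr) == 0) { log[[comp]] <- "no miRNAs"; next }
      ct <- build_contingencies(it, enr, diff$mirna_id)
      scr <- rbp_screen(ct, alpha = cfg$p_adj_cutoff)
      f1 <- p(sprintf("rbp_%s.tsv", comp))
      f2 <- p(sprintf("rbp_%s_top.tsv", comp))
      write.table(scr$table, f1, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(scr$top, f2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f1, f2)
      log[[comp]] <- nrow(scr$top)
    }
    list(value = TRUE, files = files, log = list(top_counts = log))
  })

  run_stage("celltypes", !is.null(diff), function() {
    it <- read_interaction_table(default_input(cfg, "mrna",
                                               "mirna_mrna.tsv"),
                                 "mirna-mrna")
    mk <- read_marker_table(default_input(cfg, "markers", "markers.tsv"))
    scr <- cell_type_screen(diff, it, mk, alpha = cfg$p_adj_cutoff)
    write.table(scr$enrichment, p("celltype_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- p("celltype_enrichment.tsv")
    for (ct in names(scr$subnetworks)) {
      f <- p(sprintf("network_%s.tsv", gsub("[^A-Za-z0-9_]", "_", ct)))
      write_interaction_table(scr$subnetworks[[ct]], f)
      files <- c(files, f)
    }
    list(value = scr, files = files,
         log = list(headline = scr$headline,
                    n_significant = length(scr$subnetworks)))
  })

  run_stage("clinical", !is.null(diff), function() {
    cl <- read_clinical_table(default_input(cfg, "clinical",
                                            "clinical.tsv"))
    sig <- diff$mirna_id[diff$compartment == "secretory"]
    sc <- signature_score(cl, sig)
    occ <- occult_contrast(sc, cl)
    cut <- optimal_cutpoint_survival(sc, cl$time, cl$event,
                                     n_perm = cfg$cutpoint_n_perm,
                                     min_arm_frac = cfg$min_arm_frac,
                                     min_arm_n = cfg$min_arm_n,
                                     seed = cfg$seed)
    write.table(sc, p("signature_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(cut$scan, p("cutpoint_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- p(c("signature_scores.tsv", "cutpoint_scan.tsv"))
    for (g in names(cut$fit$fits)) {
      f <- p(sprintf("km_%s.tsv", g))
      write.table(cut$fit$fits[[g]], f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f)
    }
    occ_tab <- data.frame(
      comparison = names(occ),
      status = vapply(occ, `[[`, "", "status"),
      p_value = vapply(occ, function(o) o$p_value %||% NA_real_, 0),
      stringsAsFactors = FALSE)
    write.table(occ_tab, p("occult_contrasts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, p("occult_contrasts.tsv"))
    list(value = list(scores = sc, occult = occ, cut = cut),
         files = files,
         log = list(cutpoint_p = cut$p_value,
                    occult_status = occ_tab$status))
  })

  manifest$outputs <- outputs
  manifest$checksums <- as.list(tools::md5sum(outputs[file.exists(outputs)]))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
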