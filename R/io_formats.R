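#' Construct a validated miRNA count matrix
#'
#' The central container for the pipeline: an miRNA x sample matrix of
#' non-negative integer counts together with per-sample compartment
#' (`"cell"` or `"sev"`) and cell-line annotations.
#'
#' @param counts integer matrix, rows = miRNAs, columns = samples, with
#'   rownames and colnames set.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"cell"`/`"sev"`) and `cell_line`; one row per column of `counts`.
#' @return An object of class `mir_counts`: a list with elements `counts`
#'   (the matrix) and `samples` (the annotation table, ordered as the
#'   matrix columns).
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts)) stop_input("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_input("counts must have miRNA rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_input("duplicate miRNA id: ",
               rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop_input("duplicate sample id: ",
               colnames(counts)[duplicated(colnames(counts))][1])
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop_input("counts must be finite numbers")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("negative or non-integer count at miRNA '",
               rownames(counts)[bad[1, 1]], "', sample '",
               colnames(counts)[bad[1, 2]], "'")
  req <- c("sample_id", "condition", "cell_line")
  if (!all(req %in% names(samples)))
    stop_input("sample metadata needs columns: ", paste(req, collapse = ", "))
  missing_meta <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_meta) > 0)
    stop_input("sample missing from metadata: ", missing_meta[1])
  samples <- samples[match(colnames(counts), samples$sample_id), req,
                     drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$condition %in% c("cell", "sev")))
    stop_input("condition labels must be 'cell' or 'sev'")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat(sprintf("mir_counts: %d miRNAs x %d samples (%d cell, %d sEV)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$condition == "cell"),
              sum(x$samples$condition == "sev")))
  invisible(x)
}

#' Read an miRNA count matrix and its sample metadata from TSV
#'
#' The matrix TSV has a header row of sample ids and miRNA ids in the first
#' column; the metadata TSV maps `sample_id` to `condition` and `cell_line`.
#' Row and column order are preserved from the files.
#'
#' @param path path to the count TSV.
#' @param meta_path path to the sample metadata TSV.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_input("count matrix needs >= 1 sample column")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop_input("non-numeric count in ", path)
  rownames(mat) <- ids
  meta <- read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE)
  count_matrix(mat, meta)
}

#' Write a count matrix and its metadata as TSV
#' @param x a `mir_counts` object.
#' @param path,meta_path output paths for the matrix and metadata TSVs.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, path, meta_path) {
  tab <- data.frame(mirna_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

#' Read mature miRNA sequences from FASTA
#'
#' Sequences are uppercased and DNA-style `T` is converted to `U`, so all
#' downstream motif matching uses the RNA alphabet. The id is the header
#' token up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_sequences_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || !startsWith(lines[1], ">"))
    stop_input("not a FASTA file: ", path)
  hdr <- startsWith(lines, ">")
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  names(seqs) <- ids[as.integer(names(seqs))]
  if (length(seqs) < sum(hdr)) stop_input("FASTA record with empty sequence")
  validate_sequences(seqs)
}

validate_sequences <- function(seqs) {
  if (anyDuplicated(names(seqs)))
    stop_input("duplicate sequence id: ",
               names(seqs)[duplicated(names(seqs))][1])
  seqs <- chartr("t", "u", chartr("T", "U", toupper(seqs)))
  bad <- regexpr("[^ACGU]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_input("invalid character in sequence '", names(seqs)[i],
               "' at position ", bad[i])
  }
  if (any(nchar(seqs) < 1)) stop_input("empty sequence")
  seqs
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return Invisibly, `seqs`.
#' @export
write_sequences_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(seqs)
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then members, all tab-separated.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (member ids); descriptions kept
#'   in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop_input("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop_input("duplicate set name: ", names(sets)[duplicated(names(sets))][1])
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (length(sets) == 0) stop_input("empty gene-set collection")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

#' Read an interaction edge list (miRNA-RBP or miRNA-mRNA) from TSV
#'
#' Two-column TSV, source then target; an optional header is detected when
#' the first line contains no value seen again in the body. Duplicate edges
#' are removed.
#'
#' @param path path to the TSV.
#' @param kind `"mirna-rbp"` or `"mirna-mrna"`.
#' @param header does the file carry a header line?
#' @return data.frame with columns `source`, `target` and attribute `kind`.
#' @export
read_interaction_table <- function(path, kind = c("mirna-rbp", "mirna-mrna"),
                                   header = TRUE) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    warning("empty interaction table: ", path)
    return(interaction_table(character(), character(), kind))
  }
  tab <- read.delim(path, sep = "\t", header = header,
                    stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop_input("interaction table needs 2 columns")
  empty <- !nzchar(tab[[1]]) | !nzchar(tab[[2]])
  if (any(empty))
    stop_input("empty id on interaction line ",
               which(empty)[1] + as.integer(header))
  interaction_table(tab[[1]], tab[[2]], kind)
}

#' @rdname read_interaction_table
#' @param source,target character vectors of edge endpoints.
#' @export
interaction_table <- function(source, target, kind = c("mirna-rbp",
                                                       "mirna-mrna")) {
  kind <- match.arg(kind)
  edges <- unique(data.frame(source = as.character(source),
                             target = as.character(target),
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  attr(edges, "kind") <- kind
  edges
}

#' Write an interaction table (or any edge list) as TSV
#' @param edges data.frame with columns `source` and `target` (an optional
#'   third column is written too, giving a SIF-style annotated edge list).
#' @param path output path.
#' @param header write the header line?
#' @return Invisibly, `edges`.
#' @export
write_interaction_table <- function(edges, path, header = TRUE) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(edges)
}

#' Read a cell-type marker table from TSV
#'
#' Two columns: `cell_type`, `gene`. Returns one marker set per cell type.
#'
#' @param path path to the TSV.
#' @return Named list of character vectors of marker gene ids.
#' @export
read_marker_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("cell_type", "gene") %in% names(tab)))
    stop_input("marker table needs columns cell_type, gene")
  if (any(!nzchar(tab$cell_type) | !nzchar(tab$gene)))
    stop_input("empty field in marker table")
  sets <- lapply(split(tab$gene, tab$cell_type), unique)
  if (any(lengths(sets) == 0)) stop_input("empty marker set")
  sets
}

#' @rdname read_marker_table
#' @param markers named list of character vectors.
#' @export
write_marker_table <- function(markers, path) {
  tab <- data.frame(cell_type = rep(names(markers), lengths(markers)),
                    gene = unlist(markers, use.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(markers)
}

stage_levels <- list(pT = paste0("T", 1:4), pN = paste0("N", 0:3),
                     cN = paste0("N", 0:3))

#' Read a patient clinical table from TSV
#'
#' Required columns: `patient_id`, `time` (survival time in days, > 0) and
#' `event` (0/1). Optional: `pT`, `pN`, `cN` stages (missing values kept as
#' `NA`, never imputed or dropped at read time) and any number of
#' miRNA expression columns (every remaining column is treated as one).
#'
#' @param path path to the TSV.
#' @return data.frame of class `mir_clinical`; expression column names are
#'   stored in the `"expression_cols"` attribute.
#' @export
read_clinical_table <- function(path) {
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  clinical_table(tab)
}

#' @rdname read_clinical_table
#' @param tab a data.frame with the columns described above.
#' @export
clinical_table <- function(tab) {
  req <- c("patient_id", "time", "event")
  if (!all(req %in% names(tab)))
    stop_input("clinical table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(tab$patient_id))
    stop_input("duplicate patient id: ",
               tab$patient_id[duplicated(tab$patient_id)][1])
  bad_t <- !is.finite(tab$time) | tab$time <= 0
  if (any(bad_t))
    stop_input("non-positive survival time for patient '",
               tab$patient_id[bad_t][1], "'")
  bad_e <- !tab$event %in% c(0, 1)
  if (any(bad_e))
    stop_input("event must be 0/1; offending patient '",
               tab$patient_id[bad_e][1], "'")
  for (s in names(stage_levels)) {
    if (!s %in% names(tab)) next
    v <- as.character(tab[[s]])
    v[v %in% c("", "NA", "missing")] <- NA
    ok <- is.na(v) | v %in% stage_levels[[s]]
    if (!all(ok))
      stop_input("invalid ", s, " stage '", v[!ok][1], "'")
    tab[[s]] <- v
  }
  expr_cols <- setdiff(names(tab), c(req, names(stage_levels)))
  for (cc in expr_cols) {
    if (!is.numeric(tab[[cc]]))
      stop_input("expression column '", cc, "' is not numeric")
  }
  rownames(tab) <- NULL
  structure(tab, expression_cols = expr_cols,
            class = c("mir_clinical", "data.frame"))
}

#' Write a clinical table as TSV
#' @param tab a `mir_clinical` data.frame.
#' @param path output path.
#' @return Invisibly, `tab`.
#' @export
write_clinical_table <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tab)
}
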