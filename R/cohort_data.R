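# Harmonized data model: directional alteration calls derived from GISTIC-style
# copy-number matrices plus deleterious-mutation flags, expression z-scores,
# clinical endpoints and a BED-like gene annotation.

#' Derive directional alteration calls from CNA and mutation inputs
#'
#' Converts a discretized copy-number matrix (GISTIC-style calls in
#' \{-2,-1,0,1,2\}) and an optional table of deleterious single-base
#' substitutions into boolean Loss/Gain calls. A gene is a Gain in a sample
#' when its CNA call is positive; a Loss when the call is negative or the
#' sample carries a deleterious mutation in the gene. Magnitude is ignored:
#' -2 and -1 are both Loss, +1 and +2 both Gain.
#'
#' A cell with a positive CNA call *and* a deleterious mutation is a conflict
#' the inputs cannot resolve; by default the copy-number direction dominates
#' (`gain = TRUE`, `loss = FALSE`, with a warning). `conflict = "neither"`
#' clears both flags instead. Missing CNA cells yield neither call; the sample
#' still counts in frequency denominators.
#'
#' @param cna numeric gene x sample matrix of integer calls in \{-2,..,2\}
#'   (NA allowed), with gene rownames and sample colnames.
#' @param mutations optional data.frame with columns `gene`, `sample_id`,
#'   `deleterious` (logical). Only deleterious rows create Loss calls.
#' @param conflict how to resolve gain-call-plus-deleterious-mutation cells:
#'   `"gain"` (default) or `"neither"`.
#' @return an object of class `pm_alterations`: list with `genes`, `samples`,
#'   and logical `loss` and `gain` matrices of identical shape. No cell is
#'   ever both Loss and Gain.
#' @export
derive_alteration_calls <- function(cna, mutations = NULL,
                                    conflict = c("gain", "neither")) {
  conflict <- match.arg(conflict)
  if (!is.matrix(cna) || is.null(rownames(cna)) || is.null(colnames(cna)))
    pm_stop("'cna' must be a matrix with gene rownames and sample colnames")
  if (anyDuplicated(rownames(cna)))
    pm_stop("duplicate gene symbols in CNA matrix")
  if (anyDuplicated(colnames(cna)))
    pm_stop("duplicate sample id in CNA matrix")
  vals <- cna[!is.na(cna)]
  if (length(vals) && (any(vals != round(vals)) || any(abs(vals) > 2)))
    pm_stop("non-integer CNA value: calls must be integers in {-2,-1,0,1,2}")

  loss <- !is.na(cna) & cna < 0
  gain <- !is.na(cna) & cna > 0

  if (!is.null(mutations) && nrow(mutations)) {
    req <- c("gene", "sample_id", "deleterious")
    if (!all(req %in% names(mutations)))
      pm_stop("mutation table must have columns gene, sample_id, deleterious")
    mut <- mutations[as.logical(mutations$deleterious), , drop = FALSE]
    bad_g <- setdiff(unique(mutations$gene), rownames(cna))
    bad_s <- setdiff(unique(mutations$sample_id), colnames(cna))
    if (length(bad_g) || length(bad_s))
      pm_stop("mutation rows reference unknown ",
              if (length(bad_g)) paste0("genes: ",
                paste(bad_g, collapse = ", ")) else "",
              if (length(bad_g) && length(bad_s)) "; " else "",
              if (length(bad_s)) paste0("samples: ",
                paste(bad_s, collapse = ", ")) else "")
    if (nrow(mut)) {
      idx <- cbind(match(mut$gene, rownames(cna)),
                   match(mut$sample_id, colnames(cna)))
      confl <- gain[idx]
      if (any(confl)) {
        warning(sum(confl), " cell(s) with a copy-number gain and a ",
                "deleterious mutation; resolved as '", conflict, "'",
                call. = FALSE)
        if (conflict == "neither") gain[idx[confl, , drop = FALSE]] <- FALSE
        loss[idx[!confl, , drop = FALSE]] <- TRUE
      } else {
        loss[idx] <- TRUE
      }
    }
  }

  structure(list(genes = rownames(cna), samples = colnames(cna),
                 loss = loss, gain = gain),
            class = "pm_alterations")
}

read_tsv_matrix <- function(path, what) {
  if (!file.exists(path)) pm_stop(what, " file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene")
    pm_stop("malformed header in ", what, " file ", path,
            ": first column must be 'gene'")
  if (anyDuplicated(df$gene))
    pm_stop("duplicate gene symbol in ", what, " file ", path)
  if (anyDuplicated(names(df)[-1]))
    pm_stop("duplicate sample id in ", what, " file ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) pm_stop("non-numeric value in ", what, " file ", path)
  rownames(m) <- df$gene
  m
}

read_annotation <- function(path) {
  if (!file.exists(path)) pm_stop("annotation file not found: ", path)
  ann <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "gene"))
  if (anyDuplicated(ann$gene)) pm_stop("duplicate gene symbol in annotation")
  if (any(ann$start >= ann$end))
    pm_stop("annotation start must be < end (0-based half-open)")
  recompute_order_index(ann)
}

# order_index: rank of the gene along its chromosome by start coordinate
recompute_order_index <- function(ann) {
  ann$order_index <- ave(ann$start, ann$chrom,
                         FUN = function(x) rank(x, ties.method = "first"))
  ann
}

read_clinical <- function(path, cna_samples) {
  if (!file.exists(path)) pm_stop("clinical file not found: ", path)
  cl <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("sample_id", "cohort", "sample_type", "gleason", "t_stage",
           "n_stage", "pfs_time", "pfs_event")
  if (!all(req %in% names(cl)))
    pm_stop("malformed header in clinical file: need columns ",
            paste(req, collapse = ", "))
  cl <- cl[, req]
  if (anyDuplicated(cl$sample_id)) pm_stop("duplicate sample id in clinical")
  missing_s <- setdiff(cl$sample_id, cna_samples)
  if (length(missing_s))
    pm_stop("clinical sample absent from CNA matrix: ",
            paste(missing_s, collapse = ", "))
  if (!all(cl$sample_type %in% c("primary", "metastatic")))
    pm_stop("sample_type must be 'primary' or 'metastatic'")
  cl$gleason <- as.integer(cl$gleason)
  cl$pfs_time <- as.numeric(cl$pfs_time)
  cl$pfs_event <- as.logical(cl$pfs_event)
  if (any(!is.na(cl$pfs_time) & cl$pfs_time < 0))
    pm_stop("pfs_time must be nonnegative")
  if (any(is.na(cl$pfs_time) != is.na(cl$pfs_event)))
    pm_stop("pfs_event must be present exactly when pfs_time is present")
  cl
}

new_pm_dataset <- function(alterations, cna, mutations, expression, clinical,
                           annotation) {
  if (!is.null(expression) && length(expression)) {
    bad <- setdiff(colnames(expression), alterations$samples)
    if (length(bad))
      pm_stop("expression sample absent from alteration matrix: ",
              paste(bad, collapse = ", "))
  } else {
    expression <- NULL
  }
  bad <- setdiff(clinical$sample_id, alterations$samples)
  if (length(bad))
    pm_stop("clinical sample absent from alteration matrix: ",
            paste(bad, collapse = ", "))
  miss <- setdiff(alterations$genes, annotation$gene)
  if (length(miss))
    pm_stop("genes missing from annotation: ",
            paste(head(miss, 10), collapse = ", "),
            if (length(miss) > 10) ", ..." else "")
  ann <- annotation[annotation$gene %in% alterations$genes, , drop = FALSE]
  ann <- recompute_order_index(ann[order(ann$chrom, ann$start), , drop = FALSE])
  rownames(ann) <- NULL
  structure(list(alterations = alterations, cna = cna, mutations = mutations,
                 expression = expression, clinical = clinical,
                 annotation = ann),
            class = "pm_dataset")
}

#' Build a harmonized dataset from in-memory components
#'
#' Validating constructor for users whose cohort is already in memory:
#' derives directional alteration calls from the CNA matrix and mutation
#' table and assembles the dataset container.
#'
#' @param cna integer gene x sample matrix of GISTIC-style calls.
#' @param mutations optional mutation data.frame (`gene`, `sample_id`,
#'   `deleterious`).
#' @param expression optional gene x sample z-score matrix (columns must be a
#'   subset of the CNA samples).
#' @param clinical clinical data.frame (see [read_cohort()] for columns).
#' @param annotation data.frame with `chrom`, `start`, `end`, `gene`.
#' @param conflict passed to [derive_alteration_calls()].
#' @return a `pm_dataset`.
#' @export
harmonized_dataset <- function(cna, mutations = NULL, expression = NULL,
                               clinical, annotation,
                               conflict = c("gain", "neither")) {
  if (is.null(mutations))
    mutations <- data.frame(gene = character(), sample_id = character(),
                            deleterious = logical())
  alt <- derive_alteration_calls(cna, mutations, conflict = match.arg(conflict))
  new_pm_dataset(alt, cna, mutations, expression, clinical,
                 recompute_order_index(annotation))
}

#' Read one cohort from disk
#'
#' Reads the per-cohort tab-separated files into a validated single-cohort
#' dataset. The CNA and expression files are gene x sample TSVs whose first
#' column is `gene`; the mutation file is a MAF-lite TSV with columns `gene`,
#' `sample_id`, `deleterious`; the clinical TSV has columns `sample_id`,
#' `cohort`, `sample_type`, `gleason`, `t_stage`, `n_stage`, `pfs_time`,
#' `pfs_event` (empty string = missing); the annotation is a headerless
#' BED-like TSV `chrom`, `start`, `end`, `gene` with 0-based half-open
#' coordinates.
#'
#' @param cna_path,mutation_path,expression_path,clinical_path,annotation_path
#'   file paths; `expression_path = NULL` is permitted (dataset without an
#'   expression layer).
#' @param conflict passed to [derive_alteration_calls()].
#' @return a `pm_dataset` object.
#' @export
read_cohort <- function(cna_path, mutation_path, expression_path,
                        clinical_path, annotation_path,
                        conflict = c("gain", "neither")) {
  cna <- read_tsv_matrix(cna_path, "CNA")
  vals <- cna[!is.na(cna)]
  if (length(vals) && any(vals != round(vals)))
    pm_stop("non-integer CNA value in ", cna_path)
  mutations <- if (!is.null(mutation_path)) {
    if (!file.exists(mutation_path))
      pm_stop("mutation file not found: ", mutation_path)
    mut <- read.delim(mutation_path, stringsAsFactors = FALSE)
    if (nrow(mut)) mut$deleterious <- as.logical(mut$deleterious)
    mut
  } else {
    data.frame(gene = character(), sample_id = character(),
               deleterious = logical())
  }
  expression <- if (!is.null(expression_path) && !is.na(expression_path) &&
                    nzchar(expression_path)) {
    read_tsv_matrix(expression_path, "expression")
  } else {
    NULL
  }
  clinical <- read_clinical(clinical_path, colnames(cna))
  annotation <- read_annotation(annotation_path)
  alterations <- derive_alteration_calls(cna, mutations,
                                         conflict = match.arg(conflict))
  new_pm_dataset(alterations, cna, mutations, expression, clinical, annotation)
}

#' Merge single-cohort datasets into one harmonized dataset
#'
#' The merged gene set is the intersection of the cohorts' gene sets; samples
#' are concatenated with their cohort labels preserved; expression z-scores
#' are carried through unchanged (no re-normalization).
#'
#' @param cohorts list of `pm_dataset` objects with consistent annotation.
#' @return a merged `pm_dataset`.
#' @export
merge_cohorts <- function(cohorts) {
  if (!length(cohorts)) pm_stop("need at least one cohort")
  stopifnot(all(vapply(cohorts, inherits, TRUE, "pm_dataset")))
  if (length(cohorts) == 1L) return(cohorts[[1L]])
  genes <- Reduce(intersect, lapply(cohorts, function(d) d$alterations$genes))
  if (!length(genes)) pm_stop("empty gene intersection across cohorts")
  samples <- unlist(lapply(cohorts, function(d) d$alterations$samples))
  if (anyDuplicated(samples))
    pm_stop("duplicate sample id across cohorts: ",
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  loss <- do.call(cbind, lapply(cohorts,
                                function(d) d$alterations$loss[genes, , drop = FALSE]))
  gain <- do.call(cbind, lapply(cohorts,
                                function(d) d$alterations$gain[genes, , drop = FALSE]))
  cna <- do.call(cbind, lapply(cohorts,
                               function(d) d$cna[genes, , drop = FALSE]))
  alt <- structure(list(genes = genes, samples = samples,
                        loss = loss, gain = gain), class = "pm_alterations")
  mutations <- do.call(rbind, lapply(cohorts, function(d) {
    d$mutations[d$mutations$gene %in% genes, , drop = FALSE]
  }))
  rownames(mutations) <- NULL
  with_expr <- Filter(function(d) !is.null(d$expression), cohorts)
  expression <- if (length(with_expr)) {
    eg <- Reduce(intersect, lapply(with_expr, function(d) rownames(d$expression)))
    eg <- intersect(genes, eg)
    if (length(eg)) {
      do.call(cbind, lapply(with_expr,
                            function(d) d$expression[eg, , drop = FALSE]))
    } else NULL
  } else NULL
  clinical <- do.call(rbind, lapply(cohorts, function(d) d$clinical))
  rownames(clinical) <- NULL
  new_pm_dataset(alt, cna, mutations, expression, clinical,
                 cohorts[[1L]]$annotation)
}

#' Write a dataset back to the on-disk cohort formats
#'
#' Writes `cna.tsv`, `mutations.tsv`, `expression.tsv` (when present),
#' `clinical.tsv` and `annotation.bed` into `dir`, using the same formats
#' [read_cohort()] consumes, so that a read/write cycle round-trips.
#'
#' @param dataset a `pm_dataset`.
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pm_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cna = file.path(dir, "cna.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             annotation = file.path(dir, "annotation.bed"))
  write_matrix_tsv(dataset$cna, paths[["cna"]])
  write.table(dataset$mutations, paths[["mutations"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$expression)) {
    paths <- c(paths, expression = file.path(dir, "expression.tsv"))
    write_matrix_tsv(dataset$expression, paths[["expression"]])
  }
  cl <- dataset$clinical
  write.table(cl, paths[["clinical"]], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  ann <- dataset$annotation[, c("chrom", "start", "end", "gene")]
  write.table(ann, paths[["annotation"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory holding `cna.tsv`, `mutations.tsv`, `clinical.tsv`,
#'   `annotation.bed` and optionally `expression.tsv`.
#' @param conflict passed to [derive_alteration_calls()].
#' @return a `pm_dataset`.
#' @export
read_dataset <- function(dir, conflict = c("gain", "neither")) {
  expr <- file.path(dir, "expression.tsv")
  read_cohort(file.path(dir, "cna.tsv"),
              file.path(dir, "mutations.tsv"),
              if (file.exists(expr)) expr else NULL,
              file.path(dir, "clinical.tsv"),
              file.path(dir, "annotation.bed"),
              conflict = match.arg(conflict))
}

#' @export
print.pm_dataset <- function(x, ...) {
  cat("Harmonized prostate-cancer dataset\n")
  cat("  genes:   ", length(x$alterations$genes), "\n")
  cat("  samples: ", length(x$alterations$samples),
      sprintf(" (%d primary, %d metastatic)\n",
              sum(x$clinical$sample_type == "primary"),
              sum(x$clinical$sample_type == "metastatic")))
  cat("  cohorts: ", paste(unique(x$clinical$cohort), collapse = ", "), "\n")
  cat("  expression layer:",
      if (is.null(x$expression)) "absent" else
        paste0(nrow(x$expression), " x ", ncol(x$expression)), "\n")
  invisible(x)
}
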