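# Alteration landscape: per-gene directional frequencies, the tumor-coverage
# curve over frequency cutoffs, and contiguous alteration hotspots.

#' Per-gene directional alteration frequencies
#'
#' Frequency = number of tumors altered / total tumors in the subset, computed
#' independently for the Loss and Gain directions.
#'
#' @param alterations a `pm_alterations` object.
#' @param samples optional character vector restricting the tumor subset
#'   (default: all samples).
#' @return data.frame with columns `gene`, `direction` (`loss`/`gain`),
#'   `frequency`, `n_altered`, `n_total`.
#' @export
alteration_frequencies <- function(alterations, samples = NULL) {
  stopifnot(inherits(alterations, "pm_alterations"))
  if (is.null(samples)) samples <- alterations$samples
  if (!length(samples)) pm_stop("empty sample subset")
  bad <- setdiff(samples, alterations$samples)
  if (length(bad)) pm_stop("unknown samples: ", paste(bad, collapse = ", "))
  n <- length(samples)
  nl <- rowSums(alterations$loss[, samples, drop = FALSE])
  ng <- rowSums(alterations$gain[, samples, drop = FALSE])
  data.frame(gene = rep(alterations$genes, 2L),
             direction = rep(c("loss", "gain"),
                             each = length(alterations$genes)),
             frequency = c(nl, ng) / n,
             n_altered = c(nl, ng),
             n_total = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tumor coverage as a function of the alteration-frequency cutoff
#'
#' At each cutoff the captured gene set holds the genes whose larger
#' directional frequency (max of Loss and Gain) reaches the cutoff; coverage
#' is the fraction of tumors carrying at least one alteration in a captured
#' gene. Both the captured-gene count and the coverage are non-increasing in
#' the cutoff.
#'
#' @param alterations a `pm_alterations` object.
#' @param cutoffs ascending frequency grid in \[0, 1\].
#' @param samples optional sample subset.
#' @return data.frame with columns `cutoff`, `n_genes_captured`, `coverage`.
#' @export
coverage_curve <- function(alterations, cutoffs = seq(0, 1, by = 0.01),
                           samples = NULL) {
  stopifnot(inherits(alterations, "pm_alterations"))
  if (is.unsorted(cutoffs)) pm_stop("cutoffs must be sorted ascending")
  if (any(cutoffs < 0 | cutoffs > 1)) pm_stop("cutoffs must lie in [0, 1]")
  if (is.null(samples)) samples <- alterations$samples
  any_alt <- alterations$loss[, samples, drop = FALSE] |
    alterations$gain[, samples, drop = FALSE]
  fr <- alteration_frequencies(alterations, samples)
  fmax <- pmax(fr$frequency[fr$direction == "loss"],
               fr$frequency[fr$direction == "gain"])
  res <- lapply(cutoffs, function(ct) {
    captured <- fmax >= ct
    cov <- if (any(captured)) {
      mean(colSums(any_alt[captured, , drop = FALSE]) > 0)
    } else 0
    c(n = sum(captured), coverage = cov)
  })
  res <- do.call(rbind, res)
  data.frame(cutoff = cutoffs, n_genes_captured = as.integer(res[, "n"]),
             coverage = res[, "coverage"], row.names = NULL)
}

#' Detect contiguous alteration hotspots
#'
#' A hotspot is a maximal run of genes, contiguous in genomic order within a
#' chromosome, whose alteration frequency in one direction clears the cutoff,
#' with at least `min_genes` members. `max_gap` below-threshold genes may be
#' bridged inside a run (default 0, strict contiguity); bridged genes are not
#' hotspot members, so every member clears the cutoff.
#'
#' @param freq_tracks output of [alteration_frequencies()].
#' @param annotation gene annotation data.frame (`gene`, `chrom`, `start`,
#'   `end`, `order_index`); every track gene must be present.
#' @param cutoff frequency threshold (default 0.10).
#' @param min_genes minimum number of member genes (default 5).
#' @param inclusive if `TRUE` (default) a frequency equal to the cutoff
#'   qualifies; if `FALSE` the comparison is strict.
#' @param max_gap number of consecutive sub-threshold genes a run may bridge.
#' @return data.frame with one row per hotspot: `chrom`, `start`, `end`
#'   (1-based inclusive, for human-readable labels), `direction`, `n_genes`,
#'   `start_gene`, `end_gene`, `peak_gene`, `peak_frequency`, `genes`
#'   (semicolon-joined members).
#' @export
detect_hotspots <- function(freq_tracks, annotation, cutoff = 0.10,
                            min_genes = 5L, inclusive = TRUE, max_gap = 0L) {
  if (!all(c("gene", "direction", "frequency") %in% names(freq_tracks)))
    pm_stop("freq_tracks must have columns gene, direction, frequency")
  miss <- setdiff(unique(freq_tracks$gene), annotation$gene)
  if (length(miss))
    pm_stop("genes missing coordinates: ", paste(miss, collapse = ", "))
  if (!"order_index" %in% names(annotation))
    annotation <- recompute_order_index(annotation)

  out <- list()
  for (dir in unique(freq_tracks$direction)) {
    tr <- freq_tracks[freq_tracks$direction == dir, , drop = FALSE]
    freq <- setNames(tr$frequency, tr$gene)
    for (chr in unique(annotation$chrom)) {
      ann <- annotation[annotation$chrom == chr, , drop = FALSE]
      ann <- ann[order(ann$order_index), , drop = FALSE]
      ann <- ann[ann$gene %in% names(freq), , drop = FALSE]
      if (!nrow(ann)) next
      f <- freq[ann$gene]
      above <- if (inclusive) f >= cutoff else f > cutoff
      runs <- gapped_runs(above, max_gap)
      for (r in runs) {
        members <- r[above[r]]
        if (length(members) < min_genes) next
        mf <- f[members]
        peak <- members[which.max(mf)]  # which.max -> smallest index on ties
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr,
          start = ann$start[members[1L]] + 1L,
          end = ann$end[members[length(members)]],
          direction = dir,
          n_genes = length(members),
          start_gene = ann$gene[members[1L]],
          end_gene = ann$gene[members[length(members)]],
          peak_gene = ann$gene[peak],
          peak_frequency = unname(f[peak]),
          genes = paste(ann$gene[members], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), n_genes = integer(),
                      start_gene = character(), end_gene = character(),
                      peak_gene = character(), peak_frequency = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Maximal runs of TRUE positions allowing up to `max_gap` consecutive FALSEs
# inside a run; runs begin and end at TRUE positions. Returns a list of index
# vectors (positions spanned, including bridged gaps).
gapped_runs <- function(above, max_gap = 0L) {
  idx <- which(above)
  if (!length(idx)) return(list())
  breaks <- which(diff(idx) > max_gap + 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  lapply(seq_along(starts),
         function(i) seq(idx[starts[i]], idx[ends[i]]))
}
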