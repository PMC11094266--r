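# Subgrouping of primary tumors: consensus clustering of binary alteration
# profiles, pairwise mutual exclusivity / co-occurrence, and association of
# subgroups with clinical features.

#' Consensus clustering of binary alteration profiles
#'
#' Resampling-based clustering: for each k, samples are repeatedly
#' subsampled, clustered (k-medoids on Jaccard distance by default), and
#' co-assignments accumulated into a sample x sample consensus matrix
#' (co-assignment count / co-subsample count). Final memberships come from
#' clustering `1 - consensus` as a distance. The cluster number is suggested
#' by the change in area under the consensus CDF: `chosen_k` is the largest k
#' whose relative area increase `delta_area(k)/area(k-1)` is at least
#' `rel_threshold` (advisory; pass `fixed_k` to pin it).
#'
#' @param x binary feature x sample matrix (columns are samples).
#' @param k_range candidate cluster numbers (default 2:6).
#' @param n_resamples number of subsampling iterations per k (default 1000).
#' @param subsample_fraction fraction of samples drawn per iteration
#'   (default 0.8).
#' @param seed integer seed (mandatory; runs are bit-reproducible).
#' @param inner inner clustering: `"pam"` (k-medoids, default) or `"hclust"`
#'   (average linkage), both on Jaccard distance.
#' @param fixed_k optional user-fixed cluster number overriding the elbow.
#' @param rel_threshold relative delta-area threshold for the elbow rule.
#' @return object of class `pm_consensus`: list with `k_values`, `consensus`
#'   (list of matrices, symmetric with unit diagonal), `memberships` (sample x
#'   k matrix of integer labels), `area`, `delta_area`, `rel_delta`,
#'   `chosen_k`.
#' @export
consensus_cluster <- function(x, k_range = 2:6, n_resamples = 1000,
                              subsample_fraction = 0.8, seed,
                              inner = c("pam", "hclust"), fixed_k = NULL,
                              rel_threshold = 0.1) {
  inner <- match.arg(inner)
  if (missing(seed)) pm_stop("a seed is mandatory for consensus clustering")
  x <- as.matrix(x)
  n <- ncol(x)
  if (n <= max(k_range)) pm_stop("k must be smaller than the number of samples")
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))

  D <- as.matrix(stats::dist(t(x), method = "binary"))
  D[is.na(D)] <- 0  # pairs of all-zero profiles are identical
  m <- max(floor(subsample_fraction * n), max(k_range) + 1L)

  with_seed(seed, {
    draws <- replicate(n_resamples, sample.int(n, m), simplify = FALSE)
    consensus <- memberships <- list()
    for (k in k_range) {
      M <- matrix(0, n, n); I <- matrix(0, n, n)
      for (idx in draws) {
        cl <- inner_cluster(D[idx, idx], k, inner)
        co <- outer(cl, cl, "==")
        M[idx, idx] <- M[idx, idx] + co
        I[idx, idx] <- I[idx, idx] + 1
      }
      C <- ifelse(I > 0, M / pmax(I, 1), 0)
      diag(C) <- 1
      dimnames(C) <- list(ids, ids)
      consensus[[as.character(k)]] <- C
      memberships[[as.character(k)]] <-
        inner_cluster(1 - C, k, inner)
    }
  })

  area <- vapply(consensus, consensus_cdf_area, numeric(1))
  delta <- c(area[1L], diff(area))
  rel <- c(NA_real_, diff(area) / head(area, -1L))
  elbow <- k_range[rel >= rel_threshold & !is.na(rel)]
  chosen <- if (!is.null(fixed_k)) fixed_k else
    if (length(elbow)) max(elbow) else k_range[1L]

  mem <- do.call(cbind, memberships)
  dimnames(mem) <- list(ids, names(memberships))
  structure(list(k_values = k_range, consensus = consensus,
                 memberships = mem, area = unname(area),
                 delta_area = unname(delta), rel_delta = unname(rel),
                 chosen_k = chosen, seed = seed),
            class = "pm_consensus")
}

inner_cluster <- function(dmat, k, inner) {
  d <- stats::as.dist(dmat)
  if (inner == "pam") {
    cluster::pam(d, k, diss = TRUE, cluster.only = TRUE)
  } else {
    stats::cutree(stats::hclust(d, method = "average"), k = k)
  }
}

# Area under the empirical CDF of the off-diagonal consensus entries over
# [0, 1]; larger = more entries near 0 (cleaner consensus).
consensus_cdf_area <- function(C) {
  v <- sort(C[upper.tri(C)])
  m <- length(v)
  if (!m) return(0)
  xs <- c(0, v, 1)
  heights <- c(0, seq_len(m)) / m
  sum(diff(xs) * heights)
}

#' @export
print.pm_consensus <- function(x, ...) {
  cat("Consensus clustering over k =", paste(range(x$k_values), collapse = ".."),
      "\n  CDF areas: ", paste(sprintf("%.3f", x$area), collapse = ", "),
      "\n  chosen k:  ", x$chosen_k, "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, around 0
#' for independent ones.
#'
#' @param a,b integer/factor membership vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ni <- rowSums(tab); nj <- colSums(tab); n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  comb_a <- sum(choose(ni, 2)); comb_b <- sum(choose(nj, 2))
  expected <- comb_a * comb_b / choose(n, 2)
  max_idx <- (comb_a + comb_b) / 2
  if (max_idx == expected) return(1)
  (sum_comb - expected) / (max_idx - expected)
}

#' Pairwise mutual exclusivity / co-occurrence of gene alterations
#'
#' For every unordered pair of the given genes, tallies the 2x2 table of
#' altered (Loss or Gain) versus not across the sample subset and tests
#' association with a two-sided Fisher's exact test. Odds ratio > 1 is
#' labelled co-occurrence, < 1 exclusivity; p-values are BH-adjusted across
#' all pairs.
#'
#' @param alterations a `pm_alterations` object.
#' @param genes character vector of at least two genes.
#' @param samples optional sample subset (default all).
#' @return data.frame with one row per pair: `gene_a`, `gene_b`, `n_both`,
#'   `n_a_only`, `n_b_only`, `n_neither`, `odds_ratio`, `direction`
#'   (`co_occurrence`/`exclusivity`/`none`), `p_value`, `fdr`.
#' @export
mutual_exclusivity <- function(alterations, genes, samples = NULL) {
  stopifnot(inherits(alterations, "pm_alterations"))
  if (length(genes) < 2) pm_stop("need at least two genes")
  bad <- setdiff(genes, alterations$genes)
  if (length(bad)) pm_stop("genes absent from matrix: ",
                           paste(bad, collapse = ", "))
  if (is.null(samples)) samples <- alterations$samples
  alt <- alterations$loss[genes, samples, drop = FALSE] |
    alterations$gain[genes, samples, drop = FALSE]
  pairs <- utils::combn(genes, 2)
  res <- apply(pairs, 2, function(pr) {
    va <- alt[pr[1], ]; vb <- alt[pr[2], ]
    a <- sum(va & vb); b <- sum(va & !vb)
    c <- sum(!va & vb); d <- sum(!va & !vb)
    ft <- fisher_exact(a, b, c, d, "two_sided")
    data.frame(gene_a = pr[1], gene_b = pr[2], n_both = a, n_a_only = b,
               n_b_only = c, n_neither = d,
               odds_ratio = ft$extra$odds_ratio,
               direction = c("exclusivity", "none",
                             "co_occurrence")[ft$effect_direction + 2L],
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- bh_adjust(res$p_value)
  rownames(res) <- NULL
  res
}

#' Associate tumor subgroups with clinical features
#'
#' Per subgroup: enrichment of high Gleason grade (>= `gleason_cutoff`) and of
#' T2+ stage versus all other tumors (one-sided Fisher, BH-adjusted across
#' subgroups); progression-free survival versus the reference subgroup
#' (logrank p and Cox hazard ratio with 95\% CI); and mean per-sample
#' alteration burden when `alterations` is supplied.
#'
#' @param memberships named vector (sample -> subgroup label).
#' @param clinical clinical table (see [read_cohort()]).
#' @param reference_group subgroup label used as the survival reference.
#' @param alterations optional `pm_alterations` for the burden summary.
#' @param gleason_cutoff high-grade threshold (default 8).
#' @return data.frame with one row per subgroup.
#' @export
subgroup_clinical_association <- function(memberships, clinical,
                                          reference_group,
                                          alterations = NULL,
                                          gleason_cutoff = 8) {
  groups <- sort(unique(memberships))
  if (!reference_group %in% groups)
    pm_stop("reference group '", reference_group, "' not among memberships")
  cl <- clinical[match(names(memberships), clinical$sample_id), , drop = FALSE]
  high_gl <- !is.na(cl$gleason) & cl$gleason >= gleason_cutoff
  t2plus <- !is.na(cl$t_stage) & grepl("^T[234]", cl$t_stage)
  burden <- if (!is.null(alterations)) {
    colSums(alterations$loss | alterations$gain)[names(memberships)]
  } else rep(NA_real_, length(memberships))

  ref <- names(memberships)[memberships == reference_group]
  ref_cl <- cl[memberships == reference_group, , drop = FALSE]
  ref_surv <- !is.na(ref_cl$pfs_time)

  rows <- lapply(groups, function(g) {
    ing <- memberships == g
    gl_ok <- !is.na(cl$gleason)
    ft_gl <- fisher_exact(sum(ing & high_gl & gl_ok),
                          sum(!ing & high_gl & gl_ok),
                          sum(ing & !high_gl & gl_ok),
                          sum(!ing & !high_gl & gl_ok), "greater")
    st_ok <- !is.na(cl$t_stage)
    ft_t <- fisher_exact(sum(ing & t2plus & st_ok),
                         sum(!ing & t2plus & st_ok),
                         sum(ing & !t2plus & st_ok),
                         sum(!ing & !t2plus & st_ok), "greater")
    surv_ok <- ing & !is.na(cl$pfs_time)
    if (g == reference_group) {
      lr_p <- 1; hr <- 1; lo <- NA_real_; hi <- NA_real_
    } else if (!any(surv_ok) || !any(ref_surv) ||
               !any(c(cl$pfs_event[surv_ok], ref_cl$pfs_event[ref_surv]))) {
      lr_p <- NA_real_; hr <- NA_real_; lo <- NA_real_; hi <- NA_real_
    } else {
      lr <- logrank_test(cl$pfs_time[surv_ok], cl$pfs_event[surv_ok],
                         ref_cl$pfs_time[ref_surv], ref_cl$pfs_event[ref_surv])
      lr_p <- lr$p_value
      cx <- cox_univariate(c(cl$pfs_time[surv_ok], ref_cl$pfs_time[ref_surv]),
                           c(cl$pfs_event[surv_ok], ref_cl$pfs_event[ref_surv]),
                           rep(c(1L, 0L), c(sum(surv_ok), sum(ref_surv))))
      hr <- cx$extra$hr; lo <- cx$extra$ci_lower; hi <- cx$extra$ci_upper
    }
    data.frame(subgroup = g, n = sum(ing),
               gleason_high_p = ft_gl$p_value,
               gleason_direction = ft_gl$effect_direction,
               t2plus_p = ft_t$p_value,
               t2plus_direction = ft_t$effect_direction,
               logrank_p_vs_reference = lr_p,
               hazard_ratio_vs_reference = hr,
               hr_ci_lower = lo, hr_ci_upper = hi,
               mean_alteration_burden = mean(burden[ing]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$gleason_high_fdr <- bh_adjust(res$gleason_high_p)
  res$t2plus_fdr <- bh_adjust(res$t2plus_p)
  rownames(res) <- NULL
  res
}
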