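# The mining cascade: ST/WT x primary/metastatic group definition, the
# genomic -> transcriptomic -> clinical filter cascade, and weighted
# normalized-rank scoring of the surviving co-alterations.

#' Filtering parameters for the mining cascade
#'
#' Defaults are the baseline parameterization: co-alteration frequency
#' differences of 2\%, co-alteration enrichment FDR 0.05, concordant
#' differential-expression FDR 0.2, and the survival p-value window (<= 0.2
#' in subtype tumors, >= 0.3 in wild-type tumors) with a high-Gleason cutoff
#' of 8. [prostamine_profile()] returns the stricter published reproduction
#' profile.
#'
#' @param primary_diff minimum ST-primary minus WT-primary frequency
#'   difference (arithmetic difference of frequencies).
#' @param met_diff minimum ST-metastatic minus ST-primary frequency
#'   difference.
#' @param coalt_fdr BH-FDR bound for both co-alteration enrichment contrasts.
#' @param dge_fdr BH-FDR bound for the concordant expression difference in
#'   each compartment.
#' @param survival_p_st maximum logrank p in subtype (ST) tumors.
#' @param survival_p_wt minimum logrank p in wild-type (WT) tumors.
#' @param gleason_cutoff Gleason value defining high grade.
#' @param gleason_fdr optional BH-FDR bound on the Gleason enrichment test;
#'   `NULL` (default) applies the direction-concordance requirement only.
#' @return a `pm_params` list.
#' @export
prostamine_params <- function(primary_diff = 0.02, met_diff = 0.02,
                              coalt_fdr = 0.05, dge_fdr = 0.2,
                              survival_p_st = 0.2, survival_p_wt = 0.3,
                              gleason_cutoff = 8, gleason_fdr = NULL) {
  p <- list(primary_diff = primary_diff, met_diff = met_diff,
            coalt_fdr = coalt_fdr, dge_fdr = dge_fdr,
            survival_p_st = survival_p_st, survival_p_wt = survival_p_wt,
            gleason_cutoff = gleason_cutoff, gleason_fdr = gleason_fdr)
  probs <- unlist(p[c("coalt_fdr", "dge_fdr", "survival_p_st",
                      "survival_p_wt")])
  if (any(probs < 0 | probs > 1)) pm_stop("probabilities must lie in [0, 1]")
  if (primary_diff < 0 || met_diff < 0)
    pm_stop("frequency differences must be nonnegative")
  structure(p, class = "pm_params")
}

#' Published reproduction parameter profile
#'
#' Co-alteration rate difference 0.05 (primary and metastatic), co-alteration
#' FDR 0.05, DGE FDR 0.2, and ST survival p-value 0.05 (the WT null bound
#' stays at 0.3).
#'
#' @return a `pm_params` list.
#' @export
prostamine_profile <- function() {
  prostamine_params(primary_diff = 0.05, met_diff = 0.05, coalt_fdr = 0.05,
                    dge_fdr = 0.2, survival_p_st = 0.05, survival_p_wt = 0.3)
}

#' Define the four ST/WT x primary/metastatic tumor groups
#'
#' ST tumors carry the subtype alteration (the selected gene in the selected
#' direction); WT tumors are diploid for the gene (neither Loss nor Gain).
#' Samples altered only in the opposite direction are excluded, as are
#' samples without clinical typing. Each of the four groups must be
#' non-empty.
#'
#' @param dataset a `pm_dataset`.
#' @param subtype_gene gene symbol present in the dataset.
#' @param direction `"loss"` or `"gain"`.
#' @return a `pm_groups` list with `st_primary`, `wt_primary`, `st_met`,
#'   `wt_met` sample-id vectors and an `excluded` data.frame
#'   (`sample_id`, `reason`).
#' @export
define_groups <- function(dataset, subtype_gene,
                          direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  alt <- dataset$alterations
  if (!subtype_gene %in% alt$genes)
    pm_stop("subtype gene '", subtype_gene, "' not in dataset")
  sel <- alt[[direction]][subtype_gene, ]
  opp <- alt[[if (direction == "loss") "gain" else "loss"]][subtype_gene, ]
  type <- setNames(dataset$clinical$sample_type, dataset$clinical$sample_id)
  type <- type[alt$samples]  # NA for samples without clinical rows

  excluded <- data.frame(sample_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  no_clin <- alt$samples[is.na(type)]
  if (length(no_clin))
    excluded <- rbind(excluded,
                      data.frame(sample_id = no_clin, reason = "no clinical data"))
  opp_only <- alt$samples[!is.na(type) & !sel & opp]
  if (length(opp_only))
    excluded <- rbind(excluded,
                      data.frame(sample_id = opp_only,
                                 reason = "opposite-direction alteration"))
  usable <- !is.na(type) & !(!sel & opp)
  st <- alt$samples[usable & sel]
  wt <- alt$samples[usable & !sel]
  grp <- list(st_primary = st[type[st] == "primary"],
              wt_primary = wt[type[wt] == "primary"],
              st_met = st[type[st] == "metastatic"],
              wt_met = wt[type[wt] == "metastatic"])
  empty <- names(grp)[!vapply(grp, length, 1L)]
  if (length(empty))
    pm_stop("empty group: ",
            paste(c(st_primary = "ST_primary", wt_primary = "WT_primary",
                    st_met = "ST_metastatic", wt_met = "WT_metastatic")[empty],
                  collapse = ", "))
  structure(c(grp, list(subtype_gene = subtype_gene, direction = direction,
                        excluded = excluded)),
            class = "pm_groups")
}

# vectorised one-sided enrichment p for columns-of-counts; see fisher_exact()
enrich_p <- function(alt1, n1, alt2, n2) {
  fisher_p_greater(alt1, alt2, n1 - alt1, n2 - alt2)
}

#' Genomic step: subtype co-alteration capture
#'
#' For every gene x direction other than the subtype gene, keeps candidates
#' whose ST-primary frequency exceeds the WT-primary frequency by at least
#' `primary_diff` with one-sided Fisher enrichment BH-FDR <= `coalt_fdr`, and
#' whose ST-metastatic frequency exceeds the ST-primary frequency by at least
#' `met_diff`, again at BH-FDR <= `coalt_fdr`. Matching the sequential
#' capture, each BH family consists of the tests actually reached at that
#' stage: the primary family is the gene x directions passing the primary
#' frequency filter; the metastatic family is those additionally passing
#' primary FDR and the metastatic frequency filter.
#'
#' @param dataset a `pm_dataset`.
#' @param groups a `pm_groups` from [define_groups()].
#' @param params a `pm_params`.
#' @return list with `candidates` (data.frame of surviving hit records) and
#'   `trace` (gene, direction, terminal_stage, reason for the removed).
#' @export
genomic_step <- function(dataset, groups, params = prostamine_params()) {
  alt <- dataset$alterations
  genes <- setdiff(alt$genes, groups$subtype_gene)
  ann <- dataset$annotation
  sub_ann <- ann[ann$gene == groups$subtype_gene, , drop = FALSE]

  per_dir <- lapply(c("loss", "gain"), function(dir) {
    m <- alt[[dir]]
    n_stp <- length(groups$st_primary); n_wtp <- length(groups$wt_primary)
    n_stm <- length(groups$st_met); n_wtm <- length(groups$wt_met)
    a_stp <- rowSums(m[genes, groups$st_primary, drop = FALSE])
    a_wtp <- rowSums(m[genes, groups$wt_primary, drop = FALSE])
    a_stm <- rowSums(m[genes, groups$st_met, drop = FALSE])
    a_wtm <- rowSums(m[genes, groups$wt_met, drop = FALSE])
    dist <- ifelse(ann$chrom[match(genes, ann$gene)] == sub_ann$chrom,
                   abs(ann$start[match(genes, ann$gene)] - sub_ann$start),
                   NA_real_)
    data.frame(gene = genes, direction = dir,
               freq_wt_primary = a_wtp / n_wtp,
               freq_st_primary = a_stp / n_stp,
               freq_wt_met = a_wtm / n_wtm,
               freq_st_met = a_stm / n_stm,
               n_alt_st_primary = a_stp, n_alt_wt_primary = a_wtp,
               n_alt_st_met = a_stm,
               primary_diff_observed = a_stp / n_stp - a_wtp / n_wtp,
               met_diff_observed = a_stm / n_stm - a_stp / n_stp,
               p_primary = enrich_p(a_stp, n_stp, a_wtp, n_wtp),
               p_met = enrich_p(a_stm, n_stm, a_stp, n_stp),
               dist_to_subtype = dist,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, per_dir)

  tab$fdr_primary <- NA_real_
  tab$fdr_met <- NA_real_
  in_primary_fam <- tab$primary_diff_observed >= params$primary_diff
  tab$fdr_primary[in_primary_fam] <- bh_adjust(tab$p_primary[in_primary_fam])
  pass_primary <- in_primary_fam & tab$fdr_primary <= params$coalt_fdr
  in_met_fam <- pass_primary & tab$met_diff_observed >= params$met_diff
  tab$fdr_met[in_met_fam] <- bh_adjust(tab$p_met[in_met_fam])
  keep <- in_met_fam & tab$fdr_met <= params$coalt_fdr

  reason <- rep("", nrow(tab))
  reason[!in_primary_fam] <- "primary frequency difference below threshold"
  reason[in_primary_fam & !pass_primary] <- "primary enrichment FDR above threshold"
  reason[pass_primary & !in_met_fam] <- "metastatic frequency difference below threshold"
  reason[in_met_fam & !keep] <- "metastatic enrichment FDR above threshold"

  trace <- data.frame(gene = tab$gene, direction = tab$direction,
                      terminal_stage = ifelse(keep, "", "genomic"),
                      reason = reason, stringsAsFactors = FALSE)
  list(candidates = tab[keep, , drop = FALSE], trace = trace)
}

#' Transcriptomic step: concordant differential expression
#'
#' Within subtype (ST) tumors, compares expression of each candidate gene
#' between altered and unaltered samples, separately in the primary and
#' metastatic compartments (difference of mean z-scores; pooled-variance
#' t-test). Losses must show negative effects in both compartments and Gains
#' positive ones; discordant candidates are removed, and the concordant ones
#' must reach BH-FDR <= `dge_fdr` in both compartments (families = concordant
#' candidates per compartment). Candidates with fewer than two altered or two
#' unaltered expressing samples in either compartment are removed.
#'
#' @inheritParams genomic_step
#' @param candidates output `candidates` of [genomic_step()].
#' @return list with `candidates` and `trace` rows for the removed.
#' @export
transcriptomic_step <- function(candidates, dataset, groups,
                                params = prostamine_params()) {
  expr <- dataset$expression
  n <- nrow(candidates)
  eff_p <- eff_m <- p_p <- p_m <- rep(NA_real_, n)
  reason <- rep("", n)
  if (n) {
    for (i in seq_len(n)) {
      g <- candidates$gene[i]; dir <- candidates$direction[i]
      if (is.null(expr) || !g %in% rownames(expr)) {
        reason[i] <- "insufficient expression"
        next
      }
      res_p <- compartment_effect(expr, dataset$alterations, g, dir,
                                  groups$st_primary)
      res_m <- compartment_effect(expr, dataset$alterations, g, dir,
                                  groups$st_met)
      if (is.null(res_p) || is.null(res_m)) {
        reason[i] <- "insufficient expression"
        next
      }
      eff_p[i] <- res_p$extra$mean_difference
      eff_m[i] <- res_m$extra$mean_difference
      p_p[i] <- res_p$p_value
      p_m[i] <- res_m$p_value
      want <- if (dir == "loss") -1 else 1
      if (sign(eff_p[i]) != want || sign(eff_m[i]) != want)
        reason[i] <- "discordant expression direction"
    }
  }
  candidates$effect_primary <- eff_p
  candidates$effect_met <- eff_m
  candidates$t_p_primary <- p_p
  candidates$t_p_met <- p_m
  candidates$t_fdr_primary <- rep(NA_real_, n)
  candidates$t_fdr_met <- rep(NA_real_, n)
  surv <- reason == ""
  if (any(surv)) {
    candidates$t_fdr_primary[surv] <- bh_adjust(p_p[surv])
    candidates$t_fdr_met[surv] <- bh_adjust(p_m[surv])
    fail_fdr <- surv & (candidates$t_fdr_primary > params$dge_fdr |
                          candidates$t_fdr_met > params$dge_fdr)
    reason[fail_fdr] <- "expression FDR above threshold"
  }
  keep <- reason == ""
  trace <- data.frame(gene = candidates$gene, direction = candidates$direction,
                      terminal_stage = ifelse(keep, "", "transcriptomic"),
                      reason = reason, stringsAsFactors = FALSE)
  list(candidates = candidates[keep, , drop = FALSE], trace = trace)
}

# t-test of candidate expression, altered vs unaltered, within one sample set;
# NULL when fewer than 2 expressing samples on either side.
compartment_effect <- function(expr, alterations, gene, direction, samples) {
  samples <- intersect(samples, colnames(expr))
  if (length(samples) < 4) return(NULL)
  altered <- alterations[[direction]][gene, samples]
  z <- expr[gene, samples]
  ok <- !is.na(z)
  if (sum(ok & altered) < 2 || sum(ok & !altered) < 2) return(NULL)
  student_t(z[ok & altered], z[ok & !altered])
}

#' Clinical step: Gleason and progression-free-survival concordance
#'
#' ST and WT primary tumors are median-stratified by each candidate gene's
#' expression; the adverse group is the lower stratum for Losses and the
#' upper stratum for Gains. A candidate is kept when (a) high Gleason grade
#' (>= cutoff) is enriched in the adverse ST stratum (direction requirement;
#' a p bound only when `gleason_fdr` is set), (b) the adverse ST stratum has
#' worse progression-free survival (logrank direction, concordant with the
#' metastatic enrichment) with p <= `survival_p_st`, and (c) the same
#' stratification in WT tumors shows no survival difference
#' (p >= `survival_p_wt`). Candidates without ST survival data are removed.
#'
#' @inheritParams transcriptomic_step
#' @return list with `candidates` and `trace`.
#' @export
clinical_step <- function(candidates, dataset, groups,
                          params = prostamine_params()) {
  expr <- dataset$expression
  cl <- dataset$clinical
  n <- nrow(candidates)
  gl_dir <- rep(NA_integer_, n)
  gl_p <- st_p <- wt_p <- st_dir <- log_hr <- hr_lo <- hr_hi <-
    rep(NA_real_, n)
  reason <- rep("", n)

  for (i in seq_len(n)) {
    g <- candidates$gene[i]; dir <- candidates$direction[i]
    adverse_side <- if (dir == "loss") "lower" else "upper"

    st_strat <- stratify_samples(expr, g, groups$st_primary)
    if (is.null(st_strat)) { reason[i] <- "insufficient expression for stratification"; next }
    adverse <- names(st_strat)[st_strat == adverse_side]
    favorable <- names(st_strat)[st_strat != adverse_side]

    cli <- cl[match(names(st_strat), cl$sample_id), , drop = FALSE]
    rownames(cli) <- cli$sample_id

    # (a) Gleason enrichment in the adverse stratum
    gl <- cli$gleason
    names(gl) <- cli$sample_id
    gl_ok <- !is.na(gl)
    high <- gl >= params$gleason_cutoff
    ft <- fisher_exact(sum(gl_ok[adverse] & high[adverse]),
                       sum(gl_ok[favorable] & high[favorable]),
                       sum(gl_ok[adverse] & !high[adverse]),
                       sum(gl_ok[favorable] & !high[favorable]), "greater")
    gl_dir[i] <- ft$effect_direction
    gl_p[i] <- ft$p_value

    # (b) survival in ST, adverse vs favorable
    t_adv <- cli[adverse, "pfs_time"]; e_adv <- cli[adverse, "pfs_event"]
    t_fav <- cli[favorable, "pfs_time"]; e_fav <- cli[favorable, "pfs_event"]
    ok_a <- !is.na(t_adv); ok_f <- !is.na(t_fav)
    if (!any(ok_a) || !any(ok_f) ||
        !any(c(e_adv[ok_a], e_fav[ok_f]))) {
      reason[i] <- "no ST survival data"
      next
    }
    lr <- logrank_test(t_adv[ok_a], e_adv[ok_a], t_fav[ok_f], e_fav[ok_f])
    st_p[i] <- lr$p_value
    st_dir[i] <- lr$effect_direction
    cx <- tryCatch(
      cox_univariate(c(t_adv[ok_a], t_fav[ok_f]), c(e_adv[ok_a], e_fav[ok_f]),
                     rep(c(1L, 0L), c(sum(ok_a), sum(ok_f)))),
      error = function(e) NULL)
    if (!is.null(cx)) {
      log_hr[i] <- cx$statistic
      hr_lo[i] <- cx$extra$ci_lower
      hr_hi[i] <- cx$extra$ci_upper
    }

    # (c) the same stratification in WT primaries must be survival-null
    wt_strat <- stratify_samples(expr, g, groups$wt_primary)
    if (is.null(wt_strat)) {
      wt_p[i] <- NA_real_
    } else {
      adv_w <- names(wt_strat)[wt_strat == adverse_side]
      fav_w <- names(wt_strat)[wt_strat != adverse_side]
      cw <- cl[match(names(wt_strat), cl$sample_id), , drop = FALSE]
      rownames(cw) <- cw$sample_id
      tw_a <- cw[adv_w, "pfs_time"]; ew_a <- cw[adv_w, "pfs_event"]
      tw_f <- cw[fav_w, "pfs_time"]; ew_f <- cw[fav_w, "pfs_event"]
      oa <- !is.na(tw_a); of <- !is.na(tw_f)
      wt_p[i] <- if (any(oa) && any(of)) {
        logrank_test(tw_a[oa], ew_a[oa], tw_f[of], ew_f[of])$p_value
      } else 1
    }

    if (gl_dir[i] <= 0) {
      reason[i] <- "Gleason enrichment direction discordant"
    } else if (st_dir[i] <= 0) {
      reason[i] <- "ST survival direction discordant"
    } else if (st_p[i] > params$survival_p_st) {
      reason[i] <- "ST survival p above threshold"
    } else if (is.na(wt_p[i]) || wt_p[i] < params$survival_p_wt) {
      reason[i] <- "WT survival difference not null"
    }
  }

  candidates$gleason_direction <- gl_dir
  candidates$gleason_p <- gl_p
  candidates$st_logrank_p <- st_p
  candidates$st_surv_direction <- st_dir
  candidates$wt_logrank_p <- wt_p
  candidates$st_log_hr <- log_hr
  candidates$st_hr_ci_lower <- hr_lo
  candidates$st_hr_ci_upper <- hr_hi

  if (!is.null(params$gleason_fdr) && n) {
    surv <- reason == ""
    if (any(surv)) {
      gfdr <- rep(NA_real_, n)
      gfdr[surv] <- bh_adjust(gl_p[surv])
      fail <- surv & gfdr > params$gleason_fdr
      reason[fail] <- "Gleason enrichment FDR above threshold"
      candidates$gleason_fdr <- gfdr
    }
  }

  keep <- reason == ""
  trace <- data.frame(gene = candidates$gene, direction = candidates$direction,
                      terminal_stage = ifelse(keep, "", "clinical"),
                      reason = reason, stringsAsFactors = FALSE)
  list(candidates = candidates[keep, , drop = FALSE], trace = trace)
}

# median-stratify one gene's expression over a sample set; NULL when the
# gene/expression is unavailable or the stratification is degenerate
stratify_samples <- function(expr, gene, samples) {
  if (is.null(expr) || !gene %in% rownames(expr)) return(NULL)
  samples <- intersect(samples, colnames(expr))
  z <- expr[gene, samples]
  names(z) <- samples
  z <- z[!is.na(z)]
  if (length(z) < 4) return(NULL)
  tryCatch(setNames(as.character(median_stratify(z)), names(z)),
           error = function(e) NULL)
}

#' Score and rank the final hits
#'
#' Hits are ranked in three categories: primary co-alteration frequency
#' difference (descending), metastatic frequency difference (descending), and
#' ST logrank p-value (ascending); ties share the minimum rank order. Each
#' rank is transformed to a normalized rank `1 - rank / N_hits`, and the
#' final score is the weighted combination
#' `0.3 * nr_primary + 0.3 * nr_met + 0.4 * nr_surv`. Output is sorted by
#' score (descending), ties broken by gene symbol.
#'
#' @param hits data.frame of final hits from [clinical_step()].
#' @return the hits with `rank_primary`, `rank_met`, `rank_surv`,
#'   `nr_primary`, `nr_met`, `nr_surv`, `score` columns added.
#' @export
score_hits <- function(hits) {
  n <- nrow(hits)
  if (!n) pm_stop("no hits to score")
  hits$rank_primary <- rank(-hits$primary_diff_observed, ties.method = "min")
  hits$rank_met <- rank(-hits$met_diff_observed, ties.method = "min")
  hits$rank_surv <- rank(hits$st_logrank_p, ties.method = "min")
  hits$nr_primary <- 1 - hits$rank_primary / n
  hits$nr_met <- 1 - hits$rank_met / n
  hits$nr_surv <- 1 - hits$rank_surv / n
  hits$score <- 0.3 * hits$nr_primary + 0.3 * hits$nr_met + 0.4 * hits$nr_surv
  hits <- hits[order(-hits$score, hits$gene), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Run the full mining cascade for one subtype
#'
#' Composition of [define_groups()], [genomic_step()],
#' [transcriptomic_step()], [clinical_step()] and [score_hits()]. Every
#' tested gene x direction appears in the filter trace with its terminal
#' stage and removal reason; the run is deterministic given its inputs.
#'
#' @param dataset a `pm_dataset` with primary and metastatic samples,
#'   expression and clinical layers.
#' @param subtype_gene gene defining the molecular subtype.
#' @param direction `"loss"` or `"gain"`.
#' @param params a `pm_params` (default [prostamine_params()]).
#' @return object of class `pm_result`: list with `subtype_gene`,
#'   `direction`, `params`, `groups`, `hits` (scored, possibly zero-row) and
#'   `trace`.
#' @export
run_prostamine <- function(dataset, subtype_gene,
                           direction = c("loss", "gain"),
                           params = prostamine_params()) {
  direction <- match.arg(direction)
  stopifnot(inherits(dataset, "pm_dataset"))
  groups <- define_groups(dataset, subtype_gene, direction)
  gs <- genomic_step(dataset, groups, params)
  ts <- transcriptomic_step(gs$candidates, dataset, groups, params)
  cs <- clinical_step(ts$candidates, dataset, groups, params)

  trace <- gs$trace
  trace <- merge_trace(trace, ts$trace)
  trace <- merge_trace(trace, cs$trace)
  trace$terminal_stage[trace$terminal_stage == ""] <- "hit"

  hits <- if (nrow(cs$candidates)) score_hits(cs$candidates) else cs$candidates
  structure(list(subtype_gene = subtype_gene, direction = direction,
                 params = params, groups = groups, hits = hits,
                 trace = trace[order(trace$gene, trace$direction), ]),
            class = "pm_result")
}

merge_trace <- function(trace, stage_trace) {
  if (!nrow(stage_trace)) return(trace)
  key <- paste(trace$gene, trace$direction)
  skey <- paste(stage_trace$gene, stage_trace$direction)
  idx <- match(skey, key)
  upd <- stage_trace$terminal_stage != ""
  trace$terminal_stage[idx[upd]] <- stage_trace$terminal_stage[upd]
  trace$reason[idx[upd]] <- stage_trace$reason[upd]
  trace
}

#' @export
print.pm_result <- function(x, ...) {
  cat(sprintf("Mining run: subtype %s (%s)\n", x$subtype_gene, x$direction))
  cat(sprintf("  groups: %d ST-primary / %d WT-primary / %d ST-met / %d WT-met\n",
              length(x$groups$st_primary), length(x$groups$wt_primary),
              length(x$groups$st_met), length(x$groups$wt_met)))
  cat(sprintf("  final hits: %d\n", nrow(x$hits)))
  if (nrow(x$hits))
    print(utils::head(x$hits[, c("gene", "direction", "primary_diff_observed",
                                 "met_diff_observed", "st_logrank_p",
                                 "score")], 10))
  invisible(x)
}
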