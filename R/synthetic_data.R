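# Synthetic multi-cohort generator: background alteration noise, planted
# subtype-specific co-alterations with concordant expression shifts and
# subtype-specific survival effects, plus recurrent-loss regions that behave
# like alteration hotspots. Emulates the schema of harmonized prostate-cancer
# cohorts; it does not attempt realistic allele spectra, segment-level CNA
# correlation or batch effects.

#' Configuration for the synthetic multi-cohort generator
#'
#' Defaults describe the reference simulation: 3000 genes over 20
#' chromosomes; two primary cohorts of 200 tumors and one all-metastatic
#' cohort of 150 (metastatic samples carry no PFS or Gleason data); per-gene
#' background Loss and Gain rates of 5\%; a subtype gene lost in 50\% of
#' primaries and 60\% of metastases; and one planted Loss co-alteration with
#' a +0.25 frequency uplift in ST primaries, a further +0.25 in ST
#' metastases, a -0.8 z expression shift in altered samples, hazard ratio 3
#' for adverse-expression ST primaries, and a +0.25 uplift in the probability
#' of high Gleason grade. PFS is exponential (median 60 months at baseline)
#' with independent uniform censoring on \[0, 150\] months.
#'
#' @param n_genes number of genes.
#' @param n_primary samples per primary cohort.
#' @param n_primary_cohorts number of primary cohorts.
#' @param n_metastatic samples in the single all-metastatic cohort.
#' @param background_loss,background_gain per-gene background alteration
#'   rates.
#' @param subtype_gene symbol of the subtype-defining gene.
#' @param st_fraction_primary,st_fraction_met fraction of samples carrying
#'   the subtype loss.
#' @param subtype_gain_rate small rate of opposite-direction (Gain) calls on
#'   the subtype gene among non-ST samples (these become excluded samples).
#' @param planted_hits data.frame with columns `gene`, `direction`,
#'   `extra_primary`, `extra_met`, `expr_shift`, `hazard_ratio`,
#'   `gleason_uplift`; `NULL` for a null (no planted effects) generator.
#' @param hotspot_regions data.frame with columns `start_index`, `n_genes`,
#'   `direction`, `rate` planting contiguous recurrently altered regions;
#'   `NULL` for none.
#' @param mutation_rate per-cell rate of emitted single-base substitutions
#'   (85\% flagged deleterious).
#' @param baseline_median_pfs baseline median progression-free survival
#'   (months).
#' @param censoring_max upper bound of the uniform censoring time (months).
#' @param gleason_base baseline probability of Gleason >= 8.
#' @param seed integer seed (mandatory).
#' @return a `pm_synth_config` list.
#' @export
synthetic_config <- function(n_genes = 3000, n_primary = 200,
                             n_primary_cohorts = 2, n_metastatic = 150,
                             background_loss = 0.05, background_gain = 0.05,
                             subtype_gene = "G0001",
                             st_fraction_primary = 0.5,
                             st_fraction_met = 0.6,
                             subtype_gain_rate = 0.02,
                             planted_hits = data.frame(
                               gene = "G1500", direction = "loss",
                               extra_primary = 0.25, extra_met = 0.25,
                               expr_shift = -0.8, hazard_ratio = 3,
                               gleason_uplift = 0.25,
                               stringsAsFactors = FALSE),
                             hotspot_regions = data.frame(
                               start_index = c(301, 1201),
                               n_genes = c(8, 8),
                               direction = c("loss", "loss"),
                               rate = c(0.15, 0.15),
                               stringsAsFactors = FALSE),
                             mutation_rate = 0.001,
                             baseline_median_pfs = 60,
                             censoring_max = 150,
                             gleason_base = 0.25,
                             seed) {
  if (missing(seed)) pm_stop("a seed is mandatory for the generator")
  cfg <- list(n_genes = n_genes, n_primary = n_primary,
              n_primary_cohorts = n_primary_cohorts,
              n_metastatic = n_metastatic,
              background_loss = background_loss,
              background_gain = background_gain,
              subtype_gene = subtype_gene,
              st_fraction_primary = st_fraction_primary,
              st_fraction_met = st_fraction_met,
              subtype_gain_rate = subtype_gain_rate,
              planted_hits = planted_hits,
              hotspot_regions = hotspot_regions,
              mutation_rate = mutation_rate,
              baseline_median_pfs = baseline_median_pfs,
              censoring_max = censoring_max,
              gleason_base = gleason_base,
              seed = as.integer(seed))
  rates <- c(background_loss, background_gain, st_fraction_primary,
             st_fraction_met, subtype_gain_rate, mutation_rate, gleason_base)
  if (any(rates < 0 | rates > 1)) pm_stop("rates must lie in [0, 1]")
  if (!is.null(planted_hits)) {
    if (any(planted_hits$hazard_ratio <= 0)) pm_stop("hazard ratio must be > 0")
    if (any(background_loss + planted_hits$extra_primary +
              planted_hits$extra_met > 1))
      pm_stop("planted rates imply probability > 1")
    all_genes <- sprintf("G%04d", seq_len(n_genes))
    bad <- setdiff(c(subtype_gene, planted_hits$gene), all_genes)
    if (length(bad))
      pm_stop("genes outside the simulated gene set: ",
              paste(bad, collapse = ", "))
  }
  if (!is.null(hotspot_regions) &&
      any(hotspot_regions$start_index + hotspot_regions$n_genes - 1 > n_genes))
    pm_stop("hotspot region extends past the simulated gene set")
  structure(cfg, class = "pm_synth_config")
}

#' Simulate a harmonized multi-cohort dataset in memory
#'
#' Draws alteration calls per gene as Bernoulli with planted uplifts
#' conditional on subtype membership, expression as standard normal plus the
#' planted shift for altered samples, exponential PFS with planted hazards
#' for adverse-expression ST primaries (adverse = below the ST-primary median
#' of the planted gene's expression), independent uniform censoring, and
#' Gleason grade with the planted uplift in the adverse stratum. Fully
#' reproducible from the config seed.
#'
#' @param config a `pm_synth_config`.
#' @return list with `dataset` (merged `pm_dataset`), `cohorts` (list of
#'   per-cohort `pm_dataset`s), `truth` (data.frame of planted effects) and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "pm_synth_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    n_chrom <- min(20L, config$n_genes)
    chrom <- paste0("chr", rep(seq_len(n_chrom),
                               each = ceiling(config$n_genes / n_chrom)))[seq_len(config$n_genes)]
    # genes are laid out block-wise by chromosome, so per-chromosome position
    # sequences concatenate back in gene order
    start <- unlist(lapply(split(seq_along(genes), chrom)[unique(chrom)],
                           function(ix) (seq_along(ix) - 1L) * 100000L),
                    use.names = FALSE)
    annotation <- data.frame(chrom = chrom, start = start,
                             end = start + 10000L, gene = genes,
                             stringsAsFactors = FALSE)

    cohorts <- c(paste0("prim", LETTERS[seq_len(config$n_primary_cohorts)]),
                 "metC")
    sizes <- c(rep(config$n_primary, config$n_primary_cohorts),
               config$n_metastatic)
    types <- c(rep("primary", config$n_primary_cohorts), "metastatic")
    sample_cohort <- rep(cohorts, sizes)
    sample_type <- rep(types, sizes)
    samples <- unlist(lapply(seq_along(cohorts), function(i) {
      sprintf("%s_s%03d", cohorts[i], seq_len(sizes[i]))
    }))
    ns <- length(samples)

    st <- runif(ns) < ifelse(sample_type == "primary",
                             config$st_fraction_primary,
                             config$st_fraction_met)

    # per-cell loss/gain probabilities
    p_loss <- matrix(config$background_loss, config$n_genes, ns)
    p_gain <- matrix(config$background_gain, config$n_genes, ns)
    if (!is.null(config$hotspot_regions)) {
      for (j in seq_len(nrow(config$hotspot_regions))) {
        hs <- config$hotspot_regions[j, ]
        rows <- hs$start_index:(hs$start_index + hs$n_genes - 1L)
        if (hs$direction == "loss") p_loss[rows, ] <- hs$rate
        else p_gain[rows, ] <- hs$rate
      }
    }
    if (!is.null(config$planted_hits)) {
      for (j in seq_len(nrow(config$planted_hits))) {
        ph <- config$planted_hits[j, ]
        row <- match(ph$gene, genes)
        extra <- ifelse(st & sample_type == "primary", ph$extra_primary,
                        ifelse(st, ph$extra_primary + ph$extra_met, 0))
        if (ph$direction == "loss") p_loss[row, ] <- p_loss[row, ] + extra
        else p_gain[row, ] <- p_gain[row, ] + extra
      }
    }
    sub_row <- match(config$subtype_gene, genes)
    p_loss[sub_row, ] <- ifelse(st, 1, 0)
    p_gain[sub_row, ] <- ifelse(st, 0, config$subtype_gain_rate)

    u <- matrix(runif(config$n_genes * ns), config$n_genes, ns)
    is_loss <- u < p_loss
    is_gain <- !is_loss & u < p_loss + p_gain
    cna <- matrix(0L, config$n_genes, ns, dimnames = list(genes, samples))
    cna[is_loss] <- -(1L + (runif(sum(is_loss)) < 0.3))
    cna[is_gain] <- 1L + (runif(sum(is_gain)) < 0.3)

    # sparse single-base substitutions; never emitted on gained cells so the
    # conflict-resolution path stays a deliberate choice, not generator noise
    n_mut <- rbinom(1, config$n_genes * ns, config$mutation_rate)
    mut_cells <- sample.int(config$n_genes * ns, n_mut)
    mg <- ((mut_cells - 1L) %% config$n_genes) + 1L
    msamp <- ((mut_cells - 1L) %/% config$n_genes) + 1L
    keep_mut <- cna[cbind(mg, msamp)] <= 0
    mutations <- data.frame(gene = genes[mg[keep_mut]],
                            sample_id = samples[msamp[keep_mut]],
                            deleterious = runif(sum(keep_mut)) < 0.85,
                            stringsAsFactors = FALSE)
    mutations <- mutations[order(mutations$gene, mutations$sample_id), ]
    rownames(mutations) <- NULL

    alt <- derive_alteration_calls(cna, mutations)

    expression <- matrix(rnorm(config$n_genes * ns), config$n_genes, ns,
                         dimnames = list(genes, samples))
    shift_gene <- function(gene, direction, shift) {
      row <- match(gene, genes)
      carriers <- alt[[direction]][row, ]
      expression[row, carriers] <<- expression[row, carriers] + shift
    }
    if (!is.null(config$planted_hits)) {
      for (j in seq_len(nrow(config$planted_hits))) {
        ph <- config$planted_hits[j, ]
        shift_gene(ph$gene, ph$direction, ph$expr_shift)
      }
    }
    shift_gene(config$subtype_gene, "loss", -0.5)

    # clinical layer: PFS and Gleason for primaries only
    lambda0 <- log(2) / config$baseline_median_pfs
    log_mult <- rep(0, ns)
    adverse_any <- rep(FALSE, ns)
    is_primary <- sample_type == "primary"
    if (!is.null(config$planted_hits)) {
      for (j in seq_len(nrow(config$planted_hits))) {
        ph <- config$planted_hits[j, ]
        z <- expression[match(ph$gene, genes), ]
        stp <- st & is_primary
        med <- median(z[stp])
        adverse <- stp & (if (ph$direction == "loss") z <= med else z > med)
        log_mult <- log_mult + log(ph$hazard_ratio) * adverse
        adverse_any <- adverse_any | adverse
      }
    }
    t_event <- rexp(ns, rate = lambda0 * exp(log_mult))
    t_cens <- runif(ns, 0, config$censoring_max)
    pfs_time <- round(pmin(t_event, t_cens), 3)
    pfs_event <- t_event <= t_cens
    p_high <- pmin(0.95, config$gleason_base +
                     ifelse(adverse_any,
                            max(0, if (is.null(config$planted_hits)) 0 else
                              max(config$planted_hits$gleason_uplift)), 0))
    high <- runif(ns) < p_high
    gleason <- ifelse(high, sample(8:9, ns, replace = TRUE),
                      sample(6:7, ns, replace = TRUE))
    t_stage <- sample(c("T1c", "T2a", "T2b", "T2c", "T3a", "T3b"), ns,
                      replace = TRUE,
                      prob = c(0.2, 0.2, 0.2, 0.15, 0.15, 0.1))
    n_stage <- sample(c("N0", "N1"), ns, replace = TRUE, prob = c(0.9, 0.1))

    clinical <- data.frame(sample_id = samples, cohort = sample_cohort,
                           sample_type = sample_type,
                           gleason = ifelse(is_primary, gleason, NA_integer_),
                           t_stage = ifelse(is_primary, t_stage, NA_character_),
                           n_stage = ifelse(is_primary, n_stage, NA_character_),
                           pfs_time = ifelse(is_primary, pfs_time, NA_real_),
                           pfs_event = ifelse(is_primary, pfs_event, NA),
                           stringsAsFactors = FALSE)

    cohort_data <- lapply(seq_along(cohorts), function(i) {
      cols <- sample_cohort == cohorts[i]
      ids <- samples[cols]
      mut_i <- mutations[mutations$sample_id %in% ids, , drop = FALSE]
      rownames(mut_i) <- NULL
      new_pm_dataset(
        derive_alteration_calls(cna[, cols, drop = FALSE], mut_i),
        cna[, cols, drop = FALSE], mut_i,
        expression[, cols, drop = FALSE],
        clinical[cols, , drop = FALSE], annotation)
    })
    names(cohort_data) <- cohorts
    merged <- merge_cohorts(cohort_data)

    truth <- if (is.null(config$planted_hits)) {
      data.frame(gene = character(), direction = character(),
                 extra_primary = numeric(), extra_met = numeric(),
                 expr_shift = numeric(), hazard_ratio = numeric(),
                 gleason_uplift = numeric(), stringsAsFactors = FALSE)
    } else {
      config$planted_hits
    }
    truth$run_id <- rep(paste0("seed", config$seed), nrow(truth))

    out <- list(dataset = merged, cohorts = cohort_data, truth = truth,
                config = config)
    attr(out, "run_id") <- paste0("seed", config$seed)
    out
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes each cohort as a [write_dataset()] directory under `dir`, plus a
#' `truth.tsv` listing the planted effects. Byte-identical for a fixed
#' config and seed.
#'
#' @param config a `pm_synth_config`.
#' @param dir output directory.
#' @return invisibly, the `simulate_dataset()` result.
#' @export
generate_dataset <- function(config, dir) {
  sim <- simulate_dataset(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$cohorts))
    write_dataset(sim$cohorts[[nm]], file.path(dir, nm))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sim)
}

#' Compare planted effects against a mining hit table
#'
#' @param truth truth table from the generator (columns `gene`, `direction`,
#'   plus planted-effect sizes; optional `run_id`).
#' @param hits scored hit table from [run_prostamine()] (rows ordered by
#'   score).
#' @param run_id optional run id of the hit table; when both ids are present
#'   they must match.
#' @return data.frame with one row per planted effect (`gene`, `direction`,
#'   `detected`, `rank`, `score`) and attribute `false_hits` = number of
#'   unplanted genes in the hit table.
#' @export
truth_recovery_report <- function(truth, hits, run_id = NULL) {
  truth_id <- unique(truth$run_id)
  if (!is.null(run_id) && length(truth_id) && !all(truth_id == run_id))
    pm_stop("mismatched run ids: truth ", paste(truth_id, collapse = ","),
            " vs hits ", run_id)
  key_hits <- if (nrow(hits)) paste(hits$gene, hits$direction) else character()
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    k <- paste(truth$gene[i], truth$direction[i])
    pos <- match(k, key_hits)
    data.frame(gene = truth$gene[i], direction = truth$direction[i],
               detected = !is.na(pos),
               rank = if (is.na(pos)) NA_integer_ else pos,
               score = if (is.na(pos)) NA_real_ else hits$score[pos],
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), direction = character(),
               detected = logical(), rank = integer(), score = numeric())
  attr(res, "false_hits") <- length(setdiff(key_hits,
                                            paste(truth$gene, truth$direction)))
  res
}
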