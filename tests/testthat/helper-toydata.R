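# Hand-engineered cascade fixture: six candidate Loss genes built so that the
# filter cascade removes exactly four of them, one per distinct reason:
#   G1 fails the primary frequency-difference filter (0.016 < 0.1)
#   G2 fails the metastatic frequency-difference filter (diff 0)
#   G3 fails expression concordance (a Loss whose carriers express MORE)
#   G4 fails the WT survival-null requirement (its WT stratification tracks
#      a real WT survival split)
#   G5 and G6 survive everything; their ST strata coincide, so the survival
#      ranks tie while the frequency ranks separate them (G5 first).
# All quantities are deterministic; stage verdicts were frozen from the
# enumeration/hand-tabulation oracles in helper-oracles.R.

toy_cascade <- function() {
  stp <- sprintf("p%02d", 1:40)   # ST primaries (subtype loss)
  wtp <- sprintf("w%02d", 1:38)   # WT primaries (diploid)
  exc <- c("x01", "x02")          # subtype-gain primaries -> excluded
  stm <- sprintf("m%02d", 1:20)   # ST metastases
  wtm <- sprintf("n%02d", 1:8)    # WT metastases
  samples <- c(stp, wtp, exc, stm, wtm)
  genes <- c("SUB", paste0("G", 1:6), "F1", "F2")

  cna <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  cna["SUB", c(stp, stm)] <- -1L
  cna["SUB", exc] <- 1L
  lose <- function(gene, smp) cna[gene, smp] <<- -1L
  lose("G1", c(stp[1:8],  wtp[1:7], stm[1:8]))
  lose("G2", c(stp[1:16], wtp[1:2], stm[1:8]))
  lose("G3", c(stp[1:16], wtp[1:2], stm[1:14]))
  lose("G4", c(stp[1:16], wtp[1:2], stm[1:14]))
  lose("G5", c(stp[1:18], wtp[1:2], stm[1:16]))
  lose("G6", c(stp[1:14], wtp[1:2], stm[1:11]))

  expr <- matrix(0.5, length(genes), length(samples),
                 dimnames = list(genes, samples))
  # ST primaries: altered carriers low; the designated extra "low jitter"
  # unaltered samples complete a lower stratum of exactly p01..p20
  set_expr <- function(gene, low, lowish, high, flip = FALSE) {
    sgn <- if (flip) -1 else 1
    expr[gene, low] <<- sgn * (-1 + 0.01 * seq_along(low))
    if (length(lowish))
      expr[gene, lowish] <<- sgn * (-0.2 + 0.01 * seq_along(lowish))
    expr[gene, high] <<- sgn * (0.2 + 0.01 * seq_along(high))
  }
  set_expr("G5", stp[1:18], stp[19:20], stp[21:40])
  set_expr("G6", stp[1:14], stp[15:20], stp[21:40])
  set_expr("G4", stp[1:16], stp[17:20], stp[21:40])
  set_expr("G3", stp[1:16], stp[17:20], stp[21:40], flip = TRUE)
  set_expr("G2", stp[1:16], stp[17:20], stp[21:40])
  set_expr("G1", stp[1:8],  NULL,       stp[9:40])
  # ST metastases: concordant for G2/G4/G5/G6, discordant for G3
  set_expr("G5", stm[1:16], NULL, stm[17:20])
  set_expr("G6", stm[1:11], NULL, stm[12:20])
  set_expr("G4", stm[1:14], NULL, stm[15:20])
  set_expr("G2", stm[1:8],  NULL, stm[9:20])
  set_expr("G3", stm[1:14], NULL, stm[15:20], flip = TRUE)
  expr["G1", stm] <- 0.1 + 0.01 * seq_along(stm)
  # WT primaries: G4's strata align with the WT survival split; G5/G6 strata
  # interleave it (odd samples low), so their WT logrank is null
  expr["G4", wtp] <- c(-1 + 0.01 * (1:19), 0.2 + 0.01 * (1:19))
  odd <- as.logical(seq_along(wtp) %% 2)
  for (g in c("G1", "G2", "G5", "G6")) {
    expr[g, wtp[odd]] <- -1 + 0.01 * seq_len(sum(odd))
    expr[g, wtp[!odd]] <- 0.2 + 0.01 * seq_len(sum(!odd))
  }

  clinical <- data.frame(
    sample_id = samples,
    cohort = "toy",
    sample_type = rep(c("primary", "metastatic"),
                      c(length(stp) + length(wtp) + length(exc),
                        length(stm) + length(wtm))),
    gleason = NA_integer_, t_stage = NA_character_, n_stage = NA_character_,
    pfs_time = NA_real_, pfs_event = NA, stringsAsFactors = FALSE)
  rownames(clinical) <- clinical$sample_id
  clinical[stp, "gleason"] <- rep(c(9L, 7L), each = 20)
  clinical[wtp, "gleason"] <- 7L
  # ST primaries: the (shared) adverse stratum p01..p20 relapses early
  clinical[stp, "pfs_time"] <- c(1 + (1:20), 30 + (21:40))
  clinical[stp, "pfs_event"] <- rep(c(TRUE, FALSE), each = 20)
  # WT primaries: w01..w19 relapse early, the rest are censored late
  clinical[wtp, "pfs_time"] <- c(1 + (1:19), 10 + (20:38))
  clinical[wtp, "pfs_event"] <- c(rep(TRUE, 19), rep(FALSE, 19))
  clinical[exc, c("pfs_time", "pfs_event")] <- list(50, FALSE)
  rownames(clinical) <- NULL

  annotation <- data.frame(chrom = "chr1",
                           start = (seq_along(genes) - 1L) * 100000L,
                           end = (seq_along(genes) - 1L) * 100000L + 10000L,
                           gene = genes, stringsAsFactors = FALSE)

  list(dataset = harmonized_dataset(cna, expression = expr,
                                    clinical = clinical,
                                    annotation = annotation),
       params = prostamine_params(primary_diff = 0.1, met_diff = 0.1,
                                  coalt_fdr = 0.25, dge_fdr = 0.25,
                                  survival_p_st = 0.2, survival_p_wt = 0.3),
       groups = list(st_primary = stp, wt_primary = wtp, st_met = stm,
                     wt_met = wtm, excluded = exc))
}

# 3-gene / 4-sample fixture written to disk, for IO round-trips
write_tiny_cohort <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cna <- matrix(c(-2L, 0L, 1L, 0L, -1L, 2L, 0L, 0L, 1L, -1L, 0L, 0L), 3, 4,
                dimnames = list(c("TP53", "PTEN", "MYC"),
                                c("s1", "s2", "s3", "s4")))
  expr <- matrix(round(rnorm(12), 4), 3, 4,
                 dimnames = dimnames(cna))
  clinical <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"), cohort = "tiny",
    sample_type = c("primary", "primary", "primary", "metastatic"),
    gleason = c(7L, 9L, 6L, NA), t_stage = c("T2a", "T3a", "T1c", NA),
    n_stage = c("N0", "N1", "N0", NA),
    pfs_time = c(12.5, 3, 40, NA), pfs_event = c(TRUE, TRUE, FALSE, NA),
    stringsAsFactors = FALSE)
  mutations <- data.frame(gene = "PTEN", sample_id = "s1",
                          deleterious = TRUE, stringsAsFactors = FALSE)
  annotation <- data.frame(chrom = c("chr17", "chr10", "chr8"),
                           start = c(7500000L, 89000000L, 127000000L),
                           end = c(7590000L, 89100000L, 127100000L),
                           gene = c("TP53", "PTEN", "MYC"))
  paths <- list(cna = file.path(dir, "cna.tsv"),
                mutations = file.path(dir, "mutations.tsv"),
                expression = file.path(dir, "expression.tsv"),
                clinical = file.path(dir, "clinical.tsv"),
                annotation = file.path(dir, "annotation.bed"))
  write.table(data.frame(gene = rownames(cna), cna, check.names = FALSE),
              paths$cna, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mutations, paths$mutations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
              paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(clinical, paths$clinical, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(annotation, paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths
}

# planted multi-block binary alteration matrix for clustering tests
block_matrix <- function(n_blocks = 4, per_block = 20, n_features = 17,
                         in_rate = 0.9, out_rate = 0.05, seed = 1) {
  set.seed(seed)
  truth <- rep(seq_len(n_blocks), each = per_block)
  n <- length(truth)
  blocks <- split(seq_len(n_features),
                  rep(seq_len(n_blocks), length.out = n_features))
  x <- matrix(rbinom(n_features * n, 1, out_rate), n_features, n)
  for (b in seq_len(n_blocks)) {
    rows <- blocks[[b]]
    x[rows, truth == b] <- rbinom(length(rows) * per_block, 1, in_rate)
  }
  colnames(x) <- sprintf("s%03d", seq_len(n))
  list(x = x, truth = truth)
}
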