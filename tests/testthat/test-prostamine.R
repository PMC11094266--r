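make_group_fixture <- function(types = c("primary", "primary", "primary",
                                         "metastatic", "metastatic")) {
  cna <- matrix(0L, 2, length(types),
                dimnames = list(c("SUB", "OTHER"),
                                sprintf("s%d", seq_along(types))))
  cna["SUB", 1] <- -1L
  cna["SUB", 2] <- 1L
  if (length(types) > 3) cna["SUB", 4] <- -1L
  clinical <- data.frame(sample_id = colnames(cna), cohort = "c",
                         sample_type = types, gleason = 7L, t_stage = "T2a",
                         n_stage = "N0", pfs_time = 10, pfs_event = TRUE,
                         stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                    end = c(500L, 1500L), gene = c("SUB", "OTHER"))
  harmonized_dataset(cna, clinical = clinical, annotation = ann)
}

test_that("group definition separates ST, WT and opposite-direction samples", {
  ds <- make_group_fixture()
  g <- define_groups(ds, "SUB", "loss")
  expect_equal(g$st_primary, "s1")
  expect_equal(g$wt_primary, "s3")
  expect_equal(g$excluded$sample_id, "s2")
  expect_match(g$excluded$reason, "opposite")
  expect_equal(g$st_met, "s4")
  expect_equal(g$wt_met, "s5")

  # the symmetric subtype: Gain makes s2 the ST sample and s1 excluded
  ds2 <- make_group_fixture(c("primary", "primary", "primary",
                              "metastatic", "metastatic"))
  ds2$alterations$gain["SUB", "s4"] <- TRUE
  ds2$alterations$loss["SUB", "s4"] <- FALSE
  g2 <- define_groups(ds2, "SUB", "gain")
  expect_equal(g2$st_primary, "s2")
  expect_equal(g2$wt_primary, "s3")
  expect_equal(g2$excluded$sample_id, "s1")

  # an empty group is a named error
  ds3 <- make_group_fixture(c("primary", "primary", "primary",
                              "primary", "primary"))
  expect_error(define_groups(ds3, "SUB", "loss"), "empty group: ST_metastatic")
  expect_error(define_groups(ds, "NOPE", "loss"), "not in dataset")
})

test_that("the genomic step applies frequency-difference and enrichment-FDR filters", {
  toy <- toy_cascade()
  groups <- define_groups(toy$dataset, "SUB", "loss")
  gs <- genomic_step(toy$dataset, groups, toy$params)

  expect_setequal(gs$candidates$gene, c("G3", "G4", "G5", "G6"))
  tr <- gs$trace
  reason_of <- function(g, d = "loss")
    tr$reason[tr$gene == g & tr$direction == d]
  expect_match(reason_of("G1"), "primary frequency difference")
  expect_match(reason_of("G2"), "metastatic frequency difference")
  expect_match(reason_of("F1"), "primary frequency difference")
  # the subtype gene itself is never a candidate nor traced
  expect_false("SUB" %in% tr$gene)

  # frozen expected statistics for G5 (counts 18/40, 2/38, 16/20):
  g5 <- gs$candidates[gs$candidates$gene == "G5", ]
  expect_equal(g5$primary_diff_observed, 18 / 40 - 2 / 38, tolerance = 1e-12)
  expect_equal(g5$met_diff_observed, 16 / 20 - 18 / 40, tolerance = 1e-12)
  expect_equal(g5$p_primary, fisher_enum_oracle(18, 2, 22, 36, "greater"),
               tolerance = 1e-12)
  expect_equal(g5$p_met, fisher_enum_oracle(16, 18, 4, 22, "greater"),
               tolerance = 1e-12)
  # BH within the sequentially captured families, checked with the oracle
  prim_fam <- c(G2 = fisher_enum_oracle(16, 2, 24, 36, "greater"),
                G3 = fisher_enum_oracle(16, 2, 24, 36, "greater"),
                G4 = fisher_enum_oracle(16, 2, 24, 36, "greater"),
                G5 = fisher_enum_oracle(18, 2, 22, 36, "greater"),
                G6 = fisher_enum_oracle(14, 2, 26, 36, "greater"))
  expect_equal(g5$fdr_primary, bh_oracle(prim_fam)[["G5"]], tolerance = 1e-12)

  # the frequency filter is pure threshold arithmetic: raising primary_diff
  # just above G6's observed difference (0.297) drops exactly G6
  p2 <- prostamine_params(primary_diff = 0.30, met_diff = 0.1,
                          coalt_fdr = 0.25)
  gs2 <- genomic_step(toy$dataset, groups, p2)
  expect_setequal(gs2$candidates$gene, c("G3", "G4", "G5"))
})

test_that("the transcriptomic step enforces concordance in both compartments", {
  toy <- toy_cascade()
  groups <- define_groups(toy$dataset, "SUB", "loss")
  gs <- genomic_step(toy$dataset, groups, toy$params)
  ts <- transcriptomic_step(gs$candidates, toy$dataset, groups, toy$params)

  expect_setequal(ts$candidates$gene, c("G4", "G5", "G6"))
  expect_match(ts$trace$reason[ts$trace$gene == "G3"], "discordant")
  # Loss candidates that survive have negative effects in both compartments
  expect_true(all(ts$candidates$effect_primary < 0))
  expect_true(all(ts$candidates$effect_met < 0))

  # a concordant-primary / discordant-metastatic candidate is removed:
  # flip G5's metastatic expression
  ds2 <- toy$dataset
  stm <- groups$st_met
  ds2$expression["G5", stm] <- -ds2$expression["G5", stm]
  ts2 <- transcriptomic_step(gs$candidates, ds2, groups, toy$params)
  expect_false("G5" %in% ts2$candidates$gene)

  # candidates without enough expressing samples are removed with a reason
  ds3 <- toy$dataset
  ds3$expression["G4", stm] <- NA
  ts3 <- transcriptomic_step(gs$candidates, ds3, groups, toy$params)
  expect_match(ts3$trace$reason[ts3$trace$gene == "G4"],
               "insufficient expression")
})

test_that("the clinical step enforces the Gleason/survival concordance window", {
  toy <- toy_cascade()
  groups <- define_groups(toy$dataset, "SUB", "loss")
  gs <- genomic_step(toy$dataset, groups, toy$params)
  ts <- transcriptomic_step(gs$candidates, toy$dataset, groups, toy$params)
  cs <- clinical_step(ts$candidates, toy$dataset, groups, toy$params)

  expect_setequal(cs$candidates$gene, c("G5", "G6"))
  expect_match(cs$trace$reason[cs$trace$gene == "G4"], "WT survival")

  g5 <- cs$candidates[cs$candidates$gene == "G5", ]
  # adverse stratum = p01..p20: all Gleason 9, all early events
  expect_equal(g5$gleason_p, fisher_enum_oracle(20, 0, 0, 20, "greater"),
               tolerance = 1e-12)
  expect_equal(g5$gleason_direction, 1L)
  expect_equal(g5$st_surv_direction, 1)
  expect_lte(g5$st_logrank_p, 0.2)
  expect_gte(g5$wt_logrank_p, 0.3)
  # frozen WT logrank p for the interleaved stratification (survdiff-free
  # oracle): 0.7618
  wt_or <- logrank_oracle(c(1 + (1:19), 10 + (20:38)),
                          c(rep(TRUE, 19), rep(FALSE, 19)),
                          as.logical(1:38 %% 2))
  expect_equal(g5$wt_logrank_p, wt_or$p, tolerance = 1e-9)

  # a Loss whose LOW-expression stratum fares BETTER is removed: flip the ST
  # stratification of G5 so carriers look high-expressed
  ds2 <- toy$dataset
  stp <- groups$st_primary
  ds2$expression["G5", stp] <- -ds2$expression["G5", stp]
  cs2 <- clinical_step(ts$candidates, ds2, groups, toy$params)
  expect_false("G5" %in% cs2$candidates$gene)

  # no ST survival data -> removed with a reason
  ds3 <- toy$dataset
  ds3$clinical$pfs_time[ds3$clinical$sample_id %in% stp] <- NA
  ds3$clinical$pfs_event[ds3$clinical$sample_id %in% stp] <- NA
  cs3 <- clinical_step(ts$candidates, ds3, groups, toy$params)
  expect_true(all(grepl("no ST survival", cs3$trace$reason[
    cs3$trace$terminal_stage == "clinical"])))
})

test_that("scoring follows the normalized-rank equations exactly", {
  # direct substitution: rank 1 of 10 everywhere -> nr = 0.9, score = 0.9
  hits <- data.frame(gene = sprintf("h%02d", 1:10),
                     primary_diff_observed = seq(0.30, 0.03, length.out = 10),
                     met_diff_observed = seq(0.30, 0.03, length.out = 10),
                     st_logrank_p = seq(0.01, 0.19, length.out = 10))
  sc <- score_hits(hits)
  expect_equal(sc$score[sc$gene == "h01"], 0.9, tolerance = 1e-12)
  # ranked last everywhere -> score exactly 0
  expect_equal(sc$score[sc$gene == "h10"], 0, tolerance = 1e-12)
  # invariants for every hit: nr = 1 - rank/N, score = weighted combination
  n <- nrow(sc)
  expect_equal(sc$nr_primary, 1 - sc$rank_primary / n, tolerance = 1e-15)
  expect_equal(sc$score,
               0.3 * sc$nr_primary + 0.3 * sc$nr_met + 0.4 * sc$nr_surv,
               tolerance = 1e-15)
  expect_true(all(sc$score >= -1e-12 & sc$score <= 1 - 1 / n + 1e-12))

  # nr triple (0.5, 0.25, 0.75) -> 0.525 by Eq. substitution
  expect_equal(0.3 * 0.5 + 0.3 * 0.25 + 0.4 * 0.75, 0.525)

  # ties share the minimum rank order
  hits2 <- data.frame(gene = c("a", "b", "c"),
                      primary_diff_observed = c(0.2, 0.2, 0.1),
                      met_diff_observed = c(0.3, 0.2, 0.1),
                      st_logrank_p = c(0.01, 0.02, 0.03))
  sc2 <- score_hits(hits2)
  expect_equal(sc2$rank_primary[sc2$gene %in% c("a", "b")], c(1L, 1L))
  expect_equal(sc2$rank_primary[sc2$gene == "c"], 3L)
})

test_that("the full cascade on the engineered dataset yields exactly the two built-in hits", {
  toy <- toy_cascade()
  res <- run_prostamine(toy$dataset, "SUB", "loss", toy$params)

  expect_equal(res$hits$gene, c("G5", "G6"))
  expect_equal(res$hits$rank_primary, c(1L, 2L))
  expect_equal(res$hits$rank_met, c(1L, 2L))
  # the ST strata of G5 and G6 coincide, so the survival ranks tie at 1
  expect_equal(res$hits$rank_surv, c(1L, 1L))
  expect_equal(res$hits$score, c(0.5, 0.2), tolerance = 1e-12)

  # the filter trace covers every tested gene x direction with its terminal
  # stage; the subtype gene is excluded
  tr <- res$trace
  expect_equal(nrow(tr), 8 * 2)  # 8 non-subtype genes x 2 directions
  expect_false("SUB" %in% tr$gene)
  stage_of <- function(g) tr$terminal_stage[tr$gene == g & tr$direction == "loss"]
  expect_equal(stage_of("G1"), "genomic")
  expect_equal(stage_of("G2"), "genomic")
  expect_equal(stage_of("G3"), "transcriptomic")
  expect_equal(stage_of("G4"), "clinical")
  expect_equal(stage_of("G5"), "hit")
  expect_equal(stage_of("G6"), "hit")
  expect_true(all(tr$terminal_stage[tr$direction == "gain"] == "genomic"))

  # determinism: the same inputs give a bit-identical hit table
  res2 <- run_prostamine(toy$dataset, "SUB", "loss", toy$params)
  expect_identical(res$hits, res2$hits)
  expect_identical(res$trace, res2$trace)
})

test_that("filters are monotone: loosening never removes and tightening never adds hits", {
  toy <- toy_cascade()
  base <- run_prostamine(toy$dataset, "SUB", "loss", toy$params)

  loose <- prostamine_params(primary_diff = 0, met_diff = 0, coalt_fdr = 1,
                             dge_fdr = 1, survival_p_st = 1,
                             survival_p_wt = 0)
  all_conc <- run_prostamine(toy$dataset, "SUB", "loss", loose)
  # with every threshold disabled, hits = all direction-concordant candidates
  expect_true(all(base$hits$gene %in% all_conc$hits$gene))
  expect_setequal(all_conc$hits$gene, c("G1", "G2", "G4", "G5", "G6"))
  expect_false("G3" %in% all_conc$hits$gene)  # concordance is not a threshold

  for (tweak in list(list(primary_diff = 0.35), list(met_diff = 0.31),
                     list(coalt_fdr = 1e-4), list(survival_p_st = 1e-13),
                     list(survival_p_wt = 0.9))) {
    p <- do.call(prostamine_params,
                 utils::modifyList(unclass(toy$params), tweak))
    tighter <- run_prostamine(toy$dataset, "SUB", "loss", p)
    expect_true(all(tighter$hits$gene %in% base$hits$gene),
                info = names(tweak))
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(prostamine_params(coalt_fdr = 1.2), "\\[0, 1\\]")
  expect_error(prostamine_params(primary_diff = -0.1), "nonnegative")
  pp <- prostamine_profile()
  expect_equal(pp$primary_diff, 0.05)
  expect_equal(pp$met_diff, 0.05)
  expect_equal(pp$coalt_fdr, 0.05)
  expect_equal(pp$dge_fdr, 0.2)
  expect_equal(pp$survival_p_st, 0.05)
})
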