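test_that("consensus clustering separates two clean blocks and is deterministic", {
  # two perfectly separated alteration blocks: 20 + 20 samples
  x <- matrix(0L, 10, 40)
  x[1:5, 1:20] <- 1L
  x[6:10, 21:40] <- 1L
  colnames(x) <- sprintf("s%02d", 1:40)
  cc <- consensus_cluster(x, k_range = 2:4, n_resamples = 100, seed = 3)
  C2 <- cc$consensus[["2"]]
  expect_true(all(C2 %in% c(0, 1)))
  mem <- cc$memberships[, "2"]
  expect_equal(length(unique(mem[1:20])), 1)
  expect_equal(length(unique(mem[21:40])), 1)
  expect_true(mem[1] != mem[21])

  # consensus matrices are symmetric with unit diagonal, entries in [0, 1]
  for (C in cc$consensus) {
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), rep(1, 40))
    expect_true(all(C >= 0 & C <= 1))
  }
  expect_equal(cc$delta_area,
               c(cc$area[1], diff(cc$area)), tolerance = 1e-12)

  # same matrix, same seed -> bit-identical result
  cc2 <- consensus_cluster(x, k_range = 2:4, n_resamples = 100, seed = 3)
  expect_identical(cc, cc2)

  expect_error(consensus_cluster(x, k_range = 2:40, seed = 1), "smaller")
  expect_error(consensus_cluster(x, k_range = 2:4, n_resamples = 10), "seed")
})

test_that("a planted 4-block matrix yields chosen_k = 4 and high agreement", {
  bm <- block_matrix(n_blocks = 4, per_block = 20, seed = 17)
  cc <- consensus_cluster(bm$x, k_range = 2:6, n_resamples = 300, seed = 29)
  expect_equal(cc$chosen_k, 4)
  ari <- adjusted_rand_index(cc$memberships[, "4"], bm$truth)
  expect_gte(ari, 0.9)
  # user-fixed k always wins over the elbow
  cc2 <- consensus_cluster(bm$x, k_range = 2:6, n_resamples = 50, seed = 29,
                           fixed_k = 3)
  expect_equal(cc2$chosen_k, 3)
})

test_that("more resamples shrink the sampling variance of consensus entries", {
  bm <- block_matrix(n_blocks = 2, per_block = 15, n_features = 10,
                     in_rate = 0.7, out_rate = 0.2, seed = 4)
  entries <- function(n_res, seed) {
    C <- consensus_cluster(bm$x, k_range = 2, n_resamples = n_res,
                           seed = seed)$consensus[["2"]]
    C[upper.tri(C)]
  }
  # per-pair standard deviation of the consensus estimate across independent
  # replicate runs of the same generator
  reps_small <- sapply(1:6, function(s) entries(100, s))
  reps_large <- sapply(1:6, function(s) entries(1000, 100 + s))
  sd_small <- mean(apply(reps_small, 1, sd))
  sd_large <- mean(apply(reps_large, 1, sd))
  expect_lt(sd_large, sd_small)
})

test_that("adjusted Rand index matches mclust and behaves at the extremes", {
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(6)
  for (i in 1:20) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("mutual exclusivity tables match per-sample tallies and the Fisher oracle", {
  set.seed(12)
  alt <- random_alterations(8, 40, seed = 12)
  res <- mutual_exclusivity(alt, alt$genes)
  expect_equal(nrow(res), choose(8, 2))
  any_alt <- alt$loss | alt$gain
  for (i in seq_len(nrow(res))) {
    va <- any_alt[res$gene_a[i], ]; vb <- any_alt[res$gene_b[i], ]
    expect_equal(res$n_both[i], sum(va & vb))
    expect_equal(res$n_a_only[i], sum(va & !vb))
    expect_equal(res$n_b_only[i], sum(!va & vb))
    expect_equal(res$n_neither[i], sum(!va & !vb))
    expect_equal(res$p_value[i],
                 fisher_enum_oracle(res$n_both[i], res$n_a_only[i],
                                    res$n_b_only[i], res$n_neither[i]),
                 tolerance = 1e-9)
  }
  expect_equal(res$fdr, bh_oracle(res$p_value), tolerance = 1e-12)

  # symmetry: swapping the pair order changes nothing but the labels
  r_ab <- res[res$gene_a == "g01" & res$gene_b == "g02", ]
  res2 <- mutual_exclusivity(alt, c("g02", "g01"))
  expect_equal(res2$p_value, r_ab$p_value)
  expect_equal(res2$n_both, r_ab$n_both)

  # perfect overlap is co-occurring; disjoint halves are exclusive
  cna <- matrix(0L, 2, 20, dimnames = list(c("a", "b"), paste0("s", 1:20)))
  cna["a", 1:10] <- -1L; cna["b", 1:10] <- -1L
  r_co <- mutual_exclusivity(derive_alteration_calls(cna), c("a", "b"))
  expect_equal(r_co$direction, "co_occurrence")
  cna["b", ] <- 0L; cna["b", 11:20] <- -1L
  r_ex <- mutual_exclusivity(derive_alteration_calls(cna), c("a", "b"))
  expect_equal(r_ex$direction, "exclusivity")

  expect_error(mutual_exclusivity(alt, "g01"), "at least two")
  expect_error(mutual_exclusivity(alt, c("g01", "nope")), "absent")
})

test_that("subgroup clinical associations recover planted enrichment and are null on exchangeable data", {
  # identical clinical distributions across subgroups -> all p = 1-ish nulls
  cl <- data.frame(sample_id = sprintf("s%02d", 1:40), cohort = "c",
                   sample_type = "primary",
                   gleason = rep(c(7L, 9L), 20),
                   t_stage = rep(c("T1c", "T3a"), 20),
                   n_stage = "N0",
                   pfs_time = rep(c(5, 10, 20, 40), 10),
                   pfs_event = rep(c(TRUE, FALSE), 20),
                   stringsAsFactors = FALSE)
  mem <- setNames(rep(c("A", "B"), each = 20), cl$sample_id)
  # group B mirrors group A exactly (same clinical vectors)
  cl_m <- cl; cl_m[21:40, -1] <- cl[1:20, -1]
  res <- subgroup_clinical_association(mem, cl_m, reference_group = "A")
  expect_true(all(res$gleason_high_p > 0.5))
  expect_equal(res$logrank_p_vs_reference[res$subgroup == "B"], 1,
               tolerance = 1e-9)
  expect_equal(res$hazard_ratio_vs_reference[res$subgroup == "B"], 1,
               tolerance = 1e-6)
  # reference vs itself: p = 1, HR = 1 by definition
  expect_equal(res$logrank_p_vs_reference[res$subgroup == "A"], 1)
  expect_equal(res$hazard_ratio_vs_reference[res$subgroup == "A"], 1)

  # a subgroup holding every high-Gleason tumor: enrichment p equals the
  # hypergeometric oracle
  cl2 <- cl
  cl2$gleason <- rep(c(9L, 7L), each = 20)
  res2 <- subgroup_clinical_association(mem, cl2, reference_group = "B")
  expect_equal(res2$gleason_direction[res2$subgroup == "A"], 1L)
  expect_equal(res2$gleason_high_p[res2$subgroup == "A"],
               fisher_enum_oracle(20, 0, 0, 20, "greater"), tolerance = 1e-12)

  # planted hazard ratio ~3 recovered within 15% at n = 1000
  set.seed(33)
  n <- 1000
  g <- rep(c("risk", "ref"), each = n / 2)
  tt <- rexp(n, rate = 0.02 * ifelse(g == "risk", 3, 1))
  cens <- runif(n, 0, 120)
  cl3 <- data.frame(sample_id = sprintf("q%04d", 1:n), cohort = "c",
                    sample_type = "primary", gleason = 7L, t_stage = "T2a",
                    n_stage = "N0", pfs_time = pmin(tt, cens),
                    pfs_event = tt <= cens, stringsAsFactors = FALSE)
  mem3 <- setNames(g, cl3$sample_id)
  res3 <- subgroup_clinical_association(mem3, cl3, reference_group = "ref")
  expect_equal(res3$hazard_ratio_vs_reference[res3$subgroup == "risk"], 3,
               tolerance = 0.15)
})
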