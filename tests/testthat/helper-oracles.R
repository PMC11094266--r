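# Independent oracles used to freeze expected values. These deliberately use
# different computational routes than the package (explicit enumeration, the
# direct BH formula, hand-tabulated risk sets, exhaustive window scans).

# Fisher's exact test by full enumeration over all tables with fixed margins,
# probabilities from choose() only.
fisher_enum_oracle <- function(a, b, c, d,
                               alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  obs <- prob[xs == a]
  p <- if (alternative == "greater") sum(prob[xs >= a])
       else sum(prob[prob <= obs * (1 + 1e-7)])
  min(1, p)
}

# Benjamini-Hochberg by the direct min-over-tail formula.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  names(out) <- names(p)
  out
}

# Logrank chi-square by hand tabulation of risk sets at each event time.
logrank_oracle <- function(time, event, in_a) {
  o_a <- 0; e_a <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & in_a)
    d <- sum(event & time == t)
    d_a <- sum(event & time == t & in_a)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       direction = sign(o_a - e_a))
}

# Exhaustive all-windows hotspot scan: every window of >= min_genes
# consecutive above-threshold genes, merged to maximal runs.
hotspot_bruteforce <- function(freqs, annotation, cutoff, min_genes) {
  out <- list()
  for (dir in unique(freqs$direction)) {
    f <- freqs[freqs$direction == dir, ]
    fr <- setNames(f$frequency, f$gene)
    for (chr in unique(annotation$chrom)) {
      ann <- annotation[annotation$chrom == chr, ]
      ann <- ann[order(ann$start), ]
      ann <- ann[ann$gene %in% names(fr), ]
      if (!nrow(ann)) next
      above <- fr[ann$gene] >= cutoff
      i <- 1
      while (i <= nrow(ann)) {
        if (above[i]) {
          j <- i
          while (j < nrow(ann) && above[j + 1]) j <- j + 1
          if (j - i + 1 >= min_genes) {
            members <- ann$gene[i:j]
            mf <- fr[members]
            out[[length(out) + 1]] <- data.frame(
              chrom = chr, direction = dir,
              start_gene = members[1], end_gene = members[length(members)],
              n_genes = length(members),
              peak_gene = members[which.max(mf)],
              peak_frequency = max(mf), stringsAsFactors = FALSE)
          }
          i <- j + 1
        } else i <- i + 1
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$direction, res$chrom, res$start_gene), ]
}

# random small alteration fixture used across tests
random_alterations <- function(n_genes, n_samples, p_loss = 0.2, p_gain = 0.2,
                               seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  u <- matrix(runif(n_genes * n_samples), n_genes, n_samples)
  cna <- matrix(0L, n_genes, n_samples, dimnames = list(genes, samples))
  cna[u < p_loss] <- -1L
  cna[u > 1 - p_gain] <- 1L
  derive_alteration_calls(cna)
}
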