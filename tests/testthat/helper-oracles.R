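# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive enumeration / explicit loops
# and share no code with the functions they check.

# Exact clonal-detection power for a point-mass coverage distribution,
# enumerating tumor-read and mutation-read outcomes explicitly:
# T ~ Binomial(depth, purity), M | T ~ Binomial(T, 1/2),
# detected iff the log10 odds score of (M, depth) reaches the threshold.
oracle_exact_power <- function(depth, purity, error_rate = 0.001,
                               lod_threshold = 6.3) {
  detect <- vapply(0:depth, function(m) {
    oracle_lod(m, depth, error_rate) >= lod_threshold
  }, logical(1))
  p <- 0
  for (t in 0:depth) {
    pt <- dbinom(t, depth, purity)
    if (pt == 0) next
    for (m in 0:t) {
      if (detect[m + 1]) p <- p + pt * dbinom(m, t, 0.5)
    }
  }
  min(max(p, 0), 1)   # guard accumulated floating-point drift
}

# Direct evaluation of the log10 likelihood ratio at f = m / depth.
oracle_lod <- function(m, depth, e) {
  f <- m / depth
  lmut <- m * log10(f * (1 - e) + (1 - f) * e / 3) +
    (depth - m) * log10(f * e / 3 + (1 - f) * (1 - e))
  lnull <- m * log10(e / 3) + (depth - m) * log10(1 - e)
  lmut - lnull
}

# Position-by-position running-sum GSEA enrichment score: walk the full
# ranked list accumulating hit / miss steps and keep the extreme deviation.
oracle_gsea_es <- function(ranked_stats, gene_set, weight_p) {
  n <- length(ranked_stats)
  hit <- names(ranked_stats) %in% gene_set
  k <- sum(hit)
  w <- abs(ranked_stats)^weight_p
  nr <- sum(w[hit])
  if (nr == 0) {
    w[hit] <- 1
    nr <- k
  }
  running <- 0
  max_r <- -Inf
  min_r <- Inf
  for (i in seq_len(n)) {
    if (hit[i]) running <- running + w[i] / nr
    else running <- running - 1 / (n - k)
    if (running > max_r) max_r <- running
    if (running < min_r) min_r <- running
  }
  unname(if (max_r - abs(min_r) > 1e-10) max_r else min_r)
}

# Direct single-sample enrichment score for one expression column.
oracle_ssgsea_one <- function(x, in_set, weight_exponent) {
  n <- length(x)
  r <- rank(x, ties.method = "average") / n
  ord <- order(-rank(x, ties.method = "average"), names(x))
  hit <- in_set[ord]
  z <- r[ord]
  k <- sum(hit)
  total <- 0
  cin <- 0
  cout <- 0
  wsum <- sum(z[hit]^weight_exponent)
  for (i in seq_len(n)) {
    if (hit[i]) cin <- cin + z[i]^weight_exponent / wsum
    else cout <- cout + 1 / (n - k)
    total <- total + (cin - cout)
  }
  unname(total)
}

# Exhaustive pairwise-comparison AUC (ties count one half).
oracle_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by full hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose probability
# does not exceed the observed table's (with the customary relative-error
# guard for floating-point ties).
oracle_fisher_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Log-rank test computed from first principles: at each event time the
# observed minus expected events in group 1 with the hypergeometric
# variance, chi-square on 1 df.
oracle_logrank_p <- function(times, events, group) {
  group <- as.integer(factor(group))
  stopifnot(length(unique(group)) == 2)
  event_times <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in event_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  pchisq(o_minus_e^2 / v, df = 1, lower.tail = FALSE)
}

# Shared tiny-bundle builder for I/O and feature tests.
make_toy_bundle <- function() {
  clinical <- data.frame(
    patient_id = c("A", "B", "C"),
    best_response = c("CR", "PD", "SD"),
    prior_ipilimumab = c(1L, 0L, 1L),
    biopsy_post_ipilimumab = c(1L, 0L, 0L),
    ldh_u_per_l = c(200, NA, 410),
    lymph_node_met = c(1L, 1L, 0L),
    melanoma_subtype = c("cutaneous", "acral", "occult"),
    os_months = c(24.5, 3.2, 11), os_event = c(0L, 1L, 1L),
    pfs_months = c(20.1, 1.2, 6), pfs_event = c(0L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  mutations <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C"),
    gene = c("G1", "G2", "G3", "G1", "G4", "G5"),
    effect = c("nonsynonymous", "synonymous", "nonsynonymous",
               "nonsynonymous", "nonsynonymous", "synonymous"),
    ccf = c(0.95, 0.85, 0.4, 0.8, NA, 0.2),
    alt_count = c(10L, 5L, 3L, 20L, 7L, 2L),
    depth = c(40L, 30L, 25L, 60L, 31L, 18L),
    stringsAsFactors = FALSE
  )
  segments <- data.frame(
    patient_id = c("A", "A", "A", "B", "C"),
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr1"),
    start = c(1, 11, 1, 1, 1),
    end = c(10, 40, 60, 100, 50),
    allelic_status = c("amp", "neutral", "del", "neutral", "loh"),
    stringsAsFactors = FALSE
  )
  genomics <- data.frame(
    patient_id = c("A", "B", "C"),
    purity = c(0.7, 0.5, 0.9),
    ploidy = c(2.1, 3.6, 2.0),
    coverage_histogram = c("50:10;60:5", "80:3", "40:7;45:2"),
    nonsyn_count = c(2L, 2L, 0L),
    callable_bases = c(3e7, 2.8e7, 3.1e7),
    stringsAsFactors = FALSE
  )
  expr <- matrix(c(5, 1, 0, 2, 7, 3, 9, 4, 8, 0, 2, 6), nrow = 4,
                 dimnames = list(c("g1", "g2", "g3", "g4"),
                                 c("A", "B", "C")))
  biotype <- c(g1 = "protein_coding", g2 = "snoRNA",
               g3 = "protein_coding", g4 = "protein_coding")
  cohort_bundle(clinical, mutations, segments, genomics, expr, biotype)
}
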