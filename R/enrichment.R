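#' Renormalize a TPM matrix after biotype exclusion
#'
#' Removes genes of the excluded biotypes (snoRNAs by default, which can
#' dominate the transcriptome sum in degraded FFPE libraries) and rescales
#' every sample column so the transcriptome sum is again 1e6.
#'
#' @param expr Numeric TPM matrix, genes x samples.
#' @param biotype Character vector of biotypes named by gene symbol.
#' @param excluded_biotypes Biotypes to drop (default `"snoRNA"`).
#' @return The filtered, renormalized matrix.
#' @export
renormalize_tpm <- function(expr, biotype,
                            excluded_biotypes = c("snoRNA")) {
  if (is.null(names(biotype))) {
    stop("biotype must be named by gene symbol", call. = FALSE)
  }
  keep <- !(biotype[rownames(expr)] %in% excluded_biotypes)
  keep[is.na(keep)] <- TRUE
  out <- expr[keep, , drop = FALSE]
  sums <- colSums(out)
  zero <- sums <= 0
  if (any(zero)) {
    stop("sample(s) with zero total expression after exclusion: ",
         paste(colnames(out)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(out, 2, sums, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Keeps genes with TPM > 0 in at least `min_nonzero_fraction` of samples
#' (default 25%, inclusive).
#'
#' @param expr Numeric matrix, genes x samples.
#' @param min_nonzero_fraction Minimum fraction of samples with nonzero
#'   expression.
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(expr, min_nonzero_fraction = 0.25) {
  if (ncol(expr) < 1) stop("expression matrix has no samples", call. = FALSE)
  keep <- rowMeans(expr > 0) >= min_nonzero_fraction
  expr[keep, , drop = FALSE]
}

#' Convert FPKM to TPM
#'
#' Per sample, `tpm_g = fpkm_g / sum_g(fpkm_g) * 1e6`. The result is
#' invariant to any positive rescaling of a sample's FPKM values.
#'
#' @param fpkm Numeric matrix of non-negative FPKM values, genes x samples.
#' @return TPM matrix of the same shape.
#' @export
fpkm_to_tpm <- function(fpkm) {
  if (any(fpkm < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  sums <- colSums(fpkm)
  zero <- sums <= 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(if (!is.null(colnames(fpkm))) colnames(fpkm)[zero]
               else which(zero), collapse = ", "), call. = FALSE)
  }
  sweep(fpkm, 2, sums, "/") * 1e6
}

# Signed-maximum-deviation enrichment statistic for hits at (sorted, 1-based)
# positions `pos` of an N-long ranked list, with unnormalized hit weights
# `w`. Misses step down by 1/(N - k). The running sum's extreme deviation is
# attained at a hit position (maximum) or immediately before one (minimum).
.es_running_sum_extreme <- function(pos, w, n_genes) {
  k <- length(pos)
  if (k >= n_genes) {
    stop("gene set must be smaller than the ranked list", call. = FALSE)
  }
  total <- sum(w)
  if (total <= 0) {
    w <- rep(1, k)
    total <- k
  }
  cumw <- cumsum(w) / total
  miss_step <- 1 / (n_genes - k)
  miss_before <- (pos - seq_len(k)) * miss_step
  at_hit <- cumw - miss_before
  before_hit <- c(0, cumw[-k]) - miss_before
  max_dev <- max(at_hit)
  min_dev <- min(before_hit)
  # reference convention: on a magnitude tie (to numerical tolerance) the
  # negative extreme wins
  if (max_dev - abs(min_dev) > 1e-10) max_dev else min_dev
}

#' GSEA enrichment score
#'
#' The weighted running-sum (Kolmogorov-Smirnov-like) enrichment statistic:
#' walking down the ranked gene list, in-set genes increment the sum by
#' `|stat|^weight_p` (normalized over the set) and out-of-set genes
#' decrement it by `1/(N - k)`; the ES is the signed maximum deviation from
#' zero. `weight_p = 0` gives the classic unweighted statistic; `weight_p =
#' 1` is the standard weighted form.
#'
#' @param ranked_stats Named numeric vector of per-gene association scores,
#'   already ordered from most positively to most negatively associated.
#'   The given order defines the ranking (ties are the caller's
#'   responsibility; [gsea_cohort()] orders deterministically).
#' @param gene_set Character vector of member gene symbols.
#' @param weight_p Weighting exponent on `|stat|`.
#' @return The enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(ranked_stats, gene_set, weight_p = 1) {
  if (is.null(names(ranked_stats))) {
    stop("ranked_stats must be named by gene", call. = FALSE)
  }
  n <- length(ranked_stats)
  pos <- which(names(ranked_stats) %in% gene_set)
  if (length(pos) == 0) {
    stop("no gene-set member present in the ranked list", call. = FALSE)
  }
  if (length(gene_set) > n) {
    stop("gene set larger than the ranked list", call. = FALSE)
  }
  w <- abs(ranked_stats[pos])^weight_p
  .es_running_sum_extreme(pos, w, n)
}

#' Single-sample GSEA projection
#'
#' Rank-normalized per-sample enrichment scores. For each sample, genes are
#' ranked by expression (average ranks for ties, deterministic gene-name
#' tiebreak for the ordering), ranks are normalized to (0, 1], and the
#' score is the sum over all list positions of the difference between the
#' weighted in-set empirical distribution (weights `rank^weight_exponent`)
#' and the unweighted out-of-set one. The score depends on the expression
#' values only through their ranks, so it is invariant under strictly
#' monotone transforms of a sample's profile.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param gene_set Character vector of member gene symbols; members absent
#'   from the matrix are dropped with a warning.
#' @param weight_exponent Weighting exponent on the normalized rank
#'   (default 0.25, the published single-sample default; 0 gives the
#'   unweighted running sum).
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea <- function(expr, gene_set, weight_exponent = 0.25) {
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) {
    stop("no gene-set member present in the expression matrix",
         call. = FALSE)
  }
  if (length(present) < length(gene_set)) {
    warning(length(gene_set) - length(present),
            " gene-set member(s) absent from the matrix dropped",
            call. = FALSE)
  }
  if (length(present) >= nrow(expr)) {
    stop("gene set must be smaller than the gene universe", call. = FALSE)
  }
  n <- nrow(expr)
  in_set <- rownames(expr) %in% present
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    z <- r / n
    # descending expression order; gene name breaks ties deterministically
    ord <- order(-r, rownames(expr))
    hit <- in_set[ord]
    w <- ifelse(hit, z[ord]^weight_exponent, 0)
    cdf_in <- cumsum(w) / sum(w)
    cdf_out <- cumsum(!hit) / (n - length(present))
    sum(cdf_in - cdf_out)
  }, numeric(1))
  stats::setNames(scores, colnames(expr))
}

# Signal-to-noise ratio per gene: (mean2 - mean1) / (sd2 + sd1) for the two
# levels of `labels`; positive values mean higher expression in level 2.
# Genes with zero pooled spread get statistic 0.
.signal_to_noise <- function(expr, labels) {
  labels <- droplevels(factor(labels))
  stopifnot(nlevels(labels) == 2)
  g1 <- labels == levels(labels)[1]
  g2 <- labels == levels(labels)[2]
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  s1 <- apply(expr[, g1, drop = FALSE], 1, stats::sd)
  s2 <- apply(expr[, g2, drop = FALSE], 1, stats::sd)
  denom <- s1 + s2
  stat <- ifelse(denom > 0, (m2 - m1) / denom, 0)
  stats::setNames(stat, rownames(expr))
}

#' Cohort-level GSEA with a gene-set permutation null
#'
#' Ranks genes by the signal-to-noise ratio between the two phenotype
#' groups (difference of group means over the sum of group standard
#' deviations; positive = higher in the second factor level), computes the
#' weighted enrichment score of each gene set, and builds the null from
#' random gene sets of matching size drawn from the ranked list (gene-set
#' permutation). NES is the ES divided by the mean absolute null ES of
#' matching sign; nominal p is the same-sign null tail fraction; FDR q
#' follows the standard pooled-NES procedure.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param group_labels Two-level factor (or coercible) over samples, each
#'   level with at least 3 samples.
#' @param gene_sets Named list of gene symbol vectors.
#' @param n_perm Number of random gene sets per set size (default 10000).
#' @param seed Integer seed for the permutation draws.
#' @param weight_p ES weighting exponent (default 1).
#' @return Data frame with one row per gene set: `gene_set`, `size`, `es`,
#'   `nes`, `nominal_p`, `fdr_q`.
#' @export
gsea_cohort <- function(expr, group_labels, gene_sets, n_perm = 10000,
                        seed = 1, weight_p = 1) {
  labels <- droplevels(factor(group_labels))
  if (nlevels(labels) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) < 3)) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  stat <- .signal_to_noise(expr, labels)
  ord <- order(-stat, names(stat))
  ranked <- stat[ord]
  n <- length(ranked)
  absw <- abs(ranked)^weight_p

  set.seed(seed)
  sizes <- vapply(gene_sets, function(gs) {
    length(intersect(gs, names(ranked)))
  }, integer(1))
  if (any(sizes == 0)) {
    stop("gene set(s) with no member in the matrix: ",
         paste(names(gene_sets)[sizes == 0], collapse = ", "),
         call. = FALSE)
  }

  # one null ES panel per distinct set size (the gene-set permutation null
  # depends only on k)
  null_by_size <- list()
  for (k in sort(unique(sizes))) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(b) {
      pos <- sort.int(sample.int(n, k))
      .es_running_sum_extreme(pos, absw[pos], n)
    }, numeric(1))
  }

  norm_es <- function(es, null) {
    pos_mean <- mean(null[null > 0])
    neg_mean <- mean(abs(null[null < 0]))
    if (es >= 0) {
      if (!is.finite(pos_mean)) NA_real_ else es / pos_mean
    } else {
      if (!is.finite(neg_mean)) NA_real_ else es / neg_mean
    }
  }

  res <- lapply(names(gene_sets), function(nm) {
    k <- sizes[[nm]]
    es <- gsea_es(ranked, gene_sets[[nm]], weight_p)
    null <- null_by_size[[as.character(k)]]
    if (es >= 0) {
      same <- null[null >= 0]
      p <- if (length(same) == 0) 1 else mean(same >= es)
    } else {
      same <- null[null < 0]
      p <- if (length(same) == 0) 1 else mean(same <= es)
    }
    data.frame(gene_set = nm, size = k, es = es,
               nes = norm_es(es, null), nominal_p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  # pooled-NES FDR
  null_nes <- unlist(lapply(names(null_by_size), function(kk) {
    null <- null_by_size[[kk]]
    pos_mean <- mean(null[null > 0])
    neg_mean <- mean(abs(null[null < 0]))
    ifelse(null >= 0, null / pos_mean, null / neg_mean)
  }), use.names = FALSE)
  null_nes <- null_nes[is.finite(null_nes)]
  obs_nes <- res$nes
  res$fdr_q <- vapply(obs_nes, function(nes) {
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes)
      den <- mean(obs_nes[is.finite(obs_nes) & obs_nes >= 0] >= nes)
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes)
      den <- mean(obs_nes[is.finite(obs_nes) & obs_nes < 0] <= nes)
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))
  res
}

#' Per-gene rank-sum comparison between two groups
#'
#' For every gene, the two-sided Mann-Whitney-Wilcoxon p-value and the
#' difference of group medians (second factor level minus first; with a
#' `progressor`/`responder` contrast this is responder minus progressor).
#' Genes constant across all samples get p = 1 by convention.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param group_labels Two-level factor over samples.
#' @return Data frame with `gene`, `median_diff`, `p`.
#' @export
gene_wise_mww <- function(expr, group_labels) {
  labels <- droplevels(factor(group_labels))
  if (nlevels(labels) != 2) stop("exactly two groups required", call. = FALSE)
  g1 <- labels == levels(labels)[1]
  g2 <- labels == levels(labels)[2]
  if (!any(g1) || !any(g2)) stop("both groups must be nonempty",
                                 call. = FALSE)
  out <- lapply(seq_len(nrow(expr)), function(i) {
    x1 <- expr[i, g1]
    x2 <- expr[i, g2]
    p <- if (stats::sd(c(x1, x2)) == 0) 1 else {
      suppressWarnings(stats::wilcox.test(x2, x1, exact = FALSE)$p.value)
    }
    data.frame(gene = rownames(expr)[i],
               median_diff = stats::median(x2) - stats::median(x1),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Collective directional binomial test for a gene family
#'
#' Tests whether the per-gene median differences of a gene family share a
#' direction more often than chance: a two-sided exact binomial test of the
#' count of positive differences against success probability 1/2, after
#' dropping exact zeros. With all 13 MHC-II genes higher in responders this
#' gives p = 2 * 0.5^13 = 0.000244.
#'
#' @param median_diffs Numeric vector of per-gene median differences.
#' @return Two-sided binomial p-value.
#' @export
directional_binomial_test <- function(median_diffs) {
  d <- median_diffs[!is.na(median_diffs) & median_diffs != 0]
  if (length(d) == 0) {
    stop("all median differences are zero or missing; test undefined",
         call. = FALSE)
  }
  stats::binom.test(sum(d > 0), length(d), p = 0.5)$p.value
}
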