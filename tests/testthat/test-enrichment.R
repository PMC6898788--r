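test_that("snoRNA exclusion renormalizes every sample to one million", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:10)
  expr <- matrix(rlnorm(10 * 4, 3, 1), 10, 4,
                 dimnames = list(genes, paste0("s", 1:4)))
  biotype <- setNames(rep("protein_coding", 10), genes)
  biotype[c("g02", "g07")] <- "snoRNA"
  out <- renormalize_tpm(expr, biotype)
  expect_equal(nrow(out), 8)
  expect_false(any(c("g02", "g07") %in% rownames(out)))
  expect_equal(unname(colSums(out)), rep(1e6, 4), tolerance = 1e-9)
  # no excluded biotype present: values change only by the closure rescale
  bio2 <- setNames(rep("protein_coding", 10), genes)
  out2 <- renormalize_tpm(expr, bio2)
  expect_equal(out2, sweep(expr, 2, colSums(expr), "/") * 1e6)
  # an annotation marking many genes removes exactly that many rows
  bio3 <- setNames(rep("snoRNA", 10), genes)
  bio3[1:3] <- "protein_coding"
  expect_equal(nrow(renormalize_tpm(expr, bio3)), 3)
})

test_that("low-expression filter keeps genes nonzero in >= 25% of samples", {
  expr <- rbind(
    quarter = c(5, 0, 0, 0),       # 1 of 4 = exactly 25%: kept
    none = c(0, 0, 0, 0),          # dropped
    all = c(1, 2, 3, 4)
  )
  colnames(expr) <- paste0("s", 1:4)
  out <- filter_low_expression(expr)
  expect_setequal(rownames(out), c("quarter", "all"))
  # 1 of 5 = 20%: dropped
  expr5 <- cbind(expr, s5 = c(0, 0, 5))
  expect_false("quarter" %in% rownames(filter_low_expression(expr5)))
})

test_that("FPKM to TPM conversion is a per-sample closure", {
  f <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(fpkm_to_tpm(f)[, 1]), c(250000, 750000))
  one <- matrix(7, 1, 1, dimnames = list("a", "s1"))
  expect_equal(fpkm_to_tpm(one)[1, 1], 1e6)
  # invariant to positive per-sample rescaling
  set.seed(4)
  f2 <- matrix(rlnorm(20), 5, 4)
  expect_equal(fpkm_to_tpm(sweep(f2, 2, c(2, 0.5, 10, 1), "*")),
               fpkm_to_tpm(f2))
  f2[, 2] <- 0
  expect_error(fpkm_to_tpm(f2), "all-zero")
})

test_that("enrichment scores match exhaustive running-sum oracles", {
  set.seed(10)
  for (n in 3:8) {
    genes <- paste0("g", seq_len(n))
    stats_vec <- setNames(sort(rnorm(n), decreasing = TRUE), genes)
    # every non-empty proper subset of the list
    for (mask in 1:(2^n - 2)) {
      members <- genes[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
      if (length(members) == 0 || length(members) == n) next
      for (p in c(0, 1)) {
        expect_equal(gsea_es(stats_vec, members, weight_p = p),
                     oracle_gsea_es(stats_vec, members, p),
                     tolerance = 1e-12,
                     label = sprintf("n=%d mask=%d p=%d", n, mask, p))
      }
    }
  }
})

test_that("enrichment score extremes behave as the statistic dictates", {
  genes <- paste0("g", 1:10)
  stats_vec <- setNames(seq(5, -4), genes)
  # set packed at the top of the list: maximum deviation 1 at position k
  expect_equal(gsea_es(stats_vec, genes[1:3], weight_p = 0), 1.0)
  # uniform interleaving of half the genes stays within 2/N
  n <- 20
  alt <- setNames(seq(n, 1), paste0("g", 1:n))
  expect_lte(abs(gsea_es(alt, paste0("g", seq(1, n, by = 2)),
                         weight_p = 0)), 2 / n)
  expect_error(gsea_es(stats_vec, paste0("x", 1:20)), "no gene-set member")
})

test_that("ssGSEA equals its direct per-position oracle", {
  set.seed(12)
  for (rep_i in 1:3) {
    n <- 6 + rep_i
    genes <- paste0("g", seq_len(n))
    expr <- matrix(rlnorm(n * 3, 2, 1), n, 3,
                   dimnames = list(genes, c("s1", "s2", "s3")))
    members <- sample(genes, 3)
    for (expo in c(0, 0.25)) {
      got <- ssgsea(expr, members, weight_exponent = expo)
      for (j in 1:3) {
        x <- setNames(expr[, j], genes)
        expect_equal(unname(got[j]),
                     oracle_ssgsea_one(x, genes %in% members, expo),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("ssGSEA is rank-based and orders planted sets correctly", {
  set.seed(13)
  genes <- paste0("g", 1:40)
  expr <- matrix(rlnorm(40 * 6, 3, 1), 40, 6,
                 dimnames = list(genes, paste0("s", 1:6)))
  s <- ssgsea(expr, genes[1:5])
  # invariance under strictly monotone transforms of each sample
  expect_equal(ssgsea(log1p(expr), genes[1:5]), s, tolerance = 1e-12)
  expect_equal(ssgsea(expr^3, genes[1:5]), s, tolerance = 1e-12)
  # the top-ranked singleton scores above the bottom-ranked singleton
  x <- matrix(sort(rlnorm(12), decreasing = TRUE), 12, 1,
              dimnames = list(paste0("g", 1:12), "s1"))
  expect_gt(ssgsea(x, "g1")[1], ssgsea(x, "g12")[1])
  expect_warning(ssgsea(expr, c(genes[1:3], "absent")), "absent")
  expect_error(ssgsea(expr, "nope"), "no gene-set member")
})

test_that("cohort GSEA recovers a planted set and guards degeneracy", {
  set.seed(14)
  genes <- sprintf("g%03d", 1:200)
  expr <- matrix(rlnorm(200 * 24, 3, 1), 200, 24,
                 dimnames = list(genes, paste0("s", 1:24)))
  labels <- factor(rep(c("progressor", "responder"), each = 12),
                   levels = c("progressor", "responder"))
  sets <- list(planted = genes[1:15], noise1 = genes[101:115],
               noise2 = genes[121:135])
  expr[sets$planted, labels == "responder"] <-
    expr[sets$planted, labels == "responder"] * 3
  res <- gsea_cohort(expr, labels, sets, n_perm = 1000, seed = 1)
  planted_row <- res[res$gene_set == "planted", ]
  expect_gt(planted_row$nes, 0)
  expect_lt(planted_row$nominal_p, 0.01)
  expect_lt(planted_row$fdr_q,
            min(res$fdr_q[res$gene_set != "planted"]) + 1e-12)
  # identical expression in both groups: all statistics zero, ES defined
  flat <- matrix(rep(rlnorm(50), 10), 50, 10,
                 dimnames = list(paste0("f", 1:50), paste0("s", 1:10)))
  res_flat <- gsea_cohort(flat, rep(c("a", "b"), each = 5),
                          list(s = paste0("f", 1:5)), n_perm = 50,
                          seed = 2)
  expect_true(is.finite(res_flat$es))
  expect_error(gsea_cohort(expr, rep("a", 24), sets, 10, 1), "two groups")
  expect_error(gsea_cohort(expr[, 11:15], labels[11:15], sets, 10, 1),
               "at least 3")
})

test_that("per-gene rank-sum tests detect shifts with the right sign", {
  set.seed(15)
  n <- 20
  expr <- matrix(rnorm(3 * 2 * n), 3, 2 * n,
                 dimnames = list(c("null", "up", "const"),
                                 paste0("s", 1:(2 * n))))
  labels <- factor(rep(c("progressor", "responder"), each = n),
                   levels = c("progressor", "responder"))
  expr["up", labels == "responder"] <-
    expr["up", labels == "responder"] + 10
  expr["const", ] <- 1
  res <- gene_wise_mww(expr, labels)
  expect_lt(res$p[res$gene == "up"], 1e-4)
  expect_gt(res$median_diff[res$gene == "up"], 0)
  expect_equal(res$p[res$gene == "const"], 1)
  expect_gt(res$p[res$gene == "null"], 0.01)
})

test_that("directional binomial test matches closed forms", {
  expect_equal(directional_binomial_test(rep(1, 13)), 2 * 0.5^13)
  expect_equal(round(directional_binomial_test(rep(1, 13)), 4), 2e-04)
  expect_equal(directional_binomial_test(rep(1, 8)), 2 * 0.5^8)
  expect_equal(directional_binomial_test(c(rep(1, 6), rep(-1, 6))), 1)
  # zeros are dropped before testing
  expect_equal(directional_binomial_test(c(rep(1, 8), 0, 0)), 2 * 0.5^8)
  expect_error(directional_binomial_test(c(0, 0)), "undefined")
})

test_that("preprocessing commutes with sample reordering", {
  b <- simulate_cohort(default_sim_config(n_patients = 10, n_genes = 300),
                       seed = 6)
  expr <- b$expression
  perm <- sample(ncol(expr))
  a <- filter_low_expression(renormalize_tpm(expr, b$biotype))
  z <- filter_low_expression(renormalize_tpm(expr[, perm], b$biotype))
  expect_equal(z, a[, perm])
})
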