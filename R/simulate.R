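#' Default simulation configuration
#'
#' Returns the configuration of the synthetic melanoma anti-PD1 cohort
#' generator. Defaults reproduce, in expectation, the marginal structure of
#' the study cohort the pipeline was designed around: 41.7% of patients with
#' previous ipilimumab exposure; melanoma subtype frequencies 0.729 / 0.132 /
#' 0.069 / 0.069 (cutaneous / occult / acral / mucosal); subtype-dependent
#' nonsynonymous mutation burden (lognormal, median 297.5 for
#' cutaneous/occult vs 58 for acral/mucosal); tumor purity Beta(2.2, 1.2)
#' (median 0.68, IQR approx. 0.48-0.84); ploidy a diploid/genome-doubled
#' mixture with 38% doubled (overall median approx. 2.15); heterogeneity
#' (subclonal mutation fraction) Beta(4, 18) (median approx. 0.17); LDH
#' lognormal with median 247 U/l and a positive shift in progressors; and
#' response-linked exponential survival. The MHC-II expression effect (a
#' log2 shift applied to the 13 MHC-II HLA genes) is confined to
#' ipilimumab-experienced responders.
#'
#' @param n_patients Number of patients (default 144).
#' @param n_genes Number of genes in the simulated expression matrix.
#' @param mhc2_effect_size Log2 TPM shift applied to MHC-II genes in
#'   ipilimumab-experienced responders (free parameter; default 1).
#' @param ... Override any other configuration element by name.
#' @return An object of class `sim_config` (a validated list).
#' @export
default_sim_config <- function(n_patients = 144, n_genes = 5000,
                               mhc2_effect_size = 1, ...) {
  cfg <- list(
    n_patients = n_patients,
    subtype_probs = c(cutaneous = 0.729, occult = 0.132,
                      acral = 0.069, mucosal = 0.07),
    prior_ipi_prob = 0.417,
    biopsy_post_ipi_prob = 0.75,   # P(biopsy after ipi | prior ipi)
    # P(CR, PR, SD, MR, PD) by subtype group; marginals give ~38% ORR,
    # ~45% PD, and a ~40% vs ~20% response rate by subtype group
    response_probs = list(
      cutaneous_occult = c(CR = 0.13, PR = 0.28, SD = 0.14, MR = 0.03,
                           PD = 0.42),
      acral_mucosal = c(CR = 0.05, PR = 0.15, SD = 0.12, MR = 0.03,
                        PD = 0.65)
    ),
    tmb_lognormal_params = list(
      cutaneous_occult = c(meanlog = log(297.5), sdlog = 1.35),
      acral_mucosal = c(meanlog = log(58), sdlog = 1.0)
    ),
    synonymous_ratio = 0.35,       # synonymous per nonsynonymous
    purity_beta_params = c(shape1 = 2.2, shape2 = 1.2),
    ploidy_mixture = list(weight_doubled = 0.38,
                          diploid = c(mean = 2.06, sd = 0.10),
                          doubled = c(mean = 3.3, sd = 0.40)),
    heterogeneity_beta_params = c(shape1 = 4, shape2 = 18),
    aneuploidy_beta_params = c(shape1 = 2, shape2 = 4),
    coverage_negbin_params = c(size = 6, mean_depth_meanlog = log(120),
                               mean_depth_sdlog = 0.25),
    callable_bases_params = c(mean = 30e6, sd = 2e6),
    ccf_missing_prob = 0.02,
    mhc2_effect_size = mhc2_effect_size,
    ldh_lognormal_params = c(meanlog = log(247), sdlog = 0.45,
                             pd_shift = 0.25),
    lymph_node_met_prob = 0.5,
    # exponential rates (per month) by response group
    survival_exponential_rates = list(
      os = c(responder = log(2) / 60, sd_mr = log(2) / 24, pd = log(2) / 9),
      pfs = c(responder = log(2) / 30, sd_mr = log(2) / 8, pd = log(2) / 2.5)
    ),
    censor_window_months = c(18, 42),
    n_genes = n_genes,
    sno_fraction = 0.02,           # fraction of genes annotated snoRNA
    expr_baseline = c(meanlog = 2, sdlog_between_genes = 1.5,
                      sdlog_within = 1.0, mhc_meanlog = 4)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(override)] <- override
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 4) stop("n_patients must be >= 4", call. = FALSE)
  if (abs(sum(cfg$subtype_probs) - 1) > 1e-8) {
    stop("subtype_probs must sum to 1", call. = FALSE)
  }
  for (p in cfg$response_probs) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("response_probs must be probability vectors summing to 1",
           call. = FALSE)
    }
  }
  if (cfg$prior_ipi_prob < 0 || cfg$prior_ipi_prob > 1) {
    stop("prior_ipi_prob must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(cfg$mhc2_effect_size)) {
    stop("mhc2_effect_size must be finite", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Expected responder fraction under a simulation configuration
#'
#' Marginal probability that a simulated patient is a responder (CR or PR),
#' mixing the subtype-group conditional response distributions over the
#' subtype frequencies.
#'
#' @param config A `sim_config`.
#' @return Scalar probability.
#' @export
expected_responder_fraction <- function(config) {
  p_co <- sum(config$subtype_probs[c("cutaneous", "occult")])
  p_am <- sum(config$subtype_probs[c("acral", "mucosal")])
  rp <- config$response_probs
  unname(p_co * sum(rp$cutaneous_occult[c("CR", "PR")]) +
         p_am * sum(rp$acral_mucosal[c("CR", "PR")]))
}

#' Simulate a synthetic anti-PD1 melanoma cohort
#'
#' Generates a complete [cohort_bundle()]: clinical records, somatic
#' mutations with cancer cell fractions, allelic copy-number segments,
#' sample genomics (purity, ploidy, coverage histogram, callable bases) and
#' a TPM expression matrix with biotype annotation. All draws come from one
#' RNG stream seeded once, in a fixed documented order (clinical, genomics,
#' mutations, segments, expression, survival), so a given `(config, seed)`
#' pair is fully reproducible.
#'
#' Structural features planted by design:
#' * mutation burden depends on melanoma subtype only (the confounding the
#'   downstream analysis is meant to expose);
#' * per-patient CCFs are drawn so the expected subclonal fraction equals
#'   the patient's heterogeneity parameter (clonal CCF ~ U(0.8, 1),
#'   subclonal CCF ~ U(0.05, 0.8));
#' * MHC-II HLA gene TPMs are multiplied by `2^mhc2_effect_size` only in
#'   ipilimumab-experienced responders;
#' * LDH is shifted upward in progressors; survival times are exponential
#'   with response-dependent rates and administrative censoring.
#'
#' @param config A `sim_config` from [default_sim_config()].
#' @param seed Integer seed.
#' @return A `cohort_bundle`.
#' @export
simulate_cohort <- function(config = default_sim_config(), seed = 1) {
  config <- validate_sim_config(unclass(config))
  set.seed(seed)
  n <- config$n_patients

  ## --- clinical -----------------------------------------------------------
  subtype <- sample(names(config$subtype_probs), n, replace = TRUE,
                    prob = config$subtype_probs)
  grp <- ifelse(subtype %in% c("cutaneous", "occult"),
                "cutaneous_occult", "acral_mucosal")
  prior_ipi <- stats::runif(n) < config$prior_ipi_prob
  biopsy_post <- prior_ipi & (stats::runif(n) < config$biopsy_post_ipi_prob)
  best_response <- vapply(grp, function(g) {
    sample(names(config$response_probs[[g]]), 1,
           prob = config$response_probs[[g]])
  }, character(1))
  responder <- best_response %in% c("CR", "PR")
  pd <- best_response == "PD"

  ldhp <- config$ldh_lognormal_params
  ldh <- stats::rlnorm(n, ldhp[["meanlog"]] + ldhp[["pd_shift"]] * pd,
                       ldhp[["sdlog"]])
  ln_met <- stats::runif(n) < config$lymph_node_met_prob
  patient_id <- sprintf("P%03d", seq_len(n))

  ## --- sample genomics ----------------------------------------------------
  pb <- config$purity_beta_params
  purity <- pmin(pmax(stats::rbeta(n, pb[["shape1"]], pb[["shape2"]]),
                      0.1), 1)
  pm <- config$ploidy_mixture
  doubled <- stats::runif(n) < pm$weight_doubled
  ploidy <- ifelse(doubled,
                   stats::rnorm(n, pm$doubled[["mean"]], pm$doubled[["sd"]]),
                   stats::rnorm(n, pm$diploid[["mean"]], pm$diploid[["sd"]]))
  ploidy <- pmax(ploidy, 1.2)
  hb <- config$heterogeneity_beta_params
  heterogeneity <- stats::rbeta(n, hb[["shape1"]], hb[["shape2"]])

  cv <- config$coverage_negbin_params
  mean_depth <- stats::rlnorm(n, cv[["mean_depth_meanlog"]],
                              cv[["mean_depth_sdlog"]])
  hist_list <- lapply(seq_len(n), function(i) {
    d <- stats::rnbinom(2000, size = cv[["size"]], mu = mean_depth[i])
    d <- d[d > 0]
    tab <- table(d)
    stats::setNames(as.numeric(tab), names(tab))
  })
  cb <- config$callable_bases_params
  callable <- pmax(round(stats::rnorm(n, cb[["mean"]], cb[["sd"]])), 1e7)

  tmbp <- config$tmb_lognormal_params
  nonsyn <- vapply(seq_len(n), function(i) {
    p <- tmbp[[grp[i]]]
    max(1L, as.integer(round(stats::rlnorm(1, p[["meanlog"]],
                                           p[["sdlog"]]))))
  }, integer(1))

  genomics <- data.frame(
    patient_id = patient_id, purity = purity, ploidy = ploidy,
    coverage_histogram = vapply(hist_list, format_coverage_histogram,
                                character(1)),
    nonsyn_count = nonsyn, callable_bases = callable,
    stringsAsFactors = FALSE
  )

  ## --- mutations ----------------------------------------------------------
  gene_pool <- sprintf("G%04d", seq_len(2000))
  mut_list <- lapply(seq_len(n), function(i) {
    n_ns <- nonsyn[i]
    n_syn <- stats::rpois(1, config$synonymous_ratio * n_ns)
    m <- n_ns + n_syn
    subclonal <- stats::runif(m) < heterogeneity[i]
    ccf <- ifelse(subclonal, stats::runif(m, 0.05, 0.8),
                  stats::runif(m, 0.8, 1))
    ccf[stats::runif(m) < config$ccf_missing_prob] <- NA
    depth <- stats::rnbinom(m, size = cv[["size"]], mu = mean_depth[i]) + 1
    vaf <- pmin(ifelse(is.na(ccf), 0.5, ccf) * purity[i] / 2, 1)
    alt <- stats::rbinom(m, depth, vaf)
    data.frame(
      patient_id = patient_id[i],
      gene = sample(gene_pool, m, replace = TRUE),
      effect = c(rep("nonsynonymous", n_ns), rep("synonymous", n_syn)),
      ccf = ccf, alt_count = alt, depth = depth,
      stringsAsFactors = FALSE
    )
  })
  mutations <- do.call(rbind, mut_list)

  ## --- copy-number segments ----------------------------------------------
  ab <- config$aneuploidy_beta_params
  aneu_target <- stats::rbeta(n, ab[["shape1"]], ab[["shape2"]])
  chrom_len <- 1.3e8
  seg_list <- lapply(seq_len(n), function(i) {
    segs <- lapply(1:22, function(ch) {
      k <- 1 + stats::rpois(1, 1.5)
      cuts <- sort(stats::runif(k - 1, 0, chrom_len))
      start <- floor(c(1, cuts + 1))
      end <- floor(c(cuts, chrom_len))
      data.frame(chrom = paste0("chr", ch), start = start, end = end)
    })
    segs <- do.call(rbind, segs)
    u <- stats::runif(nrow(segs))
    f <- aneu_target[i]
    status <- ifelse(u < f / 2, "amp",
                     ifelse(u < f, "del",
                            ifelse(u < f + 0.08, "loh", "neutral")))
    data.frame(patient_id = patient_id[i], segs, allelic_status = status,
               stringsAsFactors = FALSE)
  })
  segments <- do.call(rbind, seg_list)

  ## --- expression ---------------------------------------------------------
  mhc <- mhc_gene_sets()
  mhc_genes <- unlist(mhc, use.names = FALSE)
  n_sno <- max(2L, round(config$sno_fraction * config$n_genes))
  n_bg <- config$n_genes - length(mhc_genes) - n_sno
  if (n_bg < 10) stop("n_genes too small for gene annotation", call. = FALSE)
  genes <- c(mhc_genes, sprintf("SNORD%03d", seq_len(n_sno)),
             sprintf("BG%05d", seq_len(n_bg)))
  biotype <- stats::setNames(
    c(rep("protein_coding", length(mhc_genes)), rep("snoRNA", n_sno),
      rep("protein_coding", n_bg)), genes)

  eb <- config$expr_baseline
  mu_g <- stats::rnorm(length(genes), eb[["meanlog"]],
                       eb[["sdlog_between_genes"]])
  mu_g[seq_along(mhc_genes)] <- stats::rnorm(length(mhc_genes),
                                             eb[["mhc_meanlog"]], 0.5)
  expr <- matrix(stats::rlnorm(length(genes) * n, mu_g, eb[["sdlog_within"]]),
                 nrow = length(genes), ncol = n,
                 dimnames = list(genes, patient_id))
  # sparse dropout so some genes fail the low-expression filter
  p0 <- pmin(pmax(stats::plogis(-1.2 * mu_g), 0), 0.9)
  zero_mask <- matrix(stats::runif(length(expr)) <
                        rep(p0, times = n), nrow = length(genes))
  expr[zero_mask] <- 0
  # planted subgroup-restricted MHC-II effect
  target_samples <- patient_id[prior_ipi & responder]
  if (length(target_samples) > 0 && config$mhc2_effect_size != 0) {
    expr[mhc$MHC_II, target_samples] <-
      expr[mhc$MHC_II, target_samples] * 2^config$mhc2_effect_size
  }
  # TPM closure
  expr <- sweep(expr, 2, colSums(expr), "/") * 1e6

  ## --- survival -----------------------------------------------------------
  sgrp <- ifelse(responder, "responder", ifelse(pd, "pd", "sd_mr"))
  rates <- config$survival_exponential_rates
  os_true <- stats::rexp(n, rates$os[sgrp])
  pfs_true <- stats::rexp(n, rates$pfs[sgrp])
  cw <- config$censor_window_months
  cens <- stats::runif(n, cw[1], cw[2])
  os_months <- pmin(os_true, cens)
  pfs_months <- pmin(pfs_true, cens, os_months)

  clinical <- data.frame(
    patient_id = patient_id, best_response = best_response,
    prior_ipilimumab = prior_ipi, biopsy_post_ipilimumab = biopsy_post,
    ldh_u_per_l = round(ldh, 1), lymph_node_met = ln_met,
    melanoma_subtype = subtype,
    os_months = round(os_months, 2), os_event = os_true <= cens,
    pfs_months = round(pfs_months, 2),
    pfs_event = pfs_true <= pmin(cens, os_months),
    stringsAsFactors = FALSE
  )

  cohort_bundle(clinical, mutations, segments, genomics, expr, biotype)
}

#' Plant a multiplicative expression effect
#'
#' Multiplies the named gene x sample cells by `2^log2_shift`, leaving all
#' other cells untouched. No renormalization is applied; callers wanting TPM
#' closure should renormalize afterwards. Intended for planted-effect
#' recovery experiments.
#'
#' @param expr Numeric expression matrix (genes x samples).
#' @param genes Character vector of gene symbols (rows).
#' @param samples Character vector of sample ids (columns).
#' @param log2_shift Log2 multiplicative shift.
#' @return The modified matrix.
#' @export
plant_expression_effect <- function(expr, genes, samples, log2_shift) {
  missing_g <- setdiff(genes, rownames(expr))
  missing_s <- setdiff(samples, colnames(expr))
  if (length(missing_g) > 0) {
    stop("unknown gene(s): ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  }
  if (length(missing_s) > 0) {
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  expr[genes, samples] <- expr[genes, samples] * 2^log2_shift
  expr
}
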