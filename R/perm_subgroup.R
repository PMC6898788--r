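#' Stratified permutation of subgroup labels
#'
#' Shuffles the subgroup assignment (e.g. ipilimumab-experienced vs
#' ipilimumab-naive) across patients while preserving, exactly, both the
#' subgroup sizes and the number of patients of each response class in
#' each subgroup. This is achieved by permuting the subgroup labels within
#' each response class, so both preserved-count invariants hold by
#' construction for every draw.
#'
#' @param subgroup_labels Two-level vector of subgroup assignments.
#' @param response_labels Response-class vector (typically two classes).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so callers can draw repeatedly inside their own seeded stream).
#' @return List with `subgroup` (permuted assignment), `preserved` (the
#'   subgroup x response count table, identical to the observed one) and
#'   `seed`.
#' @export
permute_preserving_strata <- function(subgroup_labels, response_labels,
                                      seed = NULL) {
  if (length(subgroup_labels) != length(response_labels)) {
    stop("label vectors must be aligned", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  permuted <- subgroup_labels
  for (cls in unique(response_labels)) {
    idx <- which(response_labels == cls)
    permuted[idx] <- subgroup_labels[sample(idx)]
  }
  list(subgroup = permuted,
       preserved = table(subgroup = permuted, response = response_labels),
       seed = seed)
}

# Floor q-values away from zero before taking logs; resolution-limited
# permutation q-values of exactly 0 are set to 1/n_perm_gsea.
.log_q <- function(q, n_perm_gsea) {
  log(pmax(q, 1 / n_perm_gsea))
}

#' Empiric p-value for subgroup-specific pathway enrichment
#'
#' Tests whether a pathway's enrichment (responders vs progressors) is
#' specific to one subgroup. The observed statistic per gene set is the
#' difference in log FDR q between the two subgroups' cohort GSEA runs,
#' `log q(other) - log q(interest)` (large when the set is enriched only
#' in the subgroup of interest). The null is built by repeatedly permuting
#' the subgroup labels with [permute_preserving_strata()] and rerunning
#' the per-subgroup GSEA; a permutation counts as at least as extreme when
#' BOTH its log-q difference reaches the observed difference AND its
#' q-value in the pseudo-subgroup of interest is as small as or smaller
#' than the observed one. The reported empiric p uses the add-one
#' correction `(1 + b) / (1 + n_perm)`.
#'
#' @param expr Expression matrix, genes x samples.
#' @param response Two-level response factor over samples (e.g.
#'   progressor/responder).
#' @param subgroup Two-level subgroup factor over samples.
#' @param gene_sets Named list of gene sets.
#' @param subgroup_of_interest Level of `subgroup` whose enrichment is
#'   being tested for specificity.
#' @param n_perm Outer permutations (default 100, the scaled-down
#'   profile).
#' @param n_perm_gsea Gene-set permutations inside each GSEA run (default
#'   200, scaled down; raise both for publication-grade runs).
#' @param seed Integer seed.
#' @param weight_p GSEA weighting exponent.
#' @return Data frame with one row per gene set: observed q in each
#'   subgroup, the observed log-q difference, and `empiric_p`.
#' @export
differential_enrichment_empiric_p <- function(expr, response, subgroup,
                                              gene_sets,
                                              subgroup_of_interest,
                                              n_perm = 100,
                                              n_perm_gsea = 200,
                                              seed = 1, weight_p = 1) {
  response <- droplevels(factor(response))
  subgroup <- droplevels(factor(subgroup))
  if (nlevels(subgroup) != 2) {
    stop("exactly two subgroups required", call. = FALSE)
  }
  if (!subgroup_of_interest %in% levels(subgroup)) {
    stop("subgroup_of_interest must be a level of subgroup", call. = FALSE)
  }
  other <- setdiff(levels(subgroup), subgroup_of_interest)

  run_q <- function(sub_assign, gsea_seed) {
    qs <- lapply(levels(subgroup), function(lv) {
      cols <- sub_assign == lv
      if (any(table(response[cols]) < 3)) {
        stop(sprintf(
          "subgroup '%s' too small for GSEA (needs >= 3 per response class)",
          lv), call. = FALSE)
      }
      res <- gsea_cohort(expr[, cols, drop = FALSE], response[cols],
                         gene_sets, n_perm = n_perm_gsea, seed = gsea_seed,
                         weight_p = weight_p)
      stats::setNames(res$fdr_q, res$gene_set)
    })
    stats::setNames(qs, levels(subgroup))
  }

  obs <- run_q(subgroup, gsea_seed = seed)
  q_int <- obs[[subgroup_of_interest]]
  q_oth <- obs[[other]]
  obs_dlogq <- .log_q(q_oth, n_perm_gsea) - .log_q(q_int, n_perm_gsea)

  set.seed(seed)
  hits <- stats::setNames(integer(length(gene_sets)), names(gene_sets))
  for (b in seq_len(n_perm)) {
    perm <- permute_preserving_strata(subgroup, response, seed = NULL)
    pq <- run_q(perm$subgroup, gsea_seed = seed + b)
    p_int <- pq[[subgroup_of_interest]]
    p_dlogq <- .log_q(pq[[other]], n_perm_gsea) -
      .log_q(p_int, n_perm_gsea)
    extreme <- (p_dlogq >= obs_dlogq) & (p_int <= q_int)
    hits <- hits + extreme[names(hits)]
  }

  data.frame(
    gene_set = names(gene_sets),
    q_interest = unname(q_int[names(gene_sets)]),
    q_other = unname(q_oth[names(gene_sets)]),
    delta_log_q = unname(obs_dlogq[names(gene_sets)]),
    empiric_p = unname((1 + hits[names(gene_sets)]) / (1 + n_perm)),
    stringsAsFactors = FALSE
  )
}
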