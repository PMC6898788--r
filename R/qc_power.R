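#' Power-calculation configuration
#'
#' Settings for the per-sample Monte-Carlo power calculation used as a
#' somatic-calling quality-control filter.
#'
#' @param n_sim Number of simulated clonal mutations per sample (default
#'   1000).
#' @param lod_threshold Detection threshold on the log10 odds score
#'   (default 6.3, the MuTect-style tumor LOD cutoff).
#' @param error_rate Per-base sequencing error probability (default 0.001,
#'   i.e. Q30).
#' @param min_power Minimum acceptable detection power; samples below it are
#'   excluded (default 0.80).
#' @return A validated list of class `power_config`.
#' @export
power_config <- function(n_sim = 1000, lod_threshold = 6.3,
                         error_rate = 0.001, min_power = 0.80) {
  if (error_rate <= 0 || error_rate >= 0.25) {
    stop("error_rate must lie in (0, 0.25)", call. = FALSE)
  }
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  if (min_power < 0 || min_power > 1) {
    stop("min_power must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_sim = as.integer(n_sim), lod_threshold = lod_threshold,
                 error_rate = error_rate, min_power = min_power),
            class = "power_config")
}

#' Tumor LOD score for a candidate mutation
#'
#' Log10 likelihood ratio of the mutant model at the maximum-likelihood
#' allele fraction f = alt_count / depth against the no-mutation model
#' (f = 0). Per-read likelihoods follow the substitution-error model
#' P(alt read | f) = f (1 - e) + (1 - f) e/3 and
#' P(ref read | f) = f e/3 + (1 - f)(1 - e), where e is the per-base error
#' rate; under the null every alt read is an error toward one of the three
#' alternative bases. Detection in the power simulation requires
#' LOD >= `lod_threshold` (6.3 by default).
#'
#' Vectorized over `alt_count` and `depth`.
#'
#' @param alt_count Number of reads supporting the alternate allele.
#' @param depth Total read depth (>= 1).
#' @param error_rate Per-base error probability.
#' @return Numeric vector of log10 odds scores; 0 when `alt_count` is 0.
#' @export
tumor_lod <- function(alt_count, depth, error_rate = 0.001) {
  if (any(depth < 1)) stop("depth must be >= 1", call. = FALSE)
  if (any(alt_count < 0 | alt_count > depth)) {
    stop("alt_count must lie in [0, depth]", call. = FALSE)
  }
  e <- error_rate
  f <- alt_count / depth
  p_alt <- f * (1 - e) + (1 - f) * e / 3
  p_ref <- f * e / 3 + (1 - f) * (1 - e)
  ll_mut <- alt_count * log10(p_alt) + (depth - alt_count) * log10(p_ref)
  ll_null <- alt_count * log10(e / 3) + (depth - alt_count) * log10(1 - e)
  ll_mut - ll_null
}

.sample_depths <- function(coverage_histogram, n) {
  depths <- as.numeric(names(coverage_histogram))
  counts <- as.numeric(coverage_histogram)
  if (length(depths) == 0 || sum(counts) <= 0) {
    stop("coverage histogram is empty or all-zero", call. = FALSE)
  }
  if (length(depths) == 1) rep(depths, n)
  else sample(depths, n, replace = TRUE, prob = counts)
}

#' Monte-Carlo power to detect clonal mutations
#'
#' For each of `n_sim` hypothetical true clonal mutations: draw the locus
#' depth N from the sample's coverage distribution; draw the number of
#' tumor-derived reads T ~ Binomial(N, purity); draw the number of
#' mutation-supporting reads M ~ Binomial(T, 1/2) (heterozygous mutation,
#' no copy-number alteration); call the mutation detected when
#' `tumor_lod(M, N)` meets the LOD threshold. The estimated power is the
#' detected fraction.
#'
#' @param coverage_histogram Numeric count vector named by depth (see
#'   [parse_coverage_histogram()]).
#' @param purity Tumor purity in `[0, 1]`.
#' @param config A [power_config()].
#' @return Estimated detection power in `[0, 1]`.
#' @export
simulate_clonal_detection_power <- function(coverage_histogram, purity,
                                            config = power_config()) {
  if (purity < 0 || purity > 1) {
    stop("purity must lie in [0, 1]", call. = FALSE)
  }
  n <- config$n_sim
  depth <- .sample_depths(coverage_histogram, n)
  if (any(depth < 1)) stop("coverage histogram contains depth < 1",
                           call. = FALSE)
  tumor_reads <- stats::rbinom(n, depth, purity)
  mut_reads <- stats::rbinom(n, tumor_reads, 0.5)
  lod <- tumor_lod(mut_reads, depth, config$error_rate)
  mean(lod >= config$lod_threshold)
}

#' Apply the detection-power exclusion filter to a cohort
#'
#' Computes per-sample clonal-mutation detection power from each sample's
#' coverage histogram and purity, and excludes samples whose power falls
#' below `config$min_power`.
#'
#' @param bundle A [cohort_bundle()].
#' @param config A [power_config()].
#' @return List with `kept_ids`, `excluded_ids` and `power_table` (a data
#'   frame of patient_id, purity, power, excluded).
#' @export
apply_power_filter <- function(bundle, config = power_config()) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  g <- bundle$genomics
  missing <- setdiff(bundle$clinical$patient_id, g$patient_id)
  if (length(missing) > 0) {
    stop("no genomics record for patient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hists <- parse_coverage_histogram(g$coverage_histogram)
  power <- vapply(seq_len(nrow(g)), function(i) {
    simulate_clonal_detection_power(hists[[i]], g$purity[i], config)
  }, numeric(1))
  excluded <- power < config$min_power
  list(
    kept_ids = g$patient_id[!excluded],
    excluded_ids = g$patient_id[excluded],
    power_table = data.frame(patient_id = g$patient_id, purity = g$purity,
                             power = power, excluded = excluded,
                             stringsAsFactors = FALSE)
  )
}
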