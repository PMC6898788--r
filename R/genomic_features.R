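#' Nonsynonymous mutation burden
#'
#' Counts the nonsynonymous somatic mutations of one patient and returns the
#' log-scale tumor mutational burden, log10(count + 1). The pseudocount
#' keeps zero-mutation tumors finite.
#'
#' @param mutations Mutation data frame (columns `patient_id`, `effect`).
#' @param patient_id Patient to summarize.
#' @return List with `count` (integer) and `log_tmb`.
#' @export
nonsynonymous_burden <- function(mutations, patient_id) {
  rows <- mutations$patient_id == patient_id
  count <- sum(mutations$effect[rows] == "nonsynonymous")
  list(count = as.integer(count), log_tmb = log10(count + 1))
}

#' Mutations per callable megabase
#'
#' Nonsynonymous mutation count divided by the number of megabases with
#' sufficient coverage to call mutations.
#'
#' @param count Nonsynonymous mutation count.
#' @param callable_bases Number of callable bases (> 0).
#' @return Mutations per Mb.
#' @export
mutations_per_megabase <- function(count, callable_bases) {
  if (any(callable_bases <= 0)) {
    stop("callable_bases must be positive", call. = FALSE)
  }
  count / (callable_bases / 1e6)
}

#' Tumor heterogeneity from cancer cell fractions
#'
#' The proportion of a tumor's mutations that are subclonal. A mutation is
#' clonal when its cancer cell fraction is at or above
#' `clonal_ccf_threshold` (0.8 by default, a conservative high-specificity
#' rule); all others are subclonal. Missing CCFs are excluded from both
#' numerator and denominator.
#'
#' @param ccfs Numeric vector of cancer cell fractions in `[0, 1]`.
#' @param clonal_ccf_threshold Clonality cutoff (mutations with CCF >=
#'   threshold are clonal).
#' @return Subclonal fraction in `[0, 1]`, or NA (with a warning) when no
#'   non-missing CCF is available.
#' @export
heterogeneity <- function(ccfs, clonal_ccf_threshold = 0.8) {
  ccfs <- ccfs[!is.na(ccfs)]
  if (length(ccfs) == 0) {
    warning("no non-missing CCF values; heterogeneity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(ccfs < clonal_ccf_threshold)
}

#' Allelic aneuploidy fraction
#'
#' The proportion of the profiled genome carrying an allelic amplification
#' or deletion: the summed length (end - start + 1) of segments whose
#' `allelic_status` is `amp` or `del`, divided by the total segment length.
#' Copy-neutral LOH segments count toward the denominator only.
#'
#' @param segments Segment data frame for one patient (columns `chrom`,
#'   `start`, `end`, `allelic_status`).
#' @return Fraction in `[0, 1]`.
#' @export
aneuploidy_fraction <- function(segments) {
  if (nrow(segments) == 0) stop("no segments supplied", call. = FALSE)
  if (any(segments$end < segments$start)) {
    stop("segment with end < start", call. = FALSE)
  }
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch, call. = FALSE)
    }
  }
  len <- segments$end - segments$start + 1
  altered <- segments$allelic_status %in% c("amp", "del")
  sum(len[altered]) / sum(len)
}

#' Per-patient whole-exome scalar features
#'
#' Computes the tumor-level features used throughout the analysis: the
#' nonsynonymous mutation count and log10 burden, mutations per callable
#' megabase, clonality-based heterogeneity, allelic aneuploidy fraction,
#' and the consumed purity and ploidy estimates.
#'
#' @param bundle A [cohort_bundle()].
#' @return Data frame with one row per patient in the genomics table.
#' @export
genomic_features <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  g <- bundle$genomics
  out <- lapply(seq_len(nrow(g)), function(i) {
    pid <- g$patient_id[i]
    mut <- bundle$mutations[bundle$mutations$patient_id == pid, ,
                            drop = FALSE]
    burden <- nonsynonymous_burden(mut, pid)
    segs <- bundle$segments[bundle$segments$patient_id == pid, ,
                            drop = FALSE]
    het <- if (nrow(mut) > 0) {
      suppressWarnings(heterogeneity(mut$ccf))
    } else NA_real_
    aneu <- if (nrow(segs) > 0) aneuploidy_fraction(segs) else NA_real_
    data.frame(
      patient_id = pid, nonsyn_count = burden$count,
      log_tmb = burden$log_tmb,
      mut_per_mb = mutations_per_megabase(burden$count,
                                          g$callable_bases[i]),
      heterogeneity = het, aneuploidy_fraction = aneu,
      purity = g$purity[i], ploidy = g$ploidy[i],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
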