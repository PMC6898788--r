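#' @keywords internal
"_PACKAGE"

# Response categories recognised in clinical tables. CR/PR = responder,
# PD = progressor; SD/MR are retained but excluded from the responder vs
# progressor contrast.
RESPONSE_LEVELS <- c("CR", "PR", "SD", "MR", "PD")
SUBTYPE_LEVELS <- c("cutaneous", "occult", "acral", "mucosal", "other")

.required_clinical_cols <- c(
  "patient_id", "best_response", "prior_ipilimumab", "biopsy_post_ipilimumab",
  "ldh_u_per_l", "lymph_node_met", "melanoma_subtype",
  "os_months", "os_event", "pfs_months", "pfs_event"
)
.required_mutation_cols <- c("patient_id", "gene", "effect", "ccf",
                             "alt_count", "depth")
.required_segment_cols <- c("patient_id", "chrom", "start", "end",
                            "allelic_status")
.required_genomics_cols <- c("patient_id", "purity", "ploidy",
                             "coverage_histogram", "nonsyn_count",
                             "callable_bases")

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

.check_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.as_logical01 <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  x %in% c("1", "true", "t", "yes")
}

#' Parse a serialized coverage histogram
#'
#' Coverage histograms are stored in genomics tables as a single string of
#' `depth:count` pairs separated by semicolons, e.g. `"10:4;11:9;12:20"`.
#'
#' @param s Character vector of serialized histograms.
#' @return A list of numeric count vectors named by depth.
#' @export
parse_coverage_histogram <- function(s) {
  lapply(s, function(one) {
    if (is.na(one) || !nzchar(one)) {
      stop("empty coverage histogram", call. = FALSE)
    }
    parts <- strsplit(strsplit(one, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    depth <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    count <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    if (anyNA(depth) || anyNA(count) || any(count < 0)) {
      stop("malformed coverage histogram: ", one, call. = FALSE)
    }
    stats::setNames(count, depth)
  })
}

#' Serialize a coverage histogram
#'
#' Inverse of [parse_coverage_histogram()].
#'
#' @param h Numeric count vector named by depth.
#' @return Single string of `depth:count` pairs.
#' @export
format_coverage_histogram <- function(h) {
  paste(sprintf("%s:%s", names(h), as.numeric(h)), collapse = ";")
}

#' Assemble a validated cohort bundle
#'
#' A cohort bundle joins the per-patient clinical table with the somatic
#' mutation table, allelic copy-number segments, sample-level genomics
#' (purity, ploidy, coverage histogram, callable bases), and optionally a
#' gene x sample TPM expression matrix. Every downstream stage of the
#' pipeline consumes this object.
#'
#' Rows of the mutation/segment/genomics tables whose `patient_id` does not
#' appear in the clinical table are dropped with a message; likewise
#' expression columns without a clinical record. Drop counts are recorded in
#' `bundle$dropped`.
#'
#' @param clinical Clinical data frame (see `load_cohort` for columns).
#' @param mutations Somatic mutation data frame.
#' @param segments Copy-number segment data frame.
#' @param genomics Sample genomics data frame.
#' @param expression Optional numeric matrix of TPM values, genes in rows
#'   (rownames = gene symbols), samples in columns (colnames = patient ids).
#' @param biotype Optional character vector of gene biotypes named by gene
#'   symbol; required by [renormalize_tpm()].
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(clinical, mutations, segments, genomics,
                          expression = NULL, biotype = NULL) {
  .check_cols(clinical, .required_clinical_cols, "clinical")
  .check_cols(mutations, .required_mutation_cols, "mutation")
  .check_cols(segments, .required_segment_cols, "segment")
  .check_cols(genomics, .required_genomics_cols, "genomics")

  clinical$patient_id <- trimws(as.character(clinical$patient_id))
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicate patient_id in clinical table: ",
         paste(unique(clinical$patient_id[duplicated(clinical$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_resp <- setdiff(unique(clinical$best_response), RESPONSE_LEVELS)
  if (length(bad_resp) > 0) {
    stop("unknown best_response value(s): ", paste(bad_resp, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("prior_ipilimumab", "biopsy_post_ipilimumab",
                "lymph_node_met", "os_event", "pfs_event")) {
    clinical[[col]] <- .as_logical01(clinical[[col]])
  }
  if (any(clinical$os_months < 0, na.rm = TRUE) ||
      any(clinical$pfs_months < 0, na.rm = TRUE)) {
    stop("negative survival time in clinical table", call. = FALSE)
  }

  ids <- clinical$patient_id
  dropped <- c(mutations = 0L, segments = 0L, genomics = 0L, expression = 0L)

  drop_unknown <- function(df, what) {
    unknown <- !(df$patient_id %in% ids)
    if (any(unknown)) {
      message(sum(unknown), " ", what,
              " row(s) with unknown patient_id dropped")
    }
    dropped[[what]] <<- sum(unknown)
    df[!unknown, , drop = FALSE]
  }
  mutations <- drop_unknown(mutations, "mutations")
  segments <- drop_unknown(segments, "segments")
  genomics <- drop_unknown(genomics, "genomics")

  if (anyDuplicated(genomics$patient_id)) {
    stop("duplicate patient_id in genomics table", call. = FALSE)
  }
  if (any(genomics$purity <= 0 | genomics$purity > 1, na.rm = TRUE)) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  with_ccf <- !is.na(mutations$ccf)
  if (any(mutations$ccf[with_ccf] < 0 | mutations$ccf[with_ccf] > 1)) {
    stop("ccf must lie in [0, 1] when present", call. = FALSE)
  }
  if (any(mutations$alt_count > mutations$depth, na.rm = TRUE)) {
    stop("alt_count exceeds depth in mutation table", call. = FALSE)
  }
  if (any(segments$end < segments$start)) {
    stop("segment with end < start", call. = FALSE)
  }

  if (!is.null(expression)) {
    expression <- as.matrix(expression)
    if (any(expression < 0, na.rm = TRUE)) {
      stop("expression matrix has negative entries", call. = FALSE)
    }
    extra <- setdiff(colnames(expression), ids)
    if (length(extra) > 0) {
      message(length(extra),
              " expression sample(s) without a clinical record dropped")
      expression <- expression[, !(colnames(expression) %in% extra),
                               drop = FALSE]
    }
    dropped[["expression"]] <- length(extra)
    if (!is.null(biotype)) biotype <- biotype[rownames(expression)]
  }

  structure(
    list(clinical = clinical, mutations = mutations, segments = segments,
         genomics = genomics, expression = expression, biotype = biotype,
         dropped = dropped),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", nrow(x$clinical), "patients;",
      nrow(x$mutations), "mutations;",
      nrow(x$segments), "segments;",
      if (is.null(x$expression)) "no expression (WES-only)"
      else paste(nrow(x$expression), "genes x", ncol(x$expression),
                 "expression samples"), "\n")
  invisible(x)
}

#' Load a cohort from TSV components
#'
#' Reads the five tabular components of a cohort and assembles them with
#' [cohort_bundle()]. All files are tab-separated with a header row; missing
#' numeric values are encoded `NA` and booleans as 0/1. The expression table,
#' when given, has columns `gene`, `biotype`, then one column per sample.
#' Expression is optional: cohorts with exome data only (no RNA) are valid.
#'
#' @param clinical_path,mutations_path,segments_path,genomics_path Paths to
#'   the required TSV components.
#' @param expression_path Optional path to the expression TSV.
#' @return A `cohort_bundle`.
#' @export
load_cohort <- function(clinical_path, mutations_path, segments_path,
                        genomics_path, expression_path = NULL) {
  for (p in c(clinical_path, mutations_path, segments_path, genomics_path,
              expression_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  clinical <- .read_tsv(clinical_path)
  mutations <- .read_tsv(mutations_path)
  segments <- .read_tsv(segments_path)
  genomics <- .read_tsv(genomics_path)

  expression <- NULL
  biotype <- NULL
  if (!is.null(expression_path)) {
    etab <- .read_tsv(expression_path)
    .check_cols(etab, c("gene", "biotype"), "expression")
    if (anyDuplicated(etab$gene)) {
      stop("duplicate gene symbol in expression table", call. = FALSE)
    }
    genes <- trimws(etab$gene)
    biotype <- stats::setNames(etab$biotype, genes)
    expression <- as.matrix(etab[, setdiff(names(etab), c("gene", "biotype")),
                                 drop = FALSE])
    rownames(expression) <- genes
  }
  cohort_bundle(clinical, mutations, segments, genomics, expression, biotype)
}

#' Write a cohort bundle to TSV components
#'
#' Inverse of [load_cohort()]; writes the clinical, mutation, segment and
#' genomics tables (plus expression when present) into `dir` with stable
#' column order so that a reload reproduces the bundle.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write1 <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    df <- as.data.frame(df)
    for (col in names(df)) {
      if (is.logical(df[[col]])) df[[col]] <- as.integer(df[[col]])
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE)
    path
  }
  paths <- c(clinical = write1(bundle$clinical, "clinical"),
             mutations = write1(bundle$mutations, "mutations"),
             segments = write1(bundle$segments, "segments"),
             genomics = write1(bundle$genomics, "genomics"))
  if (!is.null(bundle$expression)) {
    etab <- data.frame(gene = rownames(bundle$expression),
                       biotype = unname(bundle$biotype[rownames(bundle$expression)]),
                       bundle$expression, check.names = FALSE,
                       stringsAsFactors = FALSE)
    paths <- c(paths, expression = write1(etab, "expression"))
  }
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' One gene set per line: set name, description, then member gene symbols,
#' all tab-separated. Duplicate members within a set are removed with a
#' warning; symbols are whitespace-stripped and matched case-sensitively.
#'
#' @param gmt_path Path to a GMT file.
#' @return Named list of character vectors of member gene symbols.
#' @export
read_gene_sets <- function(gmt_path) {
  if (!file.exists(gmt_path)) stop("file not found: ", gmt_path, call. = FALSE)
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    name <- trimws(fields[1])
    members <- trimws(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': duplicate members removed", name),
              call. = FALSE)
      members <- unique(members)
    }
    sets[[name]] <- members
  }
  sets
}

#' MHC class I and class II antigen-presentation gene sets
#'
#' The 13 MHC-II HLA genes (HLA-DMA, HLA-DMB, HLA-DOA, HLA-DOB, HLA-DPA1,
#' HLA-DPB1, HLA-DQA1, HLA-DQA2, HLA-DQB1, HLA-DQB2, HLA-DRA, HLA-DRB1,
#' HLA-DRB5) and the 8 MHC-I genes (HLA-A, HLA-B, HLA-C, HLA-E, HLA-F,
#' TAP1, TAP2, B2M) used for antigen-presentation enrichment scoring.
#'
#' @return Named list with elements `MHC_II` and `MHC_I`.
#' @export
mhc_gene_sets <- function() {
  read_gene_sets(system.file("extdata", "mhc_gene_sets.gmt",
                             package = "icbResist", mustWork = TRUE))
}

#' Write a per-patient feature table
#'
#' @param features Data frame with one row per patient (must contain
#'   `patient_id`).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features), "patient_id" %in% names(features))
  df <- features
  for (col in names(df)) {
    if (is.logical(df[[col]])) df[[col]] <- as.integer(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Responder / progressor contrast labels
#'
#' Patients with CR or PR as best response are responders; PD are
#' progressors; SD and MR are excluded (NA).
#'
#' @param best_response Character vector of best-response categories.
#' @return Factor with levels `progressor`, `responder` (NA for SD/MR).
#' @export
response_contrast <- function(best_response) {
  out <- rep(NA_character_, length(best_response))
  out[best_response %in% c("CR", "PR")] <- "responder"
  out[best_response == "PD"] <- "progressor"
  factor(out, levels = c("progressor", "responder"))
}
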