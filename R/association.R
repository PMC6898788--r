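#' Fisher's exact test with the sample odds ratio
#'
#' For a 2x2 table laid out as exposure (rows: high/positive first) by
#' outcome (columns: responder first), returns the sample cross-product
#' odds ratio `(a*d)/(b*c)` and the two-sided Fisher exact p-value (summing
#' all tables as or less probable than the observed one under the
#' hypergeometric null). With `adjusted = TRUE` the conservative adjusted
#' OR is computed by adding one to both exposure-positive cells (the
#' exposed responders and exposed progressors) before testing, which keeps
#' the OR finite when a cell is empty.
#'
#' @param table 2x2 matrix or table of non-negative integer counts.
#' @param adjusted Apply the add-one adjustment to the first row.
#' @param conf_level Confidence level for the Woolf interval (reported when
#'   all cells are positive).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `method`, and `infinite_or` flag.
#' @export
fisher_or <- function(table, adjusted = FALSE, conf_level = 0.95) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    stop("table must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  }
  if (sum(m) == 0) stop("table has no observations", call. = FALSE)
  if (adjusted) m[1, ] <- m[1, ] + 1
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  infinite_or <- (b * c_) == 0
  or <- if (infinite_or) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  p <- stats::fisher.test(m)$p.value
  ci <- if (all(m > 0)) woolf_ci(m, conf_level) else c(NA_real_, NA_real_)
  list(odds_ratio = or, ci_low = ci[1], ci_high = ci[2], p_value = p,
       method = if (adjusted) "fisher_adjusted" else "fisher",
       infinite_or = infinite_or)
}

#' Woolf confidence interval for an odds ratio
#'
#' Normal-approximation interval on the log odds ratio,
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Requires all four
#' cells positive; for tables with an empty cell use the adjusted mode of
#' [fisher_or()].
#'
#' @param table 2x2 matrix of positive counts.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
woolf_ci <- function(table, level = 0.95) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(m <= 0)) {
    stop("all cells must be positive; use fisher_or(adjusted = TRUE) for ",
         "tables with empty cells", call. = FALSE)
  }
  log_or <- log((m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(log_or + c(-1, 1) * z * se)
}

#' Median split of a numeric feature
#'
#' Labels values strictly greater than the median `"high"` and the rest
#' `"low"` (ties at the median go low); missing values stay missing. A
#' constant vector yields all-low with a warning.
#'
#' @param values Numeric vector (at least 2 non-missing).
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values", call. = FALSE)
  med <- stats::median(values[ok])
  if (all(values[ok] == med)) {
    warning("constant vector: all values labeled low", call. = FALSE)
  }
  out <- rep(NA_character_, length(values))
  out[ok] <- ifelse(values[ok] > med, "high", "low")
  factor(out, levels = c("low", "high"))
}

#' Interaction test from stratified 2x2 counts
#'
#' Fits the saturated logistic model
#' `outcome ~ exposure + stratum + exposure:stratum` by maximum likelihood
#' on per-subject rows expanded from a 2x2x2 count array, and returns the
#' exponentiated interaction coefficient with its Wald confidence interval
#' and p-value. In the saturated model the interaction OR equals the ratio
#' of the within-stratum odds ratios.
#'
#' @param counts 2x2x2 array of counts with dimensions
#'   `exposure x outcome x stratum`. The first index level of each
#'   dimension is the reference (unexposed / failure / reference stratum).
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `odds_ratio` (interaction), `ci_low`, `ci_high`,
#'   `p_value`, `fit` (the `glm` object), `separation` flag.
#' @export
interaction_logistic <- function(counts, conf_level = 0.95) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3 || !all(dim(counts) == c(2, 2, 2))) {
    stop("counts must be a 2x2x2 array (exposure x outcome x stratum)",
         call. = FALSE)
  }
  if (any(apply(counts, 3, sum) == 0)) {
    stop("each stratum must contain subjects", call. = FALSE)
  }
  grid <- expand.grid(exposure = c(0, 1), outcome = c(0, 1),
                      stratum = c(0, 1))
  n <- as.vector(counts[cbind(grid$exposure + 1, grid$outcome + 1,
                              grid$stratum + 1)])
  rows <- grid[rep(seq_len(nrow(grid)), n), , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm(outcome ~ exposure * stratum, family = stats::binomial(),
               data = rows)
  )
  co <- summary(fit)$coefficients
  term <- "exposure:stratum"
  b <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  separation <- !fit$converged || abs(b) > 15 || se > 100
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    odds_ratio = exp(b),
    ci_low = if (separation) 0 else exp(b - z * se),
    ci_high = if (separation) Inf else exp(b + z * se),
    p_value = co[term, "Pr(>|z|)"],
    fit = fit, separation = separation
  )
}

#' Two-group and k-group comparisons
#'
#' Dispatches the named two-sided test: `mww` (Mann-Whitney-Wilcoxon
#' rank-sum, two groups), `kruskal` (Kruskal-Wallis, any number of groups),
#' or `chi2` (chi-squared on the contingency table of `values` x `labels`,
#' for categorical `values`).
#'
#' @param values Numeric (mww/kruskal) or categorical (chi2) vector.
#' @param labels Group labels.
#' @param test One of `"mww"`, `"kruskal"`, `"chi2"`.
#' @return Two-sided p-value.
#' @export
compare_groups <- function(values, labels, test = c("mww", "kruskal",
                                                    "chi2")) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- droplevels(factor(labels[keep]))
  if (nlevels(labels) < 2) stop("need at least two groups", call. = FALSE)
  switch(test,
    mww = {
      if (nlevels(labels) != 2) {
        stop("mww requires exactly two groups", call. = FALSE)
      }
      suppressWarnings(
        stats::wilcox.test(values ~ labels, exact = FALSE)$p.value)
    },
    kruskal = stats::kruskal.test(values, labels)$p.value,
    chi2 = suppressWarnings(
      stats::chisq.test(table(values, labels))$p.value)
  )
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival estimates per group, the per-group median
#' survival (earliest time at which the survival estimate drops to 0.5 or
#' below; NA when never reached), and the log-rank chi-square p-value for
#' the group comparison.
#'
#' @param times Non-negative survival/censoring times.
#' @param events Event indicator (1/TRUE = event, 0/FALSE = censored).
#' @param group_labels Group labels (>= 2 groups, each nonempty).
#' @return List with `p`, `medians` (named by group), `fit` (the
#'   `survfit` object).
#' @export
km_logrank <- function(times, events, group_labels) {
  if (any(times < 0, na.rm = TRUE)) {
    stop("negative survival times", call. = FALSE)
  }
  group <- droplevels(factor(group_labels))
  if (nlevels(group) < 2) stop("need at least two groups", call. = FALSE)
  events <- as.integer(.as_logical01(events))
  df <- data.frame(times = times, events = events, group = group)
  fit <- survival::survfit(survival::Surv(times, events) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group,
                            data = df)
  p <- stats::pchisq(sd_$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) {
    medians <- stats::setNames(tab[["median"]], levels(group))
  } else {
    medians <- stats::setNames(tab[, "median"],
                               sub("^group=", "", rownames(tab)))
  }
  list(p = p, medians = medians, fit = fit)
}
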