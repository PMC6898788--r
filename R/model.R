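#' Maximum-likelihood logistic model fit
#'
#' Fits `outcome ~ features` by iteratively reweighted least squares and
#' returns the coefficient table with Wald p-values, the log-likelihood,
#' AIC (`2k - 2l`), BIC (`k ln n - 2l`) and the in-sample ROC AUC of the
#' fitted probabilities. Complete quasi-separation is flagged rather than
#' treated as an error.
#'
#' @param features Data frame or matrix of predictors (columns named).
#' @param outcomes Binary outcome vector (1/TRUE = event, e.g. PD).
#' @return Object of class `icb_model_fit`: list with `fit`,
#'   `coefficients`, `loglik`, `aic`, `bic`, `auc`, `separation`,
#'   `features`, `n`.
#' @export
fit_logistic_ml <- function(features, outcomes) {
  x <- as.data.frame(features)
  y <- as.integer(.as_logical01(outcomes))
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  n <- length(y)
  if (ncol(x) > 0) {
    constant <- vapply(x, function(col) length(unique(col)) == 1, logical(1))
    if (any(constant)) {
      stop("constant feature(s): ",
           paste(names(x)[constant], collapse = ", "), call. = FALSE)
    }
    if (n < ncol(x) + 2) stop("too few subjects for the design",
                              call. = FALSE)
    if (qr(stats::model.matrix(~ ., x))$rank < ncol(x) + 1) {
      stop("singular design matrix", call. = FALSE)
    }
  }
  dat <- cbind(.y = y, x)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat)
  )
  co <- summary(fit)$coefficients
  separation <- !fit$converged ||
    any(abs(co[, "Estimate"]) > 15 & co[, "Std. Error"] > 100)
  if (separation) {
    warning("possible complete separation; coefficients unstable",
            call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  structure(list(
    fit = fit, coefficients = co, loglik = ll,
    aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
    auc = roc_auc(stats::fitted(fit), y),
    separation = separation, features = names(x), n = n
  ), class = "icb_model_fit")
}

#' @export
print.icb_model_fit <- function(x, ...) {
  cat("logistic model:", if (length(x$features) == 0) "(intercept only)"
      else paste(x$features, collapse = " + "), "\n")
  cat(sprintf("n = %d, logLik = %.3f, AIC = %.2f, BIC = %.2f, AUC = %.3f%s\n",
              x$n, x$loglik, x$aic, x$bic, x$auc,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, with ties counted one half (the Mann-Whitney U
#' statistic divided by `n1 * n0`).
#'
#' @param scores Numeric prediction scores.
#' @param outcomes Binary outcomes (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, outcomes) {
  y <- .as_logical01(outcomes)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Forward feature selection for a logistic model
#'
#' Starting from the intercept-only model, repeatedly considers each
#' remaining candidate: a candidate is eligible when its Wald p-value upon
#' addition to the current model is below `alpha`, and among eligible
#' candidates the one maximizing the combined model's in-sample AUC is
#' added. Selection stops when no candidate is eligible (or when adding any
#' eligible candidate no longer fits, e.g. through collinearity). An
#' optional `whitelist` restricts and orders the candidate pool before
#' ranking, making an otherwise manual review step reproducible. Setting
#' `alpha = 1` disables the significance gate and yields a pure greedy AUC
#' ordering.
#'
#' @param candidate_features Character vector of candidate column names.
#' @param data Data frame containing the candidates.
#' @param outcomes Binary outcome vector aligned with `data`.
#' @param alpha Wald significance gate (default 0.05).
#' @param whitelist Optional ordered subset of candidates to consider.
#' @param max_features Optional cap on the number of selected features.
#' @return List with `selected` (ordered character vector) and `trace`
#'   (data frame of per-step AIC/BIC/AUC of the growing model).
#' @export
forward_select <- function(candidate_features, data, outcomes, alpha = 0.05,
                           whitelist = NULL, max_features = Inf) {
  if (!is.null(whitelist)) {
    candidate_features <- whitelist[whitelist %in% candidate_features]
  }
  missing_cols <- setdiff(candidate_features, names(data))
  if (length(missing_cols) > 0) {
    stop("candidate(s) absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  selected <- character(0)
  remaining <- candidate_features
  trace <- list()
  while (length(remaining) > 0 && length(selected) < max_features) {
    evals <- lapply(remaining, function(cand) {
      fit <- tryCatch(
        fit_logistic_ml(data[, c(selected, cand), drop = FALSE], outcomes),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      co <- fit$coefficients
      # Wald p of the newly added term (last row of the coefficient table)
      list(cand = cand, p = co[nrow(co), "Pr(>|z|)"], auc = fit$auc,
           aic = fit$aic, bic = fit$bic)
    })
    evals <- Filter(function(e) !is.null(e) && is.finite(e$p), evals)
    eligible <- Filter(function(e) e$p < alpha, evals)
    if (length(eligible) == 0) break
    best <- eligible[[which.max(vapply(eligible, `[[`, numeric(1), "auc"))]]
    selected <- c(selected, best$cand)
    remaining <- setdiff(remaining, best$cand)
    trace[[length(trace) + 1]] <- data.frame(
      step = length(selected), feature = best$cand, wald_p = best$p,
      auc = best$auc, aic = best$aic, bic = best$bic,
      stringsAsFactors = FALSE)
  }
  list(selected = selected,
       trace = if (length(trace) > 0) do.call(rbind, trace)
               else data.frame(step = integer(0), feature = character(0),
                               wald_p = numeric(0), auc = numeric(0),
                               aic = numeric(0), bic = numeric(0)))
}

# Stratified fold assignment: shuffle within each outcome class once, then
# deal subjects round-robin into k folds, continuing the rotation across
# classes so every fold is populated even when k approaches n.
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  offset <- 0L
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' Stratified k-fold cross-validated AUC
#'
#' Refits the model with FIXED features on each training partition and
#' scores the held-out subjects; feature selection is not repeated inside
#' cross-validation. Folds are stratified by outcome. The mean of the
#' per-fold holdout AUCs is returned; when holdout folds are too small to
#' contain both classes (e.g. leave-one-out), a single pooled AUC over all
#' holdout predictions is returned instead.
#'
#' @param feature_names Character vector of model features.
#' @param data Data frame containing the features.
#' @param outcomes Binary outcome vector.
#' @param k Number of folds.
#' @param seed Integer seed for the fold shuffle.
#' @return Mean holdout AUC.
#' @export
kfold_cv_auc <- function(feature_names, data, outcomes, k, seed = 1) {
  y <- as.integer(.as_logical01(outcomes))
  n <- length(y)
  if (k < 2 || k > n) stop("k must lie in [2, n]", call. = FALSE)
  set.seed(seed)
  folds <- .stratified_folds(y, k)
  preds <- rep(NA_real_, n)
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test)) next
    if (length(unique(y[!test])) < 2) {
      stop("training fold lacking an outcome class; reduce k", call. = FALSE)
    }
    fit <- fit_logistic_ml(data[!test, feature_names, drop = FALSE],
                           y[!test])
    p <- stats::predict(fit$fit,
                        newdata = data[test, feature_names, drop = FALSE],
                        type = "response")
    preds[test] <- p
    if (length(unique(y[test])) == 2) {
      fold_auc[f] <- roc_auc(p, y[test])
    }
  }
  if (all(is.na(fold_auc))) roc_auc(preds, y) else mean(fold_auc,
                                                        na.rm = TRUE)
}

#' Likelihood-ratio test for an added feature
#'
#' Chi-square test on twice the log-likelihood difference between nested
#' fits, with degrees of freedom equal to the parameter-count difference.
#'
#' @param base_fit,augmented_fit Nested `icb_model_fit` objects on the same
#'   subjects (base features must be a subset of the augmented ones).
#' @return p-value.
#' @export
lr_test_add_feature <- function(base_fit, augmented_fit) {
  stopifnot(inherits(base_fit, "icb_model_fit"),
            inherits(augmented_fit, "icb_model_fit"))
  if (base_fit$n != augmented_fit$n ||
      !all(base_fit$features %in% augmented_fit$features)) {
    stop("models are not nested on identical subjects", call. = FALSE)
  }
  df <- length(augmented_fit$features) - length(base_fit$features)
  if (df <= 0) stop("augmented model adds no parameters", call. = FALSE)
  lr <- 2 * (augmented_fit$loglik - base_fit$loglik)
  stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
}

#' Label-permutation empiric p-value for model AUC
#'
#' Permutes the outcome labels (preserving the class counts exactly),
#' refits the model with fixed features on each permuted outcome, and
#' reports the add-one-corrected empiric p-value
#' `(1 + #{AUC_perm >= AUC_obs}) / (1 + n_perm)` for the in-sample AUC and
#' (optionally) the cross-validated AUC. Permuting the phenotype rather
#' than the predictors preserves the inter-predictor correlation
#' structure.
#'
#' @param feature_names Model features.
#' @param data Data frame of predictors.
#' @param outcomes Binary outcomes.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @param cv_k Folds for the cross-validated AUC; `NULL` skips the CV
#'   component.
#' @return List with `auc`, `empiric_p`, and when `cv_k` is given
#'   `cv_auc`, `cv_empiric_p`.
#' @export
permutation_auc_p <- function(feature_names, data, outcomes, n_perm = 999,
                              seed = 1, cv_k = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  y <- as.integer(.as_logical01(outcomes))
  obs_fit <- fit_logistic_ml(data[, feature_names, drop = FALSE], y)
  obs_auc <- obs_fit$auc
  obs_cv <- if (!is.null(cv_k)) {
    kfold_cv_auc(feature_names, data, y, cv_k, seed = seed)
  } else NULL
  set.seed(seed)
  ge_auc <- 0L
  ge_cv <- 0L
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    fit_b <- fit_logistic_ml(data[, feature_names, drop = FALSE], yp)
    if (fit_b$auc >= obs_auc) ge_auc <- ge_auc + 1L
    if (!is.null(cv_k)) {
      cv_b <- kfold_cv_auc(feature_names, data, yp, cv_k, seed = seed + b)
      if (cv_b >= obs_cv) ge_cv <- ge_cv + 1L
    }
  }
  out <- list(auc = obs_auc, empiric_p = (1 + ge_auc) / (1 + n_perm))
  if (!is.null(cv_k)) {
    out$cv_auc <- obs_cv
    out$cv_empiric_p <- (1 + ge_cv) / (1 + n_perm)
  }
  out
}

#' Survival stratified by model score
#'
#' Splits the cohort at the median of the fitted model probabilities (ties
#' at the median go low, per [median_split()]) and compares the survival of
#' the high- and low-score halves by Kaplan-Meier log-rank for both
#' overall and progression-free survival.
#'
#' @param fit An `icb_model_fit`.
#' @param data Data frame of the model features for the same subjects.
#' @param survival_df Data frame with `os_months`, `os_event`,
#'   `pfs_months`, `pfs_event` aligned with `data`.
#' @return List with `score`, `score_group`, `os` and `pfs` (each a
#'   [km_logrank()] result).
#' @export
stratify_by_model_score <- function(fit, data, survival_df) {
  stopifnot(inherits(fit, "icb_model_fit"))
  score <- stats::predict(fit$fit,
                          newdata = data[, fit$features, drop = FALSE],
                          type = "response")
  grp <- median_split(score)
  if (any(table(grp) < 2)) {
    stop("a score group has fewer than 2 subjects", call. = FALSE)
  }
  list(
    score = score, score_group = grp,
    os = km_logrank(survival_df$os_months, survival_df$os_event, grp),
    pfs = km_logrank(survival_df$pfs_months, survival_df$pfs_event, grp)
  )
}

#' Assemble the per-patient modeling feature table
#'
#' Joins the whole-exome scalar features with clinical covariates and,
#' when expression is present, the MHC-I and MHC-II ssGSEA scores computed
#' on the renormalized, low-expression-filtered TPM matrix. LDH is also
#' dichotomized at 247 U/l (`ldh_high`). This is the default candidate
#' pool for [forward_select()].
#'
#' @param bundle A [cohort_bundle()].
#' @param ldh_cut LDH dichotomization threshold in U/l (default 247, the
#'   cohort median the analysis is anchored to).
#' @return Data frame, one row per patient with genomics data.
#' @export
cohort_features <- function(bundle, ldh_cut = 247) {
  feats <- genomic_features(bundle)
  cl <- bundle$clinical[match(feats$patient_id, bundle$clinical$patient_id),
                        , drop = FALSE]
  feats$prior_ipilimumab <- cl$prior_ipilimumab
  feats$lymph_node_met <- as.integer(cl$lymph_node_met)
  feats$ldh_u_per_l <- cl$ldh_u_per_l
  feats$ldh_high <- as.integer(cl$ldh_u_per_l > ldh_cut)
  feats$best_response <- cl$best_response
  feats$pd <- as.integer(cl$best_response == "PD")
  feats$os_months <- cl$os_months
  feats$os_event <- cl$os_event
  feats$pfs_months <- cl$pfs_months
  feats$pfs_event <- cl$pfs_event
  if (!is.null(bundle$expression)) {
    expr <- renormalize_tpm(bundle$expression, bundle$biotype)
    expr <- filter_low_expression(expr)
    mhc <- mhc_gene_sets()
    s2 <- ssgsea(expr, mhc$MHC_II)
    s1 <- ssgsea(expr, mhc$MHC_I)
    feats$mhc2_ssgsea <- unname(s2[feats$patient_id])
    feats$mhc1_ssgsea <- unname(s1[feats$patient_id])
  }
  feats
}
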